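# Read recruitment: alignment of reads to reference sequences, hit
# filtering by aligned length and identity, alignment import from external
# mappers, and per-position coverage profiles.

#' Recruitment parameters
#'
#' @param min_hit_len_dna minimum aligned length (bp, exclusive) for DNA
#'   (metagenome) hits; default 100, i.e. hits longer than 100 bp are
#'   retained.
#' @param min_hit_len_rna minimum aligned length for RNA
#'   (metatranscriptome) hits; default 200.
#' @param min_identity minimum percent identity (default 70, the floor of
#'   the recruitment-spectrum range).
#' @param seed_kmer exact-seed k-mer length of the built-in aligner
#'   (default 15).
#' @param best_hit_only keep at most one hit per read, the highest-scoring
#'   one (ties broken by lexicographically smallest reference id).
#' @param min_ref_len reference length threshold (bp, exclusive) for
#'   [filter_references()]; default 5000 so only contigs larger than 5 kbp
#'   are analyzed.
#' @param match,mismatch,gap_open,gap_extend alignment scores: match +1,
#'   mismatch -2, affine gaps costing `gap_open + L * gap_extend` for a
#'   gap of length L (defaults 5 / 2).
#' @param band,pad seed-diagonal grouping band and reference-window pad of
#'   the seed-and-extend stage.
#' @return a list of class `"recruitment_params"`.
#' @export
recruitment_params <- function(min_hit_len_dna = 100L, min_hit_len_rna = 200L,
                               min_identity = 70, seed_kmer = 15L,
                               best_hit_only = TRUE, min_ref_len = 5000L,
                               match = 1L, mismatch = -2L,
                               gap_open = 5L, gap_extend = 2L,
                               band = 32L, pad = 40L) {
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must lie in [0, 100]")
  if (min_hit_len_dna < seed_kmer || min_hit_len_rna < seed_kmer)
    stop("minimum hit lengths must be >= seed_kmer")
  structure(list(min_hit_len_dna = as.integer(min_hit_len_dna),
                 min_hit_len_rna = as.integer(min_hit_len_rna),
                 min_identity = min_identity,
                 seed_kmer = as.integer(seed_kmer),
                 best_hit_only = isTRUE(best_hit_only),
                 min_ref_len = as.integer(min_ref_len),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band = as.integer(band), pad = as.integer(pad)),
            class = "recruitment_params")
}

#' Drop references at or below a length threshold
#'
#' Only sequences strictly longer than `min_ref_len` are retained (so the
#' default keeps contigs larger than 5 kbp); input order is preserved.
#'
#' @param sequences named character vector of reference sequences.
#' @param min_ref_len length threshold in bp (exclusive).
#' @return the retained sequences; a warning (not an error) if none
#'   remain.
#' @export
filter_references <- function(sequences, min_ref_len = 5000L) {
  keep <- nchar(sequences) > min_ref_len
  out <- sequences[keep]
  if (length(sequences) && !length(out))
    warning("no references longer than ", min_ref_len, " bp")
  out
}

#' Align reads to references with the built-in seed-and-extend aligner
#'
#' Exact k-mer seeds are grouped by diagonal and extended by full
#' affine-gap Smith-Waterman within a reference window around the seeded
#' diagonals; both strands are searched.  Percent identity counts gap
#' columns as non-matches.  Reported hits satisfy the aligned-length
#' (strictly longer than the molecule's minimum) and identity filters; if
#' `best_hit_only`, at most one hit per read is kept.
#'
#' @param reads named character vector of reads.
#' @param refs named character vector of references.
#' @param params a [recruitment_params()].
#' @param molecule `"DNA"` or `"RNA"`, selecting the minimum hit length.
#' @return data.frame of hits: `read_id`, `ref_id`, `ref_start`/`ref_end`
#'   (0-based half-open), `read_start`/`read_end` (on the oriented read),
#'   `aligned_length` (alignment columns), `matches`, `percent_identity`,
#'   `score`, `strand`.  The number of reads shorter than the seed k-mer
#'   (skipped) is in attribute `"n_too_short"`.
#' @export
align_reads <- function(reads, refs, params = recruitment_params(),
                        molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!length(refs)) stop("refs must be nonempty")
  min_len <- if (molecule == "DNA") params$min_hit_len_dna else params$min_hit_len_rna
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  if (is.null(names(refs))) stop("refs must be named")
  res <- cpp_align_reads(unname(reads), names(reads), unname(refs), names(refs),
                         params$seed_kmer, params$min_identity, min_len,
                         params$best_hit_only, params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         params$band, params$pad)
  hits <- res$hits
  attr(hits, "n_too_short") <- res$n_too_short
  hits
}

#' Import alignments produced by an external mapper
#'
#' Supports SAM and the 12-column tabular format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore).  Coordinates are normalized to
#' 0-based half-open reference intervals and reverse-strand hits flagged.
#' Tabular identities are taken as given; SAM identities are recomputed
#' from the CIGAR string and the `NM` tag (gap columns count as
#' non-matches).
#'
#' @param path alignment file.
#' @param dialect `"tabular"` or `"sam"`.
#' @return data.frame of hits in the [align_reads()] layout (without
#'   scores for SAM records lacking `AS`).
#' @export
import_alignments <- function(path, dialect = c("tabular", "sam")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    nf <- count.fields(path, sep = "\t", comment.char = "#")
    if (!length(nf))
      return(data.frame(read_id = character(0), ref_id = character(0),
                        ref_start = integer(0), ref_end = integer(0),
                        aligned_length = integer(0), matches = numeric(0),
                        percent_identity = numeric(0), score = numeric(0),
                        strand = character(0), stringsAsFactors = FALSE))
    bad <- which(nf != 12)
    if (length(bad))
      stop("malformed tabular alignment line ", bad[1], " in ", path,
           " (expected 12 fields, got ", nf[bad[1]], ")")
    tb <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE,
                     col.names = c("query", "subject", "pident", "length",
                                   "mismatch", "gapopen", "qstart", "qend",
                                   "sstart", "send", "evalue", "bitscore"))
    rev <- tb$sstart > tb$send
    ref_start <- ifelse(rev, tb$send - 1L, tb$sstart - 1L)
    ref_end <- ifelse(rev, tb$sstart, tb$send)
    data.frame(read_id = tb$query, ref_id = tb$subject,
               ref_start = as.integer(ref_start),
               ref_end = as.integer(ref_end),
               aligned_length = as.integer(tb$length),
               matches = round(tb$pident / 100 * tb$length),
               percent_identity = tb$pident,
               score = tb$bitscore,
               strand = ifelse(rev, "-", "+"),
               stringsAsFactors = FALSE)
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "strand", "flag"),
      tag = c("NM", "AS"))
    rec <- Rsamtools::scanBam(bam, param = p)[[1]]
    mapped <- !is.na(rec$pos)
    if (!any(mapped))
      return(data.frame(read_id = character(0), ref_id = character(0),
                        ref_start = integer(0), ref_end = integer(0),
                        aligned_length = integer(0), matches = numeric(0),
                        percent_identity = numeric(0), score = numeric(0),
                        strand = character(0), stringsAsFactors = FALSE))
    cig <- rec$cigar[mapped]
    ops <- lapply(cig, function(cg) {
      len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
      op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
      setNames(tapply(len, op, sum), NULL)
      tapply(len, op, sum)
    })
    opsum <- function(o, keys) sum(o[names(o) %in% keys])
    ref_span <- vapply(ops, opsum, numeric(1), keys = c("M", "D", "N", "=", "X"))
    n_M <- vapply(ops, opsum, numeric(1), keys = c("M", "=", "X"))
    n_I <- vapply(ops, opsum, numeric(1), keys = "I")
    n_D <- vapply(ops, opsum, numeric(1), keys = "D")
    nm <- rec$tag$NM[mapped]
    if (is.null(nm) || all(is.na(nm)))
      stop("SAM records lack the NM tag needed to recompute identity")
    mismatches <- pmax(0, nm - n_I - n_D)
    matches <- n_M - mismatches
    cols <- n_M + n_I + n_D
    score <- rec$tag$AS[mapped] %||% rep(NA_real_, sum(mapped))
    data.frame(read_id = rec$qname[mapped],
               ref_id = as.character(rec$rname[mapped]),
               ref_start = rec$pos[mapped] - 1L,
               ref_end = rec$pos[mapped] - 1L + as.integer(ref_span),
               aligned_length = as.integer(cols),
               matches = matches,
               percent_identity = 100 * matches / cols,
               score = as.numeric(score),
               strand = as.character(rec$strand[mapped]),
               stringsAsFactors = FALSE)
  }
}

#' Per-position coverage of one reference in one sample
#'
#' `depth[p]` is the number of hits whose reference interval
#' `[ref_start, ref_end)` contains position `p` (0-based).
#'
#' @param hits hits data.frame ([align_reads()] layout).
#' @param ref_id reference identifier.
#' @param ref_length reference length in bp.
#' @param sample_id optional sample label stored on the profile.
#' @return an object of class `"coverage_profile"`: list with `ref_id`,
#'   `sample_id`, `depth` (integer vector of length `ref_length`).
#' @export
compute_coverage <- function(hits, ref_id, ref_length, sample_id = NA_character_) {
  h <- hits[hits$ref_id == ref_id, , drop = FALSE]
  if (nrow(h) &&
      (any(h$ref_start < 0) || any(h$ref_end > ref_length) ||
       any(h$ref_start >= h$ref_end)))
    stop("hit outside reference bounds for ", ref_id)
  delta <- integer(ref_length + 1L)
  if (nrow(h)) {
    starts <- tabulate(h$ref_start + 1L, nbins = ref_length)
    ends <- tabulate(h$ref_end + 1L, nbins = ref_length + 1L)
    delta <- c(starts, 0L) - ends
  }
  depth <- cumsum(delta[seq_len(ref_length)])
  structure(list(ref_id = ref_id, sample_id = sample_id,
                 depth = as.integer(depth)),
            class = "coverage_profile")
}
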