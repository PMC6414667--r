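# Marker-gene read partitioning: a position-specific scoring matrix
# (PSSM) built from curated marker proteins (psbA / PS-II D1, Gp23),
# empirical null calibration of the score threshold, six-frame read
# search, nearest-reference group assignment, and the derived expression
# fractions, viral:host ratio and infected-fraction estimate.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a position-specific profile from aligned marker proteins
#'
#' Per-column log-odds scores `log2(((count + 0.5) / (N + 10)) /
#' background)` with pseudocount 0.5 and a uniform 1/20 background;
#' columns with more than 50% gaps are dropped.  The references
#' (restricted to the kept columns, sorted by id) are stored on the
#' profile for nearest-reference assignment.
#'
#' @param refs a [make_marker_refs()] set, or a named character vector of
#'   aligned, equal-length protein sequences.
#' @param groups named character vector of group labels (required when
#'   `refs` is a bare vector).
#' @param pseudocount count pseudocount (default 0.5).
#' @param background residue background frequency (default uniform 1/20).
#' @param max_gap_frac gap fraction above which a column is dropped
#'   (default 0.5).
#' @return an object of class `"marker_profile"`: `pssm` (20 x C matrix,
#'   rows in alphabetical one-letter order), `kept_cols`, `ref_cols`
#'   (references at the kept columns), `groups`, `threshold` (NULL until
#'   calibrated).
#' @export
build_profile <- function(refs, groups = NULL, pseudocount = 0.5,
                          background = 1 / 20, max_gap_frac = 0.5) {
  if (inherits(refs, "marker_ref_set")) {
    groups <- refs$groups
    refs <- refs$proteins
  }
  if (is.null(groups) || is.null(names(refs)))
    stop("refs must be named and groups supplied")
  if (length(refs) < 5) stop("at least 5 aligned reference sequences required")
  w <- nchar(refs)
  if (length(unique(w)) != 1)
    stop("reference sequences are not aligned (unequal lengths)")
  N <- length(refs)
  mat <- do.call(rbind, strsplit(unname(refs), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  kept <- which(gap_frac <= max_gap_frac)
  if (!length(kept)) stop("all columns exceed the gap fraction limit")
  pssm <- matrix(0, 20, length(kept),
                 dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_along(kept)) {
    col <- mat[, kept[j]]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    pssm[, j] <- log2(((as.numeric(cnt) + pseudocount) /
                         (N + 20 * pseudocount)) / background)
  }
  ord <- order(names(refs))
  ref_cols <- vapply(ord, function(i) paste(mat[i, kept], collapse = ""),
                     character(1))
  names(ref_cols) <- names(refs)[ord]
  structure(list(pssm = pssm, kept_cols = kept, ref_cols = ref_cols,
                 groups = groups[names(ref_cols)], threshold = NULL),
            class = "marker_profile")
}

#' Calibrate the profile score threshold on an empirical null
#'
#' The threshold is the `(1 - target_fpr)` quantile of the best-frame
#' profile scores of `n_null` random reads drawn from uniform nucleotide
#' background at the configured read length, so that a random read passes
#' with probability about `target_fpr`.
#'
#' @param profile a [build_profile()] profile.
#' @param n_null number of null reads (default 10000).
#' @param target_fpr target false-positive rate (default 1e-3).
#' @param read_length null read length in bp (default 250).
#' @param seed integer seed (deterministic threshold).
#' @param min_seg minimum translated segment length in codons (default 10).
#' @return the score threshold (also usable via
#'   `profile$threshold <- calibrate_threshold(...)`).
#' @export
calibrate_threshold <- function(profile, n_null = 10000L, target_fpr = 1e-3,
                                read_length = 250L, seed = 1L, min_seg = 10L) {
  stopifnot(inherits(profile, "marker_profile"))
  with_seed(seed, {
    nulls <- vapply(seq_len(n_null), function(i) random_dna(read_length),
                    character(1))
    sc <- cpp_marker_scan(nulls, profile$pssm, min_seg)$score
    quantile(sc, probs = 1 - target_fpr, type = 1, names = FALSE)
  })
}

#' Search reads against a marker profile
#'
#' Each read is translated in all six frames; stop codons break the
#' translation into segments, and every segment of at least `min_seg`
#' residues is scanned ungapped across all profile placements.  The
#' best-scoring placement is retained iff its score reaches the
#' threshold.
#'
#' @param reads named character vector of reads (nucleotide).
#' @param profile a [build_profile()] profile.
#' @param threshold score threshold from [calibrate_threshold()].
#' @param min_seg minimum segment length in codons (default 10); reads
#'   shorter than `3 * min_seg` bp are skipped and counted in the
#'   `"n_skipped"` attribute.
#' @return data.frame of candidates: `read_id`, `score`, `frame` (1--6;
#'   4--6 are reverse-complement frames), `offset` (0-based profile
#'   column), `seg_len`, `segment`.
#' @export
search_reads <- function(reads, profile, threshold = profile$threshold,
                         min_seg = 10L) {
  stopifnot(inherits(profile, "marker_profile"))
  if (is.null(threshold)) stop("profile threshold not calibrated")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  short <- nchar(reads) < 3L * min_seg
  rd <- reads[!short]
  if (!length(rd)) {
    out <- data.frame(read_id = character(0), score = numeric(0),
                      frame = integer(0), offset = integer(0),
                      seg_len = integer(0), segment = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- sum(short)
    return(out)
  }
  sc <- cpp_marker_scan(unname(rd), profile$pssm, min_seg)
  pass <- is.finite(sc$score) & sc$score >= threshold
  out <- data.frame(read_id = names(rd)[pass], score = sc$score[pass],
                    frame = sc$frame[pass], offset = sc$offset[pass],
                    seg_len = sc$seg_len[pass],
                    segment = as.character(sc$segment)[pass],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(short)
  out
}

#' Assign one profile-matched candidate to its nearest reference group
#'
#' The translated segment is compared, ungapped and at the profile
#' placement's columns, to every reference; the assigned group is the
#' group of the highest-identity reference (ties broken by higher
#' profile-region coverage, then lexicographically smallest reference
#' id).
#'
#' @param segment translated candidate segment (character scalar).
#' @param offset 0-based profile column of the placement.
#' @param profile a [build_profile()] profile.
#' @return list with `group`, `nearest_ref`, `identity` (percent).
#' @export
assign_group <- function(segment, offset, profile) {
  m <- nchar(segment)
  seg <- strsplit(segment, "", fixed = TRUE)[[1]]
  best <- NULL; bid <- -1; bcov <- -1
  for (r in names(profile$ref_cols)) {
    rseg <- strsplit(substr(profile$ref_cols[[r]], offset + 1, offset + m),
                     "", fixed = TRUE)[[1]]
    id <- sum(rseg == seg) / m
    cov <- sum(rseg != "-")
    if (id > bid || (id == bid && cov > bcov)) { bid <- id; bcov <- cov; best <- r }
  }
  list(group = unname(profile$groups[best]), nearest_ref = best,
       identity = 100 * bid)
}

#' Classify a batch of reads into marker-gene groups
#'
#' [search_reads()] plus nearest-reference assignment for every passing
#' candidate (batch implementation; agrees with [assign_group()]).
#'
#' @inheritParams search_reads
#' @return data.frame: `read_id`, `sample_id` (NA), `score`, `frame`,
#'   `offset`, `group`, `nearest_ref`, `identity`.
#' @export
classify_marker_reads <- function(reads, profile, threshold = profile$threshold,
                                  min_seg = 10L) {
  cand <- search_reads(reads, profile, threshold, min_seg)
  if (!nrow(cand)) {
    out <- cbind(cand[, c("read_id", "score", "frame", "offset")],
                 data.frame(group = character(0), nearest_ref = character(0),
                            identity = numeric(0), stringsAsFactors = FALSE))
    attr(out, "n_skipped") <- attr(cand, "n_skipped")
    return(out)
  }
  asg <- cpp_assign_nearest(cand$segment, cand$offset,
                            unname(profile$ref_cols))
  out <- data.frame(read_id = cand$read_id, score = cand$score,
                    frame = cand$frame, offset = cand$offset,
                    group = unname(profile$groups[asg$ref]),
                    nearest_ref = names(profile$ref_cols)[asg$ref],
                    identity = asg$identity, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- attr(cand, "n_skipped")
  out
}

#' Partition marker-gene assignments into group fractions and ratios
#'
#' Counts reads by group and derives, over the cyanobacterial +
#' cyanophage total: per-group fractions, the T4-like fraction, the
#' viral fraction (T4-like + T7-like), the viral:host ratio (T4-like
#' count over the two cyanobacterial groups, flagged undefined when the
#' host count is 0; a second ratio including T7-like is also reported)
#' and the infected-fraction estimate `r / (r + alpha)`.
#'
#' @param assignments a [classify_marker_reads()] data.frame, or a named
#'   integer vector of per-group counts.
#' @param sample_id sample label.
#' @param alpha relative per-cell expression assumption (default 1).
#' @param host_groups,viral_t4,viral_t7 group labels making up the
#'   partition.
#' @return an object of class `"partition_result"`: list with `sample_id`,
#'   `counts`, `fractions`, `t4_fraction`, `viral_fraction`,
#'   `viral_host_ratio`, `viral_host_ratio_all`,
#'   `infected_fraction_estimate`, `flagged` (character vector of
#'   conditions such as `"no_assignments"` or `"host_zero"`).
#' @export
partition <- function(assignments, sample_id = NA_character_, alpha = 1,
                      host_groups = c("cyano_synechococcus", "cyano_prochlorococcus"),
                      viral_t4 = "T4like", viral_t7 = "T7like") {
  all_groups <- c(host_groups, viral_t4, viral_t7)
  if (is.data.frame(assignments)) {
    counts <- table(factor(assignments$group, levels = all_groups))
  } else {
    counts <- assignments[all_groups]
    counts[is.na(counts)] <- 0
    names(counts) <- all_groups
  }
  counts <- setNames(as.numeric(counts), all_groups)
  tot <- sum(counts)
  flagged <- character(0)
  if (tot == 0) flagged <- c(flagged, "no_assignments")
  fractions <- if (tot > 0) counts / tot else counts
  host <- sum(counts[host_groups])
  t4 <- counts[[viral_t4]]; t7 <- counts[[viral_t7]]
  if (host == 0 && tot > 0) flagged <- c(flagged, "host_zero")
  ratio <- if (host > 0) t4 / host else NA_real_
  ratio_all <- if (host > 0) (t4 + t7) / host else NA_real_
  structure(list(sample_id = sample_id, counts = counts,
                 fractions = fractions,
                 t4_fraction = if (tot > 0) t4 / tot else 0,
                 viral_fraction = if (tot > 0) (t4 + t7) / tot else 0,
                 viral_host_ratio = ratio,
                 viral_host_ratio_all = ratio_all,
                 infected_fraction_estimate =
                   if (!is.na(ratio)) infected_fraction(ratio, alpha) else NA_real_,
                 flagged = flagged),
            class = "partition_result")
}

#' Infected-fraction estimate from the viral:host expression ratio
#'
#' Under the assumption that per-cell marker expression in infected cells
#' is `alpha` times that in uninfected cells, an observed viral:host
#' transcript ratio `r` implies an infected fraction `I = r / (r +
#' alpha)`; monotone increasing in `r`, with `I = 0.5` exactly when
#' `r = alpha`.
#'
#' @param r viral:host marker transcript ratio (>= 0).
#' @param alpha relative per-infected-cell expression (> 0, default 1).
#' @return infected fraction in \[0, 1\].
#' @export
infected_fraction <- function(r, alpha = 1) {
  if (any(r < 0, na.rm = TRUE)) stop("ratio must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  r / (r + alpha)
}

#' Partition Gp23 (major capsid) reads into cyanophage vs. heterophage
#'
#' Same profile / nearest-reference machinery as for psbA, applied to a
#' Gp23 reference set labelled `cyanophage` / `heterophage`.
#'
#' @param reads named character vector of reads.
#' @param gp23_refs a [make_marker_refs()] set (or profile inputs) with
#'   groups `cyanophage` and `heterophage`.
#' @param threshold optional precalibrated threshold; when NULL,
#'   [calibrate_threshold()] is run with `seed`.
#' @param seed calibration seed.
#' @param sample_id sample label.
#' @param ... passed to [calibrate_threshold()].
#' @return list with `sample_id`, `counts`, `fractions` (over the two
#'   groups) and `flagged` (`"no_assignments"` for an empty result).
#' @export
gp23_partition <- function(reads, gp23_refs, threshold = NULL, seed = 1L,
                           sample_id = NA_character_, ...) {
  profile <- if (inherits(gp23_refs, "marker_profile")) gp23_refs
             else build_profile(gp23_refs)
  if (!all(c("cyanophage", "heterophage") %in% profile$groups))
    stop("Gp23 reference set must carry cyanophage and heterophage labels")
  if (is.null(threshold))
    threshold <- calibrate_threshold(profile, seed = seed, ...)
  asg <- classify_marker_reads(reads, profile, threshold)
  counts <- table(factor(asg$group, levels = c("cyanophage", "heterophage")))
  counts <- setNames(as.numeric(counts), c("cyanophage", "heterophage"))
  tot <- sum(counts)
  list(sample_id = sample_id, counts = counts,
       fractions = if (tot > 0) counts / tot else counts,
       flagged = if (tot == 0) "no_assignments" else character(0))
}
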