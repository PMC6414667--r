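# Synthetic host + phage communities with controlled microdiversity and
# full ground truth.  The generator emulates the sampling design of a
# multi-site, multi-date survey (3 sites x 4 dates x {DNA, RNA} by
# default), viral populations whose variants form clonal clouds, genomic
# continua, or two discrete clouds, conserved high-identity sub-regions
# ("islands") within otherwise divergent genomes, marker genes (psbA-like,
# Gp23-like) carried by hosts and phages, and infection states that drive
# viral transcript production.

#' Describe a synthetic viral or host population
#'
#' A population is a set of genome variants derived from a common random
#' ancestor by i.i.d. substitution.  The `cloud_model` controls the
#' divergence structure observed when reads simulated from the population
#' are recruited back to the ancestor:
#' \describe{
#'   \item{single}{one variant identical to the ancestor.}
#'   \item{clonal}{variants within 0--2% of the ancestor (recruitment
#'     concentrates at 98--100% identity).}
#'   \item{continuum}{variant divergences drawn uniformly across 0--20%
#'     (recruitment spread over a broad identity range).}
#'   \item{two_cloud}{one set of variants at <= 2% and one within the
#'     8--15% divergence range (discrete clouds separated by an identity
#'     gap).  The far cloud is drawn at 11--15% by default so that the
#'     defining recruitment discontinuity below ~95% identity survives
#'     the per-read binomial identity spread of 200--250 bp reads; at
#'     smaller far-cloud divergences the two clouds' read-level identity
#'     distributions merge into an apparent continuum.}
#' }
#'
#' @param name population identifier.
#' @param kind `"viral"` or `"host"`.
#' @param cloud_model one of `"single"`, `"clonal"`, `"continuum"`,
#'   `"two_cloud"`.
#' @param ancestor_length genome length in bp (>= 1000).
#' @param n_variants number of variants (>= 1).
#' @param divergence_params optional list overriding the per-model
#'   substitution fractions: `max_div` (clonal, default 0.02), `min_div` /
#'   `max_div` (continuum, defaults 0 / 0.20), `near` / `far` (two_cloud,
#'   defaults `c(0, 0.02)` / `c(0.11, 0.15)`).  All fractions must lie in
#'   \[0, 0.30\].
#' @param conserved_islands optional data.frame (or 2-column matrix) with
#'   columns `start`, `length` giving 0-based intervals exempt from
#'   divergence; intervals must lie within the genome and not overlap.
#' @param marker_genes optional data.frame with columns `gene`, `group`,
#'   `position` (0-based insert position) naming marker genes to embed.
#' @return an object of class `"population_spec"`.
#' @export
population_spec <- function(name, kind = c("viral", "host"),
                            cloud_model = c("clonal", "continuum", "two_cloud", "single"),
                            ancestor_length = 20000L, n_variants = 10L,
                            divergence_params = list(),
                            conserved_islands = NULL, marker_genes = NULL) {
  kind <- match.arg(kind)
  if (length(cloud_model) != 1L || !cloud_model %in% c("clonal", "continuum", "two_cloud", "single"))
    stop("unknown cloud model: ", paste(cloud_model, collapse = ", "))
  if (ancestor_length < 1000) stop("ancestor_length must be >= 1000")
  if (n_variants < 1) stop("n_variants must be >= 1")
  dp <- switch(cloud_model,
    single = list(),
    clonal = list(max_div = 0.02),
    continuum = list(min_div = 0, max_div = 0.20),
    two_cloud = list(near = c(0, 0.02), far = c(0.11, 0.15)))
  dp[names(divergence_params)] <- divergence_params
  fr <- unlist(dp)
  if (length(fr) && (any(fr < 0) || any(fr > 0.30)))
    stop("divergence fractions must lie in [0, 0.30]")
  if (!is.null(conserved_islands)) {
    conserved_islands <- as.data.frame(conserved_islands)
    names(conserved_islands)[1:2] <- c("start", "length")
    ivl <- conserved_islands[order(conserved_islands$start), , drop = FALSE]
    if (any(ivl$start < 0) || any(ivl$start + ivl$length > ancestor_length))
      stop("conserved islands must lie within [0, ancestor_length)")
    if (nrow(ivl) > 1 &&
        any(ivl$start[-1] < (ivl$start + ivl$length)[-nrow(ivl)]))
      stop("conserved islands must not overlap")
    conserved_islands <- ivl
  }
  if (!is.null(marker_genes)) marker_genes <- as.data.frame(marker_genes)
  structure(list(name = name, kind = kind, cloud_model = cloud_model,
                 ancestor_length = as.integer(ancestor_length),
                 n_variants = as.integer(n_variants),
                 divergence_params = dp,
                 conserved_islands = conserved_islands,
                 marker_genes = marker_genes),
            class = "population_spec")
}

#' @noRd
island_positions <- function(islands, L) {
  if (is.null(islands) || nrow(islands) == 0) return(integer())
  unlist(lapply(seq_len(nrow(islands)), function(i) {
    seq.int(islands$start[i] + 1L, islands$start[i] + islands$length[i])
  }))
}

#' @noRd
substitute_bases <- function(chars, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- chars[pos]
  # draw uniformly among the three non-identical bases
  repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
  chars[pos] <- repl
  chars
}

#' Generate the variant genomes of a population
#'
#' Draws a random ancestor, inserts any configured marker genes, then
#' derives `n_variants` genomes by i.i.d. substitution at a per-variant
#' divergence sampled according to the population's cloud model.
#' Conserved islands and marker-gene regions are exempt from divergence,
#' so every variant is identical to the ancestor there.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; identical seeds give identical populations.
#' @param marker_seqs named list of nucleotide sequences for the genes
#'   named in `spec$marker_genes` (see [make_marker_refs()]); gene names
#'   are looked up as `"<gene>:<group>"` then `"<gene>"`.
#' @return an object of class `"population"`: a list with the ancestor,
#'   the named variant sequences, a divergence table (`variant`,
#'   `target_divergence`, `realized_divergence`), the exempt intervals and
#'   the spec.
#' @export
generate_population <- function(spec, seed, marker_seqs = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    L <- spec$ancestor_length
    ancestor <- random_dna(L)
    exempt <- spec$conserved_islands
    marker_regions <- NULL
    if (!is.null(spec$marker_genes) && nrow(spec$marker_genes)) {
      for (i in seq_len(nrow(spec$marker_genes))) {
        mg <- spec$marker_genes[i, ]
        key <- paste0(mg$gene, ":", mg$group)
        seq_i <- marker_seqs[[key]] %||% marker_seqs[[mg$gene]]
        if (is.null(seq_i))
          stop("no marker sequence supplied for gene ", mg$gene)
        ancestor <- insert_marker_gene(ancestor, seq_i, mg$position,
                                       islands = spec$conserved_islands)
        marker_regions <- rbind(marker_regions, data.frame(
          gene = mg$gene, group = mg$group, start = mg$position,
          end = mg$position + nchar(seq_i), stringsAsFactors = FALSE))
        exempt <- rbind(exempt, data.frame(start = mg$position,
                                           length = nchar(seq_i)))
      }
    }
    dp <- spec$divergence_params
    n <- spec$n_variants
    target <- switch(spec$cloud_model,
      single = rep(0, n),
      clonal = runif(n, 0, dp$max_div),
      continuum = runif(n, dp$min_div, dp$max_div),
      two_cloud = {
        n_near <- ceiling(n / 2)
        c(runif(n_near, dp$near[1], dp$near[2]),
          runif(n - n_near, dp$far[1], dp$far[2]))
      })
    anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    fixed <- island_positions(exempt, L)
    mutable <- setdiff(seq_len(L), fixed)
    variants <- character(n)
    realized <- numeric(n)
    for (v in seq_len(n)) {
      n_sub <- min(round(target[v] * L), length(mutable))
      ch <- anc_chars
      if (n_sub > 0) {
        pos <- sample(mutable, n_sub)
        ch <- substitute_bases(ch, pos)
      }
      variants[v] <- paste(ch, collapse = "")
      realized[v] <- sum(ch != anc_chars) / L
    }
    names(variants) <- sprintf("%s_v%02d", spec$name, seq_len(n))
    structure(list(
      name = spec$name, kind = spec$kind, cloud_model = spec$cloud_model,
      ancestor = ancestor, variants = variants,
      divergence = data.frame(variant = names(variants),
                              target_divergence = target,
                              realized_divergence = realized,
                              stringsAsFactors = FALSE),
      islands = spec$conserved_islands, marker_regions = marker_regions,
      spec = spec), class = "population")
  })
}

#' Embed a marker gene into a genome sequence by replacement
#'
#' The marker replaces the stretch starting at `position` (0-based), so
#' genome length and all downstream coordinates are preserved.  The
#' replaced region must not overlap a conserved island.
#'
#' @param sequence genome sequence (character scalar).
#' @param marker marker nucleotide sequence; an empty marker leaves the
#'   sequence unchanged.
#' @param position 0-based start of the replaced region.
#' @param islands optional conserved-island table as in
#'   [population_spec()]; overlap is a configuration error.
#' @return the modified sequence.
#' @export
insert_marker_gene <- function(sequence, marker, position, islands = NULL) {
  ml <- nchar(marker)
  if (ml == 0) return(sequence)
  L <- nchar(sequence)
  if (position < 0 || position + ml > L)
    stop("marker does not fit: position + marker length exceeds sequence length")
  if (!is.null(islands) && nrow(islands)) {
    s <- position; e <- position + ml
    if (any(s < islands$start + islands$length & islands$start < e))
      stop("marker region overlaps a conserved island")
  }
  paste0(substr(sequence, 1, position), marker,
         substr(sequence, position + ml + 1, L))
}

# Inverse codon table for reverse translation (standard code).
#' @noRd
codons_for_aa <- function() {
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aas <- vapply(cods, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd)))
  }, character(1))
  split(cods, aas)
}

#' @noRd
reverse_translate <- function(protein, codon_map) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cods <- vapply(aa, function(a) {
    opts <- codon_map[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste(cods, collapse = "")
}

#' Generate a synthetic curated marker-protein reference set
#'
#' Builds a fully synthetic stand-in for a curated, aligned set of marker
#' proteins (e.g. PS-II D1 / psbA, or the T4-like major capsid protein
#' Gp23) partitioned into labelled taxon groups.  A random ancestral
#' protein is diverged into per-group consensus sequences (inter-group
#' divergence) and then into individual reference sequences (intra-group
#' divergence).  Sequences are ungapped and equal-length, i.e. trivially
#' aligned.  Nucleotide versions (reverse-translated, plus a stop codon)
#' are provided for embedding into genomes and for read simulation.
#'
#' @param groups named integer vector: references per group.  The default
#'   emulates a psbA reference set with two cyanobacterial and two
#'   cyanophage groups.
#' @param length_aa protein length in residues (default 360, the length of
#'   PS-II D1; the nucleotide version is then 1083 bp including the stop).
#' @param inter_divergence substitution fraction between group consensuses
#'   (default 0.05).
#' @param intra_divergence maximum substitution fraction within a group
#'   (default 0.02).
#' @param seed integer seed.
#' @return an object of class `"marker_ref_set"`: `proteins` (named
#'   character), `groups` (named character, reference -> group label),
#'   `ncol` (alignment columns), `nt` (named character, per-reference
#'   nucleotide sequences), `group_nt` (per-group consensus nucleotide
#'   sequence, used for genome embedding).
#' @export
make_marker_refs <- function(groups = c(cyano_synechococcus = 4L,
                                        cyano_prochlorococcus = 4L,
                                        T4like = 4L, T7like = 4L),
                             length_aa = 360L, inter_divergence = 0.05,
                             intra_divergence = 0.02, seed = 1L) {
  aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    anc <- sample(aa_alpha, length_aa, replace = TRUE)
    codon_map <- codons_for_aa()
    mutate_prot <- function(p, n_sub) {
      if (n_sub == 0) return(p)
      pos <- sample(length(p), n_sub)
      p[pos] <- vapply(p[pos], function(a) sample(setdiff(aa_alpha, a), 1L),
                       character(1))
      p
    }
    proteins <- character(0); labels <- character(0)
    group_prot <- list()
    for (g in names(groups)) {
      cons <- mutate_prot(anc, round(inter_divergence * length_aa))
      group_prot[[g]] <- paste(cons, collapse = "")
      for (i in seq_len(groups[[g]])) {
        d <- runif(1, 0, intra_divergence)
        p <- mutate_prot(cons, round(d * length_aa))
        id <- sprintf("%s_ref%02d", g, i)
        proteins[id] <- paste(p, collapse = "")
        labels[id] <- g
      }
    }
    proteins <- proteins[order(names(proteins))]
    labels <- labels[names(proteins)]
    nt <- vapply(proteins, function(p)
      paste0(reverse_translate(p, codon_map), "TAA"), character(1))
    group_nt <- vapply(group_prot, function(p)
      paste0(reverse_translate(p, codon_map), "TAA"), character(1))
    structure(list(proteins = proteins, groups = labels,
                   ncol = length_aa, nt = nt, group_nt = group_nt),
              class = "marker_ref_set")
  })
}

#' Define the sample grid and read-simulation parameters
#'
#' @param sites site identifiers (default the three study-like sites).
#' @param dates date identifiers (default four seasonal dates).
#' @param molecules subset of `c("DNA", "RNA")`.
#' @param n_reads genome-wide reads per sample.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param infected_fraction fraction of host cells infected (scalar or a
#'   host x site_date matrix).  The default 0.545 corresponds, under
#'   `alpha = 1`, to a viral:host marker expression ratio of 1.2.
#' @param alpha per-infected-cell viral marker expression relative to
#'   per-uninfected-cell host marker expression (default 1: equal
#'   per-cell expression).
#' @param n_marker_reads marker-gene reads per RNA sample (0 disables).
#' @param seed master seed; all randomness derives from it.
#' @return an object of class `"sample_design"` with a `samples`
#'   data.frame (`sample_id`, `site`, `date`, `molecule`) and the
#'   simulation parameters.
#' @export
sample_design <- function(sites = c("POLA", "SPOT", "CAT"),
                          dates = c("Jul", "Oct", "Jan", "Apr"),
                          molecules = c("DNA", "RNA"),
                          n_reads = 2000L, read_length = 250L,
                          error_rate = 0.001,
                          infected_fraction = 0.545, alpha = 1,
                          n_marker_reads = 0L, seed = 1L) {
  stopifnot(all(molecules %in% c("DNA", "RNA")), length(molecules) >= 1)
  if (any(infected_fraction < 0) || any(infected_fraction > 1))
    stop("infected_fraction must lie in [0, 1]")
  if (alpha < 0) stop("alpha must be >= 0")
  if (n_reads < 0) stop("n_reads must be >= 0")
  grid <- expand.grid(molecule = molecules, date = dates, site = sites,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(grid$site, grid$date, grid$molecule, sep = "_"),
    site = grid$site, date = grid$date, molecule = grid$molecule,
    stringsAsFactors = FALSE)
  structure(list(sites = sites, dates = dates, molecules = molecules,
                 samples = samples, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 infected_fraction = infected_fraction, alpha = alpha,
                 n_marker_reads = as.integer(n_marker_reads),
                 seed = as.integer(seed)),
            class = "sample_design")
}

#' Assemble a community from population specs
#'
#' @param specs list of [population_spec()] objects.
#' @param seed master seed; each population gets a derived seed.
#' @param host_links named character vector mapping phage population names
#'   to the host population they infect (`NA` for phages whose RNA is not
#'   gated on a host, e.g. heterophage background).
#' @param marker_refs optional [make_marker_refs()] set supplying the
#'   nucleotide sequences of marker genes named in the specs.
#' @return an object of class `"community"`.
#' @export
build_community <- function(specs, seed = 1L, host_links = NULL,
                            marker_refs = NULL) {
  marker_seqs <- NULL
  if (!is.null(marker_refs)) {
    marker_seqs <- as.list(marker_refs$group_nt)
    # allow lookup as "<gene>:<group>" for any gene name
    names(marker_seqs) <- names(marker_refs$group_nt)
  }
  pops <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    ms <- NULL
    if (!is.null(sp$marker_genes) && nrow(sp$marker_genes)) {
      ms <- list()
      for (j in seq_len(nrow(sp$marker_genes))) {
        key <- paste0(sp$marker_genes$gene[j], ":", sp$marker_genes$group[j])
        ms[[key]] <- marker_seqs[[sp$marker_genes$group[j]]]
      }
    }
    generate_population(sp, seed = derive_seed(seed, i), marker_seqs = ms)
  })
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  structure(list(populations = pops, host_links = host_links,
                 marker_refs = marker_refs, seed = seed),
            class = "community")
}

#' @noRd
apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  n_err <- rbinom(length(reads), rl, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample(rl[i], n_err[i])
    ch <- substitute_bases(ch, pos)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' @noRd
draw_reads_from_seqs <- function(seqs, n, read_length, error_rate, prefix) {
  # seqs: named character; one variant drawn uniformly per read
  if (n == 0) return(list(reads = character(0),
                          origin = data.frame(read_id = character(0),
                                              variant = character(0),
                                              stringsAsFactors = FALSE)))
  vi <- sample(length(seqs), n, replace = TRUE)
  L <- nchar(seqs)[vi]
  if (any(L < read_length))
    stop("sequence shorter than read length")
  start <- floor(runif(n) * (L - read_length + 1)) + 1
  rd <- substr(rep(unname(seqs)[vi], 1), start, start + read_length - 1)
  rev <- runif(n) < 0.5
  if (any(rev)) rd[rev] <- revcomp_chr(rd[rev])
  rd <- apply_read_errors(rd, error_rate)
  ids <- sprintf("%s_r%06d", prefix, seq_len(n))
  names(rd) <- ids
  list(reads = rd, origin = data.frame(read_id = ids,
                                       variant = names(seqs)[vi],
                                       stringsAsFactors = FALSE))
}

#' @noRd
infected_fraction_for <- function(design, host, site_date) {
  I <- design$infected_fraction
  if (is.matrix(I)) {
    if (!is.null(host) && host %in% rownames(I) && site_date %in% colnames(I))
      return(I[host, site_date])
    return(0)
  }
  I
}

#' Simulate DNA and RNA reads for every sample of a design
#'
#' DNA reads are drawn from variant genomes in proportion to the
#' population abundances.  RNA reads for a phage are drawn only when its
#' linked host is present in the sample and the infected fraction is
#' positive, reflecting that viral transcripts require an ongoing
#' infection; host populations contribute RNA in proportion to abundance.
#' When `design$n_marker_reads > 0`, each RNA sample additionally receives
#' marker-gene reads whose expected viral fraction is
#' `alpha * I / (alpha * I + (1 - I))` for infected fraction `I`
#' (see [simulate_marker_reads()]).
#'
#' @param community a [build_community()] object.
#' @param design a [sample_design()].
#' @param abundance population x site_date abundance matrix (rownames are
#'   population names, colnames are `"<site>_<date>"`); nonnegative.
#' @return a list with `reads` (per-sample named character vectors),
#'   `marker_reads` (per-RNA-sample, if requested) and `truth` (read
#'   counts per population and sample, per-phage activity flags, expected
#'   viral marker fractions, variant divergences, infection links).
#' @export
simulate_reads <- function(community, design, abundance) {
  stopifnot(inherits(community, "community"), inherits(design, "sample_design"))
  pops <- community$populations
  if (!all(rownames(abundance) %in% names(pops)))
    stop("abundance rows must name community populations")
  samples <- design$samples
  reads <- list(); marker_reads <- list()
  truth_counts <- list(); activity <- list(); marker_truth <- list()
  vmf <- list()
  with_seed(design$seed, {
    for (si in seq_len(nrow(samples))) {
      sm <- samples[si, ]
      site_date <- paste(sm$site, sm$date, sep = "_")
      if (!site_date %in% colnames(abundance))
        stop("abundance has no column for ", site_date)
      ab <- abundance[, site_date]
      names(ab) <- rownames(abundance)
      w <- numeric(length(ab)); names(w) <- names(ab)
      for (p in names(ab)) {
        if (sm$molecule == "DNA" || pops[[p]]$kind == "host") {
          w[p] <- ab[p]
        } else {
          host <- unname(community$host_links[p])
          if (is.null(host) || is.na(host)) {
            w[p] <- ab[p]  # ungated phage RNA (no host link configured)
          } else {
            host_present <- host %in% names(ab) && ab[host] > 0
            I <- infected_fraction_for(design, host, site_date)
            w[p] <- if (host_present && I > 0) ab[p] else 0
          }
        }
      }
      if (design$n_reads > 0 && sum(w) <= 0)
        stop("zero total abundance in sample ", sm$sample_id)
      counts <- if (design$n_reads > 0)
        rmultinom(1, design$n_reads, w)[, 1] else setNames(rep(0L, length(w)), names(w))
      sample_reads <- character(0)
      for (p in names(counts)) {
        if (counts[p] == 0) next
        dr <- draw_reads_from_seqs(pops[[p]]$variants, counts[p],
                                   design$read_length, design$error_rate,
                                   prefix = paste(sm$sample_id, p, sep = "|"))
        sample_reads <- c(sample_reads, dr$reads)
      }
      reads[[sm$sample_id]] <- sample_reads
      truth_counts[[sm$sample_id]] <- data.frame(
        sample_id = sm$sample_id, population = names(counts),
        count = as.integer(counts), row.names = NULL,
        stringsAsFactors = FALSE)
      if (sm$molecule == "RNA") {
        viral <- names(pops)[vapply(pops, `[[`, character(1), "kind") == "viral"]
        activity[[sm$sample_id]] <- data.frame(
          sample_id = sm$sample_id, population = viral,
          active = w[viral] > 0, row.names = NULL, stringsAsFactors = FALSE)
        if (design$n_marker_reads > 0) {
          if (is.null(community$marker_refs))
            stop("marker reads requested but community has no marker_refs")
          I <- infected_fraction_for(design, rownames(abundance)[1], site_date)
          if (!is.matrix(design$infected_fraction)) I <- design$infected_fraction
          mr <- simulate_marker_reads(community$marker_refs,
                                      n_reads = design$n_marker_reads,
                                      infected_fraction = I,
                                      alpha = design$alpha,
                                      read_length = design$read_length,
                                      error_rate = design$error_rate,
                                      seed = NULL,
                                      prefix = sm$sample_id)
          marker_reads[[sm$sample_id]] <- mr$reads
          marker_truth[[sm$sample_id]] <- mr$truth
          vmf[[sm$sample_id]] <- mr$expected_viral_fraction
        }
      }
    }
  })
  truth <- list(
    read_counts = do.call(rbind, truth_counts),
    activity = if (length(activity)) do.call(rbind, activity) else NULL,
    marker_truth = if (length(marker_truth)) do.call(rbind, marker_truth) else NULL,
    expected_viral_marker_fraction = unlist(vmf),
    variant_divergence = do.call(rbind, lapply(pops, `[[`, "divergence")),
    infection_links = community$host_links)
  list(reads = reads, marker_reads = marker_reads, truth = truth)
}

#' Simulate marker-gene reads with a known viral transcript fraction
#'
#' Each read originates from the marker gene of a viral group with
#' probability `alpha * I / (alpha * I + (1 - I))` (the closed-form
#' expected viral marker fraction for infected fraction `I` and relative
#' per-cell expression `alpha`), and from a host group otherwise.  Within
#' the viral and host compartments, groups are weighted by `viral_split` /
#' `host_split`, and the concrete reference sequence within the chosen
#' group is drawn uniformly.
#'
#' @param marker_refs a [make_marker_refs()] set.
#' @param n_reads number of marker reads.
#' @param infected_fraction infected fraction `I` in \[0, 1\].
#' @param alpha relative per-cell expression (default 1).
#' @param viral_split named weights over viral groups (default: T4-like
#'   cyanomyoviruses dominate, T7-like cyanopodoviruses are a minor
#'   contribution, 95:5).
#' @param host_split named weights over host groups (default equal
#'   Synechococcus / Prochlorococcus).
#' @param read_length,error_rate,seed as in [sample_design()].
#' @param prefix read-id prefix.
#' @return list with `reads` (named character), `truth` (read_id, group,
#'   reference of origin) and `expected_viral_fraction`.
#' @export
simulate_marker_reads <- function(marker_refs, n_reads, infected_fraction,
                                  alpha = 1,
                                  viral_split = c(T4like = 0.95, T7like = 0.05),
                                  host_split = c(cyano_synechococcus = 0.5,
                                                 cyano_prochlorococcus = 0.5),
                                  read_length = 250L, error_rate = 0.001,
                                  seed = NULL, prefix = "marker") {
  stopifnot(inherits(marker_refs, "marker_ref_set"))
  I <- infected_fraction
  v <- if (alpha * I + (1 - I) > 0) alpha * I / (alpha * I + (1 - I)) else 0
  with_seed(seed, {
    gw <- c(viral_split / sum(viral_split) * v,
            host_split / sum(host_split) * (1 - v))
    gw <- gw[gw >= 0]
    if (n_reads == 0) {
      return(list(reads = character(0),
                  truth = data.frame(read_id = character(0), group = character(0),
                                     ref = character(0), stringsAsFactors = FALSE),
                  expected_viral_fraction = v))
    }
    grp <- sample(names(gw), n_reads, replace = TRUE, prob = gw)
    refs_by_group <- split(names(marker_refs$groups), marker_refs$groups)
    ref <- character(n_reads)
    for (g in unique(grp)) {
      opts <- refs_by_group[[g]]
      if (is.null(opts)) stop("marker reference set has no group ", g)
      idx <- which(grp == g)
      ref[idx] <- opts[sample.int(length(opts), length(idx), replace = TRUE)]
    }
    nt <- marker_refs$nt[ref]
    L <- nchar(nt)
    if (any(L < read_length))
      stop("marker gene shorter than read length")
    start <- floor(runif(n_reads) * (L - read_length + 1)) + 1
    rd <- substr(unname(nt), start, start + read_length - 1)
    rev <- runif(n_reads) < 0.5
    if (any(rev)) rd[rev] <- revcomp_chr(rd[rev])
    rd <- apply_read_errors(rd, error_rate)
    ids <- sprintf("%s|m%06d", prefix, seq_len(n_reads))
    names(rd) <- ids
    list(reads = rd,
         truth = data.frame(read_id = ids, group = unname(grp),
                            ref = unname(ref), stringsAsFactors = FALSE),
         expected_viral_fraction = v)
  })
}

#' Build a 16S ASV relative-abundance table from a presence map
#'
#' @param design a [sample_design()] (samples of one molecule are rows).
#' @param presence ASV x site_date logical matrix (present / absent).
#' @param abundance optional ASV x site_date nonnegative matrix of raw
#'   abundances; defaults to 1 for every present ASV.  Absent ASVs always
#'   get 0.
#' @param molecule which molecule's samples to tabulate (default both).
#' @return matrix of relative abundances, samples x ASVs; each row sums to
#'   1 except all-absent samples, which stay all-zero and are flagged in
#'   the `"empty_samples"` attribute (with a warning).
#' @export
generate_asv_table <- function(design, presence, abundance = NULL,
                               molecule = design$molecules) {
  stopifnot(is.matrix(presence) || is.data.frame(presence))
  presence <- as.matrix(presence)
  if (is.null(abundance)) abundance <- (presence > 0) * 1
  abundance <- as.matrix(abundance)
  abundance[!(presence > 0)] <- 0
  samples <- design$samples[design$samples$molecule %in% molecule, ]
  out <- matrix(0, nrow(samples), nrow(presence),
                dimnames = list(samples$sample_id, rownames(presence)))
  for (i in seq_len(nrow(samples))) {
    sd <- paste(samples$site[i], samples$date[i], sep = "_")
    if (!sd %in% colnames(abundance))
      stop("presence map has no column for ", sd)
    a <- abundance[, sd]
    tot <- sum(a)
    out[i, ] <- if (tot > 0) a / tot else 0
  }
  empty <- rownames(out)[rowSums(out) == 0]
  if (length(empty))
    warning("all ASVs absent in sample(s): ", paste(empty, collapse = ", "),
            " (left unnormalized)")
  attr(out, "empty_samples") <- empty
  out
}

#' Write reads to a FASTQ file (Phred+33, uniform quality)
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(Biostrings::width(x), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path.
#' @return named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
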