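# Pipeline orchestration: run every stage on a config, write all tabular
# outputs (abundance, normalized heights, dissimilarity, dendrogram,
# persistence, identity spectra, islands, marker partitions, host
# rankings) plus a machine-readable run summary.

#' Demo run configuration
#'
#' A small synthetic-community configuration exercising every pipeline
#' stage: three viral contig populations with different cloud models
#' (clonal, continuum, two-cloud), one Synechococcus-like and one
#' Prochlorococcus-like host carrying psbA marker genes, a T4-like
#' cyanophage carrying the viral psbA, the default 3-site x 4-date x
#' {DNA, RNA} grid, marker reads, and an ASV presence map reproducing a
#' one-host-absent-at-one-site pattern.
#'
#' @param seed master seed.
#' @param n_reads genome-wide reads per sample.
#' @param n_marker_reads marker reads per RNA sample.
#' @return a config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, n_reads = 1500L, n_marker_reads = 2000L) {
  mk <- make_marker_refs(seed = derive_seed(seed, 101))
  specs <- list(
    population_spec("contig01", "viral", "clonal", 8000, 6),
    population_spec("contig02", "viral", "continuum", 8000, 30),
    population_spec("contig03", "viral", "two_cloud", 8000, 12,
                    marker_genes = data.frame(gene = "psbA", group = "T4like",
                                              position = 3000)),
    population_spec("hostSyn", "host", "clonal", 6000, 4,
                    marker_genes = data.frame(gene = "psbA",
                                              group = "cyano_synechococcus",
                                              position = 2000)),
    population_spec("hostPro", "host", "clonal", 6000, 4,
                    marker_genes = data.frame(gene = "psbA",
                                              group = "cyano_prochlorococcus",
                                              position = 2000)))
  design <- sample_design(n_reads = n_reads, n_marker_reads = n_marker_reads,
                          seed = seed)
  site_dates <- unique(paste(design$samples$site, design$samples$date, sep = "_"))
  pops <- c("contig01", "contig02", "contig03", "hostSyn", "hostPro")
  ab <- matrix(0, length(pops), length(site_dates),
               dimnames = list(pops, site_dates))
  ab["hostSyn", ] <- 2
  ab["hostPro", ] <- 2
  ab["hostPro", grep("^POLA", site_dates)] <- 0   # host absent at one site
  ab["contig01", ] <- 3                            # persistent everywhere
  ab["contig02", grep("Oct", site_dates)] <- 3     # one date per site
  ab["contig03", grep("Oct", site_dates)] <- 3
  presence <- rbind(Syn_ASV10 = ab["hostSyn", ] > 0,
                    Pro_ASV4 = ab["hostPro", ] > 0)
  list(seed = as.integer(seed), populations = specs, design = design,
       abundance = ab, host_links = c(contig03 = "hostSyn"),
       marker_refs = mk, asv_presence = presence,
       recruitment = recruitment_params(min_ref_len = 5000L),
       dynamics = dynamics_params(), spectrum = spectrum_params(),
       marker_target_fpr = 1e-3, marker_n_null = 5000L)
}

#' @noRd
config_echo <- function(config) {
  list(seed = config$seed,
       n_populations = length(config$populations),
       populations = vapply(config$populations, `[[`, character(1), "name"),
       sites = config$design$sites, dates = config$design$dates,
       molecules = config$design$molecules,
       n_reads = config$design$n_reads,
       n_marker_reads = config$design$n_marker_reads,
       read_length = config$design$read_length,
       infected_fraction = config$design$infected_fraction,
       alpha = config$design$alpha)
}

#' Run the full recruitment pipeline on a configuration
#'
#' Stages: simulate (community + reads + ASV tables), recruit (alignment
#' and coverage), dynamics (trimmed-coverage abundance, normalized
#' heights, Bray-Curtis dissimilarity, contig clustering, persistence
#' calls), spectrum (identity histograms, population-structure classes,
#' conserved-island reports), markers (psbA partition per RNA sample) and
#' hosts (activity-consistency rankings).  All tables are written as
#' tab-separated files with `#` header comments carrying the tool
#' version, config hash and coordinate convention; a JSON summary echoes
#' the config and seed.  Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config a config list as produced by [demo_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results and the
#'   output file paths.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)
  echo <- config_echo(config)
  echo_path <- file.path(outdir, "run_config.json")
  jsonlite::write_json(echo, echo_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  cfg_hash <- unname(tools::md5sum(echo_path))
  hdr <- c(paste0("phagedyn ", packageVersion("phagedyn")),
           paste0("config_md5 ", cfg_hash),
           "coordinates: 1-based inclusive unless stated otherwise")

  # --- simulate ---
  community <- build_community(config$populations, seed = config$seed,
                               host_links = config$host_links,
                               marker_refs = config$marker_refs)
  design <- config$design
  sim <- simulate_reads(community, design, config$abundance)

  # --- recruit ---
  rp <- config$recruitment %||% recruitment_params()
  viral <- names(community$populations)[vapply(community$populations, `[[`,
                                               character(1), "kind") == "viral"]
  refs <- vapply(community$populations[viral], `[[`, character(1), "ancestor")
  refs <- filter_references(refs, rp$min_ref_len)
  samples <- design$samples
  profiles <- list(); all_hits <- list()
  for (i in seq_len(nrow(samples))) {
    sm <- samples[i, ]
    hits <- align_reads(sim$reads[[sm$sample_id]], refs, rp,
                        molecule = sm$molecule)
    all_hits[[sm$sample_id]] <- hits
    for (r in names(refs)) {
      profiles[[paste(sm$sample_id, r, sep = ".")]] <-
        compute_coverage(hits, r, nchar(refs[[r]]), sample_id = sm$sample_id)
    }
  }

  # --- dynamics ---
  dp <- config$dynamics %||% dynamics_params()
  abm <- abundance_matrix(profiles, dp)
  write_tsv(data.frame(sample_id = rownames(abm), abm, check.names = FALSE),
            file.path(outdir, "abundance_matrix.tsv"), hdr)
  norm <- t(apply(abm, 1, normalize_sample, log_base = dp$log_base,
                  pseudocount = dp$pseudocount))
  dimnames(norm) <- dimnames(abm)
  write_tsv(data.frame(sample_id = rownames(norm), norm, check.names = FALSE),
            file.path(outdir, "normalized_heights.tsv"), hdr)
  for (mol in design$molecules) {
    ids <- samples$sample_id[samples$molecule == mol]
    sub <- abm[ids, , drop = FALSE]
    n <- nrow(sub)
    bc <- matrix(0, n, n, dimnames = list(ids, ids))
    for (a in seq_len(n)) for (b in seq_len(n))
      if (a != b) bc[a, b] <- bray_curtis(sub[a, ], sub[b, ])
    write_tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
              file.path(outdir, paste0("bray_curtis_", mol, ".tsv")), hdr)
  }
  cl <- if (ncol(abm) >= 2) cluster_contigs(abm, dp) else NULL
  if (!is.null(cl)) writeLines(cl$newick, file.path(outdir, "contig_dendrogram.nwk"))

  persistence <- NULL
  if ("RNA" %in% design$molecules) {
    calls <- lapply(colnames(abm), function(r) {
      cov <- matrix(NA_real_, length(design$sites), length(design$dates),
                    dimnames = list(design$sites, design$dates))
      for (s in design$sites) for (d in design$dates)
        cov[s, d] <- abm[paste(s, d, "RNA", sep = "_"), r]
      classify_persistence(cov, dp, ref_id = r)
    })
    persistence <- data.frame(
      ref_id = vapply(calls, `[[`, character(1), "ref_id"),
      global_status = vapply(calls, `[[`, character(1), "global_status"),
      stringsAsFactors = FALSE)
    for (s in design$sites) {
      persistence[[paste0("status_", s)]] <-
        vapply(calls, function(x) x$site_status[[s]], character(1))
      persistence[[paste0("dates_", s)]] <-
        vapply(calls, function(x) x$n_dates_detected[[s]], numeric(1))
    }
    write_tsv(persistence, file.path(outdir, "persistence_calls.tsv"), hdr)
  } else {
    notices <- c(notices, "no RNA samples: persistence stage skipped")
  }

  # --- spectrum ---
  spp <- config$spectrum %||% spectrum_params()
  hist_rows <- list(); class_rows <- list(); island_rows <- list()
  for (r in names(refs)) {
    ref_hits <- do.call(rbind, lapply(all_hits, function(h)
      h[h$ref_id == r, , drop = FALSE]))
    hist <- identity_histogram(ref_hits, ref_id = r, sample_id = "pooled")
    cls <- classify_spectrum(hist, spp)
    hist_rows[[r]] <- cbind(ref_id = r, hist$bins)
    class_rows[[r]] <- data.frame(
      ref_id = r, label = cls$label,
      frac_98_100 = cls$stats$frac_98_100, frac_90_97 = cls$stats$frac_90_97,
      occupied_span = cls$stats$occupied_span, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(samples))) {
      pr <- profiles[[paste(samples$sample_id[i], r, sep = ".")]]
      isl <- detect_islands(pr, all_hits[[samples$sample_id[i]]])
      if (nrow(isl))
        island_rows[[length(island_rows) + 1]] <-
          cbind(sample_id = samples$sample_id[i], isl)
    }
  }
  write_tsv(do.call(rbind, hist_rows),
            file.path(outdir, "identity_histograms.tsv"), hdr)
  write_tsv(do.call(rbind, class_rows),
            file.path(outdir, "spectrum_classes.tsv"), hdr)
  islands <- if (length(island_rows)) do.call(rbind, island_rows) else
    data.frame(sample_id = character(0), ref_id = character(0),
               start = integer(0), end = integer(0),
               island_mean_depth = numeric(0), background_depth = numeric(0),
               enrichment_ratio = numeric(0), median_identity = numeric(0))
  write_tsv(islands, file.path(outdir, "island_reports.tsv"), hdr)

  # --- markers ---
  partitions <- NULL
  if (length(sim$marker_reads)) {
    profile <- build_profile(community$marker_refs)
    thr <- calibrate_threshold(profile,
                               n_null = config$marker_n_null %||% 10000L,
                               target_fpr = config$marker_target_fpr %||% 1e-3,
                               read_length = design$read_length,
                               seed = derive_seed(config$seed, 7))
    part_rows <- lapply(names(sim$marker_reads), function(sid) {
      asg <- classify_marker_reads(sim$marker_reads[[sid]], profile, thr)
      p <- partition(asg, sample_id = sid, alpha = design$alpha)
      data.frame(sample_id = sid, t(p$counts), t4_fraction = p$t4_fraction,
                 viral_fraction = p$viral_fraction,
                 viral_host_ratio = p$viral_host_ratio,
                 infected_fraction_estimate = p$infected_fraction_estimate,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    partitions <- do.call(rbind, part_rows)
    write_tsv(partitions, file.path(outdir, "psba_partition.tsv"), hdr)
  } else {
    notices <- c(notices, "no marker reads: marker partition stage skipped")
  }

  # --- hosts ---
  rankings <- NULL
  if (!is.null(config$asv_presence) && "RNA" %in% design$molecules) {
    asv <- generate_asv_table(design, config$asv_presence, molecule = "RNA")
    write_tsv(data.frame(sample_id = rownames(asv), asv, check.names = FALSE),
              file.path(outdir, "asv_table_rna.tsv"), hdr)
    rna_ids <- samples$sample_id[samples$molecule == "RNA"]
    rank_rows <- list()
    for (ph in names(config$host_links %||% character(0))) {
      if (!ph %in% colnames(abm)) next
      act <- activity_profile(abm[rna_ids, ph], threshold = dp$persistence_cov,
                              phage_id = ph)
      rk <- rank_hosts(act, asv[rna_ids, , drop = FALSE],
                       phage_rna_coverage = abm[rna_ids, ph])
      rank_rows[[ph]] <- cbind(phage = ph, as.data.frame(rk))
    }
    if (length(rank_rows)) {
      rankings <- do.call(rbind, rank_rows)
      rownames(rankings) <- NULL
      write_tsv(rankings, file.path(outdir, "host_rankings.tsv"), hdr)
    }
  } else if (is.null(config$asv_presence)) {
    notices <- c(notices, "no ASV presence map: host matching stage skipped")
  } else {
    notices <- c(notices, "no RNA samples: host matching stage skipped")
  }

  summary <- list(config = echo, config_md5 = cfg_hash,
                  version = as.character(packageVersion("phagedyn")),
                  n_references = length(refs),
                  n_samples = nrow(samples), notices = notices)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(community = community, sim = sim, hits = all_hits,
                 abundance = abm, persistence = persistence,
                 partitions = partitions, rankings = rankings,
                 islands = islands, notices = notices, outdir = outdir))
}
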