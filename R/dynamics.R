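# Coverage-derived abundance, normalization, dissimilarity, clustering and
# persistence classification across a site x date x molecule sample grid.

#' Dynamics parameters
#'
#' @param trim_fraction fraction of the deepest positions excluded from
#'   the mean (default 0.25: the top 25% of positions by coverage depth,
#'   which may be biased by non-specific recruitment to short conserved
#'   regions).
#' @param persistence_cov coverage threshold (x) above which a contig
#'   counts as detected in a metatranscriptome (default 0.75).
#' @param persistence_min_dates minimum number of detected dates per site
#'   for a persistent call (default 3).
#' @param n_dates number of sampling dates per site (default 4).
#' @param log_base,pseudocount log transform used for normalization and
#'   clustering (defaults: log10, pseudocount 1).
#' @return a list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(trim_fraction = 0.25, persistence_cov = 0.75,
                            persistence_min_dates = 3L, n_dates = 4L,
                            log_base = 10, pseudocount = 1) {
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must lie in [0, 1)")
  if (persistence_min_dates > n_dates)
    stop("persistence_min_dates must be <= n_dates")
  structure(list(trim_fraction = trim_fraction,
                 persistence_cov = persistence_cov,
                 persistence_min_dates = as.integer(persistence_min_dates),
                 n_dates = as.integer(n_dates),
                 log_base = log_base, pseudocount = pseudocount),
            class = "dynamics_params")
}

#' Trimmed mean coverage of a reference
#'
#' Mean per-position depth after excluding the positions whose coverage
#' depth is in the top `trim_fraction` of positions (the
#' `floor(trim_fraction * L)` deepest positions; ties at the cutoff are
#' broken by position index, lower index dropped first).  Zero-depth
#' positions are included in the mean, so the statistic is coverage per
#' position of the whole reference, robust to short conserved
#' high-identity islands that would otherwise inflate the plain mean.
#'
#' @param profile a [compute_coverage()] profile, or a bare depth vector.
#' @param trim_fraction fraction of positions to drop (default 0.25).
#' @return the trimmed mean (a single number).
#' @export
trimmed_mean_coverage <- function(profile, trim_fraction = 0.25) {
  depth <- if (inherits(profile, "coverage_profile")) profile$depth else profile
  L <- length(depth)
  if (L == 0) stop("empty coverage profile")
  n_drop <- floor(trim_fraction * L)
  if (n_drop == 0) return(mean(depth))
  drop_idx <- order(-depth, seq_len(L))[seq_len(n_drop)]
  mean(depth[-drop_idx])
}

#' Normalize a sample's abundances to relative bar heights
#'
#' Heights are relative to the highest log-transformed mean coverage
#' within the sample: `h_i = log10(1 + c_i) / log10(1 + max_j c_j)`.
#' If the maximum is 0 all heights are 0.
#'
#' @param row nonnegative numeric vector of per-contig coverages.
#' @param log_base,pseudocount transform parameters.
#' @return numeric vector of heights in \[0, 1\].
#' @export
normalize_sample <- function(row, log_base = 10, pseudocount = 1) {
  if (!length(row)) stop("empty abundance row")
  mx <- max(row)
  if (mx <= 0) return(rep(0, length(row)))
  log(pseudocount + row, base = log_base) /
    log(pseudocount + mx, base = log_base)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`; defined as 0 (with a
#' warning) when both vectors are all-zero.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    warning("both vectors all-zero; Bray-Curtis defined as 0")
    return(0)
  }
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Build the sample x contig trimmed-coverage abundance matrix
#'
#' @param profiles list of [compute_coverage()] profiles (one per contig
#'   per sample).
#' @param params a [dynamics_params()].
#' @return numeric matrix, rows = sample ids, columns = reference ids,
#'   values = trimmed mean coverage (x).
#' @export
abundance_matrix <- function(profiles, params = dynamics_params()) {
  sample_ids <- sort(unique(vapply(profiles, `[[`, character(1), "sample_id")))
  ref_ids <- sort(unique(vapply(profiles, `[[`, character(1), "ref_id")))
  m <- matrix(0, length(sample_ids), length(ref_ids),
              dimnames = list(sample_ids, ref_ids))
  for (p in profiles)
    m[p$sample_id, p$ref_id] <- trimmed_mean_coverage(p, params$trim_fraction)
  m
}

#' Classify per-site persistence of a contig
#'
#' A contig is detected at a (site, date) when its metatranscriptome
#' trimmed coverage is at or above `persistence_cov`.  Per site it is
#' `persistent` when detected in at least `persistence_min_dates` of
#' `n_dates` dates, `ephemeral` when detected in at least one but fewer
#' dates, and `absent` when never detected.  The global status is
#' `persistent` if the contig is persistent at one or more sites, else
#' `ephemeral` if detected anywhere, else `absent`.
#'
#' @param coverages site x date numeric matrix of RNA (metatranscriptome)
#'   trimmed coverages for one contig; `NA` dates are treated as missing
#'   (computed over available dates, with a warning, `n_dates` unchanged).
#' @param params a [dynamics_params()].
#' @param ref_id contig identifier carried on the result.
#' @return an object of class `"persistence_call"`: list with `ref_id`,
#'   `site_status` (named character), `n_dates_detected` (named integer)
#'   and `global_status`.
#' @export
classify_persistence <- function(coverages, params = dynamics_params(),
                                 ref_id = NA_character_) {
  stopifnot(is.matrix(coverages))
  if (anyNA(coverages))
    warning("missing dates; detection computed over available dates")
  detected <- !is.na(coverages) & coverages >= params$persistence_cov
  n_det <- rowSums(detected)
  status <- ifelse(n_det >= params$persistence_min_dates, "persistent",
                   ifelse(n_det >= 1, "ephemeral", "absent"))
  names(status) <- rownames(coverages)
  global <- if (any(status == "persistent")) "persistent"
            else if (any(status == "ephemeral")) "ephemeral" else "absent"
  structure(list(ref_id = ref_id, site_status = status,
                 n_dates_detected = n_det, global_status = global),
            class = "persistence_call")
}

#' Hierarchically cluster contigs by abundance
#'
#' Average-linkage agglomerative clustering of the contig columns on
#' Bray-Curtis distances of log-transformed abundances.  Columns are
#' sorted by label beforehand so the leaf ordering is deterministic.
#'
#' @param abundance sample x contig abundance matrix (>= 2 columns with
#'   unique labels).
#' @param params a [dynamics_params()].
#' @return list with `order` (leaf labels in dendrogram order), `hclust`
#'   (the tree) and `newick` (the tree serialized as a Newick string).
#' @export
cluster_contigs <- function(abundance, params = dynamics_params()) {
  if (is.null(colnames(abundance)) || anyDuplicated(colnames(abundance)))
    stop("contig columns must carry unique labels")
  abundance <- abundance[, order(colnames(abundance)), drop = FALSE]
  n <- ncol(abundance)
  if (n < 2) {
    return(list(order = colnames(abundance), hclust = NULL,
                newick = paste0("(", colnames(abundance), ");")))
  }
  la <- log(params$pseudocount + abundance, base = params$log_base)
  d <- matrix(0, n, n, dimnames = list(colnames(la), colnames(la)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(la[, i], la[, j])
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  list(order = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}
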