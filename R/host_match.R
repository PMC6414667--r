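# Phage-host matching by co-occurrence: an actively infecting phage must
# have host cells present at the time of sampling, so candidate host ASVs
# are ranked by how consistently they are present in the samples where
# the phage is transcriptionally active.

#' Per-sample activity profile of a phage
#'
#' Active iff the RNA (metatranscriptome) trimmed coverage reaches the
#' detection threshold.  With `threshold = 0`, activity means strictly
#' positive coverage (otherwise every sample would be trivially active).
#'
#' @param coverages named numeric vector of RNA trimmed coverages per
#'   sample.
#' @param threshold detection threshold in coverage units (default 0.75).
#' @param phage_id identifier carried on the profile.
#' @return an object of class `"activity_profile"`: list with `phage_id`,
#'   `active` (named logical) and `threshold`.
#' @export
activity_profile <- function(coverages, threshold = 0.75,
                             phage_id = NA_character_) {
  active <- if (threshold > 0) coverages >= threshold else coverages > 0
  structure(list(phage_id = phage_id, active = active,
                 threshold = threshold),
            class = "activity_profile")
}

#' Consistency of an ASV's presence with a phage's activity
#'
#' The fraction of phage-active samples in which the candidate host ASV
#' is present.  A score of 1 means the necessary condition (host present
#' whenever the phage is actively infecting) holds in every sample; lower
#' scores flag incompatible samples.  Undefined (NA, flagged) when the
#' phage is never active.
#'
#' @param activity an [activity_profile()].
#' @param presence named logical vector (ASV present per sample) or a
#'   named numeric vector of relative abundances, thresholded at
#'   `presence_floor`.
#' @param presence_floor relative-abundance floor defining presence
#'   (default 0.001).
#' @return score in \[0, 1\], with attributes `"violating_samples"` and
#'   `"undefined"` (TRUE when the phage is never active).
#' @export
consistency_score <- function(activity, presence, presence_floor = 0.001) {
  stopifnot(inherits(activity, "activity_profile"))
  if (is.numeric(presence)) presence <- presence >= presence_floor
  if (!setequal(names(activity$active), names(presence)))
    stop("activity and presence cover different sample sets")
  presence <- presence[names(activity$active)]
  act <- activity$active
  if (!any(act)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "violating_samples") <- character(0)
    return(out)
  }
  ok <- act & presence
  out <- sum(ok) / sum(act)
  attr(out, "undefined") <- FALSE
  attr(out, "violating_samples") <- names(act)[act & !presence]
  out
}

#' Rank candidate host ASVs for a phage
#'
#' Candidates are ordered by consistency score (descending), ties broken
#' by the Pearson correlation between the phage RNA coverage and the
#' ASV's RNA relative abundance across samples (descending; correlation
#' is only a tie-breaker, not evidence), then by ASV id (ascending).
#' Candidates with score below 1 carry an incompatibility flag listing
#' the violating samples.
#'
#' @param activity an [activity_profile()].
#' @param asv_rna samples x ASVs matrix of RNA relative abundances (the
#'   sample set of `activity`).
#' @param phage_rna_coverage named numeric vector of the phage's RNA
#'   trimmed coverage per sample (for the correlation tie-break;
#'   defaults to the coverages implied by `activity` being unavailable,
#'   in which case correlations are NA).
#' @param presence_floor relative-abundance floor defining presence.
#' @return an object of class `"host_ranking"`: data.frame with columns
#'   `asv_id`, `score`, `correlation`, `incompatible`,
#'   `violating_samples` (comma-separated), ordered as above; the phage
#'   id is in attribute `"phage_id"`.
#' @export
rank_hosts <- function(activity, asv_rna, phage_rna_coverage = NULL,
                       presence_floor = 0.001) {
  stopifnot(inherits(activity, "activity_profile"))
  if (!nrow(asv_rna) || !ncol(asv_rna)) stop("no candidate ASVs")
  asv_ids <- colnames(asv_rna)
  rows <- lapply(asv_ids, function(a) {
    sc <- consistency_score(activity, asv_rna[, a], presence_floor)
    corr <- NA_real_
    if (!is.null(phage_rna_coverage)) {
      sm <- intersect(names(phage_rna_coverage), rownames(asv_rna))
      if (length(sm) >= 3 && stats::sd(asv_rna[sm, a]) > 0 &&
          stats::sd(phage_rna_coverage[sm]) > 0)
        corr <- cor(phage_rna_coverage[sm], asv_rna[sm, a])
    }
    data.frame(asv_id = a, score = as.numeric(sc), correlation = corr,
               incompatible = !is.na(sc) && sc < 1,
               violating_samples = paste(attr(sc, "violating_samples"),
                                         collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$score, -ifelse(is.na(out$correlation), -Inf, out$correlation),
               out$asv_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phage_id") <- activity$phage_id
  class(out) <- c("host_ranking", class(out))
  out
}
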