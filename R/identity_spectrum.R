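# Percent-identity recruitment spectra: histograms of recruitment vs.
# percent identity, population-structure classification (clonal /
# continuum / discrete clouds), and detection of conserved high-identity
# islands that bias mean coverage.

#' Spectrum classification parameters
#'
#' Quantitative renderings of qualitative population-structure
#' descriptions; all config-exposed.
#'
#' @param clonal_high_frac minimum weight fraction in \[98, 100\] for a
#'   clonal call (default 0.5).
#' @param clonal_mid_frac maximum weight fraction in \[90, 97) for a
#'   clonal call (default 0.10).
#' @param occupancy_frac minimum weight fraction for a bin to count as
#'   occupied (default 0.01).
#' @param gap_bins minimum run of empty bins within \[88, 98\] separating
#'   two occupied regions for a gapped ("discrete clouds") call
#'   (default 3).
#' @param continuum_span minimum span (percentage points) of occupied
#'   bins within \[80, 98\] for a continuum call (default 10).
#' @param continuum_max_gap largest internal gap (bins) tolerated inside
#'   a continuum span (default 1, i.e. no gap of >= 2 bins).
#' @return a list of class `"spectrum_params"`.
#' @export
spectrum_params <- function(clonal_high_frac = 0.5, clonal_mid_frac = 0.10,
                            occupancy_frac = 0.01, gap_bins = 3L,
                            continuum_span = 10L, continuum_max_gap = 1L) {
  structure(list(clonal_high_frac = clonal_high_frac,
                 clonal_mid_frac = clonal_mid_frac,
                 occupancy_frac = occupancy_frac,
                 gap_bins = as.integer(gap_bins),
                 continuum_span = as.integer(continuum_span),
                 continuum_max_gap = as.integer(continuum_max_gap)),
            class = "spectrum_params")
}

#' Percent-identity recruitment histogram
#'
#' One-percentage-point bins spanning \[70, 100\]: bin `[b, b+1)` for
#' `b = 70..98` and a closed top bin `[99, 100]`.  Each hit adds its
#' aligned length (and one hit count) to the bin containing its percent
#' identity; hits below 70% identity are excluded and counted.
#'
#' @param hits hits data.frame ([align_reads()] layout).
#' @param ref_id reference to tabulate (default: all hits).
#' @param sample_id label carried on the histogram.
#' @return an object of class `"identity_histogram"`: list with `ref_id`,
#'   `sample_id`, `bins` data.frame (`lower`, `upper`, `bases`, `hits`)
#'   and `n_excluded`.
#' @export
identity_histogram <- function(hits, ref_id = NULL, sample_id = NA_character_) {
  h <- if (is.null(ref_id)) hits else hits[hits$ref_id == ref_id, , drop = FALSE]
  lower <- 70:99
  bases <- numeric(30); counts <- integer(30)
  excl <- 0L
  if (nrow(h)) {
    pid <- h$percent_identity
    excl <- sum(pid < 70)
    keep <- pid >= 70
    bin <- pmin(floor(pid[keep]), 99) - 69L  # 100% falls in the [99,100] bin
    bases <- as.numeric(tapply(h$aligned_length[keep], factor(bin, levels = 1:30),
                               sum, default = 0))
    counts <- as.integer(tapply(rep(1L, sum(keep)), factor(bin, levels = 1:30),
                                sum, default = 0))
  }
  structure(list(ref_id = ref_id %||% NA_character_, sample_id = sample_id,
                 bins = data.frame(lower = lower, upper = lower + 1,
                                   bases = bases, hits = counts),
                 n_excluded = excl),
            class = "identity_histogram")
}

#' @noRd
longest_ok_span <- function(occ_bins, max_gap) {
  # longest span (in percentage points) covered by occupied bins such that
  # consecutive occupied bins are separated by gaps of <= max_gap bins
  if (!length(occ_bins)) return(0L)
  occ_bins <- sort(occ_bins)
  best <- 1L; start <- occ_bins[1]
  for (i in seq_along(occ_bins)[-1]) {
    if (occ_bins[i] - occ_bins[i - 1] - 1L > max_gap) start <- occ_bins[i]
    best <- max(best, occ_bins[i] - start + 1L)
  }
  best
}

#' Classify the population structure of a recruitment spectrum
#'
#' Labels, in order of precedence:
#' \describe{
#'   \item{clonal}{at least 50% of recruitment weight at 98--100% identity
#'     and at most 10% at 90--97%: many nearly identical relatives, few
#'     moderately close ones.}
#'   \item{gapped}{two occupied identity regions separated by a run of at
#'     least `gap_bins` empty bins within \[88, 98\]: discrete clouds with
#'     a recruitment discontinuity.}
#'   \item{continuum}{occupied bins spanning at least `continuum_span`
#'     consecutive percentage points within \[80, 98\] with no internal
#'     gap of 2+ bins: a genomic continuum of relatives.}
#'   \item{sparse}{anything else, including empty histograms.}
#' }
#'
#' @param hist an [identity_histogram()].
#' @param params a [spectrum_params()].
#' @return an object of class `"spectrum_class"`: list with `label` and
#'   `stats` (fraction at 98--100, fraction at 90--97, occupied span, gap
#'   intervals).
#' @export
classify_spectrum <- function(hist, params = spectrum_params()) {
  b <- hist$bins
  tot <- sum(b$bases)
  make <- function(label, frac98 = NA, frac9097 = NA, span = NA, gaps = NULL)
    structure(list(label = label,
                   stats = list(frac_98_100 = frac98, frac_90_97 = frac9097,
                                occupied_span = span, gap_intervals = gaps)),
              class = "spectrum_class")
  if (tot <= 0) return(make("sparse"))
  frac98 <- sum(b$bases[b$lower >= 98]) / tot
  frac9097 <- sum(b$bases[b$lower >= 90 & b$lower <= 96]) / tot
  occupied <- b$lower[b$bases >= params$occupancy_frac * tot]
  span <- longest_ok_span(occupied[occupied >= 80 & occupied <= 97],
                          params$continuum_max_gap)
  # gap search within [88, 98]
  gaps <- NULL
  win <- 88:97  # bin lower bounds inside the window
  emp <- setdiff(win, occupied)
  if (length(emp)) {
    runs <- split(emp, cumsum(c(1, diff(emp) != 1)))
    for (r in runs) {
      if (length(r) >= params$gap_bins &&
          any(occupied < min(r)) && any(occupied > max(r)))
        gaps <- rbind(gaps, c(min(r), max(r) + 1))
    }
  }
  label <- if (frac98 >= params$clonal_high_frac &&
               frac9097 <= params$clonal_mid_frac) "clonal"
    else if (!is.null(gaps)) "gapped"
    else if (span >= params$continuum_span) "continuum"
    else "sparse"
  make(label, frac98, frac9097, span, gaps)
}

#' Detect conserved high-identity islands in a coverage profile
#'
#' Sliding windows (step = `window / 2`) whose mean depth is at least
#' `enrichment` times the median contig depth are merged into maximal
#' intervals; the median is used (not the mean) to stay robust to the
#' islands themselves, and when the median is 0 the mean of nonzero
#' positions is used instead.  Intervals longer than
#' `max_island_frac * L` are discarded (an elevated whole contig is not
#' an island).  Each island is annotated with its enrichment ratio and
#' the median identity of hits overlapping it.
#'
#' @param profile a [compute_coverage()] profile.
#' @param hits optional hits data.frame used for the island's median
#'   identity annotation.
#' @param window window size in bp (default 500).
#' @param enrichment depth enrichment threshold (default 5.0).
#' @param max_island_frac maximum island length as a fraction of the
#'   reference length (default 0.10).
#' @return data.frame with one row per island: `ref_id`, `start`, `end`
#'   (0-based half-open), `island_mean_depth`, `background_depth`,
#'   `enrichment_ratio`, `median_identity`.
#' @export
detect_islands <- function(profile, hits = NULL, window = 500L,
                           enrichment = 5.0, max_island_frac = 0.10) {
  depth <- profile$depth
  L <- length(depth)
  empty <- data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), island_mean_depth = numeric(0),
                      background_depth = numeric(0),
                      enrichment_ratio = numeric(0),
                      median_identity = numeric(0), stringsAsFactors = FALSE)
  if (L < window) stop("profile shorter than the window")
  bg <- median(depth)
  if (bg == 0) {
    nz <- depth[depth > 0]
    if (!length(nz)) return(empty)
    bg <- mean(nz)
  }
  step <- max(1L, window %/% 2L)
  starts <- seq.int(0L, L - window, by = step)
  if (utils::tail(starts, 1) + window < L) starts <- c(starts, L - window)
  wmean <- vapply(starts, function(s) mean(depth[(s + 1):(s + window)]),
                  numeric(1))
  flagged <- wmean >= enrichment * bg
  if (!any(flagged)) return(empty)
  # merge overlapping / adjacent flagged windows
  iv <- cbind(starts[flagged], starts[flagged] + window)
  merged <- list(); cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2])
    else { merged[[length(merged) + 1]] <- cur; cur <- iv[i, ] }
  }
  merged[[length(merged) + 1]] <- cur
  out <- do.call(rbind, lapply(merged, function(m) {
    len <- m[2] - m[1]
    if (len > max_island_frac * L) return(NULL)
    imean <- mean(depth[(m[1] + 1):m[2]])
    med_id <- NA_real_
    if (!is.null(hits) && nrow(hits)) {
      ov <- hits$ref_id == profile$ref_id &
        hits$ref_start < m[2] & hits$ref_end > m[1]
      if (any(ov)) med_id <- median(hits$percent_identity[ov])
    }
    data.frame(ref_id = profile$ref_id, start = m[1], end = m[2],
               island_mean_depth = imean, background_depth = bg,
               enrichment_ratio = imean / bg, median_identity = med_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) empty else out
}
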