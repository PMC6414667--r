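mkhits <- function(pid, len = 200L) {
  n <- length(pid)
  data.frame(read_id = sprintf("r%04d", seq_len(n)), ref_id = rep("r", n),
             ref_start = rep(0L, n), ref_end = rep(len, n),
             aligned_length = rep(len, n),
             matches = round(pid / 100 * len), percent_identity = pid,
             score = rep(1, n), strand = rep("+", n),
             stringsAsFactors = FALSE)
}

test_that("identity histograms bin hits and conserve aligned bases", {
  h <- identity_histogram(mkhits(c(100, 100, 99.2)), "r")
  expect_equal(sum(h$bins$bases), 600)
  expect_equal(h$bins$bases[h$bins$lower == 99], 600)  # top bin is [99,100]
  h2 <- identity_histogram(mkhits(c(85.5, 86.5)), "r")
  expect_equal(h2$bins$bases[h2$bins$lower == 85], 200)
  expect_equal(h2$bins$bases[h2$bins$lower == 86], 200)
  expect_true(all(identity_histogram(mkhits(numeric(0)), "r")$bins$bases == 0))
  # sub-70% identities are excluded and counted
  h3 <- identity_histogram(mkhits(c(65, 95)), "r")
  expect_identical(h3$n_excluded, 1L)
  expect_equal(sum(h3$bins$bases), 200)
  # weight conservation against retained hit lengths
  set.seed(51)
  pid <- runif(200, 70, 100)
  h4 <- identity_histogram(mkhits(pid), "r")
  expect_equal(sum(h4$bins$bases), 200 * 200)
  expect_equal(sum(h4$bins$hits), 200)
})

test_that("spectrum classification follows the clonal/gapped/continuum rules", {
  # all weight at [99,100]: clonal
  expect_identical(classify_spectrum(identity_histogram(mkhits(rep(99.5, 50)), "r"))$label,
                   "clonal")
  # weight spread evenly over [82,96]: continuum
  cont <- classify_spectrum(identity_histogram(
    mkhits(rep(seq(82.5, 95.5, by = 1), each = 10)), "r"))
  expect_identical(cont$label, "continuum")
  expect_gte(cont$stats$occupied_span, 10)
  # clouds at [84,88) and [96,100) with empty [88,96): gapped
  gap <- classify_spectrum(identity_histogram(
    mkhits(rep(c(84.5, 85.5, 86.5, 87.5, 96.5, 97.5, 98.5, 99.5), each = 10)), "r"))
  expect_identical(gap$label, "gapped")
  expect_false(is.null(gap$stats$gap_intervals))
  # empty histogram: sparse
  expect_identical(classify_spectrum(identity_histogram(mkhits(numeric(0)), "r"))$label,
                   "sparse")
  # precedence: clonal beats gapped when both patterns are present
  both <- classify_spectrum(identity_histogram(
    mkhits(c(rep(99.5, 80), rep(84.5, 5))), "r"))
  expect_identical(both$label, "clonal")
})

test_that("conserved islands are detected and whole-contig elevation is not", {
  # uniform coverage: no islands
  flat <- structure(list(ref_id = "r", sample_id = "s",
                         depth = rep(3L, 20000)), class = "coverage_profile")
  expect_identical(nrow(detect_islands(flat)), 0L)
  # 400 bp at depth 50 over background 1 on 20 kb: one island covering it
  d <- rep(1L, 20000); d[10001:10400] <- 50L
  prof <- structure(list(ref_id = "r", sample_id = "s", depth = d),
                    class = "coverage_profile")
  isl <- detect_islands(prof)
  expect_identical(nrow(isl), 1L)
  expect_lte(isl$start, 10000)
  expect_gte(isl$end, 10400)
  expect_gte(isl$enrichment_ratio, 5)
  # whole contig elevated: interval exceeds max_island_frac, discarded
  high <- structure(list(ref_id = "r", sample_id = "s",
                         depth = rep(50L, 20000)), class = "coverage_profile")
  expect_identical(nrow(detect_islands(high)), 0L)
  expect_error(detect_islands(structure(list(ref_id = "r", sample_id = "s",
                                             depth = rep(1L, 100)),
                                        class = "coverage_profile")),
               "window")
})

test_that("islands carry the median identity of their overlapping hits", {
  d <- rep(1L, 10000); d[5001:5300] <- 40L
  prof <- structure(list(ref_id = "r", sample_id = "s", depth = d),
                    class = "coverage_profile")
  hits <- data.frame(read_id = c("a", "b", "c"), ref_id = "r",
                     ref_start = c(5000L, 5100L, 100L),
                     ref_end = c(5200L, 5300L, 300L),
                     aligned_length = 200L, matches = 200L,
                     percent_identity = c(100, 99, 80), score = 1,
                     strand = "+", stringsAsFactors = FALSE)
  isl <- detect_islands(prof, hits)
  expect_identical(nrow(isl), 1L)
  expect_equal(isl$median_identity, 99.5)  # hits a and b overlap the island
})

test_that("trimming suppresses the coverage bias of a conserved island", {
  # island of 400 bp (4% of contig) at 10x-plus enrichment
  d <- rep(1, 10000); d[4001:4400] <- 50
  untrimmed <- mean(d)
  trimmed <- trimmed_mean_coverage(d, 0.25)
  island_share <- sum(d[4001:4400]) / sum(d)
  expect_equal(trimmed, 1)  # background recovered exactly
  expect_gte((untrimmed - trimmed) / untrimmed, 0.95 * island_share)
})
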