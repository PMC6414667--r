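test_that("profile log-odds follow the closed form and gap columns drop", {
  # 10 sequences, one column with 6 L and 4 V
  refs <- setNames(paste0(c(rep("L", 6), rep("V", 4)), "AAAAAAAAA"),
                   sprintf("ref%02d", 1:10))
  groups <- setNames(rep(c("g1", "g2"), each = 5), names(refs))
  prof <- build_profile(refs, groups)
  expect_equal(unname(prof$pssm["L", 1]), log2((6.5 / 20) / 0.05))
  expect_equal(unname(prof$pssm["V", 1]), log2((4.5 / 20) / 0.05))
  expect_equal(unname(prof$pssm["A", 2]), log2((10.5 / 20) / 0.05))
  # an all-'A' column scores highest for A
  expect_identical(rownames(prof$pssm)[which.max(prof$pssm[, 2])], "A")
  # all-gap column dropped
  refs2 <- setNames(paste0(substr(refs, 1, 5), "-", substr(refs, 6, 10)),
                    names(refs))
  prof2 <- build_profile(refs2, groups)
  expect_identical(ncol(prof2$pssm), 10L)
  expect_false(6L %in% prof2$kept_cols)
  # unaligned input errors; too few sequences error
  expect_error(build_profile(setNames(c("AAAA", "AAA", "AA", "A", "AAAAA"),
                                      paste0("r", 1:5)),
                             setNames(rep("g", 5), paste0("r", 1:5))),
               "aligned")
  expect_error(build_profile(refs[1:4], groups[1:4]), "5")
})

test_that("threshold calibration hits its quantile endpoints", {
  prof <- build_profile(test_marker_refs())
  # target_fpr = 1 accepts everything: threshold equals the minimum null score
  t_all <- calibrate_threshold(prof, n_null = 300, target_fpr = 1,
                               read_length = 150, seed = 5)
  t_none <- calibrate_threshold(prof, n_null = 300, target_fpr = 1e-9,
                                read_length = 150, seed = 5)
  t_mid <- calibrate_threshold(prof, n_null = 300, target_fpr = 0.05,
                               read_length = 150, seed = 5)
  expect_lte(t_all, t_mid)
  expect_lte(t_mid, t_none)
  # deterministic under a fixed seed
  expect_identical(t_mid, calibrate_threshold(prof, n_null = 300,
                                              target_fpr = 0.05,
                                              read_length = 150, seed = 5))
})

test_that("marker reads are detected on both strands and assigned to their group", {
  mk <- test_marker_refs()
  prof <- build_profile(mk)
  thr <- calibrate_threshold(prof, n_null = 2000, seed = 6)
  # reads simulated from known references with 1% nucleotide error
  mr <- simulate_marker_reads(mk, 300, infected_fraction = 0.5,
                              error_rate = 0.01, seed = 7)
  asg <- classify_marker_reads(mr$reads, prof, thr)
  expect_gte(nrow(asg), 295)  # essentially all detected
  m <- merge(asg, mr$truth, by = "read_id")
  expect_gte(mean(m$group.x == m$group.y), 0.9)
  # reverse-complementing every read leaves the partition unchanged
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(mr$reads))), names(mr$reads))
  asg_rc <- classify_marker_reads(rc, prof, thr)
  expect_identical(asg$group[order(asg$read_id)],
                   asg_rc$group[order(asg_rc$read_id)])
  expect_identical(asg$score[order(asg$read_id)],
                   asg_rc$score[order(asg_rc$read_id)])
  # random reads are rejected
  set.seed(8)
  nulls <- setNames(vapply(1:200, function(i) rdna(250), character(1)),
                    sprintf("n%03d", 1:200))
  expect_lte(nrow(search_reads(nulls, prof, thr)), 2)
  # reads shorter than 10 codons are skipped and counted
  short <- search_reads(setNames(rdna(20), "s"), prof, thr)
  expect_identical(nrow(short), 0L)
  expect_identical(attr(short, "n_skipped"), 1L)
})

test_that("single-candidate assignment agrees with the batch path", {
  mk <- test_marker_refs()
  prof <- build_profile(mk)
  thr <- calibrate_threshold(prof, n_null = 1000, seed = 9)
  mr <- simulate_marker_reads(mk, 40, infected_fraction = 0.5, seed = 10)
  cand <- search_reads(mr$reads, prof, thr)
  batch <- classify_marker_reads(mr$reads, prof, thr)
  for (i in seq_len(nrow(cand))) {
    one <- assign_group(cand$segment[i], cand$offset[i], prof)
    j <- match(cand$read_id[i], batch$read_id)
    expect_identical(one$group, batch$group[j])
    expect_identical(one$nearest_ref, batch$nearest_ref[j])
  }
  # a segment identical to a reference is assigned to that reference's group
  t4 <- names(mk$groups)[mk$groups == "T4like"][1]
  seg <- substr(mk$proteins[[t4]], 51, 120)
  expect_identical(assign_group(seg, 50, prof)$group, "T4like")
})

test_that("partition arithmetic reproduces fractions, ratios and estimates", {
  p <- partition(c(cyano_synechococcus = 50, cyano_prochlorococcus = 50,
                   T4like = 100, T7like = 0))
  expect_equal(p$t4_fraction, 0.5)
  expect_equal(p$viral_host_ratio, 1)
  p2 <- partition(c(cyano_synechococcus = 30, cyano_prochlorococcus = 20,
                    T4like = 60, T7like = 5))
  expect_equal(p2$viral_host_ratio, 1.2)
  expect_equal(p2$t4_fraction, 60 / 115)
  expect_equal(sum(p2$fractions), 1)
  expect_equal(p2$infected_fraction_estimate, 1.2 / 2.2)
  # zero viral counts: ratio 0, all host
  p3 <- partition(c(cyano_synechococcus = 10, cyano_prochlorococcus = 10,
                    T4like = 0, T7like = 0))
  expect_equal(p3$viral_host_ratio, 0)
  expect_equal(p3$viral_fraction, 0)
  # zero host: flagged undefined ratio
  p4 <- partition(c(cyano_synechococcus = 0, cyano_prochlorococcus = 0,
                    T4like = 5, T7like = 0))
  expect_true("host_zero" %in% p4$flagged)
  expect_true(is.na(p4$viral_host_ratio))
  # empty input flagged
  expect_true("no_assignments" %in% partition(c(T4like = 0))$flagged)
})

test_that("the infected-fraction map is monotone with its fixed points", {
  expect_equal(infected_fraction(1, 1), 0.5)
  expect_equal(infected_fraction(0), 0)
  expect_equal(infected_fraction(1.2, 1), 1.2 / 2.2)  # roughly half infected
  expect_equal(infected_fraction(2, 2), 0.5)          # I = 0.5 iff r = alpha
  r <- seq(0, 5, by = 0.25)
  expect_true(all(diff(infected_fraction(r)) > 0))
  expect_error(infected_fraction(-1), ">= 0")
  expect_error(infected_fraction(1, 0), "alpha")
})

test_that("Gp23 mixtures are partitioned into cyanophage and heterophage", {
  gp23 <- make_marker_refs(groups = c(cyanophage = 4L, heterophage = 6L),
                           length_aa = 380, seed = 12)
  prof <- build_profile(gp23)
  thr <- calibrate_threshold(prof, n_null = 2000, seed = 13)
  # 80:20 heterophage:cyanophage mix recovered within 3 binomial SE
  withr_seed <- 14
  set.seed(withr_seed)
  n <- 4000
  grp <- sample(c("heterophage", "cyanophage"), n, TRUE, prob = c(0.8, 0.2))
  by_g <- split(names(gp23$groups), gp23$groups)
  reads <- vapply(grp, function(g) {
    nt <- gp23$nt[[sample(by_g[[g]], 1)]]
    s <- sample(nchar(nt) - 249, 1)
    substr(nt, s, s + 249)
  }, character(1))
  names(reads) <- sprintf("g%05d", seq_len(n))
  res <- gp23_partition(reads, prof, threshold = thr)
  expect_lt(abs(res$fractions[["cyanophage"]] - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # all-heterophage reads give cyanophage fraction 0
  het <- reads[grp == "heterophage"][1:100]
  res_h <- gp23_partition(het, prof, threshold = thr)
  expect_equal(res_h$fractions[["cyanophage"]], 0)
  # empty read set flagged
  res_e <- gp23_partition(character(0), prof, threshold = thr)
  expect_true("no_assignments" %in% res_e$flagged)
})
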