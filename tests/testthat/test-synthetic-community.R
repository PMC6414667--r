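test_that("population specs enforce their invariants", {
  expect_error(population_spec("p", "viral", "clonal", ancestor_length = 500),
               "ancestor_length")
  expect_error(population_spec("p", "viral", "clonal", n_variants = 0),
               "n_variants")
  expect_error(population_spec("p", "viral", "wibble"), "cloud model")
  expect_error(population_spec("p", "viral", "clonal",
                               divergence_params = list(max_div = 0.5)),
               "0.30")
  expect_error(population_spec("p", "viral", "clonal", ancestor_length = 2000,
                               conserved_islands = data.frame(start = 1900,
                                                              length = 200)),
               "within")
  expect_error(population_spec("p", "viral", "clonal", ancestor_length = 5000,
                               conserved_islands = data.frame(
                                 start = c(100, 150), length = c(100, 50))),
               "overlap")
})

test_that("a single-variant population is identical to its ancestor", {
  pop <- generate_population(
    population_spec("p", "viral", "single", 2000, 1), seed = 3)
  expect_length(pop$variants, 1)
  expect_identical(unname(pop$variants[1]), pop$ancestor)
  expect_equal(pop$divergence$realized_divergence, 0)
})

test_that("clonal divergence stays within bounds and islands are invariant", {
  isl <- data.frame(start = c(2000, 12000), length = c(500, 300))
  sp <- population_spec("p", "viral", "clonal", 20000, 5,
                        divergence_params = list(max_div = 0.02),
                        conserved_islands = isl)
  pop <- generate_population(sp, seed = 1)
  # mismatch count against the ancestor is the divergence oracle
  anc <- strsplit(pop$ancestor, "")[[1]]
  for (v in pop$variants) {
    d <- sum(strsplit(v, "")[[1]] != anc) / 20000
    expect_lte(d, 0.02)
  }
  for (i in seq_len(nrow(isl))) {
    s <- isl$start[i] + 1; e <- isl$start[i] + isl$length[i]
    for (v in pop$variants)
      expect_identical(substr(v, s, e), substr(pop$ancestor, s, e))
  }
  # reproducible under the same seed
  pop2 <- generate_population(sp, seed = 1)
  expect_identical(pop$variants, pop2$variants)
})

test_that("continuum divergences span at least ten percentage points", {
  pop <- generate_population(
    population_spec("p", "viral", "continuum", 20000, 50), seed = 2)
  d <- pop$divergence$realized_divergence
  expect_gte(diff(range(d)), 0.10)
})

test_that("two-cloud populations have a near and a far cloud", {
  pop <- generate_population(
    population_spec("p", "viral", "two_cloud", 20000, 12), seed = 4)
  d <- pop$divergence$realized_divergence
  expect_true(all(d <= 0.021 | (d >= 0.105 & d <= 0.151)))
  expect_true(any(d <= 0.021) && any(d >= 0.105))
})

test_that("marker insertion replaces in place and respects islands", {
  s <- strrep("A", 10000)
  expect_identical(insert_marker_gene(s, "", 5000), s)
  marker <- rdna(1083)
  out <- insert_marker_gene(s, marker, 5000)
  expect_identical(nchar(out), 10000L)
  expect_identical(substr(out, 5001, 6083), marker)  # bases 5000..6082, 0-based
  expect_error(insert_marker_gene(s, marker, 9500), "fit")
  expect_error(insert_marker_gene(s, marker, 5000,
                                  islands = data.frame(start = 6000,
                                                       length = 100)),
               "island")
})

test_that("phage RNA reads require an infected, present host", {
  set.seed(1)
  mk <- test_marker_refs()
  specs <- list(
    population_spec("phageA", "viral", "clonal", 4000, 2),
    population_spec("hostA", "host", "clonal", 4000, 2))
  com <- build_community(specs, seed = 5, host_links = c(phageA = "hostA"),
                         marker_refs = mk)
  ab <- matrix(c(5, 5), 2, 1, dimnames = list(c("phageA", "hostA"), "S1_D1"))
  des0 <- sample_design(sites = "S1", dates = "D1", molecules = c("DNA", "RNA"),
                        n_reads = 200, infected_fraction = 0, seed = 9)
  sim0 <- simulate_reads(com, des0, ab)
  tc <- sim0$truth$read_counts
  expect_identical(tc$count[tc$sample_id == "S1_D1_RNA" &
                              tc$population == "phageA"], 0L)
  expect_gt(tc$count[tc$sample_id == "S1_D1_DNA" & tc$population == "phageA"], 0L)
  expect_false(sim0$truth$activity$active[1])
  # with infection the phage transcribes
  desI <- sample_design(sites = "S1", dates = "D1", molecules = "RNA",
                        n_reads = 200, infected_fraction = 0.5, seed = 9)
  simI <- simulate_reads(com, desI, ab)
  tcI <- simI$truth$read_counts
  expect_gt(tcI$count[tcI$population == "phageA"], 0L)
})

test_that("per-sample truth counts conserve n_reads and zero reads give empty output", {
  specs <- list(population_spec("pA", "viral", "clonal", 4000, 2),
                population_spec("hA", "host", "clonal", 4000, 2))
  com <- build_community(specs, seed = 2, host_links = c(pA = "hA"))
  ab <- matrix(c(1, 3), 2, 2, dimnames = list(c("pA", "hA"),
                                              c("S1_D1", "S1_D2")))
  des <- sample_design(sites = "S1", dates = c("D1", "D2"),
                       molecules = c("DNA", "RNA"), n_reads = 500, seed = 3)
  sim <- simulate_reads(com, des, ab)
  counts <- tapply(sim$truth$read_counts$count,
                   sim$truth$read_counts$sample_id, sum)
  expect_true(all(counts == 500))
  expect_true(all(vapply(sim$reads, length, integer(1)) == 500))
  # zero reads
  des0 <- sample_design(sites = "S1", dates = "D1", molecules = "DNA",
                        n_reads = 0, seed = 3)
  sim0 <- simulate_reads(com, des0, ab)
  expect_length(sim0$reads[["S1_D1_DNA"]], 0)
  expect_true(all(sim0$truth$read_counts$count == 0))
})

test_that("identical seeds give byte-identical FASTQ and truth tables", {
  specs <- list(population_spec("pA", "viral", "clonal", 4000, 3),
                population_spec("hA", "host", "clonal", 4000, 2))
  com <- build_community(specs, seed = 6, host_links = c(pA = "hA"),
                         marker_refs = test_marker_refs())
  ab <- matrix(c(2, 3), 2, 1, dimnames = list(c("pA", "hA"), "S1_D1"))
  des <- sample_design(sites = "S1", dates = "D1", molecules = c("DNA", "RNA"),
                       n_reads = 300, n_marker_reads = 200, seed = 11)
  sim1 <- simulate_reads(com, des, ab)
  sim2 <- simulate_reads(com, des, ab)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$truth, sim2$truth)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim1$reads[["S1_D1_DNA"]], f1)
  write_fastq(sim2$reads[["S1_D1_DNA"]], f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_identical(back, sim1$reads[["S1_D1_DNA"]])
})

test_that("marker reads realize the closed-form viral fraction", {
  mk <- test_marker_refs()
  # alpha = 1, I = 0.5, 20000 reads: viral fraction 0.5 within 3 binomial SE
  mr <- simulate_marker_reads(mk, 20000, infected_fraction = 0.5, alpha = 1,
                              seed = 21)
  expect_equal(mr$expected_viral_fraction, 0.5)
  vf <- mean(mr$truth$group %in% c("T4like", "T7like"))
  expect_lt(abs(vf - 0.5), 3 * sqrt(0.25 / 20000))
  # closed form for assorted alpha and I
  for (a in c(0.5, 1, 2)) for (I in c(0.1, 0.5, 0.9)) {
    m <- simulate_marker_reads(mk, 0, infected_fraction = I, alpha = a,
                               seed = 1)
    expect_equal(m$expected_viral_fraction, a * I / (a * I + 1 - I))
  }
  # I = 0 means zero viral marker reads
  m0 <- simulate_marker_reads(mk, 5000, infected_fraction = 0, seed = 2)
  expect_identical(sum(m0$truth$group %in% c("T4like", "T7like")), 0L)
})

test_that("ASV tables normalize per sample and honour absences", {
  des <- sample_design(sites = c("POLA", "SPOT", "CAT"), dates = "Oct",
                       molecules = "RNA", seed = 1)
  pres <- rbind(Syn_ASV10 = c(POLA_Oct = TRUE, SPOT_Oct = TRUE, CAT_Oct = TRUE),
                Pro_ASV4 = c(POLA_Oct = FALSE, SPOT_Oct = TRUE, CAT_Oct = TRUE))
  tab <- generate_asv_table(des, pres)
  expect_true(all(abs(rowSums(tab) - 1) < 1e-12))
  expect_identical(tab["POLA_Oct_RNA", "Pro_ASV4"], 0)
  expect_identical(tab["POLA_Oct_RNA", "Syn_ASV10"], 1)
  # single present host has relative abundance 1 wherever present
  one <- generate_asv_table(des, pres["Syn_ASV10", , drop = FALSE])
  expect_true(all(one[, 1] == 1))
  # all absent: zero rows, flagged, warned
  expect_warning(z <- generate_asv_table(des, pres & FALSE), "absent")
  expect_true(all(z == 0))
  expect_length(attr(z, "empty_samples"), 3)
})
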