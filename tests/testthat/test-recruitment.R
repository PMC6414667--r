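test_that("reference filtering keeps only contigs strictly longer than the threshold", {
  seqs <- setNames(vapply(c(4999, 5000, 5001), rdna, character(1)),
                   c("a", "b", "c"))
  expect_identical(names(filter_references(seqs, 5000)), "c")
  expect_identical(filter_references(seqs, 0), seqs)
  expect_identical(filter_references(character(0), 5000), character(0))
  expect_warning(filter_references(seqs["a"], 5000), "no references")
})

test_that("exact and substituted reads align with the expected identity", {
  set.seed(31)
  ref <- c(refA = rdna(2000))
  # read identical to a 150 bp slice: identity 100, aligned length 150
  rd <- setNames(substr(ref, 501, 650), "r1")
  h <- align_reads(rd, ref, recruitment_params(), "DNA")
  expect_identical(nrow(h), 1L)
  expect_equal(h$percent_identity, 100)
  expect_identical(h$aligned_length, 150L)
  expect_identical(h$ref_start, 500L)
  expect_identical(h$ref_end, 650L)
  expect_identical(h$strand, "+")
  # 10 substitutions over 200 aligned bp: identity 190/200 = 95.0
  ch <- strsplit(substr(ref, 1001, 1200), "")[[1]]
  pos <- seq(15, 195, by = 20)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  h2 <- align_reads(setNames(paste(ch, collapse = ""), "r2"), ref,
                    recruitment_params(), "DNA")
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$aligned_length, 200L)
  expect_equal(h2$percent_identity, 95.0)
  # reverse-complement read maps to the same interval on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  h3 <- align_reads(setNames(rc, "r3"), ref, recruitment_params(), "DNA")
  expect_identical(h3$strand, "-")
  expect_identical(h3$ref_start, 500L)
  expect_identical(h3$ref_end, 650L)
})

test_that("unrelated reads produce no hit, in agreement with the DP oracle", {
  set.seed(32)
  ref <- c(refA = rdna(2000))
  for (i in 1:20) {
    rd <- rdna(150)
    h <- align_reads(setNames(rd, "r"), ref, recruitment_params(), "DNA")
    o <- dp_oracle(rd, ref[[1]])
    oid <- 100 * o$matches / o$cols
    expect_false(o$cols > 100 && oid >= 70)  # oracle finds no qualifying hit
    expect_identical(nrow(h), 0L)
  }
})

test_that("multi-reference best-hit selection breaks score ties lexicographically", {
  set.seed(33)
  base <- rdna(1000)
  refs <- c(zeta = base, alpha = base)  # identical refs, different ids
  rd <- setNames(substr(base, 101, 300), "r")
  h <- align_reads(rd, refs, recruitment_params(), "DNA")
  expect_identical(nrow(h), 1L)
  expect_identical(h$ref_id, "alpha")
  # without best_hit_only both references report the hit
  h2 <- align_reads(rd, refs, recruitment_params(best_hit_only = FALSE), "DNA")
  expect_identical(sort(h2$ref_id), c("alpha", "zeta"))
})

test_that("raising filters never increases the hit count", {
  set.seed(34)
  ref <- c(refA = rdna(5000))
  reads <- setNames(
    vapply(1:60, function(i) {
      s <- sample(1:4700, 1)
      mutate_seq(substr(ref, s, s + 249), runif(1, 0, 0.25))
    }, character(1)), sprintf("r%02d", 1:60))
  base <- nrow(align_reads(reads, ref, recruitment_params(), "DNA"))
  longer <- nrow(align_reads(reads, ref,
                             recruitment_params(min_hit_len_dna = 200), "DNA"))
  stricter <- nrow(align_reads(reads, ref,
                               recruitment_params(min_identity = 90), "DNA"))
  expect_lte(longer, base)
  expect_lte(stricter, base)
})

test_that("tabular import normalizes reverse-strand coordinates", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\trefA\t98.5\t200\t3\t0\t1\t200\t101\t300\t1e-50\t350",
    "r2\trefA\t95.0\t150\t7\t1\t1\t150\t500\t351\t1e-30\t200"), tf)
  hits <- import_alignments(tf, "tabular")
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$strand, c("+", "-"))
  # sstart > send: strand -, ref_start = send - 1, ref_end = sstart
  expect_identical(hits$ref_start[2], 350L)
  expect_identical(hits$ref_end[2], 500L)
  expect_identical(hits$ref_start[1], 100L)
  expect_identical(hits$ref_end[1], 300L)
  expect_equal(hits$percent_identity, c(98.5, 95.0))
  # empty file
  empty <- tempfile(); file.create(empty)
  expect_identical(nrow(import_alignments(empty, "tabular")), 0L)
  # malformed line is reported with its line number
  bad <- tempfile()
  writeLines(c("r1\trefA\t98.5\t200\t3\t0\t1\t200\t101\t300\t1e-50\t350",
               "r2\trefA\tbroken"), bad)
  expect_error(import_alignments(bad, "tabular"), "line 2")
})

test_that("SAM import recomputes identity from CIGAR and NM and skips unmapped records", {
  sam <- tempfile(fileext = ".sam")
  seq100 <- rdna(100); seq98 <- rdna(98)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:refA\tLN:1000",
    paste("r1", 0, "refA", 11, 60, "100M", "*", 0, 0, seq100,
          strrep("I", 100), "NM:i:2", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, rdna(50), strrep("I", 50),
          sep = "\t"),
    paste("r3", 16, "refA", 51, 60, "50M2D48M", "*", 0, 0, seq98,
          strrep("I", 98), "NM:i:4", sep = "\t")), sam)
  hits <- import_alignments(sam, "sam")
  expect_identical(nrow(hits), 2L)  # unmapped r2 skipped
  r1 <- hits[hits$read_id == "r1", ]
  expect_identical(r1$ref_start, 10L)
  expect_identical(r1$ref_end, 110L)
  expect_equal(r1$percent_identity, 98)   # (100 - 2) / 100
  r3 <- hits[hits$read_id == "r3", ]
  expect_identical(r3$ref_end - r3$ref_start, 100L)  # 50M + 2D + 48M on ref
  expect_identical(r3$aligned_length, 100L)          # gap columns count
  expect_equal(r3$percent_identity, 96)   # NM 4 = 2 mismatches + 2 deleted
  expect_identical(r3$strand, "-")
})

test_that("coverage profiles follow interval arithmetic and conserve spans", {
  hits <- data.frame(read_id = c("a", "b"), ref_id = "r",
                     ref_start = c(0L, 50L), ref_end = c(100L, 150L))
  p <- compute_coverage(hits, "r", 200, "s1")
  expect_identical(p$depth[1:50], rep(1L, 50))
  expect_identical(p$depth[51:100], rep(2L, 50))
  expect_identical(p$depth[101:150], rep(1L, 50))
  expect_identical(p$depth[151:200], rep(0L, 50))
  expect_identical(sum(p$depth), sum(hits$ref_end - hits$ref_start))
  # no hits: all-zero; full-span hit: uniform depth 1
  expect_true(all(compute_coverage(hits[0, ], "r", 100)$depth == 0L))
  full <- data.frame(read_id = "a", ref_id = "r", ref_start = 0L, ref_end = 100L)
  expect_true(all(compute_coverage(full, "r", 100)$depth == 1L))
  # out-of-bounds hit errors
  oob <- data.frame(read_id = "a", ref_id = "r", ref_start = 50L, ref_end = 201L)
  expect_error(compute_coverage(oob, "r", 200), "bounds")
})
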