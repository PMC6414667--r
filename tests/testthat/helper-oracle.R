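# Shared fixtures and the independent alignment oracle.

suppressPackageStartupMessages(library(Biostrings))

# Random DNA string.
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# Substitution-only mutation at divergence d; optionally a few indels.
mutate_seq <- function(s, d, n_indel = 0) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- round(d * length(ch))
  if (n > 0) {
    p <- sample(length(ch), n)
    ch[p] <- vapply(ch[p], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  if (n_indel > 0) for (k in seq_len(n_indel)) {
    if (runif(1) < 0.5) ch <- ch[-sample(length(ch), 1)]
    else ch <- append(ch, sample(c("A", "C", "G", "T"), 1),
                      sample(length(ch), 1))
  }
  paste(ch, collapse = "")
}

# Exhaustive-DP oracle: best local alignment by Biostrings::pairwiseAlignment
# (full Smith-Waterman), with the same scoring convention as the built-in
# aligner.  Returns score, columns, matches and 1-based coordinates.
dp_oracle <- function(read, ref) {
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                      baseOnly = TRUE)
  pa <- pairwiseAlignment(read, ref, type = "local",
                          substitutionMatrix = mat,
                          gapOpening = 5, gapExtension = 2)
  pat <- pattern(pa)
  subj <- subject(pa)
  cols <- nchar(as.character(pat))  # aligned pattern string includes gaps
  list(score = score(pa), cols = cols, matches = nmatch(pa),
       q_start = start(pat), q_end = end(pat),
       s_start = start(subj), s_end = end(subj),
       gapless = cols == width(pat) && cols == width(subj))
}

# Canonical form of a gapless local alignment modulo co-optimality: extend
# both ends maximally along the diagonal by net-zero-score segments, so two
# co-optimal gapless alignments on the same diagonal compare identically.
# Coordinates are 0-based half-open.
canonical_gapless <- function(read, ref, qs, qe, ss, se) {
  rdc <- strsplit(read, "", fixed = TRUE)[[1]]
  rfc <- strsplit(ref, "", fixed = TRUE)[[1]]
  d <- 0; k <- 0; bestk <- 0
  while (qe + k < length(rdc) && se + k < length(rfc)) {
    k <- k + 1
    d <- d + if (rdc[qe + k] == rfc[se + k]) 1 else -2
    if (d == 0) bestk <- k
    if (d < -60) break
  }
  qe <- qe + bestk; se <- se + bestk
  d <- 0; k <- 0; bestk <- 0
  while (qs - k >= 1 && ss - k >= 1) {
    k <- k + 1
    d <- d + if (rdc[qs - k + 1] == rfc[ss - k + 1]) 1 else -2
    if (d == 0) bestk <- k
    if (d < -60) break
  }
  qs <- qs - bestk; ss <- ss - bestk
  matches <- sum(rdc[(qs + 1):qe] == rfc[(ss + 1):se])
  list(matches = matches, cols = qe - qs,
       identity = 100 * matches / (qe - qs))
}

# A small marker reference set reused across marker tests.
test_marker_refs <- function(seed = 11) make_marker_refs(seed = seed)
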