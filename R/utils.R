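#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a tab-separated table with '#' comment headers
#'
#' All pipeline TSV outputs are written through this helper so that headers
#' uniformly carry the tool version and the coordinate convention, and
#' re-runs are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param comments character vector of comment lines (without the leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Deterministic per-stage seed derived from a master seed; kept below 2^31.
#' @noRd
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 12345) %% 2147483647)
}
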