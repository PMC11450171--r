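# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (alphabet A/C/G/T/N).
#' @return Character vector of the same length with each sequence
#'   reverse-complemented.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences
#'
#' @param n Number of sequences.
#' @param len Length of each sequence in bp.
#' @return Character vector of `n` sequences of length `len`.
#' @export
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so library functions do not perturb user-level randomness.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate that sequences use the DNA alphabet only.
check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# C-locale deterministic sort, independent of the session locale.
sort_c <- function(x) sort(x, method = "radix")

# Stable integer fold assignment: n items into k folds, shuffled.
fold_ids <- function(n, k) sample(rep_len(seq_len(k), n))
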