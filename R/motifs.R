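# Position weight matrices: exact p-value-calibrated scanning.
#
# A PWM is scored as the sum of per-position log2 odds log2(p/bg). Scores are
# discretised onto a fixed lattice (default 1e-4 log2 units); the null score
# distribution under i.i.d. background is then computed exactly by dynamic
# programming over that lattice, and the match threshold is the smallest
# lattice score whose null exceedance probability is <= the p-value cutoff.
# The discretised score is the score definition used both for calibration and
# for scanning, so the two are always consistent.

#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix Numeric matrix, positions x 4, columns A, C, G, T. Rows may
#'   be probabilities (summing to 1) or counts; counts are normalised.
#' @param background Background base frequencies (A, C, G, T), summing to 1.
#' @param pseudo_prob Small probability added to every cell (then
#'   renormalised) so log odds stay finite at zero cells.
#' @return An object of class `pwm`.
#' @examples
#' pwm("onebase", matrix(c(1, 0, 0, 0), 1, 4))
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4), pseudo_prob = 1e-3) {
  m <- as.matrix(matrix)
  if (ncol(m) != 4 || nrow(m) < 1) stop("PWM matrix must be positions x 4")
  if (any(m < 0) || any(!is.finite(m))) stop("PWM cells must be finite and >= 0")
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("PWM has an all-zero position")
  m <- m / rs
  colnames(m) <- DNA_BASES
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 4 positive frequencies summing to 1")
  }
  structure(list(name = as.character(name), matrix = m,
                 background = as.numeric(background),
                 pseudo_prob = pseudo_prob),
            class = "pwm")
}

#' @rdname pwm
#' @param x A `pwm`.
#' @param ... Unused.
#' @method print pwm
#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d positions), consensus %s\n",
              x$name, nrow(x$matrix),
              paste(DNA_BASES[max.col(x$matrix)], collapse = "")))
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' Each position assigns probability `p` to the consensus base and
#' `(1 - p)/3` to the others.
#'
#' @param name Motif name.
#' @param consensus DNA consensus string (A/C/G/T).
#' @param p Probability of the consensus base at each position.
#' @param ... Passed to [pwm()].
#' @return A `pwm`.
#' @export
consensus_pwm <- function(name, consensus, p = 0.95, ...) {
  check_dna(consensus, what = "consensus")
  bases <- match(strsplit(consensus, "")[[1]], DNA_BASES)
  m <- matrix((1 - p) / 3, length(bases), 4)
  m[cbind(seq_along(bases), bases)] <- p
  pwm(name, m, ...)
}

# Discretised per-position log2-odds scores (integer lattice units).
pwm_int_scores <- function(x, granularity = 1e-4) {
  p <- (x$matrix + x$pseudo_prob)
  p <- p / rowSums(p)
  s <- log2(sweep(p, 2, x$background, "/"))
  storage.mode(s) <- "double"
  round(s / granularity)
}

# Exact null score distribution by DP: returns list(lo, prob) where prob[i]
# is P(score == lo + i - 1) under i.i.d. background.
pwm_null_distribution <- function(S, background) {
  lo <- 0L
  prob <- 1
  for (j in seq_len(nrow(S))) {
    sj <- S[j, ]
    lo_new <- lo + min(sj)
    hi_new <- lo + length(prob) - 1L + max(sj)
    acc <- numeric(hi_new - lo_new + 1L)
    for (b in 1:4) {
      at <- (lo + sj[b] - lo_new + 1L):(lo + sj[b] - lo_new + length(prob))
      acc[at] <- acc[at] + prob * background[b]
    }
    lo <- as.integer(lo_new)
    prob <- acc
  }
  list(lo = lo, prob = prob)
}

#' Background-calibrated PWM score threshold
#'
#' Computes the exact null distribution of the discretised log2-odds score
#' under i.i.d. background by dynamic programming, and returns the smallest
#' score whose null exceedance probability is at most `p_cutoff`.
#'
#' @param x A [pwm()].
#' @param p_cutoff Per-window null probability cutoff (default `5e-4`, the
#'   screen's scanning stringency).
#' @param granularity Score lattice spacing in log2 units.
#' @return A list with `threshold` (integer lattice score), `p_exceed`
#'   (exact null probability of scoring at or above it), `granularity`, and
#'   `scores` (the positions x 4 integer score matrix used for scanning).
#' @export
pwm_threshold <- function(x, p_cutoff = 5e-4, granularity = 1e-4) {
  stopifnot(inherits(x, "pwm"))
  if (!(p_cutoff > 0 && p_cutoff <= 1)) stop("p_cutoff must be in (0, 1]")
  S <- pwm_int_scores(x, granularity)
  nd <- pwm_null_distribution(S, x$background)
  tail_p <- rev(cumsum(rev(nd$prob)))
  ok <- which(tail_p <= p_cutoff)
  if (!length(ok)) {
    thr <- nd$lo + length(nd$prob)   # above the maximum: nothing matches
    pe <- 0
  } else {
    thr <- nd$lo + ok[1] - 1L
    pe <- tail_p[ok[1]]
  }
  list(threshold = thr, p_exceed = pe, granularity = granularity, scores = S)
}

# Integer window scores of `codes` (1..4, NA for N) against score matrix S.
window_scores <- function(codes, S) {
  k <- nrow(S)
  W <- length(codes) - k + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (j in seq_len(k)) {
    sc <- sc + S[j, ][codes[j:(j + W - 1L)]]
  }
  sc
}

# Match start intervals on both strands, in forward-strand coordinates.
scan_positions_prepared <- function(seq, thr) {
  k <- nrow(thr$scores)
  n <- nchar(seq)
  if (k > n) return(data.frame(start = integer(0), end = integer(0),
                               strand = character(0)))
  fwd <- match(strsplit(seq, "")[[1]], DNA_BASES)
  rev_codes <- match(strsplit(revcomp(seq), "")[[1]], DNA_BASES)
  sf <- window_scores(fwd, thr$scores)
  sr <- window_scores(rev_codes, thr$scores)
  hf <- which(!is.na(sf) & sf >= thr$threshold)
  hr <- which(!is.na(sr) & sr >= thr$threshold)
  out <- data.frame(
    start = c(hf, n - (hr + k - 1L) + 1L),
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    stringsAsFactors = FALSE
  )
  out$end <- out$start + k - 1L
  out[order(out$start, out$strand), c("start", "end", "strand")]
}

#' Count PWM matches in a sequence
#'
#' Scans both strands of `seq` with a background-calibrated threshold (see
#' [pwm_threshold()]) and counts windows scoring at or above it. Overlapping
#' windows are counted independently; windows containing non-ACGT characters
#' never match.
#'
#' @param seq DNA string.
#' @param x A [pwm()].
#' @param p_cutoff Null p-value cutoff for the match threshold.
#' @param granularity Score lattice spacing in log2 units.
#' @return Integer match count (both strands).
#' @examples
#' m <- consensus_pwm("gaga", "GAGAG")
#' scan_motifs(strrep("GAGAG", 3), m)
#' @export
scan_motifs <- function(seq, x, p_cutoff = 5e-4, granularity = 1e-4) {
  if (nrow(x$matrix) > nchar(seq)) {
    warning("PWM longer than sequence; count is 0")
    return(0L)
  }
  thr <- pwm_threshold(x, p_cutoff, granularity)
  nrow(scan_positions_prepared(seq, thr))
}

#' Locate PWM matches in a sequence
#'
#' Like [scan_motifs()] but returns the match coordinates.
#'
#' @inheritParams scan_motifs
#' @return Data frame with `start`, `end` (1-based, inclusive, forward-strand
#'   coordinates) and `strand`.
#' @export
scan_positions <- function(seq, x, p_cutoff = 5e-4, granularity = 1e-4) {
  thr <- pwm_threshold(x, p_cutoff, granularity)
  scan_positions_prepared(seq, thr)
}

#' Motif match counts for a set of sequences
#'
#' @param seqs Named character vector of DNA sequences (e.g. a pool's
#'   candidates).
#' @param pwms List of [pwm()] objects (or a single `pwm`).
#' @param p_cutoff,granularity Passed to [pwm_threshold()]; each threshold is
#'   computed once per PWM.
#' @return Integer matrix, sequences x motifs, of match counts (both
#'   strands).
#' @export
motif_count_matrix <- function(seqs, pwms, p_cutoff = 5e-4,
                               granularity = 1e-4) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nm <- vapply(pwms, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate PWM names")
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(names(seqs), nm))
  for (j in seq_along(pwms)) {
    thr <- pwm_threshold(pwms[[j]], p_cutoff, granularity)
    if (nrow(pwms[[j]]$matrix) > min(nchar(seqs))) {
      warning(sprintf("PWM '%s' longer than some sequences; their counts are 0",
                      nm[j]))
    }
    out[, j] <- vapply(seqs, function(s) {
      if (nrow(thr$scores) > nchar(s)) 0L
      else nrow(scan_positions_prepared(s, thr))
    }, integer(1))
  }
  out
}

#' Read and write PWM text files
#'
#' The format is one or more matrices per file: a header line `>name`
#' followed by one line per position with four whitespace-separated values
#' (A, C, G, T), either probabilities or counts.
#'
#' @param paths Character vector of PWM files, or a directory (all `*.pwm`
#'   and `*.txt` files are read).
#' @param ... Passed to [pwm()] (background, pseudo-probability).
#' @return `read_pwms` returns a named list of `pwm` objects.
#' @export
read_pwms <- function(paths, ...) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pwm|txt)$", full.names = TRUE)
  }
  out <- list()
  for (f in paths) {
    lines <- trimws(readLines(f))
    lines <- lines[nzchar(lines)]
    heads <- grep("^>", lines)
    if (!length(heads)) stop("no '>' header in PWM file: ", f)
    bounds <- c(heads, length(lines) + 1L)
    for (i in seq_along(heads)) {
      name <- sub("^>\\s*", "", lines[heads[i]])
      body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
      rows <- lapply(strsplit(body, "\\s+"), as.numeric)
      if (any(lengths(rows) != 4)) {
        stop(sprintf("PWM '%s' in %s: every position needs 4 values", name, f))
      }
      out[[name]] <- pwm(name, do.call(rbind, rows), ...)
    }
  }
  out
}

#' @rdname read_pwms
#' @param x A [pwm()].
#' @param path Output file.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  writeLines(apply(format(x$matrix, digits = 6), 1, paste, collapse = " "),
             con)
  invisible(path)
}

#' Synthetic demonstration PWM collection
#'
#' Roughly twenty motifs: consensus-based PWMs resembling well-known
#' Drosophila regulators (GAGA-factor `GAGAG`, a Twist-like E-box `CATATG`,
#' AP-1, GATA, Dref, SREBP-like CACGTG) plus random-composition PWMs. These
#' are synthetic stand-ins for a curated motif collection, intended for
#' simulation and testing.
#'
#' @param n_random Number of additional random PWMs.
#' @param seed Integer seed for the random PWMs.
#' @return Named list of [pwm()] objects.
#' @export
demo_pwms <- function(n_random = 14, seed = 1) {
  named <- list(
    consensus_pwm("Trl_like", "GAGAG"),
    consensus_pwm("Twist_like", "CATATG"),
    consensus_pwm("AP1_like", "TGACTCA"),
    consensus_pwm("GATA_like", "GATAAG"),
    consensus_pwm("Dref_like", "TATCGATA"),
    consensus_pwm("Ebox_like", "CACGTG")
  )
  rand <- with_seed(seed, lapply(seq_len(n_random), function(i) {
    k <- sample(5:9, 1)
    m <- matrix(rgamma(4 * k, shape = 0.5), k, 4)
    pwm(sprintf("rand%02d", i), m / rowSums(m))
  }))
  all <- c(named, rand)
  setNames(all, vapply(all, function(p) p$name, character(1)))
}
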