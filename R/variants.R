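# Motif paste/mutate variant construction: replace motif instances with
# motif-free random stretches, or paste consensus copies into sequences,
# rejection-sampling against a forbidden PWM set.

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv[i, 1] <= out[j, 2] + 1L) {
      out[j, 2] <- max(out[j, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

overlaps <- function(ms, me, s, e) ms <= e & me >= s

as_interval_matrix <- function(matches) {
  if (is.data.frame(matches)) {
    iv <- cbind(matches$start, matches$end)
  } else if (is.list(matches)) {
    iv <- do.call(rbind, lapply(matches, function(x) x[1:2]))
  } else {
    iv <- matrix(matches, ncol = 2, byrow = TRUE)
  }
  if (is.null(iv) || !length(iv)) return(matrix(integer(0), 0, 2))
  storage.mode(iv) <- "integer"
  iv
}

#' Replace motif instances with motif-free random sequence
#'
#' Overwrites each match interval with random bases, rejection-sampling until
#' no forbidden PWM matches overlap the replaced intervals. Positions outside
#' the intervals are untouched and the sequence length is preserved.
#' Overlapping or adjacent intervals are merged before replacement, since
#' replacing them independently would be order-dependent.
#'
#' @param seq DNA string.
#' @param matches Match intervals to erase: a data frame with `start`/`end`
#'   columns (as from [scan_positions()]), a list of `c(start, end)` pairs,
#'   or a 2-column matrix. 1-based inclusive coordinates. Empty input returns
#'   `seq` unchanged.
#' @param forbidden_pwms List of [pwm()] objects that must not match across
#'   the replaced intervals.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param p_cutoff,granularity Match stringency, as in [scan_motifs()].
#' @param max_attempts Rejection-sampling budget per interval.
#' @return The edited DNA string.
#' @export
mutate_motifs <- function(seq, matches, forbidden_pwms, seed = NULL,
                          p_cutoff = 5e-4, granularity = 1e-4,
                          max_attempts = 1000L) {
  n <- nchar(seq)
  iv <- as_interval_matrix(matches)
  if (is.null(iv) || nrow(iv) == 0) return(seq)
  if (any(iv[, 1] < 1L | iv[, 2] > n | iv[, 1] > iv[, 2])) {
    stop("match intervals out of bounds")
  }
  iv <- merge_intervals(iv)
  thrs <- lapply(forbidden_pwms, pwm_threshold,
                 p_cutoff = p_cutoff, granularity = granularity)
  maxk <- if (length(thrs)) max(vapply(thrs, function(t) nrow(t$scores),
                                       integer(1))) else 1L
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    for (r in seq_len(nrow(iv))) {
      s <- iv[r, 1]; e <- iv[r, 2]
      ws <- max(1L, s - maxk + 1L); we <- min(n, e + maxk - 1L)
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- chars
        cand[s:e] <- sample(DNA_BASES, e - s + 1L, replace = TRUE)
        window <- paste(cand[ws:we], collapse = "")
        hit <- FALSE
        for (t in thrs) {
          pos <- scan_positions_prepared(window, t)
          if (nrow(pos) &&
              any(overlaps(pos$start + ws - 1L, pos$end + ws - 1L, s, e))) {
            hit <- TRUE
            break
          }
        }
        if (!hit) {
          chars <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not clear interval [%d, %d] of forbidden motifs in %d attempts",
                     s, e, max_attempts))
      }
    }
    out <- paste(chars, collapse = "")
    # Global verification across interval boundaries.
    for (t in thrs) {
      pos <- scan_positions_prepared(out, t)
      if (nrow(pos)) {
        for (r in seq_len(nrow(iv))) {
          if (any(overlaps(pos$start, pos$end, iv[r, 1], iv[r, 2]))) {
            stop("forbidden motif persists across interval boundary")
          }
        }
      }
    }
    out
  })
}

#' Paste motif consensus copies into a sequence
#'
#' Overwrites `n_copies` non-overlapping, uniformly sampled placements of
#' `motif_consensus` into `seq` (length is preserved). Placements are drawn
#' sequentially, uniformly among the positions not overlapping previously
#' chosen copies. When `forbidden_pwms` is given, the edit is
#' rejection-sampled so that no new forbidden-PWM match is created outside
#' the pasted copies themselves.
#'
#' @param seq DNA string.
#' @param motif_consensus DNA string to paste verbatim.
#' @param n_copies Number of copies (>= 1).
#' @param forbidden_pwms Optional list of [pwm()] objects.
#' @param seed Integer seed; deterministic given the seed.
#' @param p_cutoff,granularity Match stringency for the forbidden check.
#' @param max_attempts Rejection-sampling budget over whole placements.
#' @return The edited DNA string, with attribute `"paste_starts"` giving the
#'   1-based start of each pasted copy.
#' @export
paste_motifs <- function(seq, motif_consensus, n_copies,
                         forbidden_pwms = NULL, seed = NULL,
                         p_cutoff = 5e-4, granularity = 1e-4,
                         max_attempts = 100L) {
  n <- nchar(seq)
  m <- nchar(motif_consensus)
  check_dna(motif_consensus, what = "motif consensus")
  if (n_copies < 1) stop("n_copies must be >= 1")
  if (m > n) stop("motif does not fit in the sequence")
  thrs <- lapply(forbidden_pwms, pwm_threshold,
                 p_cutoff = p_cutoff, granularity = granularity)
  base_matches <- lapply(thrs, function(t) scan_positions_prepared(seq, t))
  motif_chars <- strsplit(motif_consensus, "")[[1]]
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      avail <- seq_len(n - m + 1L)
      starts <- integer(0)
      for (i in seq_len(n_copies)) {
        if (!length(avail)) break
        s <- if (length(avail) == 1L) avail else sample(avail, 1L)
        starts <- c(starts, s)
        avail <- avail[abs(avail - s) >= m]
      }
      if (length(starts) < n_copies) next
      chars <- strsplit(seq, "")[[1]]
      for (s in starts) chars[s:(s + m - 1L)] <- motif_chars
      out <- paste(chars, collapse = "")
      new_hit <- FALSE
      for (ti in seq_along(thrs)) {
        pos <- scan_positions_prepared(out, thrs[[ti]])
        if (!nrow(pos)) next
        inside <- Reduce(`|`, lapply(starts, function(s) {
          pos$start >= s & pos$end <= s + m - 1L
        }), accumulate = FALSE)
        old <- paste(base_matches[[ti]]$start, base_matches[[ti]]$strand)
        known <- paste(pos$start, pos$strand) %in% old
        if (any(!inside & !known)) {
          new_hit <- TRUE
          break
        }
      }
      if (!new_hit) {
        return(structure(out, paste_starts = sort(starts)))
      }
    }
    stop(sprintf("could not place %d non-overlapping copies without new forbidden matches in %d attempts",
                 n_copies, max_attempts))
  })
}
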