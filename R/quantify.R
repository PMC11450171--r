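# Read-to-construct assignment, UMI collapsing and pair-level filters.

# Distinct construct ends and a lookup from (end5, end3) to pair_id.
reference_ends <- function(reference, read_length) {
  if (!length(reference)) stop("empty construct reference")
  if (read_length > min(nchar(reference))) {
    stop("reads longer than the shortest construct")
  }
  end5 <- substr(reference, 1L, read_length)
  end3 <- revcomp(substr(reference, nchar(reference) - read_length + 1L,
                         nchar(reference)))
  u5 <- unique(end5)
  u3 <- unique(end3)
  list(u5 = u5, u3 = u3,
       e5_of = match(end5, u5), e3_of = match(end3, u3),
       pair_id = names(reference))
}

# Char matrix (reads x L) from equal-length strings.
read_matrix <- function(reads) {
  L <- unique(nchar(reads))
  if (length(L) != 1) stop("reads must have equal length")
  matrix(unlist(strsplit(reads, ""), use.names = FALSE),
         nrow = length(reads), byrow = TRUE)
}

# For each read, the set of candidate end indices within the mismatch budget,
# returned as a reads x ends logical matrix.
end_match_matrix <- function(reads, ends, max_mismatches) {
  rm <- read_matrix(reads)
  out <- matrix(FALSE, length(reads), length(ends))
  for (j in seq_along(ends)) {
    ev <- strsplit(ends[j], "")[[1]]
    mism <- rowSums(rm != matrix(ev, nrow(rm), length(ev), byrow = TRUE))
    out[, j] <- mism <= max_mismatches
  }
  out
}

#' Assign read pairs to constructs
#'
#' A read pair is assigned to a construct when read 1 matches the
#' construct's 5' end in forward orientation and read 2 matches its 3' end
#' in reverse-complement orientation, each with at most `max_mismatches`
#' substitutions. Read pairs compatible with more than one construct are
#' left unassigned (uniqueness required), as are pairs whose two reads
#' implicate different constructs.
#'
#' @param read1,read2 Character vectors of equal-length reads (same length
#'   within each vector).
#' @param reference Named construct sequences from [build_reference()].
#' @param max_mismatches Per-read substitution budget (default 3).
#' @return Character vector of `pair_id`s, `NA` where unassigned.
#' @export
assign_read_pairs <- function(read1, read2, reference, max_mismatches = 3L) {
  if (length(read1) != length(read2)) stop("read1/read2 length mismatch")
  if (!length(read1)) return(character(0))
  ends <- reference_ends(reference, nchar(read1[1]))
  m5 <- end_match_matrix(read1, ends$u5, max_mismatches)
  m3 <- end_match_matrix(read2, ends$u3, max_mismatches)
  # constructs grouped by (end5 index, end3 index); a read pair is assigned
  # iff exactly one construct is compatible with its matching end sets
  n5 <- length(ends$u5)
  combo_of_construct <- (ends$e5_of - 1L) + n5 * (ends$e3_of - 1L)
  combo_counts <- tabulate(combo_of_construct + 1L,
                           nbins = n5 * length(ends$u3))
  construct_of_combo <- rep(NA_integer_, n5 * length(ends$u3))
  construct_of_combo[combo_of_construct + 1L] <- seq_along(reference)
  out <- rep(NA_character_, length(read1))
  k5 <- rowSums(m5)
  k3 <- rowSums(m3)
  # fast path: reads matching exactly one end on each side
  fast <- which(k5 == 1L & k3 == 1L)
  if (length(fast)) {
    e5 <- max.col(m5[fast, , drop = FALSE], ties.method = "first")
    e3 <- max.col(m3[fast, , drop = FALSE], ties.method = "first")
    combo <- (e5 - 1L) + n5 * (e3 - 1L) + 1L
    uniq <- combo_counts[combo] == 1L
    out[fast[uniq]] <- ends$pair_id[construct_of_combo[combo[uniq]]]
  }
  for (i in which(k5 > 1L | k3 > 1L)) {
    if (k5[i] == 0L || k3[i] == 0L) next
    combos <- as.vector(outer(which(m5[i, ]) - 1L,
                              n5 * (which(m3[i, ]) - 1L), "+")) + 1L
    if (sum(combo_counts[combos]) == 1L) {
      hit <- combos[combo_counts[combos] == 1L]
      out[i] <- ends$pair_id[construct_of_combo[hit]]
    }
  }
  out
}

#' Collapse UMIs into a pair count table
#'
#' Counts the number of distinct UMI strings per (pair, replicate, channel).
#' UMIs containing `N` are dropped. The result is order-independent: any
#' permutation of the input records yields the same table.
#'
#' @param assignments Data frame with columns `pair_id`, `replicate`,
#'   `channel`, `umi`.
#' @return Count table with columns `pair_id`, `replicate`, `channel`,
#'   `umi_count`, sorted by pair, channel, replicate.
#' @export
collapse_umis <- function(assignments) {
  cols <- c("pair_id", "replicate", "channel", "umi")
  if (!all(cols %in% names(assignments))) {
    stop("assignments need columns: ", paste(cols, collapse = ", "))
  }
  a <- assignments[!is.na(assignments$pair_id), cols]
  if (!nrow(a)) {
    return(data.frame(pair_id = character(0), replicate = integer(0),
                      channel = character(0), umi_count = integer(0)))
  }
  check_dna(a$umi, allow_n = TRUE, what = "UMI")
  if (length(unique(nchar(a$umi))) != 1) stop("inconsistent UMI lengths")
  a <- a[!grepl("N", a$umi, fixed = TRUE), ]
  key <- paste(a$pair_id, a$replicate, a$channel, sep = "\r")
  uniq <- !duplicated(paste(key, a$umi, sep = "\r"))
  counts <- table(key[uniq])
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  out <- data.frame(pair_id = parts[, 1],
                    replicate = as.integer(parts[, 2]),
                    channel = parts[, 3],
                    umi_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pair_id, out$channel, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Quantify a set of paired FASTQ files
#'
#' Runs [assign_read_pairs()] on each replicate/channel FASTQ pair (UMI taken
#' from the read header after the last `:`) and collapses UMIs into a count
#' table.
#'
#' @param manifest Data frame with `replicate`, `channel`, `r1`, `r2`
#'   columns, as returned by [emit_reads()].
#' @param reference Named construct sequences.
#' @param max_mismatches Per-read substitution budget.
#' @return A pair count table (see [collapse_umis()]).
#' @export
quantify_reads <- function(manifest, reference, max_mismatches = 3L) {
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    f1 <- read_fastq(manifest$r1[i])
    f2 <- read_fastq(manifest$r2[i])
    pid <- assign_read_pairs(f1$sequence, f2$sequence, reference,
                             max_mismatches)
    recs[[i]] <- data.frame(
      pair_id = pid,
      replicate = manifest$replicate[i],
      channel = manifest$channel[i],
      umi = sub(".*:", "", f1$header),
      stringsAsFactors = FALSE)
  }
  collapse_umis(do.call(rbind, recs))
}

#' Apply the pair-level inclusion filter
#'
#' Retains only heterotypic pairs with at least `min_input` UMI-collapsed
#' counts in every input replicate. RNA counts of retained pairs are left
#' untouched. Idempotent.
#'
#' @param counts Long-format count table (`pair_id`, `replicate`, `channel`,
#'   `umi_count`).
#' @param design The `pair_design`; pairs absent from it are an error.
#' @param min_input Minimum input UMIs per input replicate (default 5).
#' @return The filtered count table (a row subset of the input).
#' @export
filter_pairs <- function(counts, design, min_input = 5L) {
  if (!nrow(counts)) return(counts)
  idx <- match(counts$pair_id, design$pair_id)
  if (anyNA(idx)) {
    stop("pairs missing from design: ",
         paste(head(unique(counts$pair_id[is.na(idx)]), 3), collapse = ", "))
  }
  hetero <- !design$homotypic[idx]
  inp <- counts$channel == "input"
  n_inp_reps <- length(unique(counts$replicate[inp]))
  ok_input <- counts$pair_id[inp & counts$umi_count >= min_input]
  enough <- names(which(table(ok_input) == n_inp_reps))
  # a pair must also be observed in every input replicate
  seen <- table(counts$pair_id[inp])
  full <- names(which(seen == n_inp_reps))
  keep_ids <- intersect(enough, full)
  out <- counts[hetero & counts$pair_id %in% keep_ids, ]
  rownames(out) <- NULL
  out
}
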