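# Pair designs: ordered 5'x3' fusion constructs around an inert spacer.

#' Enumerate all ordered candidate pairs
#'
#' Builds the full pair design: every ordered combination of two pool
#' candidates fused to the 5' and 3' ends of a spacer, so a pool of n
#' candidates yields exactly n^2 rows (850 enhancers + 150 controls give the
#' screen's one million combinations). Homotypic rows (the same candidate on
#' both sides) are flagged; downstream quantification restricts itself to
#' heterotypic pairs.
#'
#' @param pool A [candidate_pool()], or a character vector of unique ids.
#' @param spacer_id Identifier of the spacer separating the two candidates.
#' @return A data frame of class `pair_design` with columns `pair_id`
#'   (`"{id5}__{id3}"`), `id5`, `id3`, `spacer_id`, `homotypic`, ordered
#'   lexicographically by `id5` then `id3` (C locale).
#' @examples
#' enumerate_pairs(c("X", "Y"))
#' @export
enumerate_pairs <- function(pool, spacer_id = "spacer300") {
  ids <- if (inherits(pool, "data.frame")) pool$id else as.character(pool)
  if (!length(ids)) stop("pool is empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate candidate ids: ", paste(dup, collapse = ", "))
  }
  ids <- sort_c(ids)
  n <- length(ids)
  id5 <- rep(ids, each = n)
  id3 <- rep.int(ids, n)
  out <- data.frame(
    pair_id = paste0(id5, "__", id3),
    id5 = id5, id3 = id3,
    spacer_id = spacer_id,
    homotypic = id5 == id3,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_design", "data.frame")
  out
}

#' Read and write pair designs
#'
#' TSV round trip for [enumerate_pairs()] output (columns `pair_id`, `id5`,
#' `id3`, `spacer_id`, `homotypic`).
#'
#' @param design A `pair_design` data frame.
#' @param path TSV file path.
#' @return `read_design` returns the design; `write_design` the path,
#'   invisibly.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pair_id = "character", id5 = "character",
                                   id3 = "character", spacer_id = "character",
                                   homotypic = "logical"))
  class(out) <- c("pair_design", "data.frame")
  out
}

#' Build construct reference sequences for a pair design
#'
#' Concatenates, for every design row, the 5' flank, the 5' candidate, the
#' spacer, the 3' candidate and the 3' flank into the full construct against
#' which sequencing reads are assigned.
#'
#' @param design A `pair_design` from [enumerate_pairs()].
#' @param pool The [candidate_pool()] resolving `id5`/`id3`.
#' @param spacers Named character vector mapping `spacer_id` to spacer
#'   sequence.
#' @param flank5,flank3 Constant flanking sequences (may be `""`).
#' @return Named character vector of construct sequences; names are
#'   `pair_id`s, in design row order.
#' @export
build_reference <- function(design, pool, spacers, flank5 = "", flank3 = "") {
  i5 <- match(design$id5, pool$id)
  i3 <- match(design$id3, pool$id)
  if (anyNA(i5) || anyNA(i3)) {
    bad <- unique(c(design$id5[is.na(i5)], design$id3[is.na(i3)]))
    stop("design ids not present in pool: ", paste(bad, collapse = ", "))
  }
  sp <- spacers[design$spacer_id]
  if (anyNA(sp)) {
    stop("unregistered spacer id(s): ",
         paste(unique(design$spacer_id[is.na(sp)]), collapse = ", "))
  }
  check_dna(c(flank5, flank3, unname(spacers)), what = "flank/spacer")
  setNames(
    paste0(flank5, pool$sequence[i5], sp, pool$sequence[i3], flank3),
    design$pair_id
  )
}

#' Write a construct reference to FASTA
#'
#' @param reference Named character vector from [build_reference()].
#' @param path Output FASTA path.
#' @return The path, invisibly. Output is byte-identical across calls for
#'   identical input.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a construct reference from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of construct sequences.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
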