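# Candidate pools: the sets of 249-bp sequences whose individual and
# combined activities the screen measures.

#' Construct a candidate pool
#'
#' A candidate pool is a data frame with one row per 249-bp candidate
#' sequence, each labelled as putative enhancer or negative control and, when
#' known, with its regulatory program and genomic origin.
#'
#' @param id Character vector of unique candidate identifiers.
#' @param sequence Character vector of DNA sequences (A/C/G/T).
#' @param cls Class label per candidate: `"enhancer"` or `"control"`.
#' @param program Regulatory program label: one of `"developmental"`,
#'   `"housekeeping"`, `"shared"`, `"inducible"`, `"osc-specific"`, `"none"`.
#' @param chrom,start,end,assembly Optional genomic origin (0-based
#'   half-open coordinates); `NA` when the candidate is synthetic.
#' @param expected_length Expected candidate length in bp (default 249, the
#'   oligo design length). Sequences of a different length are only accepted
#'   when flagged in `variant`.
#' @param variant Logical vector flagging candidates allowed to deviate from
#'   `expected_length` (e.g. engineered variants).
#' @return A data frame of class `candidate_pool` with columns `id`,
#'   `sequence`, `cls`, `program`, `chrom`, `start`, `end`, `assembly`,
#'   `variant`.
#' @examples
#' candidate_pool(c("E1", "C1"),
#'                c(strrep("A", 249), strrep("C", 249)),
#'                cls = c("enhancer", "control"))
#' @export
candidate_pool <- function(id, sequence, cls,
                           program = "none",
                           chrom = NA_character_, start = NA_integer_,
                           end = NA_integer_, assembly = NA_character_,
                           expected_length = 249L,
                           variant = FALSE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n) stop("id and sequence lengths differ")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate candidate ids: ", paste(dup, collapse = ", "))
  }
  check_dna(sequence, what = "candidate sequence")
  cls <- rep_len(as.character(cls), n)
  if (!all(cls %in% c("enhancer", "control"))) {
    stop("cls must be 'enhancer' or 'control'")
  }
  programs <- c("developmental", "housekeeping", "shared", "inducible",
                "osc-specific", "none")
  program <- rep_len(as.character(program), n)
  if (!all(program %in% programs)) {
    stop("unknown program label(s): ",
         paste(unique(setdiff(program, programs)), collapse = ", "))
  }
  variant <- rep_len(as.logical(variant), n)
  lens <- nchar(sequence)
  off <- lens != expected_length & !variant
  if (any(off)) {
    stop(sprintf("candidate %s has length %d, expected %d (flag variant = TRUE to allow)",
                 id[which(off)[1]], lens[which(off)[1]], expected_length))
  }
  out <- data.frame(
    id = id, sequence = sequence, cls = cls, program = program,
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    assembly = rep_len(as.character(assembly), n),
    variant = variant,
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_pool", "data.frame")
  out
}

#' Generate a random candidate pool
#'
#' Builds a synthetic pool of random-sequence enhancers (`E0001`, ...) and
#' negative controls (`C0001`, ...) for simulation and testing.
#'
#' @param n_enhancers,n_controls Number of enhancer and control candidates.
#' @param length Candidate length in bp.
#' @param seed Optional integer seed for reproducibility.
#' @param program Program label applied to the enhancers.
#' @return A [candidate_pool()].
#' @export
random_pool <- function(n_enhancers, n_controls, length = 249L, seed = NULL,
                        program = "developmental") {
  with_seed(seed, {
    n <- n_enhancers + n_controls
    ids <- c(sprintf("E%04d", seq_len(n_enhancers)),
             sprintf("C%04d", seq_len(n_controls)))
    candidate_pool(
      id = ids,
      sequence = random_dna(n, length),
      cls = rep(c("enhancer", "control"), c(n_enhancers, n_controls)),
      program = rep(c(program, "none"), c(n_enhancers, n_controls)),
      expected_length = as.integer(length)
    )
  })
}

#' Read and write candidate pools
#'
#' Pools are stored as a FASTA file of sequences plus a TSV metadata table
#' with columns `id`, `cls`, `program`, `chrom`, `start`, `end`, `assembly`,
#' `variant`.
#'
#' @param fasta Path to the pool FASTA file.
#' @param meta Path to the pool metadata TSV.
#' @param pool A [candidate_pool()] (for `write_pool`).
#' @param expected_length Expected candidate length, passed to
#'   [candidate_pool()].
#' @return `read_pool` returns a [candidate_pool()]; `write_pool` returns the
#'   paths invisibly.
#' @export
read_pool <- function(fasta, meta, expected_length = 249L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  md <- read.delim(meta, stringsAsFactors = FALSE)
  need <- c("id", "cls", "program")
  if (!all(need %in% names(md))) {
    stop("pool metadata must contain columns: ", paste(need, collapse = ", "))
  }
  idx <- match(md$id, names(seqs))
  if (anyNA(idx)) {
    stop("metadata ids missing from FASTA: ",
         paste(md$id[is.na(idx)], collapse = ", "))
  }
  candidate_pool(
    id = md$id, sequence = as.character(seqs[idx]), cls = md$cls,
    program = md$program,
    chrom = if ("chrom" %in% names(md)) md$chrom else NA,
    start = if ("start" %in% names(md)) md$start else NA,
    end = if ("end" %in% names(md)) md$end else NA,
    assembly = if ("assembly" %in% names(md)) md$assembly else NA,
    expected_length = expected_length,
    variant = if ("variant" %in% names(md)) md$variant else FALSE
  )
}

#' @rdname read_pool
#' @export
write_pool <- function(pool, fasta, meta) {
  stopifnot(inherits(pool, "candidate_pool"))
  ss <- Biostrings::DNAStringSet(setNames(pool$sequence, pool$id))
  Biostrings::writeXStringSet(ss, fasta)
  write.table(pool[, setdiff(names(pool), "sequence")], meta,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, meta = meta))
}
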