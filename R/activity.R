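# Pair activity normalisation and per-candidate individual activities.
#
# Pair activity is the log2 RNA/input fold change after pseudocount and
# median-of-ratios size-factor normalisation, anchored so that the mean
# activity of negative-control/control pairs is exactly zero; activities are
# thus fold changes over the basal core promoter in log2 units.

# counts long table -> pairs x samples matrix plus sample annotation
counts_to_matrix <- function(counts) {
  sample_key <- paste(counts$channel, counts$replicate, sep = "_")
  samples <- sort_c(unique(sample_key))
  pairs <- sort_c(unique(counts$pair_id))
  m <- matrix(NA_real_, length(pairs), length(samples),
              dimnames = list(pairs, samples))
  m[cbind(match(counts$pair_id, pairs), match(sample_key, samples))] <-
    counts$umi_count
  info <- do.call(rbind, strsplit(samples, "_"))
  list(m = m,
       channel = info[, 1],
       replicate = as.integer(info[, 2]))
}

# DESeq-style median-of-ratios size factors on pseudocounted counts.
size_factors <- function(k) {
  logk <- log(k)
  ref <- rowMeans(logk)
  apply(logk, 2, function(col) exp(median(col - ref)))
}

#' Normalise pair activities
#'
#' Adds one pseudocount to every UMI count, computes per-sample
#' median-of-ratios size factors, averages log2 normalised counts over
#' replicates within each channel, takes the RNA minus input difference as
#' the pair's log2 activity, and finally subtracts a single scalar so that
#' the mean activity of control/control pairs is exactly zero.
#'
#' @param counts Long-format count table (after [filter_pairs()]); every
#'   retained pair must be observed in every replicate of both channels.
#' @param design The `pair_design`.
#' @param pool The [candidate_pool()] (for control labels).
#' @return Data frame of class `pair_activities`: `pair_id`, `id5`, `id3`,
#'   `log2_activity`, `n_replicates_used`.
#' @export
normalize_activities <- function(counts, design, pool) {
  if (!nrow(counts)) stop("empty count table")
  cm <- counts_to_matrix(counts)
  if (anyNA(cm$m)) {
    cm$m <- cm$m[stats::complete.cases(cm$m), , drop = FALSE]
  }
  if (!nrow(cm$m)) stop("no pair observed in all samples")
  n_in <- sum(cm$channel == "input")
  n_rna <- sum(cm$channel == "rna")
  if (n_in < 2 || n_rna < 2) {
    stop("at least two replicates per channel are required")
  }
  k <- cm$m + 1
  sf <- size_factors(k)
  lognorm <- log2(sweep(k, 2, sf, "/"))
  act <- rowMeans(lognorm[, cm$channel == "rna", drop = FALSE]) -
    rowMeans(lognorm[, cm$channel == "input", drop = FALSE])
  idx <- match(names(act), design$pair_id)
  if (anyNA(idx)) stop("pairs missing from design")
  id5 <- design$id5[idx]
  id3 <- design$id3[idx]
  ctrl <- setNames(pool$cls == "control", pool$id)
  cc <- ctrl[id5] & ctrl[id3]
  if (!any(cc)) stop("no control/control pairs: control anchoring undefined")
  act <- act - mean(act[cc])
  out <- data.frame(pair_id = names(act), id5 = id5, id3 = id3,
                    log2_activity = unname(act),
                    n_replicates_used = n_in + n_rna,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pair_activities", "data.frame")
  out
}

#' Select robust negative controls
#'
#' For each side (5' and 3'), each control's activity is the mean over its
#' pairs with other controls; per-side z-scores are computed with the sample
#' (n-1) SD, and controls with z in `[-1, 1]` are retained. If the SD is
#' zero, all controls are retained.
#'
#' @param activities A `pair_activities` table.
#' @param pool The [candidate_pool()].
#' @return List of class `control_set` with `p5`, `p3` (retained control
#'   ids per side) and `stats` (per-control mean, z and retention flag).
#' @export
select_robust_controls <- function(activities, pool) {
  ctrl_ids <- pool$id[pool$cls == "control"]
  is_c5 <- activities$id5 %in% ctrl_ids
  is_c3 <- activities$id3 %in% ctrl_ids
  cc <- activities[is_c5 & is_c3, ]
  side_stats <- function(ids, acts, side) {
    mu <- tapply(acts, ids, mean)
    if (length(mu) < 3) {
      stop(sprintf("fewer than 3 eligible controls on the %s side", side))
    }
    s <- sd(mu)
    z <- if (is.na(s) || s == 0) rep(0, length(mu)) else (mu - mean(mu)) / s
    data.frame(control_id = names(mu), side = side,
               mean_activity = as.numeric(mu), z = as.numeric(z),
               retained = z >= -1 & z <= 1, stringsAsFactors = FALSE)
  }
  s5 <- side_stats(cc$id5, cc$log2_activity, "5p")
  s3 <- side_stats(cc$id3, cc$log2_activity, "3p")
  stats <- rbind(s5, s3)
  rownames(stats) <- NULL
  structure(list(p5 = s5$control_id[s5$retained],
                 p3 = s3$control_id[s3$retained],
                 stats = stats),
            class = "control_set")
}

#' @rdname select_robust_controls
#' @param x A `control_set`.
#' @param ... Unused.
#' @method print control_set
#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("Robust controls: %d retained at 5', %d at 3'\n",
              length(x$p5), length(x$p3)))
  invisible(x)
}

#' Individual candidate activities
#'
#' A candidate's activity on a side is the mean activity of its pairs with
#' retained (robust) controls on the opposite side. Candidates with fewer
#' than `min_partners` such pairs are discarded.
#'
#' @param activities A `pair_activities` table.
#' @param controls A `control_set` from [select_robust_controls()].
#' @param min_partners Minimum number of robust-control partner pairs
#'   (default 10).
#' @return Data frame: `candidate_id`, `side` (`"5p"`/`"3p"`),
#'   `log2_activity`, `n_control_partners`.
#' @export
individual_activity <- function(activities, controls, min_partners = 10L) {
  one_side <- function(cand, partner, robust, side) {
    sub <- activities[activities[[partner]] %in% robust &
                        activities[[cand]] != activities[[partner]], ]
    if (!nrow(sub)) {
      return(data.frame(candidate_id = character(0), side = character(0),
                        log2_activity = numeric(0),
                        n_control_partners = integer(0)))
    }
    mu <- tapply(sub$log2_activity, sub[[cand]], mean)
    n <- tapply(sub$log2_activity, sub[[cand]], length)
    keep <- n >= min_partners
    data.frame(candidate_id = names(mu)[keep],
               side = rep(side, sum(keep)),
               log2_activity = as.numeric(mu[keep]),
               n_control_partners = as.integer(n[keep]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side("id5", "id3", controls$p3, "5p"),
               one_side("id3", "id5", controls$p5, "3p"))
  rownames(out) <- NULL
  out
}

#' One-tailed Fisher p-value (vectorised)
#'
#' Exact one-tailed ("greater") Fisher p-value for 2x2 tables
#' `rbind(c(a, b), c(c, d))`: the hypergeometric upper-tail probability of
#' observing `a` or more in the top-left cell at fixed margins.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorised).
#' @return Numeric vector of p-values.
#' @export
fisher_p_greater <- function(a, b, c, d) {
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Classify candidates as active
#'
#' For each candidate and side, sums RNA and input UMIs over that
#' candidate's robust-control pairs and over all robust control/control
#' pairs, builds the 2x2 table (rows: candidate pairs vs control/control
#' pairs; columns: RNA vs input UMIs) and computes a one-tailed Fisher
#' p-value for RNA enrichment in the candidate row. Benjamini-Hochberg FDR
#' correction is applied per side. A candidate is active iff its
#' `log2_activity > activity_cutoff` and `fdr < alpha`.
#'
#' The contingency-table construction is the package's interpretation of a
#' count-based one-tailed Fisher comparison between a candidate's control
#' pairings and the control/control reference; it is isolated here so an
#' alternative construction can be swapped in.
#'
#' @param counts Filtered long-format count table.
#' @param activities A `pair_activities` table.
#' @param controls A `control_set`.
#' @param individuals Output of [individual_activity()].
#' @param alpha FDR threshold (default 0.05).
#' @param activity_cutoff Log2 activity threshold (default 1).
#' @param per_side Apply BH correction per side (default) or pooled.
#' @return `individuals` with `fdr` and `active` columns added.
#' @export
call_active <- function(counts, activities, controls, individuals,
                        alpha = 0.05, activity_cutoff = 1, per_side = TRUE) {
  tot <- tapply(counts$umi_count, list(counts$pair_id, counts$channel), sum)
  pr <- activities[match(rownames(tot), activities$pair_id),
                   c("id5", "id3")]
  cc <- pr$id5 %in% controls$p5 & pr$id3 %in% controls$p3 &
    !is.na(pr$id5)
  if (!any(cc)) stop("no robust control/control pairs for the Fisher reference")
  ref_rna <- sum(tot[cc, "rna"])
  ref_in <- sum(tot[cc, "input"])
  fisher_side <- function(ind_side, cand_col, partner_col, robust) {
    rows <- pr[[partner_col]] %in% robust & !is.na(pr[[partner_col]]) &
      pr[[cand_col]] != pr[[partner_col]]
    rna <- tapply(tot[rows, "rna"], pr[[cand_col]][rows], sum)
    inp <- tapply(tot[rows, "input"], pr[[cand_col]][rows], sum)
    i <- match(ind_side$candidate_id, names(rna))
    fisher_p_greater(rna[i], inp[i], ref_rna, ref_in)
  }
  out <- individuals
  out$p_value <- rep(NA_real_, nrow(out))
  for (side in c("5p", "3p")) {
    sel <- out$side == side
    if (!any(sel)) next
    out$p_value[sel] <- if (side == "5p") {
      fisher_side(out[sel, ], "id5", "id3", controls$p3)
    } else {
      fisher_side(out[sel, ], "id3", "id5", controls$p5)
    }
  }
  if (per_side) {
    out$fdr <- rep(NA_real_, nrow(out))
    for (side in c("5p", "3p")) {
      sel <- out$side == side
      out$fdr[sel] <- p.adjust(out$p_value[sel], method = "BH")
    }
  } else {
    out$fdr <- p.adjust(out$p_value, method = "BH")
  }
  out$active <- out$log2_activity > activity_cutoff & out$fdr < alpha
  out
}

#' Run the full activity stage
#'
#' Convenience wrapper: [filter_pairs()], [normalize_activities()],
#' [select_robust_controls()], [individual_activity()] and [call_active()]
#' in sequence.
#'
#' @param counts Raw long-format count table.
#' @param design The `pair_design`.
#' @param pool The [candidate_pool()].
#' @param min_input Input filter threshold (default 5).
#' @param min_partners Robust-control partner minimum (default 10).
#' @param alpha FDR threshold for active calls.
#' @param classify Run [call_active()] (default); `FALSE` skips the Fisher
#'   stage when only activities are needed.
#' @return List with `pairs` (pair activities), `controls`, `individuals`.
#' @export
starr_activities <- function(counts, design, pool, min_input = 5L,
                             min_partners = 10L, alpha = 0.05,
                             classify = TRUE) {
  filtered <- filter_pairs(counts, design, min_input)
  pairs <- normalize_activities(filtered, design, pool)
  controls <- select_robust_controls(pairs, pool)
  individuals <- individual_activity(pairs, controls, min_partners)
  if (classify) {
    individuals <- call_active(filtered, pairs, controls, individuals,
                               alpha = alpha)
  }
  list(pairs = pairs, controls = controls, individuals = individuals)
}
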