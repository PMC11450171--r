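# Motif-level analyses: enrichment-based motif curation, pairwise
# motif-combination effect grids, and L1-regularised prediction of pair
# activity (or residuals) from motif counts.

#' Select informative motifs by enrichment
#'
#' For every motif and every candidate group, a two-tailed Fisher exact test
#' compares the fraction of sequences with at least one match between the
#' group and a control set of random sequences; Benjamini-Hochberg FDR
#' correction is applied across all motif x group tests. A motif is retained
#' iff it reaches `fdr < fdr_cutoff` in at least one group and has at least
#' `min_total` matches in total across the candidate sequences.
#'
#' @param counts Motif count matrix (candidates x motifs) from
#'   [motif_count_matrix()].
#' @param groups Group label per candidate row (character/factor).
#' @param control_counts Count matrix for the control random sequences (same
#'   motif columns).
#' @param fdr_cutoff FDR threshold (default `1e-5`).
#' @param min_total Minimum total match count (default 5).
#' @return Character vector of retained motif names; the full test table is
#'   attached as attribute `"tests"`.
#' @export
select_informative_motifs <- function(counts, groups, control_counts,
                                      fdr_cutoff = 1e-5, min_total = 5L) {
  if (!identical(colnames(counts), colnames(control_counts))) {
    stop("counts and control_counts must share motif columns")
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(counts)) stop("one group label per candidate row")
  if (!nrow(control_counts)) stop("control set is empty")
  glev <- sort_c(unique(groups))
  pres <- counts >= 1
  pres_c <- control_counts >= 1
  nc <- nrow(control_counts)
  tests <- list()
  for (g in glev) {
    rows <- groups == g
    if (!any(rows)) stop("empty group: ", g)
    ng <- sum(rows)
    with_g <- colSums(pres[rows, , drop = FALSE])
    with_c <- colSums(pres_c)
    p <- vapply(seq_along(with_g), function(j) {
      fisher.test(matrix(c(with_g[j], ng - with_g[j],
                           with_c[j], nc - with_c[j]), 2, byrow = TRUE))$p.value
    }, numeric(1))
    tests[[g]] <- data.frame(motif = colnames(counts), group = g,
                             n_group_with = as.integer(with_g),
                             n_control_with = as.integer(with_c),
                             p_value = p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tests)
  tab$fdr <- p.adjust(tab$p_value, method = "BH")
  total <- colSums(counts)
  sig <- unique(tab$motif[tab$fdr < fdr_cutoff])
  keep <- intersect(sig, names(total)[total >= min_total])
  structure(sort_c(keep), tests = tab)
}

#' Pairwise motif-combination effect grid
#'
#' For each ordered motif combination (m5, m3), pairs whose 5' candidate
#' contains at least one match to m5 AND whose 3' candidate contains at
#' least one match to m3 form the "with" group; pairs lacking m5 at 5' AND
#' lacking m3 at 3' form the "without" group. The effect is the difference
#' of group means (with minus without), computed for the observed activity
#' and, when available, for the interaction-fit residuals — both already in
#' log2 units, so the difference normalises the with-group to the
#' without-group.
#'
#' @param pairs Output of [pair_predictions()]; a `residual` column (e.g.
#'   `residuals(fit)[pairs$pair_id]`) enables the residual grid.
#' @param counts5,counts3 Motif count matrices (candidates x motifs) for the
#'   5' and 3' candidates.
#' @param motifs Motif names defining the grid (e.g. 120 motifs give a
#'   14,400-entry grid).
#' @param min_pairs Minimum group size; entries with a smaller "with" or
#'   "without" group have `NA` effects (default 10).
#' @return Data frame with one row per (motif5, motif3): `n_with`,
#'   `n_without`, `activity_effect`, `residual_effect`.
#' @export
pair_motif_effect <- function(pairs, counts5, counts3, motifs,
                              min_pairs = 10L) {
  miss <- setdiff(motifs, intersect(colnames(counts5), colnames(counts3)))
  if (length(miss)) {
    stop("motifs absent from count matrices: ",
         paste(head(miss, 3), collapse = ", "))
  }
  P5 <- (counts5[pairs$id5, motifs, drop = FALSE] >= 1) * 1
  P3 <- (counts3[pairs$id3, motifs, drop = FALSE] >= 1) * 1
  Q5 <- 1 - P5
  Q3 <- 1 - P3
  grid_stats <- function(y) {
    sum_with <- crossprod(P5 * y, P3)
    sum_without <- crossprod(Q5 * y, Q3)
    list(with = sum_with, without = sum_without)
  }
  n_with <- crossprod(P5, P3)
  n_without <- crossprod(Q5, Q3)
  act <- grid_stats(pairs$observed)
  mean_or_na <- function(s, n) ifelse(n >= min_pairs, s / n, NA_real_)
  activity_effect <- mean_or_na(act$with, n_with) -
    mean_or_na(act$without, n_without)
  out <- data.frame(
    motif5 = rep(motifs, times = length(motifs)),
    motif3 = rep(motifs, each = length(motifs)),
    n_with = as.vector(n_with),
    n_without = as.vector(n_without),
    activity_effect = as.vector(activity_effect),
    stringsAsFactors = FALSE)
  if ("residual" %in% names(pairs)) {
    res <- grid_stats(pairs$residual)
    out$residual_effect <- as.vector(mean_or_na(res$with, n_with) -
                                       mean_or_na(res$without, n_without))
  } else {
    out$residual_effect <- NA_real_
  }
  out
}

#' L1-regularised (LASSO) prediction from motif counts
#'
#' Fits `glmnet` LASSO models of `target` on the feature matrix over the
#' lambda grid `10^seq(2, -3, by = -0.1)` with standardised features.
#' Performance is assessed by nested cross-validation: for each of
#' `outer_folds` non-overlapping held-out test sets, an inner
#' `inner_folds`-fold `cv.glmnet` on the training portion selects lambda,
#' the model is refit on the training portion, and R-squared is computed on
#' the held-out set. Reported coefficients come from a final full-data fit
#' at the full-data inner-CV lambda.
#'
#' @param features Numeric matrix, samples x features (e.g. 5' and 3' motif
#'   counts of each pair as separate column blocks, see
#'   [pair_motif_features()]).
#' @param target Numeric response vector.
#' @param lambda_grid Decreasing lambda grid (default `10^seq(2, -3, -0.1)`).
#' @param inner_folds Inner CV folds for lambda selection (default 5).
#' @param outer_folds Outer evaluation folds (default 9).
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `l1_fit`: `lambda_grid`, `chosen_lambda`,
#'   `coefficients` (named, incl. `(Intercept)`), `cv_r2_mean`, `cv_r2_sd`,
#'   `fold_r2`.
#' @export
l1_regression <- function(features, target,
                          lambda_grid = 10^seq(2, -3, by = -0.1),
                          inner_folds = 5L, outer_folds = 9L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n) stop("target length must match feature rows")
  if (n <= outer_folds) stop("need more samples than outer folds")
  if (any(!is.finite(features))) stop("features must be finite")
  if (sd(target) == 0) {
    warning("constant target: intercept-only fit, cv R^2 reported as 0")
    co <- setNames(c(target[1], rep(0, ncol(features))),
                   c("(Intercept)", colnames(features)))
    return(structure(list(lambda_grid = lambda_grid,
                          chosen_lambda = max(lambda_grid),
                          coefficients = co, cv_r2_mean = 0, cv_r2_sd = 0,
                          fold_r2 = rep(0, outer_folds)),
                     class = "l1_fit"))
  }
  with_seed(seed, {
    outer_id <- fold_ids(n, outer_folds)
    fold_r2 <- numeric(outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- outer_id != f
      inner_id <- fold_ids(sum(tr), inner_folds)
      cv <- glmnet::cv.glmnet(features[tr, , drop = FALSE], target[tr],
                              alpha = 1, lambda = lambda_grid,
                              standardize = TRUE, foldid = inner_id)
      fit <- glmnet::glmnet(features[tr, , drop = FALSE], target[tr],
                            alpha = 1, lambda = cv$lambda.min,
                            standardize = TRUE)
      pred <- as.vector(predict(fit, features[!tr, , drop = FALSE]))
      fold_r2[f] <- r_squared(target[!tr], pred)
    }
    inner_id_full <- fold_ids(n, inner_folds)
    cv_full <- glmnet::cv.glmnet(features, target, alpha = 1,
                                 lambda = lambda_grid, standardize = TRUE,
                                 foldid = inner_id_full)
    final <- glmnet::glmnet(features, target, alpha = 1,
                            lambda = cv_full$lambda.min, standardize = TRUE)
    co <- as.matrix(stats::coef(final))[, 1]
    structure(list(lambda_grid = lambda_grid,
                   chosen_lambda = cv_full$lambda.min,
                   coefficients = co,
                   cv_r2_mean = mean(fold_r2),
                   cv_r2_sd = sd(fold_r2),
                   fold_r2 = fold_r2),
              class = "l1_fit")
  })
}

#' @rdname l1_regression
#' @param x An `l1_fit`.
#' @param ... Unused.
#' @method print l1_fit
#' @export
print.l1_fit <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("LASSO fit: lambda = %.4g, %d nonzero coefficients, cv R^2 = %.3f +/- %.3f (9-fold)\n",
              x$chosen_lambda, nz, x$cv_r2_mean, x$cv_r2_sd))
  invisible(x)
}

#' Per-pair motif feature matrix
#'
#' Joins the 5' and 3' candidate motif counts of each pair into one feature
#' matrix with separate column blocks (`p5_<motif>`, `p3_<motif>`).
#'
#' @param pairs Data frame with `id5`, `id3`.
#' @param counts5,counts3 Motif count matrices (candidates x motifs).
#' @param motifs Motif names to include (default: all shared columns).
#' @return Numeric matrix, pairs x (2 * motifs).
#' @export
pair_motif_features <- function(pairs, counts5, counts3,
                                motifs = intersect(colnames(counts5),
                                                   colnames(counts3))) {
  f <- cbind(counts5[pairs$id5, motifs, drop = FALSE],
             counts3[pairs$id3, motifs, drop = FALSE])
  colnames(f) <- c(paste0("p5_", motifs), paste0("p3_", motifs))
  rownames(f) <- pairs$pair_id
  f
}
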