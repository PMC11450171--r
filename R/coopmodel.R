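# Cooperativity models: additive vs multiplicative predictions, the
# interaction-term fit, model comparison and promoter-saturation curves.

#' Additive prediction of combined activity
#'
#' Under additivity the RNA outputs of the two enhancers add on the linear
#' scale, so in log2 fold-change units over the basal promoter the pair
#' prediction is `log2(2^A + 2^B - 1)`: pairing with a basal (A or B = 0)
#' partner returns the other enhancer's activity unchanged.
#'
#' @param A,B Log2 individual activities (vectorised).
#' @param floor Lower clamp on the log2 argument (default `2^-30`), only
#'   reachable when both activities are deeply negative; clamping triggers a
#'   warning.
#' @return Log2 additive prediction; symmetric in `(A, B)`.
#' @examples
#' predict_additive(1, 1)  # log2(3)
#' predict_additive(2, 0)  # 2
#' @export
predict_additive <- function(A, B, floor = 2^-30) {
  arg <- 2^A + 2^B - 1
  if (any(arg < floor)) {
    warning("additive prediction argument clamped at floor")
    arg <- pmax(arg, floor)
  }
  log2(arg)
}

#' Multiplicative prediction of combined activity
#'
#' Fold changes multiply, so log2 activities add: `A + B`.
#'
#' @param A,B Log2 individual activities (vectorised).
#' @return `A + B`.
#' @examples
#' predict_multiplicative(1, 1)  # 2
#' @export
predict_multiplicative <- function(A, B) A + B

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total`. For predictions that are not least-squares
#' fits of the observations this can be negative (the predictor does worse
#' than the observed mean).
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return R-squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Assemble pair predictions from pipeline outputs
#'
#' Joins each heterotypic enhancer-enhancer pair's observed activity with
#' the 5' and 3' individual activities of its candidates and the additive
#' and multiplicative predictions. Pairs containing a control sequence, or a
#' candidate without a reported individual activity, are excluded.
#'
#' @param activities A `pair_activities` table.
#' @param individuals Output of [individual_activity()] / [call_active()].
#' @param pool The [candidate_pool()].
#' @return Data frame: `pair_id`, `id5`, `id3`, `A`, `B`, `observed`,
#'   `pred_additive`, `pred_multiplicative`, and, when `individuals` carries
#'   active flags, `active5`/`active3`.
#' @export
pair_predictions <- function(activities, individuals, pool) {
  ctrl <- pool$id[pool$cls == "control"]
  keep <- !(activities$id5 %in% ctrl) & !(activities$id3 %in% ctrl) &
    activities$id5 != activities$id3
  x <- activities[keep, ]
  i5 <- individuals[individuals$side == "5p", ]
  i3 <- individuals[individuals$side == "3p", ]
  A <- i5$log2_activity[match(x$id5, i5$candidate_id)]
  B <- i3$log2_activity[match(x$id3, i3$candidate_id)]
  out <- data.frame(pair_id = x$pair_id, id5 = x$id5, id3 = x$id3,
                    A = A, B = B, observed = x$log2_activity,
                    stringsAsFactors = FALSE)
  if ("active" %in% names(individuals)) {
    out$active5 <- i5$active[match(x$id5, i5$candidate_id)]
    out$active3 <- i3$active[match(x$id3, i3$candidate_id)]
  }
  out <- out[!is.na(out$A) & !is.na(out$B), ]
  out$pred_additive <- predict_additive(out$A, out$B)
  out$pred_multiplicative <- predict_multiplicative(out$A, out$B)
  rownames(out) <- NULL
  out
}

#' Fit the multiplicative model with interaction term
#'
#' Ordinary least squares of observed pair activity on
#' `1, A, B, A*B`: `observed = b0 + b1*A + b2*B + b3*A*B + e`. `b1`/`b2`
#' near 1 indicate that each enhancer contributes its full individual
#' activity (multiplicative cooperativity); a negative `b3` captures
#' saturation at high combined strength.
#'
#' @param pairs Data frame with columns `A`, `B`, `observed` (and optionally
#'   `pair_id`, used to name residuals), e.g. from [pair_predictions()].
#' @return Object of class `interaction_fit` with coefficients `beta0..beta3`,
#'   named residuals, adjusted R-squared (`1 - (1 - R2)(n - 1)/(n - p - 1)`,
#'   p = 3) and the underlying `lm` fit.
#' @examples
#' d <- expand.grid(A = seq(0, 3, 0.5), B = seq(0, 3, 0.5))
#' d$observed <- 0.2 + 1.1 * d$A + d$B - 0.1 * d$A * d$B
#' coef(fit_interaction_model(d))
#' @export
fit_interaction_model <- function(pairs) {
  need <- c("A", "B", "observed")
  if (!all(need %in% names(pairs))) {
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  }
  pairs <- pairs[is.finite(pairs$A) & is.finite(pairs$B) &
                   is.finite(pairs$observed), ]
  n <- nrow(pairs)
  if (n < 5) stop("need at least 5 pairs to fit")
  fit <- lm(observed ~ A + B + A:B, data = pairs)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- stats::residuals(fit)
  names(res) <- if ("pair_id" %in% names(pairs)) pairs$pair_id else NULL
  r2 <- if (var(pairs$observed) == 0) NA_real_ else
    r_squared(pairs$observed, stats::fitted(fit))
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 3 - 1)
  structure(list(coefficients = setNames(unname(coef(fit)),
                                         c("beta0", "beta1", "beta2", "beta3")),
                 residuals = res,
                 fitted_values = setNames(unname(stats::fitted(fit)),
                                          names(res)),
                 r2 = r2, r2_adjusted = r2_adj, n_pairs = n, lm = fit),
            class = "interaction_fit")
}

#' @rdname fit_interaction_model
#' @param object,x An `interaction_fit`.
#' @param ... Unused.
#' @method coef interaction_fit
#' @export
coef.interaction_fit <- function(object, ...) object$coefficients

#' @rdname fit_interaction_model
#' @method residuals interaction_fit
#' @export
residuals.interaction_fit <- function(object, ...) object$residuals

#' @rdname fit_interaction_model
#' @method fitted interaction_fit
#' @export
fitted.interaction_fit <- function(object, ...) object$fitted_values

#' Predict combined activity from an interaction fit
#'
#' @param object An `interaction_fit`.
#' @param newdata Data frame with columns `A` and `B`; omitted, returns the
#'   fitted values.
#' @param ... Unused.
#' @return Predicted log2 pair activities.
#' @export
predict.interaction_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  b <- object$coefficients
  b[1] + b[2] * newdata$A + b[3] * newdata$B + b[4] * newdata$A * newdata$B
}

#' @rdname fit_interaction_model
#' @method print interaction_fit
#' @export
print.interaction_fit <- function(x, ...) {
  b <- x$coefficients
  cat("Multiplicative model with interaction term (OLS)\n")
  cat(sprintf("  activity = %.3f + %.3f*A + %.3f*B + %.3f*A*B\n",
              b[1], b[2], b[3], b[4]))
  cat(sprintf("  n = %d pairs, adjusted R^2 = %.3f\n", x$n_pairs,
              x$r2_adjusted))
  invisible(x)
}

#' @rdname fit_interaction_model
#' @method summary interaction_fit
#' @export
summary.interaction_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(coefficients = s$coefficients, r2 = object$r2,
              r2_adjusted = object$r2_adjusted, n_pairs = object$n_pairs,
              sigma = s$sigma)
  class(out) <- "summary.interaction_fit"
  out
}

#' @method print summary.interaction_fit
#' @export
print.summary.interaction_fit <- function(x, ...) {
  cat("Interaction-term cooperativity fit\n\n")
  print(x$coefficients)
  cat(sprintf("\nn = %d, R^2 = %.4f (adjusted %.4f), residual SD = %.4f\n",
              x$n_pairs, x$r2, x$r2_adjusted, x$sigma))
  invisible(x)
}

#' @rdname fit_interaction_model
#' @method plot interaction_fit
#' @export
plot.interaction_fit <- function(x, ...) {
  plot(x$fitted_values, x$fitted_values + x$residuals,
       xlab = "predicted log2 pair activity",
       ylab = "observed log2 pair activity", pch = 16,
       col = grDevices::adjustcolor("grey30", 0.4), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare additive and multiplicative models
#'
#' Computes the R-squared of the fixed additive and multiplicative
#' predictions against observed pair activities, the adjusted R-squared of
#' the interaction fit, and the fraction of pairs for which the
#' multiplicative prediction is strictly closer to the observation than the
#' additive one (ties count as additive, the conservative direction).
#'
#' @param pairs Output of [pair_predictions()].
#' @param both_active_only Restrict the comparison to pairs in which both
#'   candidates are active (requires `active5`/`active3` columns).
#' @return List of class `model_comparison`: `r2_additive`,
#'   `r2_multiplicative`, `r2_fitted_adjusted`,
#'   `frac_multiplicative_better`, `n_pairs`, `subset`.
#' @export
compare_models <- function(pairs, both_active_only = FALSE) {
  subset_label <- "all enhancer-enhancer pairs"
  if (both_active_only) {
    if (!all(c("active5", "active3") %in% names(pairs))) {
      stop("both_active_only requires active5/active3 flags")
    }
    pairs <- pairs[!is.na(pairs$active5) & !is.na(pairs$active3) &
                     pairs$active5 & pairs$active3, ]
    subset_label <- "both-active pairs"
  }
  if (!nrow(pairs)) stop("empty pair subset")
  # the interaction refit is reported alongside; a degenerate subset (e.g.
  # all-basal partners) falls back to NA rather than blocking the comparison
  fit <- tryCatch(fit_interaction_model(pairs), error = function(e) NULL)
  frac <- mean(abs(pairs$observed - pairs$pred_multiplicative) <
                 abs(pairs$observed - pairs$pred_additive))
  structure(list(
    r2_additive = r_squared(pairs$observed, pairs$pred_additive),
    r2_multiplicative = r_squared(pairs$observed, pairs$pred_multiplicative),
    r2_fitted_adjusted = if (is.null(fit)) NA_real_ else fit$r2_adjusted,
    frac_multiplicative_better = frac,
    n_pairs = nrow(pairs), subset = subset_label, fit = fit),
    class = "model_comparison")
}

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @method print model_comparison
#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s, n = %d)\n", x$subset, x$n_pairs))
  cat(sprintf("  R^2 additive        = %.3f\n", x$r2_additive))
  cat(sprintf("  R^2 multiplicative  = %.3f\n", x$r2_multiplicative))
  cat(sprintf("  adj. R^2 fitted     = %.3f\n", x$r2_fitted_adjusted))
  cat(sprintf("  multiplicative closer for %.1f%% of pairs\n",
              100 * x$frac_multiplicative_better))
  invisible(x)
}

#' Promoter saturation curves
#'
#' Anchors are enhancers with weak (log2 individual activity in
#' `weak_range`) or strong (above `max(individual activity) - strong_margin`)
#' individual activity, on either side of the pair. For each anchor class
#' and each partner enhancer, the mean observed pair activity is returned;
#' a saturating promoter flattens the strong-anchor curve.
#'
#' @param pairs Output of [pair_predictions()].
#' @param individuals Output of [individual_activity()].
#' @param weak_range Log2 activity window defining weak anchors (default
#'   `c(1, 1.5)`).
#' @param strong_margin Strong anchors exceed the side's maximum individual
#'   activity minus this margin (default 1).
#' @return Data frame: `anchor_class` (`"weak"`/`"strong"`), `partner_id`,
#'   `partner_activity` (the partner's individual activity on its side),
#'   `mean_pair_activity`, `n_pairs`. Classes with no anchors are absent
#'   (with a warning).
#' @export
saturation_curves <- function(pairs, individuals, weak_range = c(1, 1.5),
                              strong_margin = 1) {
  act_of <- function(side) {
    i <- individuals[individuals$side == side, ]
    setNames(i$log2_activity, i$candidate_id)
  }
  a5 <- act_of("5p")
  a3 <- act_of("3p")
  amax <- max(c(a5, a3))
  classify <- function(a) {
    ifelse(a >= weak_range[1] & a <= weak_range[2], "weak",
           ifelse(a > amax - strong_margin, "strong", NA))
  }
  # anchor at 5' (partner at 3') and anchor at 3' (partner at 5')
  long <- rbind(
    data.frame(anchor_class = classify(pairs$A), partner_id = pairs$id3,
               partner_activity = pairs$B, activity = pairs$observed,
               stringsAsFactors = FALSE),
    data.frame(anchor_class = classify(pairs$B), partner_id = pairs$id5,
               partner_activity = pairs$A, activity = pairs$observed,
               stringsAsFactors = FALSE)
  )
  long <- long[!is.na(long$anchor_class), ]
  for (cls in c("weak", "strong")) {
    if (!any(long$anchor_class == cls)) {
      warning("no anchors in class: ", cls)
    }
  }
  if (!nrow(long)) {
    return(data.frame(anchor_class = character(0), partner_id = character(0),
                      partner_activity = numeric(0),
                      mean_pair_activity = numeric(0), n_pairs = integer(0)))
  }
  agg <- aggregate(activity ~ anchor_class + partner_id, long, mean)
  n <- aggregate(activity ~ anchor_class + partner_id, long, length)
  pa <- aggregate(partner_activity ~ anchor_class + partner_id, long, mean)
  out <- data.frame(anchor_class = agg$anchor_class,
                    partner_id = agg$partner_id,
                    partner_activity = pa$partner_activity,
                    mean_pair_activity = agg$activity,
                    n_pairs = as.integer(n$activity),
                    stringsAsFactors = FALSE)
  out[order(out$anchor_class, out$partner_id), ]
}

#' Least-squares slopes of the saturation curves
#'
#' @param curves Output of [saturation_curves()].
#' @return Named numeric vector with the `weak` and `strong` slopes of mean
#'   pair activity against partner activity (NA when a class is empty).
#' @export
saturation_slopes <- function(curves) {
  slope <- function(cls) {
    d <- curves[curves$anchor_class == cls, ]
    if (nrow(d) < 2) return(NA_real_)
    unname(coef(lm(mean_pair_activity ~ partner_activity, data = d))[2])
  }
  c(weak = slope("weak"), strong = slope("strong"))
}
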