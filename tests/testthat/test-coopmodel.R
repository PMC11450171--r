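test_that("additive and multiplicative predictors satisfy their identities", {
  expect_equal(predict_additive(1, 1), log2(3))
  for (A in c(0, 1, 2.7)) expect_equal(predict_additive(A, 0), A)
  expect_equal(predict_additive(0, 0), 0)
  expect_equal(predict_multiplicative(1, 1), 2)
  expect_equal(predict_multiplicative(2, -1), 1)
  expect_equal(predict_multiplicative(3.2, 0), 3.2)

  # symmetry and ordering on a grid: multiplicative >= additive for A,B >= 0,
  # equality iff one partner is basal
  g <- expand.grid(A = seq(0, 4, 0.5), B = seq(0, 4, 0.5))
  add <- predict_additive(g$A, g$B)
  mult <- predict_multiplicative(g$A, g$B)
  expect_equal(add, predict_additive(g$B, g$A))
  expect_true(all(mult - add >= -1e-12))
  eq <- abs(mult - add) < 1e-9
  expect_equal(eq, g$A == 0 | g$B == 0)

  # deep-negative clamp
  expect_warning(v <- predict_additive(-40, -40), "clamped")
  expect_true(is.finite(v))
})

test_that("r_squared follows 1 - SS_res/SS_tot", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  # non-fitted predictors can do worse than the mean
  expect_lt(r_squared(obs, c(3, 2, 1)), 0)
  expect_error(r_squared(obs, c(1, 2)), "length")
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")
})

test_that("the interaction fit is exact OLS", {
  set.seed(61)
  d <- expand.grid(A = seq(0, 3, length.out = 12),
                   B = seq(0, 3, length.out = 12))
  d$observed <- 0.2 + 1.1 * d$A + 1.0 * d$B - 0.1 * d$A * d$B
  fit <- fit_interaction_model(d)
  expect_equal(unname(coef(fit)), c(0.2, 1.1, 1.0, -0.1), tolerance = 1e-9)
  expect_equal(fit$r2_adjusted, 1, tolerance = 1e-9)
  expect_lt(abs(mean(residuals(fit))), 1e-10)

  # constant observations: intercept carries the constant
  dc <- d
  dc$observed <- 1.7
  fitc <- fit_interaction_model(dc)
  expect_equal(unname(coef(fitc)), c(1.7, 0, 0, 0), tolerance = 1e-9)

  # normal-equations oracle on 100 random instances (n <= 50)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    A <- rnorm(n); B <- rnorm(n)
    y <- rnorm(n, 0.5 + A + B - 0.2 * A * B, 0.2)
    f <- fit_interaction_model(data.frame(A = A, B = B, observed = y))
    expect_equal(unname(coef(f)), normal_equations_fit(A, B, y),
                 tolerance = 1e-8)
  }

  # rank deficiency is rejected with the collinear column named
  bad <- data.frame(A = rep(1, 10), B = rnorm(10), observed = rnorm(10))
  expect_error(fit_interaction_model(bad), "collinear")
  expect_error(fit_interaction_model(d[1:3, ]), "at least 5")
})

test_that("interaction_fit behaves like a classed model object", {
  set.seed(62)
  d <- data.frame(pair_id = sprintf("p%03d", 1:60),
                  A = runif(60, 0, 3), B = runif(60, 0, 3))
  d$observed <- d$A + d$B + rnorm(60, 0, 0.1)
  fit <- fit_interaction_model(d)
  expect_s3_class(fit, "interaction_fit")
  expect_named(coef(fit), c("beta0", "beta1", "beta2", "beta3"))
  expect_equal(names(residuals(fit)), d$pair_id)
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
  nd <- data.frame(A = c(0, 1), B = c(0, 2))
  b <- coef(fit)
  expect_equal(predict(fit, nd),
               b[1] + b[2] * nd$A + b[3] * nd$B + b[4] * nd$A * nd$B,
               ignore_attr = TRUE)
  expect_output(print(fit), "interaction term")
  expect_output(print(summary(fit)), "adjusted")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("model comparison identifies the generating regime", {
  set.seed(63)
  A <- runif(400, 0.5, 3.5); B <- runif(400, 0.5, 3.5)
  base <- data.frame(pair_id = sprintf("p%03d", 1:400), A = A, B = B)
  base$pred_additive <- predict_additive(A, B)
  base$pred_multiplicative <- predict_multiplicative(A, B)

  mult <- base; mult$observed <- base$pred_multiplicative
  cm <- compare_models(mult)
  expect_equal(cm$frac_multiplicative_better, 1.0)
  expect_equal(cm$r2_multiplicative, 1)

  addd <- base; addd$observed <- base$pred_additive
  ca <- compare_models(addd)
  expect_equal(ca$frac_multiplicative_better, 0.0)
  expect_equal(ca$r2_additive, 1)

  # ties (basal partner: predictions coincide) count as additive
  tie <- data.frame(pair_id = sprintf("t%02d", 1:20),
                    A = runif(20, 0.5, 3), B = 0)
  tie$pred_multiplicative <- predict_multiplicative(tie$A, tie$B)
  tie$pred_additive <- tie$pred_multiplicative  # basal partner: exact tie
  tie$observed <- tie$A + rnorm(20, 0, 1e-4)
  expect_equal(compare_models(tie)$frac_multiplicative_better, 0)

  # noisy multiplicative data through the real pipeline
  scr <- tiny_screen(n_enh = 60, n_ctrl = 30, noise_sd = 0.3, seed = 64)
  res <- starr_activities(scr$counts, scr$design, scr$pool)
  pp <- pair_predictions(res$pairs, res$individuals, scr$pool)
  both <- compare_models(pp, both_active_only = TRUE)
  expect_gt(both$frac_multiplicative_better, 0.5)
  expect_gt(both$r2_multiplicative, both$r2_additive)
  expect_match(both$subset, "both-active")
})

test_that("pair predictions exclude control-containing pairs", {
  scr <- tiny_screen(n_enh = 15, n_ctrl = 18, seed = 65)
  res <- starr_activities(scr$counts, scr$design, scr$pool)
  pp <- pair_predictions(res$pairs, res$individuals, scr$pool)
  ctrl <- scr$pool$id[scr$pool$cls == "control"]
  expect_false(any(pp$id5 %in% ctrl | pp$id3 %in% ctrl))
  expect_false(any(pp$id5 == pp$id3))
  expect_true(all(c("A", "B", "observed", "pred_additive",
                    "pred_multiplicative", "active5") %in% names(pp)))
})

test_that("saturation curves flatten for strong anchors under a capped promoter", {
  # all-weak pool: strong class empty with a warning
  enh <- sprintf("e%02d", 1:6)
  ctrl <- sprintf("c%02d", 1:12)
  pool <- labelled_pool(enh, ctrl)
  truth <- setNames(c(rep(1.2, 6), rep(0, 12)), pool$id)
  acts <- exact_activities(truth, pool)
  cs <- select_robust_controls(acts, pool)
  ind <- individual_activity(acts, cs)
  pp <- pair_predictions(acts, ind, pool)
  expect_warning(curves <- saturation_curves(pp, ind), "strong")
  expect_true(all(curves$anchor_class == "weak"))

  # capped vs multiplicative regimes through the pipeline
  slopes_for <- function(regime) {
    cfg <- sim_config(n_enhancers = 80, n_controls = 40, seed = 66)
    scr <- simulate_screen(cfg, activity_model(regime, cap = 4,
                                               noise_sd = 0.1))
    res <- starr_activities(scr$counts, scr$design, scr$pool,
                            classify = FALSE)
    pp <- pair_predictions(res$pairs, res$individuals, scr$pool)
    saturation_slopes(saturation_curves(pp, res$individuals))
  }
  sat <- slopes_for("saturating")
  expect_lt(sat["strong"], sat["weak"])
  mult <- slopes_for("multiplicative")
  expect_lt(abs(mult["weak"] - 1), 0.1)
  expect_lt(abs(mult["strong"] - 1), 0.1)
})
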