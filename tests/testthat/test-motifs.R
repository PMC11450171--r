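test_that("single-position PWM scanning matches hand enumeration", {
  onebase <- pwm("A_only", matrix(c(1, 0, 0, 0), 1, 4))
  # at p_cutoff 0.3 only the top base passes (null exceedance 0.25)
  expect_equal(scan_motifs("AACGT", onebase, p_cutoff = 0.3), 3L)
  # p_cutoff 1: every window on both strands
  tw <- consensus_pwm("tw", "CATATG")
  expect_equal(scan_motifs("AACGTAACGT", tw, p_cutoff = 1), 2L * (10 - 6 + 1))
  # PWM longer than sequence
  expect_warning(n <- scan_motifs("ACG", tw, p_cutoff = 1), "longer")
  expect_equal(n, 0L)
  expect_error(pwm("bad", matrix(-1, 2, 4)), ">= 0")
})

test_that("DP null distribution matches brute-force 4^k enumeration", {
  set.seed(71)
  mats <- list(
    pwm("k1", matrix(c(1, 0, 0, 0), 1, 4)),
    consensus_pwm("k5", "GAGAG", p = 0.9),
    pwm("k3rand", matrix(rgamma(12, 0.6), 3, 4)),
    pwm("k8rand", matrix(rgamma(32, 0.6), 8, 4),
        background = c(0.3, 0.2, 0.2, 0.3)),
    consensus_pwm("k8", "TATCGATA")
  )
  for (m in mats) {
    k <- nrow(m$matrix)
    thr <- pwm_threshold(m, p_cutoff = 5e-4)
    # enumerate all 4^k windows on the same integer score lattice
    idx <- as.matrix(expand.grid(rep(list(1:4), k)))
    sc <- numeric(nrow(idx))
    pr <- rep(1, nrow(idx))
    for (j in seq_len(k)) {
      sc <- sc + thr$scores[j, idx[, j]]
      pr <- pr * m$background[idx[, j]]
    }
    p_brute <- sum(pr[sc >= thr$threshold])
    expect_lt(abs(p_brute - thr$p_exceed), 1e-12)
    expect_lte(p_brute, 5e-4)
    # no lower lattice threshold would satisfy the cutoff
    below <- sum(pr[sc >= thr$threshold - 1L])
    if (thr$p_exceed > 0) expect_gt(below, 5e-4)
  }
})

test_that("scanning is strand-symmetric and monotone in the cutoff", {
  set.seed(72)
  pwms <- demo_pwms(n_random = 4, seed = 2)
  seqs <- random_dna(5, 120)
  for (m in pwms[c("Trl_like", "AP1_like", "rand01")]) {
    for (s in seqs) {
      expect_equal(scan_motifs(s, m, p_cutoff = 1e-3),
                   scan_motifs(revcomp(s), m, p_cutoff = 1e-3))
    }
    counts <- vapply(c(1, 1e-1, 1e-2, 1e-3, 1e-4), function(pc) {
      scan_motifs(seqs[1], m, p_cutoff = pc)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("PWM files round-trip and count matrices are deterministic", {
  pwms <- demo_pwms(n_random = 2, seed = 3)
  dir <- withr::local_tempdir()
  for (m in pwms) write_pwm(m, file.path(dir, paste0(m$name, ".pwm")))
  back <- read_pwms(dir)
  expect_setequal(names(back), names(pwms))
  expect_equal(back$Trl_like$matrix, pwms$Trl_like$matrix, tolerance = 1e-5)

  set.seed(73)
  seqs <- setNames(random_dna(8, 249), sprintf("s%d", 1:8))
  m1 <- motif_count_matrix(seqs, pwms, p_cutoff = 1e-3)
  m2 <- motif_count_matrix(seqs, pwms, p_cutoff = 1e-3)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(8L, length(pwms)))
  # spiked motif is counted
  spiked <- seqs
  spiked[1] <- paste_motifs(spiked[1], "TGACTCA", 3, seed = 1)
  ms <- motif_count_matrix(spiked, pwms["AP1_like"], p_cutoff = 1e-3)
  expect_gte(ms[1, "AP1_like"], 3)
})

test_that("motif curation applies enrichment FDR and the total-count floor", {
  motifs <- c("m_enriched", "m_rare", "m_flat")
  n <- 50
  counts <- cbind(m_enriched = rep(1L, n),
                  m_rare = c(rep(1L, 4), rep(0L, n - 4)),
                  m_flat = rep(c(1L, 0L), n / 2))
  ctrl <- cbind(m_enriched = rep(0L, n),
                m_rare = rep(0L, n),
                m_flat = rep(c(1L, 0L), n / 2))
  got <- select_informative_motifs(counts, rep("developmental", n), ctrl)
  expect_true("m_enriched" %in% got)
  expect_false("m_rare" %in% got)
  # the total-count floor acts independently of significance: at a permissive
  # FDR cutoff m_rare passes the test stage yet is excluded by total 4 < 5,
  # and admitting totals >= 4 brings it back
  relaxed <- select_informative_motifs(counts, rep("developmental", n), ctrl,
                                       fdr_cutoff = 0.5)
  expect_false("m_rare" %in% relaxed)
  floor4 <- select_informative_motifs(counts, rep("developmental", n), ctrl,
                                      fdr_cutoff = 0.5, min_total = 4)
  expect_true("m_rare" %in% floor4)
  # identical frequencies: p = 1
  tests <- attr(got, "tests")
  expect_equal(tests$p_value[tests$motif == "m_flat"], 1)
  expect_false("m_flat" %in% got)
})

test_that("pair motif grids measure planted activity effects", {
  set.seed(74)
  n_cand <- 60
  ids <- sprintf("e%03d", seq_len(n_cand))
  has_m <- rbinom(n_cand, 1, 0.4)
  counts <- cbind(mA = has_m, mB = rbinom(n_cand, 1, 0.5))
  rownames(counts) <- ids
  g <- expand.grid(id5 = ids, id3 = ids, stringsAsFactors = FALSE)
  g <- g[g$id5 != g$id3, ]
  pairs <- data.frame(pair_id = paste0(g$id5, "__", g$id3),
                      id5 = g$id5, id3 = g$id3, stringsAsFactors = FALSE)
  # motif mA on the 5' side adds exactly +1; noise on top
  pairs$observed <- 2 + has_m[match(pairs$id5, ids)] +
    rnorm(nrow(pairs), 0, 0.3)
  pairs$residual <- rnorm(nrow(pairs), 0, 0.3)  # pure noise
  grid <- pair_motif_effect(pairs, counts, counts, c("mA", "mB"))
  expect_equal(nrow(grid), 4L)
  eff <- grid$activity_effect[grid$motif5 == "mA" & grid$motif3 == "mB"]
  n_w <- grid$n_with[grid$motif5 == "mA" & grid$motif3 == "mB"]
  n_wo <- grid$n_without[grid$motif5 == "mA" & grid$motif3 == "mB"]
  se <- 0.3 * sqrt(1 / n_w + 1 / n_wo)
  expect_lt(abs(eff - 1), 3 * se + 0.02)
  # residual effects on pure noise stay near zero
  expect_true(all(abs(grid$residual_effect) < 3 * se + 0.02))

  # constant activities -> zero effects everywhere
  pairs0 <- pairs
  pairs0$observed <- 1.25
  grid0 <- pair_motif_effect(pairs0, counts, counts, c("mA", "mB"))
  expect_equal(grid0$activity_effect, rep(0, 4), tolerance = 1e-12)

  # undefined entries when a group is too small
  tiny <- pair_motif_effect(pairs[1:5, ], counts, counts, c("mA", "mB"),
                            min_pairs = 10)
  expect_true(all(is.na(tiny$activity_effect)))
})

test_that("LASSO recovers a planted motif signal and shrinks noise to zero", {
  ok_signal <- 0L
  ok_sparse <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    X <- matrix(rpois(n * 51, 1), n, 51,
                dimnames = list(NULL, c("signal", sprintf("noise%02d", 1:50))))
    y <- 2 * X[, "signal"] + rnorm(n, 0, 0.1)
    fit <- l1_regression(X, y, seed = seed)
    co <- fit$coefficients[-1]
    if (co["signal"] > 1.5 && co["signal"] < 2.5) ok_signal <- ok_signal + 1
    if (mean(co[names(co) != "signal"] == 0) >= 0.9) ok_sparse <- ok_sparse + 1
  }
  # signal recovery is essentially deterministic; cross-validated lambda
  # occasionally sits low enough to admit a handful of tiny noise terms
  expect_equal(ok_signal, 10)
  expect_gte(ok_sparse, 7)
})

test_that("LASSO degenerate targets and full shrinkage behave as specified", {
  set.seed(75)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_warning(fit0 <- l1_regression(X, rep(0, 50)), "constant target")
  expect_true(all(fit0$coefficients == 0))
  expect_equal(fit0$cv_r2_mean, 0)

  # enormous lambda grid: all slopes shrunk away
  y <- rnorm(50, 0, 0.1) + 0.05 * X[, 1]
  fit_big <- l1_regression(X, y, lambda_grid = c(1e6, 9e5), seed = 1)
  expect_true(all(fit_big$coefficients[-1] == 0))

  # determinism given a seed
  y2 <- rnorm(50)
  f1 <- l1_regression(X, y2, seed = 9)
  f2 <- l1_regression(X, y2, seed = 9)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$fold_r2, f2$fold_r2)
})
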