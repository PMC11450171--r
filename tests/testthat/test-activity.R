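test_that("normalisation centres control/control pairs at exactly zero", {
  scr <- tiny_screen(n_enh = 20, n_ctrl = 12, seed = 51)
  filtered <- filter_pairs(scr$counts, scr$design)
  acts <- normalize_activities(filtered, scr$design, scr$pool)
  ctrl <- scr$pool$id[scr$pool$cls == "control"]
  cc <- acts$id5 %in% ctrl & acts$id3 %in% ctrl
  expect_lt(abs(mean(acts$log2_activity[cc])), 1e-12)
  expect_true(all(is.finite(acts$log2_activity)))

  # all-zero RNA counts still yield a finite activity (pseudocount)
  zero <- filtered
  pick <- zero$pair_id == zero$pair_id[1] & zero$channel == "rna"
  zero$umi_count[pick] <- 0L
  a2 <- normalize_activities(zero, scr$design, scr$pool)
  expect_true(is.finite(a2$log2_activity[a2$pair_id == zero$pair_id[1]]))

  # no control/control pairs -> rejection
  enh_only <- filtered[!(sub("__.*", "", filtered$pair_id) %in% ctrl &
                           sub(".*__", "", filtered$pair_id) %in% ctrl), ]
  expect_error(normalize_activities(enh_only, scr$design, scr$pool),
               "control/control")
})

test_that("pair activities recover simulated truth at high depth", {
  cfg <- sim_config(n_enhancers = 25, n_controls = 15,
                    mean_input_depth = 5000, nb_dispersion = 0,
                    abundance_sdlog = 0, seed = 52)
  scr <- simulate_screen(cfg, activity_model("multiplicative", noise_sd = 0))
  filtered <- filter_pairs(scr$counts, scr$design)
  acts <- normalize_activities(filtered, scr$design, scr$pool)
  truth <- scr$true_pair_activities[acts$pair_id]
  expect_gt(mean(abs(acts$log2_activity - truth) < 0.05), 0.95)
})

test_that("robust-control selection applies the z-score window", {
  ctrl_ids <- sprintf("c%d", 1:4)
  pool <- labelled_pool(character(0), ctrl_ids)
  # 5' means {0.1, -0.1, 0, 2.0}; one partner each, mirrored on the 3' side
  grid <- expand.grid(id5 = ctrl_ids, id3 = ctrl_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$id5 != grid$id3, ]
  means <- c(c1 = 0.1, c2 = -0.1, c3 = 0, c4 = 2.0)
  acts <- data.frame(pair_id = paste0(grid$id5, "__", grid$id3),
                     id5 = grid$id5, id3 = grid$id3,
                     log2_activity = (means[grid$id5] + means[grid$id3]) / 1,
                     n_replicates_used = 4L, stringsAsFactors = FALSE)
  # activity = mean of the two controls' latent values; per-control means are
  # latent value + constant, so the z ordering matches the latent values
  acts$log2_activity <- means[grid$id5]  # 5' mean exactly the latent value
  cs <- select_robust_controls(acts, pool)
  expect_setequal(cs$p5, c("c1", "c2", "c3"))
  # oracle: recompute z with the sample SD
  z <- (means - mean(means)) / sd(means)
  expect_setequal(names(z)[abs(z) <= 1], cs$p5)

  # all identical -> SD 0 -> all retained
  acts$log2_activity <- 1
  cs0 <- select_robust_controls(acts, pool)
  expect_setequal(cs0$p5, ctrl_ids)
  expect_setequal(cs0$p3, ctrl_ids)

  # fewer than 3 controls per side -> rejection
  two <- acts[acts$id5 %in% c("c1", "c2") & acts$id3 %in% c("c1", "c2"), ]
  expect_error(select_robust_controls(two, pool), "fewer than 3")

  # Gaussian calibration: ~68% of standard-normal control means retained
  set.seed(53)
  n <- 1e4
  big_ids <- sprintf("c%05d", seq_len(n + 3))
  bpool <- labelled_pool(character(0), big_ids)
  partners <- rep(big_ids[n + (1:3)], length.out = n)
  bacts <- data.frame(pair_id = paste0(big_ids[1:n], "__", partners),
                      id5 = big_ids[1:n], id3 = partners,
                      log2_activity = rnorm(n),
                      n_replicates_used = 4L, stringsAsFactors = FALSE)
  frac <- length(select_robust_controls(bacts, bpool)$p5) / n
  expect_lt(abs(frac - 0.6827), 0.02)
})

test_that("individual activities average robust-control pairings", {
  ctrl_ids <- sprintf("c%02d", 1:14)
  pool <- labelled_pool(c("e1", "e2"), ctrl_ids)
  rows <- list()
  for (cid in ctrl_ids[1:12]) {
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = paste0("e1__", cid), id5 = "e1", id3 = cid,
      log2_activity = 1.5, n_replicates_used = 4L)
  }
  for (cid in ctrl_ids[1:9]) {
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = paste0("e2__", cid), id5 = "e2", id3 = cid,
      log2_activity = 3, n_replicates_used = 4L)
  }
  acts <- do.call(rbind, rows)
  controls <- list(p5 = ctrl_ids, p3 = ctrl_ids)
  ind <- individual_activity(acts, controls, min_partners = 10)
  expect_equal(ind$log2_activity[ind$candidate_id == "e1" & ind$side == "5p"],
               1.5)
  expect_equal(ind$n_control_partners[ind$candidate_id == "e1"], 12L)
  # 9 partners < 10 -> absent
  expect_false("e2" %in% ind$candidate_id)

  # row-order invariance
  ind2 <- individual_activity(acts[sample(nrow(acts)), ], controls,
                              min_partners = 10)
  expect_equal(ind2[order(ind2$candidate_id, ind2$side), ],
               ind[order(ind$candidate_id, ind$side), ],
               ignore_attr = TRUE)
})

test_that("noise-free individual activities equal the simulated truth", {
  set.seed(54)
  enh <- sprintf("e%02d", 1:5)
  ctrl <- sprintf("c%02d", 1:12)
  pool <- labelled_pool(enh, ctrl)
  truth <- setNames(c(runif(5, 0, 3), rep(0, 12)), pool$id)
  acts <- exact_activities(truth, pool)
  cs <- select_robust_controls(acts, pool)
  ind <- individual_activity(acts, cs, min_partners = 10)
  i5 <- ind[ind$side == "5p" & ind$candidate_id %in% enh, ]
  expect_equal(setNames(i5$log2_activity, i5$candidate_id), truth[enh])
})

test_that("one-tailed Fisher p equals the enumeration oracle", {
  expect_equal(fisher_p_greater(0, 5, 0, 10), 1)
  # identical row proportions, a = 0 -> p = 1
  expect_equal(fisher_p_greater(0, 7, 0, 7), 1)
  set.seed(57)
  for (i in 1:100) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c <- sample(0:12, 1); d <- sample(0:12, 1)
    p <- fisher_p_greater(a, b, c, d)
    expect_equal(p, fisher_greater_oracle(a, b, c, d), tolerance = 1e-12)
    # cross-check against the standard implementation
    expect_equal(p, fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("active calls require both the activity and the FDR threshold", {
  cfg <- sim_config(n_enhancers = 40, n_controls = 25,
                    activity_law = function(n) runif(n, 0, 3), seed = 58)
  scr <- simulate_screen(cfg, activity_model("multiplicative", noise_sd = 0.1))
  res <- starr_activities(scr$counts, scr$design, scr$pool)
  ind <- res$individuals
  expect_true(all(ind$active == (ind$log2_activity > 1 & ind$fdr < 0.05)))
  expect_true(all(ind$fdr >= 0 & ind$fdr <= 1))
  expect_true(all(ind$n_control_partners >= 10))
  # strong enhancers are called active, inert controls are not
  truth <- scr$true_activities
  strong <- names(truth)[truth > 2]
  called <- ind$candidate_id[ind$active & ind$side == "5p"]
  expect_gt(mean(strong %in% called), 0.9)
  ctrl <- scr$pool$id[scr$pool$cls == "control"]
  expect_lt(mean(ctrl %in% called), 0.05)
})
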