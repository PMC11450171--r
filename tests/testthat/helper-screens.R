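# Shared fixture builders (all generated in code).

# Small screen through the full count simulator.
tiny_screen <- function(n_enh = 30, n_ctrl = 20, regime = "multiplicative",
                        noise_sd = 0.1, depth = 50, seed = 3,
                        sequences = FALSE, ...) {
  simulate_screen(
    sim_config(n_enhancers = n_enh, n_ctrl, mean_input_depth = depth,
               seed = seed, ...),
    activity_model(regime, noise_sd = noise_sd),
    sequences = sequences
  )
}

# Noise-free pair-activity table built directly from known truths, bypassing
# count noise: every pair's activity is exactly a5 + a3 (multiplicative).
exact_activities <- function(acts, pool) {
  design <- enumerate_pairs(pool)
  design <- design[!design$homotypic, ]
  out <- data.frame(pair_id = design$pair_id, id5 = design$id5,
                    id3 = design$id3,
                    log2_activity = acts[design$id5] + acts[design$id3],
                    n_replicates_used = 4L, stringsAsFactors = FALSE)
  class(out) <- c("pair_activities", "data.frame")
  out
}

# Pool of n_ctrl controls and n_enh enhancers with given activities.
labelled_pool <- function(enh_ids, ctrl_ids) {
  candidate_pool(
    id = c(enh_ids, ctrl_ids),
    sequence = rep(strrep("A", 249), length(enh_ids) + length(ctrl_ids)),
    cls = rep(c("enhancer", "control"), c(length(enh_ids), length(ctrl_ids)))
  )
}

# Independent one-tailed Fisher oracle: exhaustive enumeration of the
# hypergeometric tail via log-binomial coefficients (no phyper/dhyper).
fisher_greater_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  xs <- xs[xs >= a]
  if (!length(xs)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# Independent per-base substitution-error injector (binomial oracle tests).
add_errors_for_test <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Closed-form OLS via the normal equations, independent of lm().
normal_equations_fit <- function(A, B, y) {
  X <- cbind(1, A, B, A * B)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}
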