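# Ground-truth simulator: individual activities, combined pair activities
# under four cooperativity regimes, and negative-binomially dispersed UMI
# counts with the screen's replicate/channel structure.

#' Specify a cooperativity regime for simulation
#'
#' The regime determines how the true log2 activity of a pair is derived
#' from the log2 individual activities of its 5' and 3' candidates:
#'
#' * `additive`: RNA outputs add, `log2(2^a5 + 2^a3 - 1)`;
#' * `multiplicative`: fold changes multiply, `a5 + a3`;
#' * `interaction`: `beta0 + beta1*a5 + beta2*a3 + beta3*a5*a3`, the
#'   phenomenological model fitted to enhancer-enhancer pairs;
#' * `saturating`: a smooth harmonic (soft-minimum) cap on the
#'   multiplicative prediction,
#'   `log2(2^(a5+a3) * 2^cap / (2^(a5+a3) + 2^cap))`, emulating a core
#'   promoter that cannot exceed `cap` log2 units of output.
#'
#' @param regime One of `"additive"`, `"multiplicative"`, `"interaction"`,
#'   `"saturating"`.
#' @param beta Length-4 coefficient vector `(beta0, beta1, beta2, beta3)` in
#'   log2 units, used by the interaction regime.
#' @param cap Log2 ceiling of the saturating regime (must be finite).
#' @param noise_sd Standard deviation (log2 units) of pair-level biological
#'   noise added on top of the regime law.
#' @return An object of class `activity_model`.
#' @examples
#' activity_model("multiplicative")
#' activity_model("interaction", beta = c(0.1, 1.1, 1.0, -0.1))
#' @export
activity_model <- function(regime = c("multiplicative", "additive",
                                      "interaction", "saturating"),
                           beta = c(0, 1, 1, 0), cap = 4, noise_sd = 0) {
  regime <- match.arg(regime)
  if (length(beta) != 4 || any(!is.finite(beta))) {
    stop("beta must be 4 finite coefficients")
  }
  if (regime == "saturating" && !is.finite(cap)) {
    stop("cap must be finite for the saturating regime")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(regime = regime, beta = as.numeric(beta),
                 cap = as.numeric(cap), noise_sd = as.numeric(noise_sd)),
            class = "activity_model")
}

#' Simulation configuration
#'
#' Defaults describe a screen-scale experiment: two input and two RNA
#' replicates, a mean input depth of 50 UMIs per pair, negative-binomial
#' dispersion 0.2 (variance `mu + mu^2 * 0.2`), enhancer log2 activities
#' uniform on (0, 4) with controls fixed at 0, log-normal library
#' representation skew (sdlog 0.5) and 10-nt UMIs.
#'
#' @param n_enhancers,n_controls Pool composition.
#' @param activity_law Function `n -> n` true enhancer log2 activities
#'   (controls are always exactly 0).
#' @param n_input_reps,n_rna_reps Replicates per channel (>= 2 each).
#' @param mean_input_depth Expected input UMIs per pair.
#' @param rna_depth Expected RNA UMIs per pair at activity 0 (defaults to
#'   `mean_input_depth`).
#' @param nb_dispersion Negative-binomial dispersion `d` in
#'   `var = mu + mu^2 * d`; `0` gives Poisson counts.
#' @param abundance_sdlog Log-normal sdlog of per-pair library abundance
#'   (cloning skew); 0 for perfectly even representation.
#' @param umi_length UMI length in nt.
#' @param seed Integer seed used by [simulate_screen()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_enhancers = 850, n_controls = 150,
                       activity_law = function(n) runif(n, 0, 4),
                       n_input_reps = 2, n_rna_reps = 2,
                       mean_input_depth = 50, rna_depth = mean_input_depth,
                       nb_dispersion = 0.2, abundance_sdlog = 0.5,
                       umi_length = 10, seed = 1) {
  stopifnot(n_enhancers >= 0, n_controls >= 0,
            n_enhancers + n_controls >= 1,
            is.function(activity_law))
  if (n_input_reps < 2 || n_rna_reps < 2) {
    stop("at least two replicates per channel are required")
  }
  if (mean_input_depth <= 0 || rna_depth <= 0) stop("depths must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(list(n_enhancers = as.integer(n_enhancers),
                 n_controls = as.integer(n_controls),
                 activity_law = activity_law,
                 n_input_reps = as.integer(n_input_reps),
                 n_rna_reps = as.integer(n_rna_reps),
                 mean_input_depth = mean_input_depth,
                 rna_depth = rna_depth,
                 nb_dispersion = nb_dispersion,
                 abundance_sdlog = abundance_sdlog,
                 umi_length = as.integer(umi_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw true individual log2 activities
#'
#' Enhancers draw i.i.d. from the configured activity law; controls are
#' exactly 0 (transcriptionally inert by definition, since activities are
#' fold changes over the basal core promoter).
#'
#' @param pool A [candidate_pool()].
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return Named numeric vector of log2 activities, one per pool candidate.
#' @export
simulate_true_activities <- function(pool, config, seed = config$seed) {
  with_seed(seed, {
    act <- numeric(nrow(pool))
    enh <- pool$cls == "enhancer"
    act[enh] <- config$activity_law(sum(enh))
    setNames(act, pool$id)
  })
}

#' Combined log2 activity of a pair under a regime
#'
#' Vectorised over `a5`/`a3`. See [activity_model()] for the regime
#' formulas. Pure function of its arguments; biological noise is added by
#' [simulate_counts()], not here.
#'
#' @param a5,a3 Log2 individual activities of the 5' and 3' candidates.
#' @param model An [activity_model()].
#' @return Log2 pair activity.
#' @examples
#' combined_activity(1, 1, activity_model("multiplicative"))  # 2
#' combined_activity(1, 1, activity_model("additive"))        # log2(3)
#' @export
combined_activity <- function(a5, a3, model) {
  stopifnot(inherits(model, "activity_model"))
  switch(model$regime,
    additive = predict_additive(a5, a3),
    multiplicative = a5 + a3,
    interaction = {
      b <- model$beta
      b[1] + b[2] * a5 + b[3] * a3 + b[4] * a5 * a3
    },
    saturating = {
      s <- a5 + a3
      s + model$cap - log2(2^s + 2^model$cap)
    },
    stop("unknown regime: ", model$regime)
  )
}

# True pair activities for a design. The interaction regime is a model of
# enhancer-enhancer cooperativity (it is fitted after discarding
# control-containing pairs), so control-containing pairs follow the
# basal-partner identity instead: the pair's activity is the partner's
# individual activity. The other regimes already satisfy that identity at
# a = 0 (saturating caps it, deliberately, as promoter saturation applies to
# single strong enhancers too).
true_pair_activities <- function(design, activities, pool, model) {
  a5 <- activities[design$id5]
  a3 <- activities[design$id3]
  out <- combined_activity(a5, a3, model)
  if (model$regime == "interaction") {
    ctrl <- setNames(pool$cls == "control", pool$id)
    c5 <- ctrl[design$id5]
    c3 <- ctrl[design$id3]
    out[c5 & !c3] <- a3[c5 & !c3]
    out[!c5 & c3] <- a5[!c5 & c3]
    out[c5 & c3] <- 0
  }
  setNames(out, design$pair_id)
}

# NB sampler: variance mu + mu^2 * d; d = 0 falls back to Poisson.
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate UMI count tables for a pair design
#'
#' Input counts per pair and input replicate are negative binomial with mean
#' `abundance * mean_input_depth`; RNA counts have mean
#' `abundance * rna_depth * 2^(activity + N(0, noise_sd))`, with one shared
#' biological noise draw per pair (log2 scale, applied before
#' exponentiation). Per-pair abundances are log-normal with mean 1.
#'
#' @param design A `pair_design`.
#' @param pair_activities Named numeric vector of true log2 pair activities
#'   (names = `pair_id`), e.g. from [simulate_screen()].
#' @param config A [sim_config()].
#' @param noise_sd Pair-level biological noise SD in log2 units.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return Long-format count table: `pair_id`, `replicate` (integer),
#'   `channel` (`"input"`/`"rna"`), `umi_count`.
#' @export
simulate_counts <- function(design, pair_activities, config, noise_sd = 0,
                            seed = config$seed) {
  act <- pair_activities[design$pair_id]
  if (anyNA(act)) stop("every design row needs a true pair activity")
  n <- nrow(design)
  with_seed(seed, {
    q <- if (config$abundance_sdlog > 0) {
      rlnorm(n, meanlog = -config$abundance_sdlog^2 / 2,
             sdlog = config$abundance_sdlog)
    } else rep(1, n)
    noisy <- act + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    mu_in <- q * config$mean_input_depth
    mu_rna <- q * config$rna_depth * 2^noisy
    blocks <- list()
    for (r in seq_len(config$n_input_reps)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        pair_id = design$pair_id, replicate = r, channel = "input",
        umi_count = rnb(n, mu_in, config$nb_dispersion),
        stringsAsFactors = FALSE)
    }
    for (r in seq_len(config$n_rna_reps)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        pair_id = design$pair_id, replicate = r, channel = "rna",
        umi_count = rnb(n, mu_rna, config$nb_dispersion),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, blocks)
  })
}

#' Simulate a complete paired-enhancer screen
#'
#' Convenience wrapper: builds a random pool, enumerates the full ordered
#' pair design, draws true individual activities, derives true pair
#' activities under the chosen regime, and simulates the UMI count table.
#'
#' @param config A [sim_config()].
#' @param model An [activity_model()]; its `noise_sd` is the pair-level
#'   biological noise used by [simulate_counts()].
#' @param sequences Generate random 249-bp candidate sequences (`TRUE`) or
#'   leave the pool sequence-free placeholders (`FALSE`, faster when only
#'   counts are needed).
#' @return A list of class `sim_screen` with elements `pool`, `design`,
#'   `true_activities`, `true_pair_activities`, `counts`, `config`, `model`.
#' @examples
#' scr <- simulate_screen(sim_config(n_enhancers = 5, n_controls = 4, seed = 2),
#'                        activity_model("multiplicative"))
#' head(scr$counts)
#' @export
simulate_screen <- function(config, model = activity_model("multiplicative"),
                            sequences = FALSE) {
  pool <- with_seed(config$seed, {
    n <- config$n_enhancers + config$n_controls
    ids <- c(sprintf("E%04d", seq_len(config$n_enhancers)),
             sprintf("C%04d", seq_len(config$n_controls)))
    seqs <- if (sequences) random_dna(n, 249L) else rep(strrep("A", 249L), n)
    candidate_pool(ids, seqs,
                   cls = rep(c("enhancer", "control"),
                             c(config$n_enhancers, config$n_controls)),
                   program = rep(c("developmental", "none"),
                                 c(config$n_enhancers, config$n_controls)))
  })
  design <- enumerate_pairs(pool)
  acts <- simulate_true_activities(pool, config, seed = config$seed + 1L)
  pacts <- true_pair_activities(design, acts, pool, model)
  counts <- simulate_counts(design, pacts, config, noise_sd = model$noise_sd,
                            seed = config$seed + 2L)
  structure(list(pool = pool, design = design, true_activities = acts,
                 true_pair_activities = pacts, counts = counts,
                 config = config, model = model),
            class = "sim_screen")
}

#' @rdname simulate_screen
#' @param x A `sim_screen`.
#' @param ... Unused.
#' @method print sim_screen
#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("Simulated screen: %d enhancers + %d controls, %d pairs, %d+%d replicates, regime '%s'\n",
              x$config$n_enhancers, x$config$n_controls, nrow(x$design),
              x$config$n_input_reps, x$config$n_rna_reps, x$model$regime))
  invisible(x)
}

#' Emit paired FASTQ reads for a simulated screen
#'
#' For every UMI unit in the count table, emits `duplicates` read pairs
#' sharing one UMI (placed in the read header after the last `:`). Read 1 is
#' the construct's 5' end in forward orientation; read 2 is the
#' reverse-complemented 3' end. Per-base substitution errors are applied at
#' `error_rate`.
#'
#' @param screen A `sim_screen` (or any list with `counts` and `config`).
#' @param reference Named construct sequences from [build_reference()].
#' @param dir Output directory; one R1/R2 FASTQ pair per replicate x channel.
#' @param read_length Read length in bp (must not exceed the constructs).
#' @param duplicates Read pairs per UMI (PCR duplication factor).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; deterministic output given the seed.
#' @return Data frame manifest: `replicate`, `channel`, `r1`, `r2` paths.
#' @export
emit_reads <- function(screen, reference, dir, read_length = 36,
                       duplicates = 1, error_rate = 0,
                       seed = screen$config$seed) {
  counts <- screen$counts
  umi_len <- screen$config$umi_length
  if (read_length > min(nchar(reference))) {
    stop("read_length exceeds construct length")
  }
  missing <- setdiff(unique(counts$pair_id), names(reference))
  if (length(missing)) {
    stop("constructs missing from reference: ",
         paste(head(missing, 3), collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  end5 <- substr(reference, 1L, read_length)
  end3 <- revcomp(substr(reference, nchar(reference) - read_length + 1L,
                         nchar(reference)))
  samples <- unique(counts[, c("replicate", "channel")])
  manifest <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(samples))) {
      sub <- counts[counts$replicate == samples$replicate[i] &
                      counts$channel == samples$channel[i] &
                      counts$umi_count > 0, ]
      n_umi <- sum(sub$umi_count)
      pair_of_umi <- rep(sub$pair_id, sub$umi_count)
      umis <- random_dna(n_umi, umi_len)
      # distinct UMIs within a (pair, sample): resample collisions
      key <- paste(pair_of_umi, umis)
      while (anyDuplicated(key)) {
        d <- duplicated(key)
        umis[d] <- random_dna(sum(d), umi_len)
        key <- paste(pair_of_umi, umis)
      }
      pr <- rep(pair_of_umi, each = duplicates)
      um <- rep(umis, each = duplicates)
      r1 <- add_seq_errors(end5[pr], error_rate)
      r2 <- add_seq_errors(end3[pr], error_rate)
      headers <- sprintf("read%07d:%s", seq_along(pr), um)
      tag <- sprintf("%s_%s", samples$channel[i], samples$replicate[i])
      p1 <- file.path(dir, sprintf("%s_R1.fastq", tag))
      p2 <- file.path(dir, sprintf("%s_R2.fastq", tag))
      write_fastq(headers, r1, p1)
      write_fastq(headers, r2, p2)
      manifest[[i]] <- data.frame(replicate = samples$replicate[i],
                                  channel = samples$channel[i],
                                  r1 = p1, r2 = p2, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, manifest)
}

# Apply i.i.d. substitution errors; a substituted base always differs from
# the original.
add_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(unname(reads))
  L <- nchar(reads[1])
  mat <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                nrow = length(reads), byrow = TRUE)
  hit <- matrix(runif(length(mat)) < error_rate, nrow = nrow(mat))
  if (any(hit)) {
    orig <- mat[hit]
    shift <- sample(1:3, sum(hit), replace = TRUE)
    mat[hit] <- DNA_BASES[((match(orig, DNA_BASES) - 1L + shift) %% 4L) + 1L]
  }
  apply(mat, 1, paste, collapse = "")
}

write_fastq <- function(headers, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", headers, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal reader for the 4-line-record FASTQ files this package emits.
#'
#' @param path FASTQ path.
#' @return Data frame with `header` (text after `@`) and `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(header = sub("^@", "", lines[idx]),
             sequence = lines[idx + 1L], stringsAsFactors = FALSE)
}

#' Write simulated outputs to TSV
#'
#' @param counts Long-format count table.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(pair_id = "character", channel = "character"))
}
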