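# Synthetic two-sample GWAS summary statistics with known causal structure.
#
# Generative model, per SNP j:
#   eaf_j  ~ Uniform(eaf_range)
#   gamma_j ~ Normal(0, exposure_effect_sd^2)      (true per-allele exposure effect,
#             redrawn until |gamma_j| >= min_instrument_z * se_exp_j: only
#             genome-wide-detectable instruments are emitted)
#   se_exp_j = 1 / sqrt(2 eaf_j (1-eaf_j) n1)      (allele-frequency-scaled SE)
#   beta_exp_j ~ Normal(gamma_j, se_exp_j^2)       (estimated in sample 1)
#   alpha_j: 0 / Normal(0, pleiotropy_sd^2) / Normal(pleiotropy_mean, pleiotropy_sd^2)
#            for the invalid fraction of SNPs, applied in the
#            exposure-increasing-allele frame (multiplied by sign(gamma_j)),
#            so "directional" pleiotropy pushes all invalid instruments the
#            same way after the orientation every estimator uses
#   se_out_j = 1 / sqrt(2 eaf_j (1-eaf_j) n2)
#   beta_out_j ~ Normal(theta_true gamma_j + alpha_j, se_out_j^2)  (sample 2)
# The two samples are non-overlapping: exposure and outcome estimation noise
# are independent.

#' Parameters for the synthetic two-sample generator
#'
#' Defaults emulate the scale of the study design the package targets: 25
#' instruments (the four lifestyle exposures combined), an exposure GWAS of
#' 250,000 (UK-Biobank-scale), an outcome GWAS of 180,000
#' (consortium-scale), per-allele effects with SD 0.05 in trait-SD units, and
#' no pleiotropy.
#'
#' @param n_snps Number of instruments J.
#' @param causal_effect True causal effect theta (outcome units per exposure
#'   unit).
#' @param exposure_n,outcome_n GWAS sample sizes n1, n2.
#' @param eaf_range Effect-allele frequency range, a sub-interval of (0,1).
#' @param exposure_effect_sd SD of the true per-allele exposure effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_sd,pleiotropy_mean Pleiotropy distribution parameters.
#' @param invalid_fraction Fraction of SNPs receiving pleiotropy, in [0,1].
#'   Keep below 0.5 for weighted-median recovery experiments (documented, not
#'   enforced).
#' @param corrupt Harmonization stressor applied to the emitted outcome
#'   table: `"none"`, `"strand_flip"` (complement outcome alleles),
#'   `"allele_swap"` (swap effect/other allele with sign flip), or
#'   `"palindromic"` (emit A/T allele pairs).
#' @param min_instrument_z Instrument-relevance condition: true per-allele
#'   effects are redrawn until `|gamma_j| >= min_instrument_z * se_exp_j`,
#'   emulating the genome-wide-significance selection (two-sided P < 5e-8,
#'   z = 5.45) that every real instrument set has already passed. Set to 0 to
#'   draw unconditioned effects.
#' @param seed Mandatory RNG seed; identical parameters reproduce the dataset
#'   bit-exactly.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_snps = 25, causal_effect = 0, exposure_n = 250000,
                       outcome_n = 180000, eaf_range = c(0.1, 0.9),
                       exposure_effect_sd = 0.05,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       invalid_fraction = 0, corrupt = c("none", "strand_flip", "allele_swap", "palindromic"),
                       min_instrument_z = stats::qnorm(5e-8 / 2, lower.tail = FALSE),
                       seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  corrupt <- match.arg(corrupt)
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is required")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (exposure_n < 1 || outcome_n < 1) stop("sample sizes must be positive")
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] > eaf_range[2]) {
    stop("eaf_range must be an interval inside (0,1)")
  }
  if (exposure_effect_sd <= 0) stop("exposure_effect_sd must be > 0")
  if (pleiotropy_sd < 0) stop("pleiotropy_sd must be >= 0")
  if (invalid_fraction < 0 || invalid_fraction > 1) stop("invalid_fraction must be in [0,1]")
  if (min_instrument_z < 0) stop("min_instrument_z must be >= 0")
  if (pleiotropy_mode != "none" && invalid_fraction == 0) {
    invalid_fraction <- 1
  }
  structure(
    list(n_snps = as.integer(n_snps), causal_effect = causal_effect,
         exposure_n = exposure_n, outcome_n = outcome_n, eaf_range = eaf_range,
         exposure_effect_sd = exposure_effect_sd,
         pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean, invalid_fraction = invalid_fraction,
         corrupt = corrupt, min_instrument_z = min_instrument_z,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Non-palindromic allele pairs used for simulated SNPs.
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate a two-sample summary-statistics dataset with known truth
#'
#' Draws per-SNP exposure and outcome summary statistics under the standard
#' two-sample MR generative model (see the package vignette), optionally
#' corrupting the emitted outcome table's allele encoding to exercise
#' harmonization. The generating parameters and per-SNP pleiotropy are
#' returned alongside the data so recovery can be tested.
#'
#' @param params A [sim_params()].
#' @return An object of class `synthetic_truth`: list with `params`,
#'   `exposure_set` (an [instrument_set()]), `outcome_assocs` (tibble of
#'   variant records), `per_snp_pleiotropy` (the applied alpha_j, in the
#'   emitted allele frame) and `per_snp_gamma` (the true per-allele exposure
#'   effects).
#' @export
simulate_two_sample <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  withr_seed(p$seed, {
    J <- p$n_snps
    eaf <- runif(J, p$eaf_range[1], p$eaf_range[2])
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * p$exposure_n)
    gamma <- rnorm(J, 0, p$exposure_effect_sd)
    # instrument relevance: redraw effects too weak to have passed
    # genome-wide-significant selection (see ?sim_params)
    repeat {
      weak <- which(abs(gamma) < p$min_instrument_z * se_exp)
      if (length(weak) == 0) break
      gamma[weak] <- rnorm(length(weak), 0, p$exposure_effect_sd)
    }
    beta_exp <- rnorm(J, gamma, se_exp)

    alpha <- rep(0, J)
    if (p$pleiotropy_mode != "none") {
      n_invalid <- round(p$invalid_fraction * J)
      invalid <- if (n_invalid > 0) sample.int(J, n_invalid) else integer(0)
      mu <- if (p$pleiotropy_mode == "directional") p$pleiotropy_mean else 0
      raw <- rnorm(length(invalid), mu, p$pleiotropy_sd)
      # expressed relative to the exposure-increasing allele, then mapped
      # back to the emitted allele frame
      sgn <- ifelse(gamma[invalid] < 0, -1, 1)
      alpha[invalid] <- raw * sgn
    }

    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * p$outcome_n)
    beta_out <- rnorm(J, p$causal_effect * gamma + alpha, se_out)

    if (p$corrupt == "palindromic") {
      ea <- rep("A", J); oa <- rep("T", J)
    } else {
      pick <- sample.int(nrow(.allele_pairs), J, replace = TRUE)
      ea <- .allele_pairs[pick, 1]; oa <- .allele_pairs[pick, 2]
    }

    ids <- sprintf("rs%06d", seq_len(J))
    exposure <- tibble::tibble(
      snp_id = ids, chrom = as.character(((seq_len(J) - 1) %% 22) + 1),
      pos = 1000000L * seq_len(J), gene = NA_character_,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta_exp, se = se_exp, n = as.integer(p$exposure_n),
      pvalue = pmax(2 * pnorm(-abs(beta_exp / se_exp)), .Machine$double.xmin),
      trait = "sim_exposure", ancestry = "simulated", source = "lifestyleMR simulator"
    )
    outcome <- exposure
    outcome$beta <- beta_out
    outcome$se <- se_out
    outcome$n <- as.integer(p$outcome_n)
    outcome$pvalue <- pmax(2 * pnorm(-abs(beta_out / se_out)), .Machine$double.xmin)
    outcome$trait <- "sim_outcome"

    if (p$corrupt == "strand_flip") {
      outcome$effect_allele <- complement_allele(outcome$effect_allele)
      outcome$other_allele <- complement_allele(outcome$other_allele)
    } else if (p$corrupt == "allele_swap") {
      tmp <- outcome$effect_allele
      outcome$effect_allele <- outcome$other_allele
      outcome$other_allele <- tmp
      outcome$beta <- -outcome$beta
      outcome$eaf <- 1 - outcome$eaf
    }

    structure(
      list(params = p,
           exposure_set = instrument_set("sim_exposure", exposure,
                                         source = "lifestyleMR simulator"),
           outcome_assocs = outcome,
           per_snp_pleiotropy = alpha,
           per_snp_gamma = gamma),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> J=%d, theta=%.3g, pleiotropy=%s, corrupt=%s, seed=%d\n",
              x$params$n_snps, x$params$causal_effect, x$params$pleiotropy_mode,
              x$params$corrupt, x$params$seed))
  invisible(x)
}

#' Simulate an outcome association table for an existing instrument set
#'
#' Convenience generator for exercising the pipeline against real instrument
#' tables (e.g. the packaged lifestyle fixtures): outcome effects are drawn
#' conditional on the observed exposure betas,
#' `beta_out ~ N(causal_effect * beta_exp + alpha, se_out^2)` with
#' `se_out = 1/sqrt(2 eaf (1-eaf) outcome_n)` (eaf 0.5 where unrecorded).
#' Unlike [simulate_two_sample()] no fresh exposure sample is drawn, so this
#' is a demonstration device, not the generative model used for calibration.
#'
#' @param exp_set An [instrument_set()].
#' @param causal_effect True causal effect on the outcome scale.
#' @param outcome_n Outcome GWAS sample size.
#' @param seed RNG seed.
#' @param pleiotropy_mean,pleiotropy_sd Optional per-SNP direct effects.
#' @param trait Outcome label for the emitted table.
#' @return A tibble of variant records suitable for [harmonize_set()] /
#'   [run_pair()].
#' @export
simulate_outcome_table <- function(exp_set, causal_effect, outcome_n, seed,
                                   pleiotropy_mean = 0, pleiotropy_sd = 0,
                                   trait = "sim_outcome") {
  stopifnot(inherits(exp_set, "instrument_set"))
  v <- exp_set$variants
  withr_seed(seed, {
    J <- nrow(v)
    eaf <- ifelse(is.na(v$eaf), 0.5, v$eaf)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * outcome_n)
    alpha <- if (pleiotropy_sd > 0 || pleiotropy_mean != 0) {
      rnorm(J, pleiotropy_mean, pleiotropy_sd)
    } else rep(0, J)
    beta_out <- rnorm(J, causal_effect * v$beta + alpha, se_out)
    out <- v
    out$eaf <- eaf
    out$beta <- beta_out
    out$se <- se_out
    out$n <- as.integer(outcome_n)
    out$pvalue <- pmax(2 * pnorm(-abs(beta_out / se_out)), .Machine$double.xmin)
    out$trait <- trait
    out
  })
}

#' Write a synthetic dataset as TSVs readable by [read_associations()]
#'
#' @param truth A [simulate_two_sample()] result.
#' @param out_prefix Path prefix; writes `<prefix>_exposure.tsv`,
#'   `<prefix>_outcome.tsv` and a `<prefix>_truth.tsv` sidecar with the
#'   generating parameters and per-SNP pleiotropy.
#' @return Invisibly, the three paths.
#' @export
write_synthetic <- function(truth, out_prefix) {
  stopifnot(inherits(truth, "synthetic_truth"))
  paths <- paste0(out_prefix, c("_exposure.tsv", "_outcome.tsv", "_truth.tsv"))
  write_associations(truth$exposure_set, paths[1])
  readr::write_tsv(truth$outcome_assocs, paths[2], progress = FALSE)
  par_tbl <- tibble::tibble(
    snp_id = truth$exposure_set$variants$snp_id,
    pleiotropy = truth$per_snp_pleiotropy,
    causal_effect = truth$params$causal_effect,
    pleiotropy_mode = truth$params$pleiotropy_mode,
    seed = truth$params$seed
  )
  readr::write_tsv(par_tbl, paths[3], progress = FALSE)
  invisible(paths)
}

#' Monte-Carlo calibration experiment over simulation scenarios
#'
#' For each scenario, simulates `reps` independent two-sample datasets,
#' pushes each through harmonization and the requested estimators, and
#' summarizes per method: mean bias, empirical SE of the estimates, mean
#' estimated SE, 95% CI coverage of the true effect, and rejection rate of
#' H0: theta = 0 at 0.05. For MR-Egger the intercept estimate and its test's
#' rejection rate are summarized as an additional `egger_intercept` row
#' (its "bias" column is relative to the scenario's mean directional
#' pleiotropy, its coverage column is `NA`).
#'
#' @param grid List of [sim_params()] scenarios (their seeds are replaced by
#'   per-replicate seeds derived from `seed`).
#' @param reps Replicates per scenario (>= 1; >= 100 recommended).
#' @param seed Master seed for deriving per-replicate seeds.
#' @param methods Estimators to run: subset of `"ivw_fe"`, `"egger"`,
#'   `"simple_median"`, `"weighted_median"`.
#' @param n_boot Bootstrap size for the median methods (kept small by default
#'   here; medians dominate runtime).
#' @return A tibble: scenario, method, reps, true effect, bias, empirical SE,
#'   mean estimated SE, coverage, rejection rate.
#' @export
calibration_experiment <- function(grid, reps, seed,
                                   methods = c("ivw_fe", "egger"),
                                   n_boot = 500) {
  if (!is.numeric(reps) || reps < 1) stop("reps must be >= 1")
  if (inherits(grid, "sim_params")) grid <- list(grid)
  # one master stream hands an independent seed to every (scenario, replicate)
  rep_seeds <- withr_seed(seed, matrix(
    sample.int(2147483646L, reps * length(grid)), nrow = reps))
  out <- list()
  for (i in seq_along(grid)) {
    p0 <- grid[[i]]
    stopifnot(inherits(p0, "sim_params"))
    est <- list()
    for (m in methods) est[[m]] <- matrix(NA_real_, reps, 4,
                                          dimnames = list(NULL, c("theta", "se", "cover", "reject")))
    eg_int <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("intercept", "reject")))
    for (r in seq_len(reps)) {
      p <- p0
      p$seed <- rep_seeds[r, i]
      truth <- simulate_two_sample(p)
      harm <- harmonize_set(truth$exposure_set, truth$outcome_assocs)
      hs <- harm$instruments
      for (m in methods) {
        if (m == "egger") {
          eg <- mr_egger(hs)
          e <- eg$slope
          eg_int[r, ] <- c(eg$intercept, as.numeric(eg$intercept_p < 0.05))
        } else {
          e <- switch(m,
            ivw_fe = ivw_fixed(hs),
            simple_median = simple_median(hs, n_boot = n_boot, seed = p$seed + 1L),
            weighted_median = weighted_median(hs, n_boot = n_boot, seed = p$seed + 2L))
        }
        est[[m]][r, ] <- c(e$theta, e$se,
                           as.numeric(e$ci_low <= p$causal_effect & p$causal_effect <= e$ci_high),
                           as.numeric(e$pvalue < 0.05))
      }
    }
    scen <- sprintf("scenario_%d", i)
    for (m in methods) {
      v <- est[[m]]
      out[[length(out) + 1]] <- tibble::tibble(
        scenario = scen, method = m, reps = reps, theta_true = p0$causal_effect,
        mean_estimate = mean(v[, "theta"]),
        bias = mean(v[, "theta"]) - p0$causal_effect,
        empirical_se = sd(v[, "theta"]), mean_model_se = mean(v[, "se"]),
        coverage = mean(v[, "cover"]), rejection_rate = mean(v[, "reject"])
      )
    }
    if ("egger" %in% methods) {
      target <- if (p0$pleiotropy_mode == "directional") p0$pleiotropy_mean else 0
      out[[length(out) + 1]] <- tibble::tibble(
        scenario = scen, method = "egger_intercept", reps = reps,
        theta_true = target,
        mean_estimate = mean(eg_int[, "intercept"]),
        bias = mean(eg_int[, "intercept"]) - target,
        empirical_se = sd(eg_int[, "intercept"]), mean_model_se = NA_real_,
        coverage = NA_real_, rejection_rate = mean(eg_int[, "reject"])
      )
    }
  }
  do.call(rbind, out)
}
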