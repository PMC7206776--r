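# Causal estimators for two-sample MR on harmonized instruments.
#
# Conventions shared by all methods:
#   * per-SNP Wald ratio r_j = beta_out_j / beta_exp_j
#   * inverse-variance weight w_j = beta_exp_j^2 / se_out_j^2 (first-order
#     delta-method weight; exposure-side uncertainty ignored by default)
#   * confidence level 95% throughout, z = qnorm(0.975) = 1.959964

.z95 <- qnorm(0.975)

#' Construct an MR estimate
#'
#' @param method Method label (`"wald"`, `"ivw_fe"`, `"simple_median"`,
#'   `"weighted_median"`, `"egger_slope"`).
#' @param theta Causal estimate: outcome units per exposure unit (log-OR per
#'   unit exposure for binary outcomes).
#' @param se Standard error of `theta` (> 0).
#' @param n_snps Number of instruments used.
#' @param df Degrees of freedom for a t reference distribution, or `NULL`
#'   (default) for the normal.
#' @param conf_level Confidence level (default 0.95).
#' @param outcome_type `"binary"`, `"continuous"` or `NA`; consumed by
#'   [to_or()].
#' @return An object of class `mr_estimate` with fields `method`, `theta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `n_snps`, `outcome_type`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, df = NULL, conf_level = 0.95,
                        outcome_type = NA_character_) {
  if (!is.finite(theta)) stop("theta must be finite")
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  if (is.null(df)) {
    q <- qnorm(1 - (1 - conf_level) / 2)
    pvalue <- 2 * pnorm(-abs(theta / se))
  } else {
    q <- stats::qt(1 - (1 - conf_level) / 2, df = df)
    pvalue <- 2 * pt(-abs(theta / se), df = df)
  }
  structure(
    list(method = method, theta = theta, se = se,
         ci_low = theta - q * se, ci_high = theta + q * se,
         pvalue = max(pvalue, .Machine$double.xmin), n_snps = n_snps,
         outcome_type = outcome_type),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: theta=%.4g (se %.4g), 95%% CI [%.4g, %.4g], p=%.3g, J=%d\n",
              x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

as_harm_tbl <- function(hs) {
  tbl <- if (inherits(hs, "harmonized_set")) hs$instruments else tibble::as_tibble(hs)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(setdiff(need, "se_exp"), names(tbl))
  if (length(miss) > 0) stop("harmonized instruments lack column(s): ",
                             paste(miss, collapse = ", "))
  if (!"se_exp" %in% names(tbl)) tbl$se_exp <- NA_real_
  if (!"snp_id" %in% names(tbl)) tbl$snp_id <- paste0("snp", seq_len(nrow(tbl)))
  if ("action" %in% names(tbl) && any(tbl$action == "dropped")) {
    stop("dropped instruments must not reach estimators")
  }
  tbl
}

check_nonzero_exposure <- function(tbl) {
  zero <- tbl$snp_id[tbl$beta_exp == 0]
  if (length(zero) > 0) {
    stop("degenerate instrument(s) with beta_exp = 0: ", paste(zero, collapse = ", "))
  }
}

#' Wald ratio estimate for a single instrument
#'
#' The per-SNP causal estimate: the outcome effect divided by the exposure
#' effect. By default the standard error uses the first-order delta method,
#' `se_out / |beta_exp|`, which ignores exposure-side uncertainty; the
#' second-order expansion adding the `beta_out^2 se_exp^2 / beta_exp^4` term
#' is available via `second_order = TRUE`.
#'
#' @param h A single harmonized instrument (one-row data frame or named list
#'   with `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param second_order Use the second-order delta-method SE (requires `se_exp`).
#' @param outcome_type Passed to [mr_estimate()].
#' @return An [mr_estimate()] with `method = "wald"`.
#' @export
wald_ratio <- function(h, second_order = FALSE, outcome_type = NA_character_) {
  h <- as.list(h)
  if (h$beta_exp == 0) stop("degenerate instrument: beta_exp = 0")
  theta <- h$beta_out / h$beta_exp
  se <- if (second_order) {
    if (is.null(h$se_exp) || is.na(h$se_exp)) stop("second-order SE requires se_exp")
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  } else {
    h$se_out / abs(h$beta_exp)
  }
  mr_estimate("wald", theta, se, n_snps = 1L, outcome_type = outcome_type)
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Combines per-SNP Wald ratios with weights `w_j = beta_exp_j^2 / se_out_j^2`:
#' `theta = sum(w_j r_j) / sum(w_j)`, `se = 1 / sqrt(sum(w_j))`. This is
#' algebraically the slope of a zero-intercept weighted least-squares
#' regression of outcome betas on exposure betas with weights `1/se_out^2`.
#' A multiplicative random-effects variant (residual scale inflation, clamped
#' below at 1) is available behind `random_effects = TRUE`; the fixed-effect
#' form is the default and primary method.
#'
#' @param hs Harmonized instruments ([harmonize_set()] output or a data frame).
#' @param random_effects Inflate the SE by the residual scale when it exceeds 1.
#' @param outcome_type Passed to [mr_estimate()].
#' @return An [mr_estimate()] with `method = "ivw_fe"` (or `"ivw_mre"`).
#' @export
ivw_fixed <- function(hs, random_effects = FALSE, outcome_type = NA_character_) {
  tbl <- as_harm_tbl(hs)
  if (nrow(tbl) < 1) stop("ivw_fixed requires at least 1 instrument")
  check_nonzero_exposure(tbl)
  w <- tbl$beta_exp^2 / tbl$se_out^2
  r <- tbl$beta_out / tbl$beta_exp
  theta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  method <- "ivw_fe"
  if (random_effects) {
    J <- nrow(tbl)
    if (J > 1) {
      sigma <- sqrt(sum(w * (r - theta)^2) / (J - 1))
      se <- se * max(1, sigma)
    }
    method <- "ivw_mre"
  }
  mr_estimate(method, theta, se, n_snps = nrow(tbl), outcome_type = outcome_type)
}

# Parametric bootstrap SE shared by the median estimators: redraw every
# beta_exp_j and beta_out_j from normals centred at the observed values with
# their SEs, recompute the point estimate, and take the SD across replicates.
boot_median_se <- function(tbl, point_fun, n_boot, seed) {
  if (is.null(seed) || is.na(seed)) stop("median estimators require a seed")
  J <- nrow(tbl)
  if (any(is.na(tbl$se_exp))) stop("median bootstrap requires se_exp")
  thetas <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, tbl$beta_exp, tbl$se_exp)
      bo <- rnorm(J, tbl$beta_out, tbl$se_out)
      point_fun(bo / bx, bx^2 / tbl$se_out^2)
    }, numeric(1))
  })
  sd(thetas)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o]
  S <- cumsum(w)
  p <- (S - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Simple median estimate
#'
#' The median of the per-SNP Wald ratios (for an even number of instruments,
#' the mean of the middle two). The standard error is a parametric bootstrap:
#' each replicate redraws all exposure and outcome betas from normals centred
#' at the observed values with their standard errors and recomputes the
#' median ratio; the SE is the SD over replicates. CI and p-value are
#' normal-theory from (theta, se).
#'
#' @param hs Harmonized instruments (at least 3).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @param outcome_type Passed to [mr_estimate()].
#' @return An [mr_estimate()] with `method = "simple_median"`.
#' @export
simple_median <- function(hs, n_boot = 5000, seed, outcome_type = NA_character_) {
  tbl <- as_harm_tbl(hs)
  if (nrow(tbl) < 3) stop("simple_median requires at least 3 instruments")
  check_nonzero_exposure(tbl)
  theta <- median(tbl$beta_out / tbl$beta_exp)
  se <- boot_median_se(tbl, function(r, w) median(r), n_boot, seed)
  mr_estimate("simple_median", theta, se, n_snps = nrow(tbl),
              outcome_type = outcome_type)
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the 50% point of their cumulative
#' standardized inverse-variance weights: with ratios ascending and weights
#' `w_j = beta_exp_j^2 / se_out_j^2`, the cumulative fraction is
#' `p_j = (S_j - w_j/2) / sum(w)` (S_j the running sum) and theta
#' interpolates the ratios linearly at `p = 0.5`. Consistent when valid
#' instruments carry more than half of the total weight, which is what makes
#' it the standard pleiotropy-robust sensitivity analysis. SE by the same
#' parametric bootstrap as [simple_median()].
#'
#' @inheritParams simple_median
#' @return An [mr_estimate()] with `method = "weighted_median"`.
#' @export
weighted_median <- function(hs, n_boot = 5000, seed, outcome_type = NA_character_) {
  tbl <- as_harm_tbl(hs)
  if (nrow(tbl) < 3) stop("weighted_median requires at least 3 instruments")
  check_nonzero_exposure(tbl)
  theta <- weighted_median_point(tbl$beta_out / tbl$beta_exp,
                                 tbl$beta_exp^2 / tbl$se_out^2)
  se <- boot_median_se(tbl, weighted_median_point, n_boot, seed)
  mr_estimate("weighted_median", theta, se, n_snps = nrow(tbl),
              outcome_type = outcome_type)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with weights
#' `1/se_out^2` and a free intercept, after re-orienting every instrument to
#' its exposure-increasing allele (both betas negated where `beta_exp < 0`).
#' A non-zero intercept is evidence of directional (unbalanced) horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate. Standard
#' errors are inflated by the residual scale when it exceeds 1 (clamped below
#' at 1, so overdispersion widens intervals but underdispersion never narrows
#' them); p-values use the t distribution with J - 2 degrees of freedom.
#'
#' @param hs Harmonized instruments (at least 3).
#' @param outcome_type Passed to [mr_estimate()].
#' @return An object of class `egger_result`: list with `slope` (an
#'   [mr_estimate()] with `method = "egger_slope"`), `intercept`,
#'   `intercept_se`, `intercept_p`, `scale_factor`.
#' @export
mr_egger <- function(hs, outcome_type = NA_character_) {
  tbl <- as_harm_tbl(hs)
  J <- nrow(tbl)
  if (J < 3) stop("mr_egger requires at least 3 instruments")
  check_nonzero_exposure(tbl)
  flip <- tbl$beta_exp < 0
  x <- ifelse(flip, -tbl$beta_exp, tbl$beta_exp)
  y <- ifelse(flip, -tbl$beta_out, tbl$beta_out)
  w <- 1 / tbl$se_out^2
  if (var(x) == 0) stop("collinearity: zero variance in exposure betas")

  X <- cbind(intercept = 1, slope = x)
  A <- solve(crossprod(X, w * X))              # (X' W X)^-1
  beta_hat <- drop(A %*% crossprod(X, w * y))
  resid <- y - drop(X %*% beta_hat)
  sigma <- sqrt(sum(w * resid^2) / (J - 2))
  scale_factor <- max(1, sigma)
  ses <- sqrt(diag(A)) * scale_factor

  slope <- mr_estimate("egger_slope", unname(beta_hat[2]), unname(ses[2]), n_snps = J,
                       df = J - 2, outcome_type = outcome_type)
  intercept_p <- 2 * pt(-abs(beta_hat[1] / ses[1]), df = J - 2)
  structure(
    list(slope = slope, intercept = unname(beta_hat[1]),
         intercept_se = unname(ses[1]), intercept_p = max(intercept_p, .Machine$double.xmin),
         scale_factor = scale_factor),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept=%.4g (se %.4g), p=%.3g, residual scale=%.3g\n",
              x$intercept, x$intercept_se, x$intercept_p, x$scale_factor))
  invisible(x)
}

#' Cochran's Q and I-squared heterogeneity across instruments
#'
#' `Q = sum(w_j (r_j - theta_ref)^2)` with the IVW weights, degrees of freedom
#' `J - 1`, p-value from the chi-squared distribution, and
#' `I2 = max(0, (Q - df)/Q) * 100` (0 when Q = 0): the percentage of
#' variation in per-SNP ratios attributable to heterogeneity rather than
#' sampling error.
#'
#' @param hs Harmonized instruments (at least 2).
#' @param theta_ref Reference causal estimate, usually the IVW theta.
#' @return An object of class `heterogeneity_result`: list with `Q`, `df`,
#'   `pvalue`, `I2`.
#' @export
heterogeneity <- function(hs, theta_ref) {
  tbl <- as_harm_tbl(hs)
  J <- nrow(tbl)
  if (J < 2) stop("heterogeneity requires at least 2 instruments")
  check_nonzero_exposure(tbl)
  w <- tbl$beta_exp^2 / tbl$se_out^2
  r <- tbl$beta_out / tbl$beta_exp
  Q <- sum(w * (r - theta_ref)^2)
  df <- J - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(
    list(Q = Q, df = df, pvalue = pchisq(Q, df, lower.tail = FALSE), I2 = I2),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity> Q=%.3g on %d df (p=%.3g), I2=%.1f%%\n",
              x$Q, x$df, x$pvalue, x$I2))
  invisible(x)
}

#' Convert a log-odds-scale estimate to an odds ratio with CI
#'
#' @param est An [mr_estimate()] whose theta is on the log-OR scale (binary
#'   outcome). Passing an estimate flagged `outcome_type = "continuous"` is an
#'   error: effect sizes for continuous outcomes are not exponentiated.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or`, `ci_low`, `ci_high`.
#' @export
to_or <- function(est, conf_level = 0.95) {
  stopifnot(inherits(est, "mr_estimate"))
  if (identical(est$outcome_type, "continuous")) {
    stop("estimate is for a continuous outcome; effect sizes are not exponentiated")
  }
  if (!is.finite(est$se) || est$se <= 0) stop("se must be > 0")
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(est$theta),
       ci_low = exp(est$theta - z * est$se),
       ci_high = exp(est$theta + z * est$se))
}
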