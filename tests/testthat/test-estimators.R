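test_that("wald ratio divides effects and propagates outcome-side error", {
  h <- list(beta_exp = 0.05, se_exp = 0.007, beta_out = -0.02, se_out = 0.01)
  est <- wald_ratio(h)
  expect_equal(est$theta, -0.4)
  expect_equal(est$se, 0.2)
  expect_equal(est$ci_low, -0.4 - qnorm(0.975) * 0.2)

  # allele-flip symmetry
  est2 <- wald_ratio(list(beta_exp = -0.05, se_exp = 0.007, beta_out = 0.02, se_out = 0.01))
  expect_equal(est2$theta, -0.4)
  expect_equal(est2$se, 0.2)

  expect_error(wald_ratio(list(beta_exp = 0, se_exp = 1, beta_out = 1, se_out = 1)),
               "degenerate")
})

test_that("second-order delta SE tracks the simulated SD of the ratio", {
  h <- list(beta_exp = 0.05, se_exp = 0.007, beta_out = -0.02, se_out = 0.01)
  est2 <- wald_ratio(h, second_order = TRUE)
  expect_equal(est2$se, sqrt(0.01^2 / 0.05^2 + 0.02^2 * 0.007^2 / 0.05^4))
  # independent oracle: parametric simulation of the ratio's spread
  set.seed(123)
  sim_sd <- sd(rnorm(1e6, -0.02, 0.01) / rnorm(1e6, 0.05, 0.007))
  expect_lt(abs(est2$se - sim_sd) / sim_sd, 0.05)
  # and it is closer to the simulated SD than the first-order SE
  est1 <- wald_ratio(h)
  expect_lt(abs(est2$se - sim_sd), abs(est1$se - sim_sd))
})

test_that("fixed-effect IVW reduces to the Wald ratio at J=1 and averages ratios", {
  h1 <- make_harm(0.05, -0.02, 0.01)
  expect_equal(ivw_fixed(h1)$theta, wald_ratio(h1[1, ])$theta)
  expect_equal(ivw_fixed(h1)$se, wald_ratio(h1[1, ])$se)

  # equal weights across instruments: plain mean of the ratios
  hs <- make_harm(beta_exp = c(0.1, 0.1, 0.1),
                  beta_out = c(0.05, 0.10, 0.15),
                  se_out = c(0.01, 0.01, 0.01))
  expect_equal(ivw_fixed(hs)$theta, 1.0)

  expect_error(ivw_fixed(make_harm(numeric(0), numeric(0), numeric(0))), "at least 1")
  bad <- make_harm(c(0.1, 0), c(0.1, 0.1), c(0.01, 0.01), snp_id = c("rsA", "rsZero"))
  expect_error(ivw_fixed(bad), "rsZero")
})

test_that("IVW equals zero-intercept WLS and Egger equals free-intercept WLS", {
  set.seed(42)
  for (i in 1:100) {
    J <- sample(3:12, 1)
    hs <- make_harm(beta_exp = rnorm(J, 0.08, 0.04) + 0.02,
                    beta_out = rnorm(J, 0, 0.05),
                    se_out = runif(J, 0.005, 0.05),
                    se_exp = runif(J, 0.002, 0.01))
    w <- 1 / hs$se_out^2

    ivw <- ivw_fixed(hs)
    wls0 <- lm(beta_out ~ beta_exp - 1, data = hs, weights = w)
    expect_equal(ivw$theta, unname(coef(wls0)[1]), tolerance = 1e-10)
    expect_equal(ivw$se, 1 / sqrt(sum(hs$beta_exp^2 / hs$se_out^2)), tolerance = 1e-10)

    eg <- mr_egger(hs)
    # oracle: re-orient, free-intercept WLS, residual-scale clamp at 1
    flip <- hs$beta_exp < 0
    x <- ifelse(flip, -hs$beta_exp, hs$beta_exp)
    y <- ifelse(flip, -hs$beta_out, hs$beta_out)
    wls1 <- lm(y ~ x, weights = w)
    sm <- summary(wls1)
    expect_equal(eg$slope$theta, unname(coef(wls1)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept, unname(coef(wls1)[1]), tolerance = 1e-10)
    expect_equal(eg$slope$se, unname(coef(sm)[2, 2]) / min(1, sm$sigma), tolerance = 1e-10)
    expect_equal(eg$intercept_se, unname(coef(sm)[1, 2]) / min(1, sm$sigma), tolerance = 1e-10)
    expect_equal(eg$scale_factor, max(1, sm$sigma), tolerance = 1e-10)
  }
})

test_that("median estimators take the (weighted) midpoint of the ratio distribution", {
  hs <- make_harm(beta_exp = rep(0.1, 3), beta_out = 0.1 * c(1, 2, 9),
                  se_out = rep(0.01, 3))
  expect_equal(simple_median(hs, n_boot = 100, seed = 1)$theta, 2)
  hs4 <- make_harm(beta_exp = rep(0.1, 4), beta_out = 0.1 * c(1, 2, 3, 10),
                   se_out = rep(0.01, 4))
  expect_equal(simple_median(hs4, n_boot = 100, seed = 1)$theta, 2.5)

  # worked interpolation example: ratios {1,2,3}, weights {1,1,2};
  # cumulative standardized weights p_j = (S_j - w_j/2)/sum(w)
  # = {0.125, 0.375, 0.75}, so theta interpolates to
  # 2 + (3-2)*(0.5-0.375)/(0.75-0.375) = 7/3
  hs3 <- make_harm(beta_exp = c(0.1, 0.1, 0.1 * sqrt(2)),
                   beta_out = c(0.1 * 1, 0.1 * 2, 0.1 * sqrt(2) * 3),
                   se_out = rep(0.1, 3))
  expect_equal(weighted_median(hs3, n_boot = 100, seed = 1)$theta, 7 / 3)
  # invariance to rescaling the weights (a property the interpolation
  # formula must have: only relative weights matter)
  hs3b <- hs3
  hs3b$se_out <- hs3b$se_out / 2  # multiplies every weight by 4
  expect_equal(weighted_median(hs3b, n_boot = 100, seed = 1)$theta, 7 / 3)

  # equal weights: weighted median == simple median (odd J: no interpolation)
  hs5 <- make_harm(beta_exp = rep(0.2, 5), beta_out = 0.2 * c(0.1, 0.4, 0.7, 1.1, 3),
                   se_out = rep(0.02, 5))
  expect_equal(weighted_median(hs5, n_boot = 100, seed = 9)$theta,
               simple_median(hs5, n_boot = 100, seed = 9)$theta)

  expect_error(simple_median(make_harm(c(0.1, 0.1), c(0.1, 0.1), c(0.01, 0.01)),
                             seed = 1), "at least 3")
})

test_that("median bootstrap SEs are seed-reproducible and stable in n_boot", {
  sim <- simulate_two_sample(sim_params(n_snps = 5, causal_effect = 0.2, seed = 21))
  hs <- harmonize_set(sim$exposure_set, sim$outcome_assocs)$instruments
  a <- simple_median(hs, n_boot = 5000, seed = 404)
  b <- simple_median(hs, n_boot = 5000, seed = 404)
  expect_identical(a$se, b$se)
  c2 <- simple_median(hs, n_boot = 10000, seed = 404)
  expect_lt(abs(c2$se - a$se) / a$se, 0.03)
  w1 <- weighted_median(hs, n_boot = 5000, seed = 404)
  w2 <- weighted_median(hs, n_boot = 10000, seed = 404)
  expect_lt(abs(w2$se - w1$se) / w1$se, 0.03)
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simple_median(hs, n_boot = 50, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("an exact line is recovered by MR-Egger with unit residual scale", {
  x <- c(0.02, 0.05, 0.09, 0.12)
  hs <- make_harm(beta_exp = x, beta_out = 0.1 + 0.5 * x,
                  se_out = c(0.01, 0.02, 0.015, 0.03))
  eg <- mr_egger(hs)
  expect_equal(eg$intercept, 0.1, tolerance = 1e-12)
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-12)
  expect_equal(eg$scale_factor, 1)
  expect_error(mr_egger(hs[1:2, ]), "at least 3")
  flat <- make_harm(rep(0.1, 4), c(0.1, 0.2, 0.1, 0.3), rep(0.01, 4))
  expect_error(mr_egger(flat), "collinearity")
})

test_that("heterogeneity follows the Q / I-squared formulas with clamping", {
  # Q = 10 on 4 df => I2 = 60%
  hs <- make_harm(beta_exp = rep(1, 5), beta_out = c(1, 1, 1, 1 + sqrt(5), 1 - sqrt(5)),
                  se_out = rep(1, 5))
  het <- heterogeneity(hs, theta_ref = 1)
  expect_equal(het$Q, 10)
  expect_equal(het$df, 4)
  expect_equal(het$I2, 60)
  expect_equal(het$pvalue, pchisq(10, 4, lower.tail = FALSE))

  # identical ratios: Q = 0, I2 = 0
  same <- make_harm(rep(0.1, 4), rep(0.05, 4), rep(0.01, 4))
  het0 <- heterogeneity(same, theta_ref = 0.5)
  expect_equal(het0$Q, 0)
  expect_equal(het0$I2, 0)

  # Q below its df clamps I2 at 0
  hs3 <- make_harm(beta_exp = rep(1, 5), beta_out = c(1, 1, 1, 1 + sqrt(1.5), 1 - sqrt(1.5)),
                   se_out = rep(1, 5))
  expect_equal(heterogeneity(hs3, 1)$Q, 3)
  expect_equal(heterogeneity(hs3, 1)$I2, 0)
  expect_error(heterogeneity(same[1, ], 0), "at least 2")
})

test_that("log-OR estimates exponentiate to the published display scale", {
  null <- mr_estimate("ivw_fe", 0, 0.1, 5)
  expect_equal(to_or(null)$or, 1.0)
  # the VPA -> CAD display values arise from (theta, se) = (-0.431, 0.166)
  tr <- to_or(mr_estimate("ivw_fe", -0.431, 0.166, 5))
  expect_equal(round(tr$or, 2), 0.65)
  expect_equal(round(tr$ci_low, 2), 0.47)
  expect_equal(round(tr$ci_high, 2), 0.90)
  expect_error(mr_estimate("ivw_fe", 1, 0, 5), "se must be > 0")
  cont <- mr_estimate("ivw_fe", 0.2, 0.1, 5, outcome_type = "continuous")
  expect_error(to_or(cont), "continuous")
})

test_that("estimates are scale-equivariant in the exposure units", {
  sim <- simulate_two_sample(sim_params(n_snps = 8, causal_effect = 0.3, seed = 66))
  hs <- harmonize_set(sim$exposure_set, sim$outcome_assocs)$instruments
  c_ <- 60  # e.g. hours -> minutes
  scaled <- hs
  scaled$beta_exp <- scaled$beta_exp * c_
  scaled$se_exp <- scaled$se_exp * c_

  for (pair in list(
    list(ivw_fixed(hs), ivw_fixed(scaled)),
    list(mr_egger(hs)$slope, mr_egger(scaled)$slope),
    list(simple_median(hs, n_boot = 400, seed = 3), simple_median(scaled, n_boot = 400, seed = 3)),
    list(weighted_median(hs, n_boot = 400, seed = 3), weighted_median(scaled, n_boot = 400, seed = 3))
  )) {
    expect_equal(pair[[2]]$theta, pair[[1]]$theta / c_, tolerance = 1e-8)
    expect_equal(pair[[2]]$theta / pair[[2]]$se, pair[[1]]$theta / pair[[1]]$se,
                 tolerance = 0.05)
  }
  # z-scores of the analytic methods match exactly
  expect_equal(ivw_fixed(scaled)$theta / ivw_fixed(scaled)$se,
               ivw_fixed(hs)$theta / ivw_fixed(hs)$se, tolerance = 1e-10)
})
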