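test_that("align_alleles applies the matching rules in order", {
  # identical effect alleles: kept as-is
  h <- align_alleles(make_variant(effect_allele = "G", beta = 0.028),
                     make_variant(effect_allele = "G", other_allele = "A", beta = 0.10))
  expect_equal(h$action, "as_is")
  expect_equal(h$beta_out, 0.10)

  # outcome effect allele = exposure other allele: sign flip
  h <- align_alleles(make_variant(effect_allele = "G", other_allele = "A", beta = 0.028),
                     make_variant(effect_allele = "A", other_allele = "G", beta = 0.10,
                                  eaf = 0.58))
  expect_equal(h$action, "flipped_sign")
  expect_equal(h$beta_out, -0.10)

  # exposure other allele missing (published-table situation): EAF resolves the flip
  h <- align_alleles(make_variant(effect_allele = "G", eaf = 0.415, beta = 0.028),
                     make_variant(effect_allele = "A", other_allele = "G",
                                  eaf = 0.58, beta = 0.10))
  expect_equal(h$action, "flipped_sign")
  expect_equal(h$beta_out, -0.10)
  expect_equal(h$eaf_out, 0.42)

  # alleles agree only after strand complementation
  h <- align_alleles(make_variant(effect_allele = "G", other_allele = "A", beta = 0.03),
                     make_variant(effect_allele = "C", other_allele = "T", beta = 0.2))
  expect_equal(h$action, "strand_complemented")
  expect_equal(h$beta_out, 0.2)
  h <- align_alleles(make_variant(effect_allele = "G", other_allele = "A", beta = 0.03),
                     make_variant(effect_allele = "T", other_allele = "C", beta = 0.2))
  expect_equal(h$action, "strand_complemented")
  expect_equal(h$beta_out, -0.2)

  # palindromic SNP with ambiguous frequency: dropped
  h <- align_alleles(make_variant(effect_allele = "A", other_allele = "T", eaf = 0.50),
                     make_variant(effect_allele = "A", other_allele = "T", eaf = 0.50,
                                  beta = 0.2),
                     palindrome_eaf_window = c(0.42, 0.58))
  expect_equal(h$action, "dropped")

  # palindromic outside the window: kept, oriented by frequency
  h <- align_alleles(make_variant(effect_allele = "A", other_allele = "T", eaf = 0.20),
                     make_variant(effect_allele = "A", other_allele = "T", eaf = 0.21,
                                  beta = 0.2))
  expect_equal(h$action, "palindromic_kept")
  expect_equal(h$beta_out, 0.2)
  # allele labels are strand-ambiguous for palindromes: frequency evidence
  # (0.21 ~ 0.20) overrides the nominal label swap
  h <- align_alleles(make_variant(effect_allele = "A", other_allele = "T", eaf = 0.20),
                     make_variant(effect_allele = "T", other_allele = "A", eaf = 0.21,
                                  beta = 0.2))
  expect_equal(h$action, "palindromic_kept")
  expect_equal(h$beta_out, 0.2)
  # discordant frequencies flip the sign
  h <- align_alleles(make_variant(effect_allele = "A", other_allele = "T", eaf = 0.20),
                     make_variant(effect_allele = "A", other_allele = "T", eaf = 0.79,
                                  beta = 0.2))
  expect_equal(h$action, "palindromic_kept")
  expect_equal(h$beta_out, -0.2)

  # irreconcilable alleles: dropped with a reason, not an error
  h <- align_alleles(make_variant(effect_allele = "A", other_allele = "G"),
                     make_variant(effect_allele = "A", other_allele = "C", beta = 0.2))
  expect_equal(h$action, "dropped")
  expect_match(h$reason, "irreconcilable")
})

test_that("harmonize_set intersects on rsID and logs every action", {
  vpa <- load_instrument_fixture("VPA")
  out <- vpa$variants
  out$beta <- 0.1
  out$se <- 0.02
  h <- harmonize_set(vpa, out)
  expect_equal(nrow(h$instruments), 5)
  expect_equal(unname(h$counts["dropped"]), 0)

  h4 <- harmonize_set(vpa, out[1:4, ])
  expect_equal(nrow(h4$instruments), 4)
  expect_equal(unname(h4$counts["absent_from_outcome"]), 1)
  expect_equal(sum(h4$counts) - h4$counts[["absent_from_outcome"]], 4)
  expect_equal(nrow(h4$log), 5)

  expect_error(harmonize_set(vpa, out[0, ]), "no overlapping instruments")
})

test_that("strand-corrupted outcome tables harmonize back to identical estimates", {
  for (corrupt in c("strand_flip", "allele_swap")) {
    clean <- simulate_two_sample(sim_params(n_snps = 20, causal_effect = 0.25, seed = 31))
    dirty <- simulate_two_sample(sim_params(n_snps = 20, causal_effect = 0.25, seed = 31,
                                            corrupt = corrupt))
    hc <- harmonize_set(clean$exposure_set, clean$outcome_assocs)
    hd <- harmonize_set(dirty$exposure_set, dirty$outcome_assocs)
    expected_action <- if (corrupt == "strand_flip") "strand_complemented" else "flipped_sign"
    expect_true(all(hd$instruments$action == expected_action), info = corrupt)
    expect_equal(ivw_fixed(hd$instruments)$theta, ivw_fixed(hc$instruments)$theta,
                 tolerance = 1e-12, info = corrupt)
    expect_equal(mr_egger(hd$instruments)$slope$theta,
                 mr_egger(hc$instruments)$slope$theta, tolerance = 1e-12, info = corrupt)
  }
})

test_that("harmonization is involution-safe and drops never reach estimators", {
  sim <- simulate_two_sample(sim_params(n_snps = 15, causal_effect = 0.1, seed = 77))
  h1 <- harmonize_set(sim$exposure_set, sim$outcome_assocs)
  # re-express the harmonized outcome as an association table and re-harmonize
  out2 <- sim$exposure_set$variants
  out2 <- out2[match(h1$instruments$snp_id, out2$snp_id), ]
  out2$beta <- h1$instruments$beta_out
  out2$se <- h1$instruments$se_out
  out2$eaf <- h1$instruments$eaf_out
  h2 <- harmonize_set(sim$exposure_set, out2)
  expect_true(all(h2$instruments$action == "as_is"))
  expect_identical(h2$instruments$beta_out, h1$instruments$beta_out)

  # palindromic SNPs inside the EAF window are dropped, logged, and excluded
  pal <- simulate_two_sample(sim_params(n_snps = 40, causal_effect = 0.1, seed = 78,
                                        corrupt = "palindromic"))
  hp <- harmonize_set(pal$exposure_set, pal$outcome_assocs,
                      palindrome_eaf_window = c(0.42, 0.58))
  eaf <- pal$exposure_set$variants$eaf
  in_window <- eaf >= 0.42 & eaf <= 0.58
  expect_equal(unname(hp$counts[["dropped"]]), sum(in_window))
  expect_equal(sum(hp$log$action == "dropped"), sum(in_window))
  expect_false(any(hp$instruments$action == "dropped"))
  # the estimator refuses tables still containing dropped rows
  bad <- make_harm(c(0.1, 0.2), c(0.1, 0.2), c(0.01, 0.01))
  bad$action[2] <- "dropped"
  expect_error(ivw_fixed(bad), "dropped instruments")
})

test_that("re-expressing any instrument on its other allele leaves estimates unchanged", {
  sim <- simulate_two_sample(sim_params(n_snps = 9, causal_effect = 0.4, seed = 55))
  h <- harmonize_set(sim$exposure_set, sim$outcome_assocs)$instruments
  flipped <- h
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(ivw_fixed(flipped)$theta, ivw_fixed(h)$theta, tolerance = 1e-12)
  expect_equal(simple_median(flipped, n_boot = 300, seed = 2)$theta,
               simple_median(h, n_boot = 300, seed = 2)$theta, tolerance = 1e-12)
  expect_equal(weighted_median(flipped, n_boot = 300, seed = 2)$theta,
               weighted_median(h, n_boot = 300, seed = 2)$theta, tolerance = 1e-12)
  eg1 <- mr_egger(flipped); eg2 <- mr_egger(h)
  expect_equal(eg1$slope$theta, eg2$slope$theta, tolerance = 1e-12)
  expect_equal(eg1$intercept, eg2$intercept, tolerance = 1e-12)
})
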