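# lifestyleMR

Two-sample Mendelian randomization (MR) of lifestyle exposures — physical
activity, sedentary behaviours, sleep duration — on cardiovascular outcomes
and lipid profiles, from GWAS summary statistics alone.

MR uses genetic variants as instrumental variables: because alleles are
randomized at conception, a variant robustly associated with an exposure
provides an estimate of the exposure's causal effect that is largely immune
to confounding and reverse causation. In the two-sample design the
variant–exposure effects (β̂_X, σ_X) and variant–outcome effects (β̂_Y, σ_Y)
come from different GWAS samples, so only published per-SNP summary
statistics are needed. The package is aimed at epidemiologists who want the
complete summary-statistics workflow — ingestion, harmonization, estimation,
diagnostics, reporting — as tested, scriptable R functions.

## What it computes

For harmonized instruments j = 1..J, with Wald ratios r_j = β̂_Yj / β̂_Xj
and weights w_j = β̂²_Xj / σ²_Yj:

- **Fixed-effect IVW** (primary): θ̂ = Σ w_j r_j / Σ w_j, se = (Σ w_j)^(−1/2) —
  the zero-intercept weighted-least-squares slope of β̂_Y on β̂_X;
- **Simple median** of the r_j, and the **weighted median** (linear
  interpolation of the ordered ratios at cumulative standardized weight ½;
  consistent when valid instruments carry > 50% of the weight), both with
  parametric-bootstrap standard errors;
- **MR-Egger**: free-intercept WLS after orienting instruments to the
  exposure-increasing allele; the intercept estimates average directional
  pleiotropy and its t(J−2) test is the pleiotropy diagnostic;
- **Cochran's Q / I²** heterogeneity across the per-SNP ratios;
- **Bonferroni-aware labels** over an exposure × outcome grid
  (α / (exposures × outcomes); p < 0.05 above that threshold is
  "suggestive").

Allele harmonization resolves sign flips, strand complements and
palindromic (A/T, G/C) ambiguity — palindromes with effect-allele frequency
inside a configurable window (default [0.42, 0.58]) are dropped and logged.
Instrument sets for four lifestyle exposures (9 MVPA, 5 VPA, 4 sedentary, 7
sleep-duration SNPs) ship as a packaged fixture, and a seeded synthetic
two-sample generator with known causal structure backs calibration and
type-I-error experiments (`simulate_two_sample()`,
`calibration_experiment()`).

## Worked example

Run the packaged VPA instruments against a synthetic CAD-scale outcome with
a known protective effect (log-OR −0.43 per unit log-odds of VPA):

```r
library(lifestyleMR)

vpa <- load_instrument_fixture("VPA")
out <- simulate_outcome_table(vpa, causal_effect = -0.43,
                              outcome_n = 184305, seed = 14)
cfg <- analysis_config(n_boot = 5000, seed = 14, n_tests = 12)
pr  <- run_pair(vpa, out,
                meta = outcome_meta("CAD_synthetic", "binary",
                                    n_cases = 60801, n_controls = 123504),
                cfg = cfg)
pr
#> <pair_result> VPA -> CAD_synthetic (binary outcome), J=5, significant
#> <mr_estimate> ivw_fe: theta=-0.3355 (se 0.03744), 95% CI [-0.4089, -0.2622], p=3.18e-19, J=5
#> <mr_estimate> simple_median: theta=-0.2992 (se 0.06113), 95% CI [-0.419, -0.1794], p=9.87e-07, J=5
#> <mr_estimate> weighted_median: theta=-0.3375 (se 0.05553), 95% CI [-0.4463, -0.2287], p=1.22e-09, J=5
#> <mr_estimate> egger_slope: theta=-0.4868 (se 0.1817), 95% CI [-1.065, 0.09154], p=0.0751, J=5
#> <heterogeneity> Q=3.77 on 4 df (p=0.438), I2=0.0%

to_or(pr$estimates$ivw_fe)   # report on the odds-ratio scale
#> IVW OR 0.71 (95% CI 0.66-0.77)
```

All five instruments harmonized as-is, the IVW estimate recovers the
simulated protective effect (the gap from −0.43 is one draw's sampling
noise), the medians agree, the Egger intercept test finds no directional
pleiotropy, and I² = 0 indicates homogeneous per-SNP ratios. "significant"
means the IVW p-value clears the Bonferroni threshold 0.05/12 supplied via
`n_tests`.

The `analysis/` directory stages the same workflow as a narrative pipeline —
`01_instruments.R` (instrument bookkeeping and locus pruning),
`02_simulate.R` (synthetic outcome tables at consortium scale),
`03_mr_grid.R` (the full exposure × outcome grid with TSV output),
`04_calibration.R` (Monte-Carlo calibration) — writing tables under
`results/`. Outcome summary statistics from the CAD/MI/stroke/lipid
consortia are not redistributable; users with access can supply them as
TSVs under `inst/extdata/outcomes/` (see the vignette) to reproduce the
published odds ratios.

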