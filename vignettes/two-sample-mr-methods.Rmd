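---
title: "Two-sample Mendelian randomization: models, estimators and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization: models, estimators and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifestyleMR)
```

## The problem

Observational associations between lifestyle — physical activity, sedentary
time, sleep duration — and cardiovascular disease are vulnerable to
confounding and reverse causation. Mendelian randomization (MR) sidesteps
both by using genetic variants as instrumental variables: alleles are
randomized at conception, fixed for life, and (ideally) affect the outcome
only through the exposure. In the *two-sample* design, the variant–exposure
associations ($\hat\beta_{Xj}, \sigma_{Xj}$) and variant–outcome associations
($\hat\beta_{Yj}, \sigma_{Yj}$) come from different, non-overlapping GWAS
samples, so only published summary statistics are needed.

lifestyleMR implements the full summary-statistics workflow: instrument
ingestion and selection, allele harmonization, four causal estimators,
pleiotropy and heterogeneity diagnostics, Bonferroni-aware reporting over an
exposure-by-outcome grid, and a synthetic-data generator with known causal
structure so every stage is testable without any external downloads.

## Instruments

`load_instrument_fixture()` ships the instrument sets for four lifestyle
exposures — 9 SNPs for moderate-to-vigorous physical activity (MVPA,
continuous), 5 for vigorous physical activity (VPA, binary, so estimates are
"per 1 unit higher log odds"), 4 for sedentary behaviours and 7 for sleep
duration (betas in minutes/night per allele, exactly as published; no unit
rescaling is attempted at ingest because no SD conversion factors are
available). The source tables report no non-effect allele, so
`other_allele` is stored as missing rather than invented, and harmonization
falls back on allele frequencies (below).

`apply_selection_filters()` re-expresses the stated inclusion rule: keep
genome-wide-significant variants ($P < 5\times10^{-8}$) and, where several
retained variants sit within one locus, the lowest-p variant only. Because
no LD reference panel is consulted, a "locus" is positional: same-chromosome
variants closer than `locus_window_bp` (default 500 kb, configurable —
conventional, not taken from any source table) are single-linkage-clustered.
Ties break by smaller SE, then rsID. Two quirks of the packaged sets are
worth knowing: strict re-application drops two published instruments whose
printed p-values sit just above the threshold (rs149943 at 5.6e-8, rs2764261
at 5.3e-8), and the seven sleep-duration SNPs collapse to two positional
loci (PAX8 and IER3 clusters). The fixture preserves the published sets
verbatim; pruning is the caller's choice.

## Harmonization

Both studies must report effects on the same allele per SNP.
`align_alleles()` applies, in order:

1. **palindromic check first.** A/T and G/C pairs match the plain rules on
   either strand, so they would otherwise be silently mis-oriented. Inside
   the frequency-ambiguity window (`palindrome_eaf_window`, default
   [0.42, 0.58]; [0.5, 0.5] disables) they are dropped; outside it they are
   oriented purely by frequency concordance — for palindromes the allele
   letters carry no strand information.
2. **as-is** when effect alleles (and other alleles, where present) agree.
3. **sign flip** when the outcome's effect allele is the exposure's other
   allele — or, when the exposure's other allele is unrecorded (the packaged
   fixture's situation), when the outcome EAF matches $1 - $ exposure EAF
   within `eaf_tol` (default 0.08).
4. **strand complementation** (A↔T, C↔G) followed by rules 2–3.
5. otherwise **dropped** with a logged reason — never an exception.

If both the other allele and the EAF are missing the SNP is kept as-is with
a warning; that orientation is an unverifiable assumption and is flagged as
such in the log. Dropped SNPs never reach the estimators, and
`harmonize_set()` returns a per-SNP action log whose counts always sum to
the exposure–outcome intersection.

## Estimators

With Wald ratios $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ and inverse-variance
weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$:

* **IVW (fixed-effect)** — $\hat\theta = \sum w_j r_j / \sum w_j$,
  $\mathrm{se} = (\sum w_j)^{-1/2}$; algebraically the zero-intercept WLS
  slope of $\hat\beta_Y$ on $\hat\beta_X$ with weights $1/\sigma_Y^2$. The
  primary method. A multiplicative random-effects variant (SE inflated by
  the residual scale, clamped at 1) sits behind `random_effects = TRUE`.
* **Simple median** — the median ratio; robust to up to 50% invalid
  instruments by count.
* **Weighted median** — order the ratios, form cumulative standardized
  weights $p_j = (S_j - w_j/2)/\sum w$, and interpolate linearly at
  $p = 0.5$; consistent when valid instruments carry more than half the
  weight. Only relative weights matter (the formula is invariant to
  rescaling all $w_j$), which is a property any weighted quantile must have.
* **MR-Egger** — free-intercept WLS after re-orienting every instrument to
  its exposure-increasing allele. The intercept estimates the average
  directional pleiotropy; its t-test (df $J-2$) is the pleiotropy
  diagnostic. SEs are inflated by the residual scale, clamped below at 1:
  overdispersion widens intervals, underdispersion never narrows them.
* **Cochran's Q / I²** — $Q = \sum w_j (r_j - \hat\theta_{IVW})^2$ on
  $J - 1$ df, $I^2 = \max(0, (Q - df)/Q) \times 100$.

Numerical conventions, chosen once: the Wald-ratio SE uses the first-order
delta method $\sigma_Y/|\hat\beta_X|$ (the dominant two-sample convention;
the second-order form adding $\hat\beta_Y^2\sigma_X^2/\hat\beta_X^4$ is a
flag — it tracks the simulated SD of the ratio to a few percent, the
residual gap being delta-method truncation, not error). Median-method SEs
use a parametric bootstrap (default 5000 replicates, mandatory seed; both
betas redrawn from normals at their observed values): the methods are
order statistics, so no clean closed form exists. IVW and median p-values
are normal-theory; Egger's use $t(J-2)$, acknowledging the estimated
residual scale. All intervals are 95% throughout. The bootstrap restores
the caller's RNG state, so pipeline results are reproducible independent of
evaluation order.

A degenerate $\hat\beta_{Xj} = 0$ raises an error naming the SNP (its ratio
is undefined); fewer than 3 instruments disables the medians and Egger with
a logged reason rather than failing the pair — mirroring how sparse
instrument sets are handled in practice.

## The grid and multiple testing

`run_grid()` takes the Cartesian product of exposures and outcomes in
deterministic exposure-major order. The Bonferroni threshold is
$\alpha / (\text{exposures} \times \text{outcomes})$, computed from the
*actual* grid — for 4 exposures × 7 outcomes, $0.05/28 \approx
1.8\times10^{-3}$; a user override is honoured with a warning. Labels come
from the primary (first configured) method's p-value: `significant` below
the Bonferroni threshold, `suggestive` for $p < 0.05$ above it, `null`
otherwise. Binary outcomes are reported as odds ratios (`to_or()`
exponentiates the log-OR estimate and its CI), continuous outcomes as raw
effect sizes — effect sizes are never exponentiated, and the reporting
scale is carried on the estimate so mixing them up is a type error.
Per-pair failures (e.g. no overlapping instruments) are isolated as
reasons, not propagated; the grid aborts only if every pair fails.

## The synthetic-data generator

`simulate_two_sample()` draws, per SNP: an allele frequency uniform on
`eaf_range`; a true per-allele effect $\gamma_j \sim N(0,
\text{exposure\_effect\_sd}^2)$; and summary statistics
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with the
standard allele-frequency scaling $\sigma^2 = 1/(2f(1-f)n)$. Exposure and
outcome noise are independent — the two samples do not overlap. Two
modelling choices deserve explanation:

* **Instrument relevance is part of the model.** Real instrument sets have
  already passed genome-wide selection; every packaged instrument has
  $|\hat\beta_X|/\sigma_X \gtrsim 5.4$. The generator therefore redraws
  $\gamma_j$ until $|\gamma_j| \ge z \,\sigma_{Xj}$ with $z = 5.45$
  (two-sided $P < 5\times10^{-8}$; `min_instrument_z`, settable to 0).
  Without this condition a tail of near-null instruments appears whose
  exposure-increasing orientation is undecidable — a population no real
  two-sample analysis contains, and one that distorts orientation-dependent
  quantities such as the Egger intercept.
* **Directional pleiotropy is defined in the oriented frame.** Per-allele
  effects have arbitrary sign (which allele is "effect" is a bookkeeping
  choice), so a constant added to $\hat\beta_Y$ in the emitted frame would
  average to zero after the re-orientation every estimator performs, making
  "directional" indistinguishable from balanced. The generator applies
  $\alpha_j \cdot \mathrm{sign}(\gamma_j)$, i.e. pleiotropy is directional
  relative to the exposure-increasing allele — the convention of the MR
  simulation literature.

Defaults emulate the target study's scale: 25 instruments, exposure GWAS
n = 250,000, outcome GWAS n = 180,000, per-allele effects of SD 0.05 in
trait-SD units, EAF in [0.1, 0.9], no pleiotropy, mandatory seed
(bit-reproducible). The `corrupt` switch emits strand-complemented,
allele-swapped or palindromic (A/T) encodings of the outcome table to
exercise harmonization: after harmonization, corrupted and clean datasets
must yield identical estimates to full precision, and ambiguous palindromes
must be dropped and logged.

What the generator does *not* emulate: LD between instruments, sample
overlap, winner's-curse inflation of the selected exposure betas,
non-normal effect distributions, and binary-trait liability-scale subtlety.
Passing calibration here shows the estimators and their errors are
implemented correctly under the stated model, not that MR assumptions hold
in any particular application.

## Calibration results the test suite recomputes

With 50 strong instruments and study-scale n (1000 replicates under the
null, 500 elsewhere; sizes chosen to put Monte-Carlo error well below the
bands being checked while keeping the suite quick):

* IVW type-I error at $\alpha=0.05$ and 95% CI coverage are nominal within
  Monte-Carlo error (conditional on the instruments, the null z-statistic
  is exactly standard normal under the model, so this is a check of the
  implementation, not a lucky seed);
* the mean IVW estimate recovers $\theta = 0.3$ within 1% at large outcome
  n (the residual bias is the familiar regression-dilution term
  $\sum\gamma^2/(\sum\gamma^2 + \sum\sigma_X^2)$, below 0.5% under the
  relevance condition);
* under directional pleiotropy of mean 0.05 on all instruments, the mean
  Egger intercept recovers 0.05 within 10% (typically within 1%), while
  under balanced pleiotropy its test rejects at the nominal 5% rate;
* with 30% of instruments invalid, the weighted median's bias is a fraction
  of IVW's (ordering asserted, not exact values — the estimator is only
  consistent, not unbiased, at finite n).

`scripts/acceptance.R` re-runs the same experiments from scratch at an
arbitrary seed and writes the measured rates as JSON.

## Reproducing published analyses

The pipeline reproduces a published two-sample analysis given its two
inputs: an instrument table and outcome association statistics. The
packaged fixtures cover the instrument side. Outcome statistics from the
CARDIoGRAMplusC4D, SiGN/ISGC and GLGC consortia are not redistributable
with the package; users with access can place them under
`inst/extdata/outcomes/{cad,mi,stroke}.tsv` (any column naming, via
`read_associations()`'s column map), after which the acceptance test
compares the resulting IVW odds ratios against the published values at
2-decimal precision. The `analysis/` scripts demonstrate the identical
workflow end to end on clearly-labelled synthetic outcome tables instead.

## Known limitations

* Locus pruning is positional, not LD-aware; correlated instruments within
  a window survive only by being the locus lead, and cross-window LD is
  invisible.
* When both the other allele and EAF are missing, orientation cannot be
  verified; the SNP is kept with a logged warning.
* No MR-PRESSO, mode-based estimators, multivariable MR or Steiger
  filtering; the sensitivity battery is medians + Egger + Q/I².
* Exposure units are reported exactly as published (per-SD, per-log-odds,
  minutes/night); no cross-exposure standardization is attempted.
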