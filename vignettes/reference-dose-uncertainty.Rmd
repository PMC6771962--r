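---
title: "Deconstructing a reference dose: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing a reference dose: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfduq)
```

## The problem

A chronic oral reference dose (RfD) is an estimate of a daily intake likely
to be without appreciable risk over a lifetime. It is assembled from a small
number of ingredients: a *point of departure* (POD) read off an
exposure–response dataset, a classification of that POD as a NOAEL or a
LOAEL, possibly a toxicokinetic conversion from an internal-dose metric
(here, lipid-adjusted serum concentration in ppt) to a daily intake, and a
set of multiplicative *uncertainty factors* (UFs):

$$\mathrm{RfD} = \frac{\mathrm{POD}}{\prod_i \mathrm{UF}_i}.$$

Each ingredient is a judgement call, and the judgement calls compound.
`rfduq` makes every ingredient an explicit, typed object so the whole
derivation can be recomputed under alternative assumptions — the worked
system throughout is the dioxin (TCDD) RfD, where a POD of 0.020 ng/kg/day
divided by a composite UF of 30 (10 for LOAEL→NOAEL extrapolation, 3 for
human variability) gives 0.667 pg/kg/day, presented as 0.7. Reclassifying
the same POD as a NOAEL drops the factor of 10 and yields 7 pg/kg/day: a
single categorical judgement moves the answer tenfold.

The package answers three kinds of question:

1. **Deterministic sensitivity** (`enumerate_tree()`): what RfD does each
   combination of POD choice, TEQ accounting and classification produce?
2. **Statistical uncertainty in the POD** (`fit_loglog()`,
   `inverse_predict()`): how precisely does a small exposure–outcome cohort
   pin down the concentration at which the response crosses a threshold?
3. **Probabilistic uncertainty in the whole derivation** (`uf_prior()`,
   `induced_rfd()`, `scenario_grid()`): if the UFs (and the POD) are treated
   as random variables, what distribution of RfDs do they induce, and where
   does a fixed reference value sit in it?

## Deterministic arithmetic and conventions

Doses always carry units as data (`intake_rate()`, `serum_conc()`); no bare
floats cross module boundaries, and the ng↔pg conversion is an exact factor
of 1000. Three conventions deserve a note:

* **Presentation rounding.** Final RfDs are rounded to one significant
  figure (0.6667 → 0.7, 6.667 → 7), the agency presentation convention;
  the exact value is always retained and emitted alongside
  (`derive_rfd()$value` vs `$rounded_value`).
* **Fold-change rounding** is caller-specified (`"one_sigfig"`,
  `"nearest_integer"`, `"none"`) because published fold statements mix
  conventions: a ratio of 10.78 is quoted as "~10-fold" (one significant
  figure) while 5.07 is quoted as "fivefold" (nearest integer).
* **Serum→intake conversion** is an anchored proportionality
  (`serum_to_intake()`): intake = anchor intake × serum / anchor serum.
  The toxicokinetic model that produced the anchor pair (235 ppt ↔
  0.020 ng/kg/day) is *not* re-implemented; published analyses suggesting
  that such models underpredict intake at low concentrations by a factor of
  two or more are accommodated by an explicit `kinetic_adjustment`
  multiplier, default off. The scaling acts on the lipid-adjusted
  concentration itself, so the same anchor ratio is applied to TCDD- and
  TEQ-metric concentrations.

TEQ accounting works at the aggregate level (`teq_breakdown()`): a TCDD
component plus a single non-TCDD toxic-equivalency component. Agency TEQ
totals are produced by separate exposure modelling and need not equal the
component sum (140.1 ≠ 68 + 72.5); the type therefore accepts an
authoritative supplied total, warns when it disagrees with the component sum
by more than 1%, and preserves the discrepancy rather than resolving it.
Congener-level TEF weighting is out of scope.

## Significance screening from published summaries

When only group summaries (n, mean, 95% CI or SD) are published, the
standard error of each mean is recovered from the CI via the t distribution
(`se_from_ci()`, assuming a symmetric interval on the reported scale), and
groups are compared with Welch's unequal-variance t test
(`welch_test_from_summaries()`). Welch is the default because dose-group
variances in this kind of data are visibly unequal; a pooled-variance test
is available since the original analysis' exact choice is not recorded.
Computed from summaries, either test is numerically identical to the same
test run on the raw data — the test suite verifies this equality directly.

`classify_noael_loael()` then applies the classical rule: the LOAEL is the
lowest significant dose, the NOAEL the highest non-significant dose below
it. Non-monotone significance patterns are flagged in the output, never
repaired, and no multiple-testing adjustment is applied by default (the
published conclusions are per-quartile); Bonferroni and Holm are available
through `compare_quartiles(p_adjust = )`.

## Calibration and inverse prediction

The exposure–response relationship is fit by ordinary least squares on the
log–log scale: $\log y = \alpha + \beta \log x + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$. Natural logarithms are used internally;
because every reported quantity is exponentiated back to the original
scale, the internal base is unobservable (the suite checks ppt-scale
results against an independent base-10 computation).

The POD question is an *inverse* prediction: at what exposure $x_0$ does
the fitted line reach a threshold response $y_0$ (5 or 10 µU/mL)? The point
estimate is the exact algebraic inversion
$\hat x_0 = \exp\{(\log y_0 - \hat\alpha)/\hat\beta\}$. Two interval
methods are provided:

* **`approx_se`** — the calibration standard error of Massart et al.,
  $$\mathrm{SE}(\hat x_0^{\log}) = \frac{s}{|\hat\beta|}
  \sqrt{\frac{1}{m} + \frac{1}{n} +
  \frac{(\log y_0 - \bar y)^2}{\hat\beta^2 S_{xx}}},$$
  with a symmetric t interval on the log scale. The $1/m$ replicate term
  represents sampling error in a *measured* response; a fixed regulatory
  threshold has none, so the default is $m = \infty$ (term dropped). A
  chemometric-software–compatible mode ($m = 1$) is provided and
  regression-tested because published intervals of this kind are often
  computed that way.
* **`fieller`** — Fieller's theorem for the ratio of normal means, exact
  under the model. When $g = t^2 s^2/(\hat\beta^2 S_{xx}) \ge 1$ the slope
  is not distinguishable from zero at the working level and the interval is
  unbounded; this is signalled explicitly, never clipped.

Upper limits beyond a presentation cap (default $10^7$ ppt) are flagged so
reports can print "> cap", mirroring how such intervals are published. Only
the crude (unadjusted) regression is fit; covariate-adjusted slopes can be
supplied externally for scenario comparison but cannot be re-estimated from
published material.

`pod_from_threshold()` wraps the inverse prediction as a serum-typed POD
with a default classification that follows the clinical reading of neonatal
TSH screening: 5 µU/mL is a population-screening level (regulatory reading:
LOAEL), 10 µU/mL the clinical recall threshold (NOAEL). Both defaults are
overridable, since the classification is exactly the judgement under study.

## The induced-prior RfD distribution

Treating each UF as a lognormal random variable, the RfD
$\mathrm{POD}/\prod_i \mathrm{UF}_i$ acquires a distribution — an *induced
prior*, since nothing is updated against data. Because logs add, when the
POD and all UFs are point or lognormal the result is exactly lognormal:
$$\mu = \mu_{\mathrm{POD}} - \sum_i \mu_i,\qquad
\sigma^2 = \sigma^2_{\mathrm{POD}} + \sum_i \sigma^2_i.$$
`induced_rfd()` returns both Monte Carlo draws and this closed form; all
quantile and tail queries (`lower_bound()`, `percentile_of()`) prefer the
closed form, which is what makes extreme tail placements (e.g. $10^{-30}$)
resolvable — a sampling-only run cannot certify tail mass below
$1/n_{\text{draws}}$ and says so via a censoring flag instead of inventing
a number.

**UF prior convention.** The published parameterizations behind analyses of
this kind are typically not printed, so the default is the half-log
convention of the probabilistic-UF literature (`p95_nominal`): the nominal
UF sits at the 95th percentile and the median is $\sqrt{\text{nominal}}$,
giving $\sigma = 0.5\log(\text{nominal})/z_{0.95}$. For UF 10 this is
median 3.162, $\sigma = 0.700$. Every output records the convention, and
`median_nominal`/`explicit` modes allow any other parameterization.
Sequential application of UFs ("first 10, then 3") is independent draws
whose logs add — provably identical to a single draw of the product.

**POD spread.** By default the POD is lognormal with median at the
inverse-prediction point and log-scale SD equal to the CI half-width on the
log scale divided by $z_{0.975}$ (`pod_dist_from_prediction()`); for an
interval unbounded above, the lower half-width is used. A point-mass option
is retained.

`scenario_grid()` crosses exposure metric (TCDD, TEQ) × threshold (5, 10)
× classification (NOAEL, LOAEL) into exactly eight scenarios, each with its
2.5th-percentile lower bound (the conservative candidate RfD) and the
percentile placement of a reference RfD (default 0.7 pg/kg/day).
Per-scenario seeds are derived from the master seed, so a seed reproduces
the summary table bit for bit. Two orderings follow from the construction
and are enforced by tests: the NOAEL branch's lower bound exceeds the LOAEL
branch's (fewer, smaller divisors), and the TEQ branch's is at least the
TCDD branch's (a larger serum POD under the same anchor scaling).

A sensitivity worth understanding: whether a fixed reference value lands
below the 2.5th percentile of a scenario's distribution depends on both the
scenario's deterministic RfD and the total spread. For a LOAEL branch the
log-scale gap between the deterministic RfD ($\mathrm{POD}/30$) and the
induced median ($\mathrm{POD}/\sqrt{30}$) is $0.5\log 30 \approx 1.70$, and
the UF priors alone contribute $\sigma \approx 0.78$ — so scenarios whose
deterministic RfD only marginally exceeds the reference can place the
reference *above* the 2.5th percentile once a realistic, CI-derived POD
spread is included. Tail placement statements are therefore robust for
scenarios well above the reference and fragile at the boundary; the grid
reports both the deterministic RfD and the percentile so this can be seen
directly.

## The synthetic cohort generator

`generate_tsh_cohort()` emulates the structure of a small mother–infant
serum-dioxin/neonatal-TSH cohort: lognormal exposure with a small high
tail, and TSH following the log-log model with lognormal noise. The
defaults encode the facts available about the emulated cohort, fixed once:

* **n = 51** pairs.
* **Exposure**: log-scale SD 1.0, with the location solved from the
  lognormal survival function so the expected count above 50 ppt is
  exactly 5 (the reported high-exposure subgroup). A lognormal cannot
  jointly satisfy this tail fact *and* a cohort mean of 18.9 ppt — under
  the tail constraint the minimum achievable mean is ≈ 21.6 ppt — so the
  tail was kept exact and the implied mean (≈ 22 ppt) accepted as an
  approximation. A heavier-tailed mixture can be emulated by supplying
  `exposure_log_mean`/`exposure_log_sd` directly.
* **Dose–response**: slope 0.372 and intercept −0.422, solved so the
  noise-free curve crosses 5 µU/mL at 235 ppt and 10 µU/mL at 1513.56 ppt —
  the two threshold anchor points of the emulated analysis.
* **Noise**: `noise_log_sd = 0.6`. Screening TSH in healthy neonates spans
  roughly 1.7–9.1 µU/mL, about four log-scale SDs (σ ≈ 0.42); the default
  is inflated toward 0.6 because sampling-time variability (TSH falls
  several-fold over the first days of life) adds residual spread that the
  exposure model cannot absorb.

`generate_quartile_summaries()` emulates a published dose-quartile summary
table: normal draws per group, summarized as mean and 95% t interval, with
the raw draws returned as a truth sidecar so summary-based tests can be
validated against raw-data tests. Defaults: control n = 184 / quartile
n = 34, control mean 72.5 and a top-quartile-only effect at 53.6 (outcome
units million sperm/mL), common SD 40 on the reported scale, quartile
median doses 68/172/345/733 ppt. The 172 ppt second-quartile dose is a
geometric interpolation (the true value is unpublished), and the normal
outcome model is a simplification — the published ±SD band (31.7–165.9
around 72.5) is clearly geometric, i.e. the real data are right-skewed.

What passing tests on these generators do and do not show: they demonstrate
that the estimators recover known truth under the assumed model (log-log
linearity, lognormal noise, independent sampling) at the stated sample
sizes. They cannot validate the model assumptions themselves against the
real cohorts, nor reproduce digitization error, covariate structure
(delivery mode, sampling time, iodine status) or the exclusion patterns of
the original studies.

## Numerical choices

* Natural logs internally everywhere; results are base-invariant.
* `uf_prior()` floors the log-SD at `min_log_sd = 1e-6` so a nominal of 1
  degenerates gracefully to a point mass at 1.
* The POD log-SD uses the normal quantile $z_{0.975}$ (not t) as the CI was
  already widened by its own t quantile; the small residual discrepancy is
  conservative (slightly wider POD spread).
* `percentile_of()` returns exact closed-form tail probabilities when the
  lognormal algebra applies; otherwise it censors at the Monte Carlo floor.
* Degenerate inputs: zero-noise fits yield zero-width intervals; identical
  group summaries yield t = 0, p = 1; an empty UF list composes to 1;
  write-once run directories refuse silent overwrites.

## Problem sizes used by the test suite

The suite validates distributional claims by simulation at sizes chosen to
make Monte Carlo error small relative to the tolerance being checked:
2,000 replicate cohorts (n = 49) for inverse-prediction interval coverage
(binomial SE ≈ 0.5%), 10,000 null replicates for the summary-test type-I
rate (SE ≈ 0.2%), $10^6$ draws for Monte-Carlo-versus-closed-form quantile
agreement within 2%, and $10^5$ draws per scenario for the
Kolmogorov–Smirnov check (expected distance ≈ 0.004 against a 0.01 bound).

## Known limitations

* The serum→intake step is a single proportional anchor; no body-burden,
  half-life or age-dependent kinetics.
* TEQ handling is aggregate-level only.
* Only the crude regression is estimable from published material;
  covariate-adjusted calibration requires the original data.
* The induced prior is exactly that — a prior; no posterior updating
  against data is performed.
* Published headline figures that depend on unpublished parameterizations
  (the exact UF lognormal parameters, the digitized scatter) can be matched
  in structure but not certified numerically; where a required input is
  absent the corresponding check is skipped or reported with its censoring
  flag rather than approximated silently.
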