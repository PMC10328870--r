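---
title: "Methods: meta-analysis of silvicultural effects on plantation carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of silvicultural effects on plantation carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silvicarb)
```

## The estimation problem

Plantation experiments report aboveground biomass or carbon in treated and
untreated plots. Pooling them across studies raises three statistical
problems this package addresses: effects must be placed on a common
dimensionless scale (the log response ratio), comparisons differ enormously
in precision (inverse-variance weighting from arm SDs and replicate
counts), and multiple comparisons from one publication are not independent
(publication-level random effects). The fourth, practical problem is that
many studies simply do not report SDs; these are imputed from coefficients
of variation so that the comparisons are not discarded.

## Effect sizes

For arm means $\bar X_t, \bar X_c$ (Mg C ha$^{-1}$), SDs $s_t, s_c$ and
replicate counts $n_t, n_c$:

$$\mathrm{lnRR} = \ln \bar X_t - \ln \bar X_c, \qquad
v = \frac{s_t^2}{n_t \bar X_t^2} + \frac{s_c^2}{n_c \bar X_c^2}.$$

The variance is the first-order delta-method expression: the reported arm
means are sample means whose standard errors are $s/\sqrt{n}$, and $v$
propagates those through the log ratio. Biomass rows are converted to
carbon with the standard 0.47 factor before anything else; the `unit`
column makes the conversion auditable and prevents it being applied twice.

**Missing SDs.** For each treatment analysis (interplant / npk / thin) and
each arm, the coefficient of variation $s/\bar X$ is collected from every
comparison of that analysis that reports the arm's SD, and each missing SD
becomes $\mathrm{median}(CV) \times \bar X$. Two genuinely open choices
were fixed here: the median is computed *across* studies (the pool is
larger and more stable than per-study medians, and per-study pools would
often be empty — precisely the studies needing imputation report nothing),
and an even CV count takes the midpoint of the two central values.
Imputation provenance is kept in `sd_imputed_*` flags so
`sensitivity_reanalysis()` can rerun everything on the reported-SD subset;
`run_analysis(..., exclude_imputed = TRUE)` is the same configuration as a
pipeline switch.

## The mixed-effects model

All models share one marginal structure for comparison $i$ in publication
$j$:

$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \tau^2), \quad \varepsilon_{ij} \sim N(0, v_{ij}),$$

with known $v_{ij}$. A single publication-level variance component is used
— no observation-level second component — because the clustering by
publication is the non-independence the design must absorb. $\tau^2$ is
estimated by REML: the restricted log-likelihood is profiled over
$\tau^2 \in [0, 10\,\mathrm{var}(y)]$ with a deterministic 1-D bounded
search (tolerance $10^{-8}$, no random starts), the boundary value
$\tau^2 = 0$ is compared explicitly so the optimum cannot be missed at the
edge, and $\boldsymbol\beta$ is GLS under the fitted covariance. The
covariance is block-diagonal by publication, so likelihood evaluations use
grouped sums via the Woodbury identity and scale linearly in the number of
comparisons — relevant for the simulation experiments below.

Numerical guard rails: sampling variances of exactly zero (a legal SD of 0)
are floored at $10^{-12}$ so weights stay finite, and the count of floored
values is reported in the fit; a saturated design ($k \le p$) fixes
$\tau^2 = 0$ since no residual information remains.

**Moderators** are tested one model at a time, using all comparisons that
record that moderator (rows missing it are dropped for that model only).
Categorical moderators use a cell-means (no intercept) design, so each
coefficient is a category's mean lnRR; categories with one observation are
dropped first and recorded. Continuous moderators use intercept + slope.
The omnibus statistic is the Wald $\chi^2$, $Q_M = \mathbf{b}' V_b^{-1}
\mathbf{b}$, over all coefficients of a cell-means model but only the slope
of an intercept+slope model (an intercept is not a moderator effect).
Consequently the cell-means omnibus tests "all category means are zero",
not "all categories are equal": under a nonzero overall effect it is
expected to reject, and its type-I calibration is only meaningful at the
global null — which is how the calibration experiment is run.

Confidence intervals are Wald-z, not Knapp–Hartung; z is the convention of
the standard meta-analytic toolchain and the package keeps it. Estimates
and CI bounds are back-transformed with $(e^x - 1) \times 100$; the
transform is monotone, so interval order is preserved by construction.

**Shared controls.** Comparisons that reuse one control plot are recorded
(`control_id`, `group_shared_controls()`) but induce no modeled covariance;
the publication random effect is the only non-independence adjustment. This
mirrors standard practice, understates within-control correlation, and is a
known limitation: a multivariate model with a shared-control covariance
block would be the extension.

## Time trends

Trend models are the continuous-moderator machinery with the field's
trimming rules applied first: interplanting drops stands older than 20
years, NPK drops comparisons more than 5 years after treatment, thinning
keeps everything. The reported "% per year" is $100 \times$ slope, the
small-effect reading under which a slope of 0.036 is "+3.6%/yr"; the exact
$100(e^{\text{slope}} - 1)$ is exported alongside. For NPK,
`npk_time_variable()` follows continuously fertilized stands on stand age
and pulse-fertilized stands on time since treatment. The covariate value at
which a fitted trend crosses zero effect is $-\text{intercept}/\text{slope}$,
reported only when it lies at a positive covariate value; it is invariant
to rescaling both coefficients, which the tests check.

## Fertilizer greenhouse-gas balance

Per fertilized comparison, the carbon gain is the raw arm difference
$\Delta C = \bar X_t - \bar X_c$ (a per-measurement computation, not a
model estimate), converted to CO$_2$e by 44/12 — the only mass-consistent
choice. Emissions are `n_applied` (Mg N ha$^{-1}$; per-tree values
converted with stand density) times the total factor: in-field
$0.0254 \times (44/28) \times \mathrm{GWP}_{100}$ with
$\mathrm{GWP}_{100} = 298$, giving the conventional 11.9 Mg CO$_2$e per
Mg N, plus 4.0 upstream. All constants sit in `ghg_constants()` and are
overridable. The net balance is regressed on N applied by OLS; a negative
slope with positive intercept yields the break-even rate
$-\text{intercept}/\text{slope}$. On a noiseless collinear input
`summary.lm` produces no residual variance, so the p-value is defined
directly (0 for a nonzero slope, 1 otherwise) rather than left `NaN`.

## What the synthetic generator emulates

`generate_compilation()` draws compilations with the nesting and
missingness structure of real silvicultural databases; all latent values go
into a truth ledger. The per-treatment defaults in `default_config()` are
the package's fixed study conditions:

* scale — 43 publications / ~197 comparisons (interplant), 17 / ~164
  (npk), 8 / ~62 (thin), via $1 + \mathrm{Poisson}$ comparisons per
  publication;
* true effects — marginal mean lnRR $\ln 1.20$, $\ln 1.445$, $\ln 0.66$
  respectively; covariate slopes 0.036/yr of stand age (interplant),
  $-0.0666$/yr since treatment (npk), $+0.046$/yr since thinning and
  $-0.013$ per % basal area removed (thin), each centred on the covariate's
  midrange so the marginal mean is unaffected;
* heterogeneity — $\tau^2 = 0.05$ between publications, a mid-range value
  for ecological meta-analyses (neither source states one);
* measurement — control stocks lognormal (60 Mg C ha$^{-1}$ median;
  8 Mg C ha$^{-1}$ for npk, whose fertilization trials are young stands —
  this keeps raw carbon gains on the scale where fertilizer emissions
  matter at realistic rates of 0.03–1.2 Mg N ha$^{-1}$), arm CVs uniform on
  0.10–0.30, 3–5 replicates, 30% of comparisons missing both SDs (MCAR;
  no mechanism is stated anywhere, so the simplest one is used), 30%
  shared-control reuse.

Reported arm means carry sampling error $s/\sqrt{n}$ around the latent
means — drawn once per control plot, so shared controls share their
observed value. Without this the assigned variances would overstate the
actual noise and every test would be conservative; with it, the
delta-method variance describes exactly the noise in the data, which is
what makes the coverage and type-I experiments meaningful. The generator
does *not* emulate real genus/geography frequencies, non-random
missingness, correlated moderators, or reporting bias — so passing tests
demonstrate the estimator's calibration under the stated model, not
robustness to those features of real data.

## Problem sizes and seeds

The simulation experiments are sized to be decisive yet quick: parameter
recovery uses 200 publications × 500 replicates (bias and coverage
tolerances 0.01 and [0.93, 0.97] at a Monte-Carlo SE of ~0.01), omnibus
type-I uses 1000 replicates (±3 MC SEs around 0.05), the brute-force REML
oracle runs on instances of ≤ 10 observations where a staged $\tau^2$ grid
down to $10^{-9}$ is affordable, and the acceptance script uses 300/400
replicates for the same experiments. Every stochastic step takes an
explicit seed; replicate $r$ of an experiment uses `seed + r`.

## Known limitations

No small-sample lnRR bias correction, no SMD-family effect sizes, no
multivariate/correlated-effects models, no multiple-testing correction
across moderators, no nonlinear time trends, no P/K manufacturing
emissions, and no $I^2$ reporting beyond $\tau^2$. Real compilations with
per-study idiosyncrasies (heteroscedastic CVs, informative missingness)
will stress the imputation step first; the sensitivity reanalysis is the
tool for judging whether conclusions depend on it.
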