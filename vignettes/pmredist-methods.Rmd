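---
title: "Modeling time-dependent postmortem redistribution: methods and design"
author: "pmredist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-dependent postmortem redistribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmredist)
```

# The problem

Drug concentrations measured in postmortem femoral blood are not frozen at
the moment of death: diffusion from tissues, microbial degradation and
neo-formation keep changing them, a phenomenon collectively called
postmortem redistribution (PMR). When the same case is sampled twice —
once at mortuary admission (`t1`) and again at autopsy (`t2`), typically
days apart — the paired concentrations carry information about the
*time-dependent* component of PMR. `pmredist` provides the full analysis
chain for such paired two-time-point cohorts: cohort bookkeeping and
interval arithmetic, an exponential mixed-effect model of the
concentration change, back-calculation of concentrations toward the time
of death, robustness assessment by resampling, and a rank-correlation
screen that searches endogenous metabolites for markers that co-vary with
a drug's redistribution.

# Cohort construction

A cohort row is one case × drug with concentrations `c_t1`, `c_t2` and
three timestamps: estimated death `t0`, admission sampling `t1`, autopsy
sampling `t2`. All derived intervals are in hours.

**Time-of-death imputation.** Routine casework often records only the
*day* of death. For such day-only records (`t0_day_only = TRUE`) the time
of death is imputed as 12:00 noon on the estimated day when the body was
admitted on a later calendar day, and as the midpoint between midnight
(00:00) and the admission time when admission fell on the same day. The
imputed `t0` can never exceed `t1` by construction. Note that the
imputation only affects the reported pre-admission and pre-autopsy
intervals; the model below uses only `t2 - t1`, which is computed from
the two exactly known sampling times.

**Percentage change.** The per-case change statistic is
`(c(t2) - c(t1)) / c(t1) * 100`, so decreases are negative. Summaries per
drug report the median, min, max and the 5th/95th percentiles (the
box-whisker statistics), with percentiles by linear interpolation between
order statistics (R's default type 7; configurable, since no particular
convention is canonical).

**Exclusions.** Records with a missing or non-positive concentration at
either time point are excluded from model fitting with a logged reason —
a non-positive `t2` value typically means the analyte dropped below the
lower limit of quantification, and no imputation is attempted. Records
with both concentrations but an incomplete timestamp triple are retained
for nothing beyond bookkeeping: the change statistic needs both sampling
times to be meaningful as a *time-dependent* quantity.

# The exponential mixed-effect model

Concentration change between the two sampling times is modeled
multiplicatively,

$$ c(t_1) = c(t_2)\, e^{\lambda \,\Delta t}, \qquad \Delta t = t_1 - t_2 < 0 , $$

with a single per-hour rate $\lambda$ per drug: $\lambda < 0$ means
generalized time-dependent decrease, $\lambda > 0$ increase. Taking
natural logs makes the model linear, and $\lambda$ is estimated from the
two-observation-per-case linear mixed model

$$ \log c_{ij} = \beta_0 + b_i + \lambda\, \tau_{ij} + \varepsilon_{ij},
   \qquad b_i \sim N(0, \sigma^2_{case}), \quad
   \varepsilon_{ij} \sim N(0, \sigma^2_{resid}), $$

where $\tau_{ij}$ is hours since case $i$'s admission sampling
($\tau_{i1} = 0$, $\tau_{i2} = t_2 - t_1$), fitted by REML via `lme4`.
Design choices worth spelling out:

* **Random-effects structure.** A case-level random intercept absorbs the
  very large between-case spread of absolute concentrations (dose,
  tolerance, body compartment effects). With exactly two observations per
  case, a random *slope* is not separately identifiable from the residual
  variance, so none is offered. The intercept also makes the fit
  invariant to per-case time shifts: using time since death instead of
  time since `t1` would change nothing about $\hat\lambda$.
* **Estimation scale.** Fitting after log transform corresponds exactly
  to the multiplicative back-calculation formula; $\lambda$ is unchanged
  by the transform, and multiplicative lognormal measurement noise
  becomes additive Gaussian.
* **Confidence interval.** The reported 2.5–97.5% interval is Wald-type,
  $\hat\lambda \pm z_{0.975}\,\widehat{SE}$, with the standard error
  taken from a *case-level cluster-robust (sandwich) estimator* by
  default. The reason is a genuine misspecification concern: when cases
  differ in their individual rates (which the extreme per-case ranges of
  the opioids make obvious), the omitted random slope induces residual
  variance that grows with $\Delta t^2$, and the model-based standard
  error — which assumes homoscedastic residuals — is then markedly
  anticonservative, with simulated interval coverage falling to roughly
  70–80% instead of the nominal 95% under heavy-tailed sampling-interval
  distributions. The sandwich estimator restores near-nominal coverage
  under rate heterogeneity while behaving like the model-based one when
  the single-rate model is correct. The model-based standard error
  (`ciMethod = "model"`) and a case-resampled percentile bootstrap
  (`ciMethod = "bootstrap"`, 1000 draws by default) remain available.
* **Convergence.** Optimizer warnings are captured into the fit object
  and flag it as non-converged rather than aborting; singular fits
  (`sigma_case` estimated at zero) are accepted silently, as they are the
  correct answer for noise-free or intercept-free data.

**Back-calculation and accuracy.** `backCalculate(c_t2, delta_t, lambda)`
evaluates the exponential directly. Prediction accuracy on a held-out
case is the back-calculated `t1` concentration divided by the measured
one, × 100 — values above 100% are overestimates. The model is blind to
the first hours after death (no sample exists before mortuary admission),
so the command-line wrapper refuses to extrapolate earlier than each
case's `t1` unless explicitly forced.

**Train/test splitting and robustness.** Training sets contain
`floor(0.8 n)` cases sampled uniformly without replacement — the floor
convention is pinned by the published cohort arithmetic (137 cases → 109
training, 126 → 100, 55 → 44; rounding half-up would give 110/101
instead. And the
published test-set sizes, 28 and 26, are the complements). Robustness is
quantified by refitting on 50 independent random training sets and
reporting the relative standard deviation, RSD = SD/|mean| × 100, of the
fitted rates; each repeat redraws both the training set and, implicitly,
the test complement. Per-repeat sub-seeds are derived from the master
seed by a counter, so a robustness run is exactly reproducible. Failed
repeats are recorded and skipped in the RSD, with the converged count
reported. The pipeline's verdict is "robust" only when the RSD is at most
a configurable threshold (default 10%, between the published accepted
7.2%/5.4% and rejected 27%/15%) *and* the confidence interval excludes
zero. No automatic outlier removal is performed; extreme cases are part
of the phenomenon.

# The correlation screen

For a drug and a table of endogenous feature abundances at both time
points, the screen computes every feature's per-case percentage change,
Spearman-correlates it with the drug's percentage change over
pairwise-complete cases (mid-ranks for ties), adjusts p-values across all
features tested for that drug by Benjamini–Hochberg FDR, and flags
features with $|\rho| > 0.5$ and adjusted $p < 0.05$ as significant.
Details:

* The p-value uses the large-sample t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom; an
  exact tie-free permutation p-value is available for $n \le 10$.
* BH is the default FDR procedure (the common default in metabolomics
  software); Benjamini–Yekutieli is available where dependence-robust
  control is wanted. Adjustment is per drug, not across drugs, matching
  how per-drug marker tables are reported.
* Features with fewer than 5 complete pairs, a non-positive `t1`
  abundance (change undefined) in too many cases, or zero rank variance
  are skipped and listed in the result's metadata rather than silently
  dropped.
* Results are sorted by $|\rho|$; with `topK` set, the output keeps all
  significant features plus the `topK` strongest correlates, mirroring
  how screening tables are usually published. Targeted and untargeted
  records for the same metabolite are both kept and labeled via the
  `workflow` column; no deduplication is attempted.
* Constant-median normalization (`medianNormalize`) scales each case ×
  time-point sample so all samples share the global median of per-sample
  medians; medians are taken over positive values and zeros stay zero.

# The synthetic-data generator

Authentic paired postmortem cohorts are not publicly distributable, so
the package ships a generator that emulates their statistical structure
and makes every stage testable end to end. Its defaults encode the study
conditions reported for a 477-case cohort of six drugs:

* **Timing.** Pre-admission interval and the `t1`→`t2` sampling interval
  are lognormal — chosen because the published interval means exceed the
  medians (16 vs 9 h pre-admission; 83 vs 70 h between samplings),
  indicating right skew — parameterized by median (9 h, 70 h) with
  log-scale SDs solved from the mean/median ratio
  ($\sigma^2 = 2\log(\text{mean}/\text{median})$, giving 1.07 and 0.58),
  truncated to the published min–max bounds (1.25–292 h and 6.5–434 h)
  by rejection, with the pre-autopsy interval capped at 478 h.
* **Death-estimate precision.** Each case is day-only with probability
  163/477 ≈ 0.34; those cases' recorded `t0` is degraded to a calendar
  date, exercising the imputation rule.
* **Concentrations.** Case rate $\lambda_i \sim N(\mu_\lambda,
  \sigma_\lambda^2)$; baseline $\log c(t_1) \sim N(\mu_0, \sigma_0^2)$
  (default $\sigma_0 = 1$, the "strong inter-individual variability"
  regime); noise-free $c(t_2) = c(t_1) e^{\lambda_i (t_2 - t_1)}$; both
  observations then get independent multiplicative lognormal measurement
  noise (log-scale SD 0.25 by default), consistent with log-scale
  fitting and strictly positive concentrations.
* **Outliers.** With a small per-drug probability the autopsy
  concentration is additionally multiplied by a heavy-tailed log-Laplace
  factor — mimicking redistribution spikes of several thousand percent
  without disturbing the admission sample.
* **Rates.** The six preset profiles carry the published fitted rates
  (diazepam −0.00296044 h⁻¹, nordiazepam −0.00303677, morphine
  +0.0014037, codeine +0.00020796, mirtazapine +0.00333899, citalopram
  +0.0037752). The between-case rate SD is published nowhere; the
  defaults (0.004 for the benzodiazepines, 0.006 for
  mirtazapine/citalopram, 0.013–0.015 for the opioids) were set once to
  reproduce the qualitative spread of the reported percentage-change
  ranges and should be treated as unvalidated.
* **Features.** Feature percentage changes are generated through a
  Gaussian copula on the normal scores of the drug's changes: a feature
  planted at target Spearman $\rho$ uses latent correlation
  $r = 2\sin(\pi\rho/6)$ (exact for Gaussian ranks), and latent scores
  map monotonically to a lognormal change distribution, so the planted
  rank correlation survives all downstream monotone transforms. Null
  features draw independent scores. Note an intrinsic limit: the
  sampling SD of Spearman's $\rho$ at $n = 122$ and $\rho = 0.6$ is
  about 0.06, so roughly 90% of replicates land within ±0.1 of the
  target — no copula construction can do better.

Everything is deterministic given the config seed; cohort and feature
draws use separate derived streams.

**What the generator does not emulate:** early-phase kinetics between
death and admission (the model is equally blind to them), batch effects
and instrument drift, censoring at the limit of quantification,
correlations *between* null features, and any chemistry-driven structure
in which metabolites correlate with which drugs. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
data-generating model, not validity of the biological conclusions on
real casework.

# Method agreement

`blandAltman` implements the classic agreement analysis between two
quantification methods: per-pair differences (absolute, or as a
percentage of the pair mean) against pair means, bias ± 1.96 SD limits of
agreement (SD with the $n-1$ denominator), and a proportional-bias check
as the two-sided t test on the OLS slope of differences on means — the
operational form of "concentration-dependent difference". Both absolute
and ratio modes are provided since published agreement analyses rarely
state which was used.

# Numerical choices and degenerate inputs

* Hours are the time unit everywhere; timestamps are parsed as UTC and
  the generator emits whole-second timestamps so intervals recovered
  from files match the generating draws exactly.
* "12 pm" is noon and "12 am" is midnight (US convention), consistent
  with the midpoint construction of the imputation rule.
* `t1 = t2` is an invalid-chronology error; `t0 = t1` is allowed
  (interval zero).
* Percentile, quantile and FDR ties follow the respective R defaults
  (type-7 quantiles, mid-ranks, BH step-up with capping at 1).
* An RSD over a zero-mean set of rates is undefined and returned as NA
  with a flag rather than ±Inf.
* Empty cohorts are valid objects and write header-only CSVs.

# Problem sizes used by the test suite

The package's own checks run the pipeline at the published design points:
exact split arithmetic at n = 137/126/55; rate recovery and interval
coverage over 200 replicate cohorts of 137 cases; null-rate behaviour
over 200 replicates of 122 cases; robustness-RSD ordering over 12
replicate cohorts each at n = 50 and n = 137 with 50 resampling repeats
apiece; screen power and false-flag control over 100 replicates with one
planted and 200 null features; and a 12-case deterministic end-to-end
run regenerated byte-identically from its manifest.

# Known limitations

* The model deliberately estimates one population rate per drug; it is a
  research tool for cohort-level description, not a case-level forensic
  predictor, and the extreme inter-individual variability it quantifies
  is precisely why single-case back-calculation would be misleading.
* With two time points per case the residual and any real random slope
  are confounded; the robust interval accounts for the variance
  consequences but cannot separate the components.
* Day-only imputation biases individual pre-admission intervals by up to
  half a day; only interval *reporting* is affected, never the fit.
* The screen's significance rule (|ρ| > 0.5 and FDR p < 0.05) is a
  screening convention, not a causal claim; the |ρ| gate dominates the
  FDR gate at cohort sizes above ~100, making the screen very strict
  against weak correlates.
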