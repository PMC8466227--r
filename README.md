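# pmredist

Time-dependent postmortem redistribution (PMR) analysis for paired
two-time-point forensic toxicology cohorts.

After death, drug concentrations in femoral blood keep changing —
diffusion from tissues, microbial degradation and neo-formation all
contribute. When each case is sampled twice, at mortuary admission
(`t1`) and again at autopsy (`t2`), the paired concentrations let the
*time-dependent* component of PMR be modeled. `pmredist` implements the
full analysis chain for such cohorts:

* **Cohort handling** — timestamp parsing, time-of-death imputation for
  day-only death estimates (noon rule / midnight–admission midpoint),
  sampling-interval arithmetic in hours, and per-case percentage
  concentration changes `(c(t2) − c(t1))/c(t1) × 100` with box-whisker
  summaries (median, min/max, 5–95 percentiles).
* **Exponential mixed-effect model** — the concentration-change model
  `c(t1) = c(t2)·exp(λ·Δt)` with `Δt = t1 − t2` (negative), fitted on the
  natural-log scale as a linear mixed model with a case-level random
  intercept (REML via `lme4`); a negative rate λ (per hour) means
  generalized time-dependent decrease. Confidence intervals are
  Wald-type with a case-level cluster-robust standard error (model-based
  and case-bootstrap alternatives available).
* **Back-calculation & accuracy** — projecting autopsy concentrations
  back to the admission sampling time and scoring held-out cases as
  back-calculated/observed × 100.
* **Robustness** — repeated 80/20 train/test resampling (floor rule:
  137 cases → 109 training) and the relative standard deviation of the
  refitted rates as the robustness metric.
* **Correlation screen** — Spearman rank correlation of endogenous
  metabolite-feature percentage changes against a drug's percentage
  changes, Benjamini–Hochberg FDR per drug, significance rule
  |ρ| > 0.5 and adjusted p < 0.05.
* **Method agreement** — Bland-Altman bias, 1.96·SD limits of agreement
  and a proportional-bias slope test.
* **Synthetic cohorts** — a seeded generator emulating the structure of
  paired postmortem data (lognormal right-skewed sampling intervals,
  day-only death estimates, lognormal measurement noise, heavy-tailed
  outliers, features planted at target Spearman correlations through a
  Gaussian copula), so the whole pipeline is testable without access to
  authentic casework data.

The data containers are Bioconductor-style S4: `PMCohort` for case
records, `PMFeatureSet` (a `SummarizedExperiment` with `t1`/`t2` assays)
for feature tables.

## Worked example

Simulate a diazepam-like cohort of 137 cases (the generator's defaults
encode published cohort conditions: median 9 h pre-admission and 70 h
between samplings, 34% day-only death estimates, rate −0.00296 h⁻¹),
fit the model, and screen a feature table:

```r
library(pmredist)

cfg <- simConfig("diazepam", nCases = 137, seed = 42,
                 planted = data.frame(feature_id = "fumarate_like", rho = 0.45),
                 nNullFeatures = 100)
cohort <- simulateCohort(cfg)
cohort
#> PMCohort with 137 case record(s), 1 drug(s)
#>   diazepam     n=137 (model-ready 137), median change -18.6%

summarizeChanges(cohort, "diazepam")
#>        drug   n median_pct  min_pct max_pct   p5_pct p95_pct
#> 1  diazepam 137   -18.5987 -95.6069 154.138 -66.1553 63.0513

recs  <- cohortRecords(cohort, "diazepam")
split <- trainTestSplit(recs, 0.8, seed = 42)     # 109 train / 28 test
fit   <- fitLambda(split$train, drug = "diazepam")
fit
#> ModelFit [diazepam]: lambda = -0.0033701711 /h  (95.0% CI -0.0050152222 .. -0.0017251199, robust)
#>   sigma_case = 1.058, sigma_resid = 0.3587 (log scale), n = 109

predictionAccuracy(split$test, fit)
#> AccuracyResult: median 95.0%, range 29.9-200.7% (n = 28)

resampleRobustness(recs, nRepeats = 50, seed = 42)
#> RobustnessResult: 50/50 repeats converged, RSD(lambda) = 10.90%

scr <- correlationScreen(cohort, simulateFeatures(cohort, cfg),
                         "diazepam", topK = 3)
as.data.frame(scr)[, c("feature_id", "rho", "p_fdr", "significant")]
#>      feature_id        rho        p_fdr significant
#> 1 fumarate_like  0.5611571 9.955670e-11        TRUE
#> 2      null0001 -0.1919559 9.184213e-01       FALSE
#> 3      null0086 -0.1730636 9.184213e-01       FALSE
```

Reading the output: the fitted rate is negative — a generalized
time-dependent concentration decrease of about 0.34% per hour on this
replicate (the generating value was −0.00296 h⁻¹ and lies inside the
CI). The median change of −19% over a median 70 h sampling interval is
the same signal seen case by case. Held-out autopsy concentrations
back-calculate to a median 95% of the measured admission concentrations,
with the wide 30–200% range reflecting the strong inter-individual
variability the random intercept absorbs. A resampling RSD of ~11% means
the rate estimate is borderline-stable at this cohort size, and the
planted moderate correlate is recovered by the screen while the 100 null
features stay far below the |ρ| > 0.5 significance gate.

Back-calculation itself is one exponential:

```r
backCalculate(50, -70, -0.00296044)   # autopsy 50 units, 70 h earlier
#> [1] 61.51332
```

An end-to-end run (summary TSV, per-drug fit JSON, screen TSV, Markdown
report, reproducibility manifest) is one call:

```r
runPipeline("cohort.csv", "features.csv", outDir = "report", seed = 1)
```

and `inst/scripts/pmr.R` wraps the same functions as `simulate` / `fit` /
`backcalc` / `screen` / `compare` / `report` subcommands for shell use.

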