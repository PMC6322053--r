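---
title: "Methods: exposure fusion and cohort surveillance with airsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure fusion and cohort surveillance with airsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airsurv)
```

## The surveillance problem

`airsurv` implements a low-cost national surveillance design for long-term
health effects of ambient air pollution. The cohort is a two-stage household
interview survey (municipalities first, households within municipalities,
every household member enrolled), followed up passively through record
linkage to death certificates and hospital discharge archives. Exposure
cannot be assigned at the address level — only the municipality of residence
is known — so the pipeline builds municipality-level annual exposures from a
national dispersion model corrected with monitoring-station data, and feeds
them into a Cox model with time-varying exposure.

The package covers five stages, each usable on its own:

1. **Fusion** — quality-control station series, then combine the model
   concentration field with observations by kriging with external drift
   (KED).
2. **Upscaling** — collapse fused grids to municipality means with
   built-up-area weights, and build cumulative-mean risk-set exposures.
3. **Outcomes** — classify ICD-coded records into cause groups, reduce
   repeat admissions to incident events, and expand subjects into
   counting-process intervals.
4. **Linkage QC** — person-years, expected events from reference rates,
   observed/expected ratios, and representativeness checks.
5. **Survival** — Cox proportional hazards with time-varying exposure and
   age class, cluster-robust variance, PH diagnostics and interaction tests.

A sixth component, the synthetic-world generator, produces all inputs with
known ground truth so that every stage — and the pipeline end to end — is
testable without any external data.

## The fusion model

Annual-mean observations at background stations are modelled as a Gaussian
spatial process

$$Y(s) = \mu(s) + w(s) + \varepsilon(s),$$

where the trend $\mu(s)$ is a linear function of the dispersion-model value
at $s$ (drift functions $\{1, \text{model}(s)\}$), $w(s)$ is a stationary
correlated residual and $\varepsilon(s)$ a nugget/measurement error. The KED
predictor at each grid cell solves the universal kriging system with those
two drift functions; the kriging weights therefore satisfy
$\sum_i \lambda_i = 1$ and $\sum_i \lambda_i\,\mu(s_i) = \mu(s_0)$, which the
test suite verifies to $10^{-8}$.

Choices a user should know about:

* **Station QC.** Completeness is valid days / days of the year; series at
  or above the threshold (default 0.80) are averaged to annual values, the
  rest rejected with a reason. Only `background`-type stations enter the
  assimilation, because their spatial representativeness matches the 4-km
  urban-background model support.
* **Variogram.** The residual (observation minus drift at the containing
  cell) semivariogram is fitted by weighted least squares with pairs-per-lag
  weights. The exponential form is the default — a common choice for annual
  air-pollution residuals — with spherical and Gaussian available. The
  sill/range pair of the exponential model is weakly identified on a single
  realization and the WLS estimator is heavy-tailed; the search is therefore
  bounded (sills at ten times the residual variance, range at twice the
  cutoff), and parameter-recovery checks summarise replicates by the median.
  With fewer than five stations a configured fallback variogram is returned
  with a warning; identical residuals yield a degenerate zero-sill model,
  under which fusion reduces to a generalised-least-squares fit of the
  affine drift link.
* **Numerics.** Global neighbourhood (all stations for every cell) — at
  national-scale station counts a local search is unnecessary. Duplicate
  locations are averaged before solving. The nugget is treated as
  measurement error, so predictions target the smooth annual-mean signal;
  with a zero nugget the predictor interpolates the data exactly. Negative
  predictions are clipped at zero and counted. Concentrations are kriged on
  the natural scale (no log transform). With zero usable observations the
  drift field is returned unchanged, flagged with infinite variance.

## Change of support

Municipality exposure is the built-up-area-weighted block average

$$C_i = \sum_{p=1}^{n_i} \gamma_{ip}\, y_p, \qquad
  \gamma_{ip} = A_{ip} / A_i,$$

with $A_{ip}$ the municipality's built-up area inside cell $p$ and
$A_i = \sum_p A_{ip}$. Built-up weighting concentrates the average where
people live and work. Weights are non-negative and sum to one, so $C_i$
always lies within the range of its member-cell values. A municipality with
zero recorded built-up area falls back to the unweighted cell mean, with a
warning — every inhabited municipality must receive an exposure. A cell
split across municipalities may appear in each with its within-municipality
area.

Follow-up (1999–2008) is divided into four calendar risk sets, each assigned
the cumulative mean of the model-year exposures available up to its start:
1999–2002 uses 1999; 2003–2004 the mean of 1999 and 2003; 2005–2006 the mean
of 1999, 2003 and 2005; 2007–2008 the mean of all four model years. A
single-year sensitivity mode assigns one model year (default 2005) to the
whole follow-up. Missing model years are an error, never imputed.

## Outcome definitions

Deaths are classified by the underlying-cause code, ICD-9 through 2002 and
ICD-10 from 2003, into six groups (non-accidental, cardiovascular,
respiratory, neoplasms excluding lung cancer, lung cancer, nervous system).
Groups overlap by construction — a lung-cancer death is also non-accidental.
ICD-9 comparison uses the 3-digit rubric (longer codes are truncated);
ICD-10 uses the letter+2-digit rubric. Admissions are ICD-9 coded with up to
six diagnosis positions; most causes inspect the main cause only, while
diabetes and COPD are searched in all six positions.

Repeat admissions reduce to incident events: first admission only for most
causes; for myocardial infarction and angina a later event counts as new
after a 28-day washout, for lower respiratory tract infections after 90
days. The washout is anchored at the last *kept* event (greedy scan), and
the operation is idempotent.

Counting-process expansion splits each linked subject's follow-up at
risk-set boundaries and 5-year age-class boundaries (the survey literature
does not fix a class width; five years is conventional and configurable).
Ages advance continuously from a reconstructed birth date, so age-class
boundaries fall on fractional days; person-time accounting handles this
exactly. Follow-up is censored at death from any cause, end of window, or
the first analyzed incident event; admission outcomes start the clock at
2001-01-01, when admission records become linkable, and events dated before
a subject's start are dropped with a logged count. Competing risks are
handled as censoring only — no competing-risk model is fitted.

## Linkage completeness and representativeness

Record linkage is the design's weak point, so two checks are built in. The
expected-deaths check multiplies reference rates per (year, sex, age class)
with the cohort's person-years in that stratum and compares observed counts
via O/E ratios with exact Poisson 95% intervals; a stratum is flagged when
the interval excludes 1 (the flag rule is a package choice — the design
itself states no numeric criterion). In synthetic mode the rate table is the
generator's own baseline hazard, which makes the check self-consistent by
construction (mean O/E near 1 over replicates). The representativeness check
compares covariate category proportions between the full and linked samples,
flagging absolute differences above a threshold (default one percentage
point).

## The hazard model

For each cause and pollutant the model is a Cox proportional hazards fit on
(start, stop] rows, with the risk-set exposure (per 10 µg/m³ — a
conventional reporting increment, configurable) and age class time-varying,
adjusted for sex, education (four ISCED groups), marital status, occupation,
smoking, physical activity and BMI. The variance is a cluster-robust
sandwich aggregated at the municipality — the first-stage sampling unit —
with household available as an alternative. Ties use the Efron
approximation, inevitable at day granularity. Age class enters by default as
a baseline stratification, which is robust when thin age classes hold no
events; age-as-factor-covariate is available per configuration, and both are
correctly specified for the generator's multiplicative baseline.

Proportionality is tested per fixed predictor with scaled Schoenfeld
residuals; predictors failing at the configured alpha (default 0.05) are
refitted as strata and then carry no coefficient. Effect modification is
assessed by a likelihood-ratio test between nested fits with and without
exposure-by-modifier terms. Non-convergence and exact collinearity are
errors, not silent results.

## What the synthetic world emulates — and what it does not

The generator reproduces the *structure* of the study: a regular grid
(default 25×20 cells of 4 km — a desk-scale stand-in for a national domain),
a smooth true concentration surface (trend + hotspots + correlated
residual), a distorted model surrogate (affine bias plus smooth error),
stations with daily noise and missingness, contiguous municipalities with
built-up areas and all three population size classes, a two-stage household
sample with the survey covariates and an independent 0.92 Bernoulli linkage
flag, and events drawn from a piecewise-constant hazard
$\lambda(t) = \text{baseline}(\text{age class}, \text{sex})
\exp(\beta\,x(t)/10 + \text{covariate effects})$ with ICD codes following
the coding-era rule. Covariate effects default to a 0.1 log-HR education
gradient and 0.5 for current smoking — arbitrary but recorded in the ground
truth so recovery is checkable. The baseline is Gompertz-like,
$3\times10^{-5} e^{0.085\,\text{age}}$ per person-year with a 1.5× male
excess — the right order of magnitude for a western European population. An
optional shared municipality frailty induces within-cluster correlation for
robust-variance checks. The enrolment age range (0–95, adult-weighted) is an
assumption; the survey design enrols whole households but states no age
distribution.

It does **not** emulate atmospheric chemistry, emissions or meteorology,
real geography, household-correlated linkage failure (available as a config
idea, off by default), residential mobility, or coding error. Passing tests
therefore demonstrate the statistical machinery — unbiasedness, exactness,
calibration — under known smooth fields and clean records, not robustness
to the messiness of real archives.

## Problem sizes and numerical tolerances

The shipped tests run the Monte-Carlo checks at deliberate desk scales: 300
replicate fields for the variogram check, 100 worlds for the
fusion-beats-model comparison (36 stations on an 18×14 grid), 200 replicates
of ~5,000-subject cohorts for hazard-ratio recovery — drawn as 75 sampled
municipalities of ~26 households, because a national survey has many small
first-stage clusters and the cluster-robust sandwich only reaches nominal
coverage when clusters are plentiful — and 500 replicates of
~1,500-subject cohorts for the O/E self-consistency check (small cohorts
inflate the O/E ratio's small-sample bias, which is why the replicate
cohorts are not made smaller). Deterministic identities (kriging exactness,
weight constraints, block-average arithmetic, risk-set means) are asserted
at 10⁻⁶ to 10⁻¹² as appropriate; all stochastic checks run under fixed
seeds.

## A worked miniature

```{r example, eval = FALSE}
cfg <- default_world_config(
  grid = list(nx = 14, ny = 10, cell_km = 4, origin = c(0, 0)),
  n_stations = 25, n_munis = 25, n_munis_sampled = 12,
  households_per_muni = 25)
rep <- run_surveillance(cfg, seed = 21,
                        causes = c("non_accidental", "cvd"),
                        covariates = c("sex", "smoking"))
rep$results
rep$linkage
```

The report bundles the hazard-ratio table (cause × pollutant), PH
diagnostics, the station QC table, exposure tables, the linkage and O/E
reports, and a manifest with the seed and a configuration hash; re-running
with the same seed and configuration reproduces the tables exactly.

## Known limitations

* Kriging is purely spatial per year; no space-time or multi-pollutant
  co-kriging (annual PM2.5 and PM10 municipal means are too collinear for a
  joint model to be useful at this support).
* Exposure enters the hazard linearly in concentration; no splines.
* The O/E flag rule and the PH/interaction alpha are conventions, not
  validated thresholds.
* ICD handling covers range membership on printed rubrics, not full
  coding-system semantics (no V/E-code causes, no 4-digit exceptions).
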