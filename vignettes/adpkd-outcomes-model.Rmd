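---
title: "Methods: an annual-cycle patient-level model of ADPKD progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an annual-cycle patient-level model of ADPKD progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpkdsim)
```

## The model

Autosomal dominant polycystic kidney disease (ADPKD) progresses over
decades: cyst growth enlarges the kidneys (measured as total kidney
volume, TKV, in mL) and the loss of functional tissue erodes the
glomerular filtration rate (eGFR, mL/min/1.73 m^2) until end-stage renal
disease (ESRD, defined throughout as eGFR < 15). `adpkdsim` simulates this
process one patient at a time in fixed annual cycles, driven by two
log-linear annual-change equations fitted to placebo-arm data from the
TEMPO 3:4 trial:

$$\Delta TKV = \exp\!\big(\lambda_T + \alpha\,age + \beta_T \ln TKV +
\gamma\,[female] + \delta\,age \cdot \ln TKV\big) - 500$$

$$\Delta eGFR = \exp\!\big(\lambda_G + \beta_G \ln TKV\big) - 60$$

The offsets arise from the fitting procedure: the regressions were
estimated on annual changes shifted by +500 mL and +60 respectively so
that the natural logarithm is defined, which also bounds the predicted
changes below (`> -500` mL/y and `> -60`/y) by construction. The default
coefficients are bundled (`tempo34_tkv_coefficients()`,
`tempo34_egfr_coefficients()`); any other fit with the same functional
form can be supplied as JSON.

Within each 1-year cycle the event order is fixed and documented, because
no ordering is canonical and reproducibility requires choosing one:

1. background mortality is evaluated first, using the sex-specific annual
   death probability at `floor(age)` — a patient cannot progress in the
   cycle in which they die;
2. both annual changes are computed from the state at cycle start
   (current age and *current* TKV — see design choices below);
3. the state is updated, age advances one year, and one year is credited
   to the KDIGO CKD stage occupied at cycle start (half-open bins:
   stage 1 $[90,\infty)$, 2 $[60,90)$, 3 $[30,60)$, 4 $[15,30)$; stage 3
   is one state, not 3a/3b);
4. if the updated eGFR is below 15 the patient is absorbed into ESRD,
   with the age at ESRD resolved at whole-cycle granularity.

Simulation stops at ESRD, death, or an 80-year (lifetime) horizon;
survivors are censored, counted in incidence denominators but excluded
from age-at-ESRD statistics.

## Sources of variability

Three mechanisms make simulated patients differ:

* **Baseline heterogeneity.** Only mean ± SD summaries of the reference
  cohort are published, so `sample_baseline_cohort()` draws age, TKV and
  eGFR from independent truncated normal distributions whose parameters
  are the published moments (of the untruncated parent) and sex from a
  Bernoulli distribution. Default truncation bounds are age 18–60 years,
  TKV 300–8000 mL, eGFR 20–150 — wide enough to be clinically inclusive
  while excluding impossible values. Note that truncation is not
  moment-preserving: with TKV 1692 ± 905 truncated at 300 the realized
  mean is about 7% above 1692. An optional Gaussian-copula correlation
  matrix couples the three marginals for sensitivity analyses; the
  default is independence because no joint distribution is published.
* **Coefficient uncertainty.** Each patient receives one multivariate
  normal draw of each equation's coefficient vector, held fixed for that
  patient's lifetime, so identical baselines diverge into persistently
  fast and slow progressors. A per-cycle redraw option exists
  (`redraw_each_cycle`) but is off by default: per-cycle redraws average
  out across a lifetime and collapse the between-patient dispersion this
  mechanism is meant to create.
* **Mortality.** Gender-specific life-table draws (below).

### The covariance question

The published fit reports coefficient standard errors but not the full
variance-covariance matrices. Sampling coefficients independently
(`default_vcov_from_se()`, a diagonal of squared SEs) is offered as an
explicit fallback but is a poor default: with uncentred covariates the
intercept and slope estimates of a regression are almost perfectly
anticorrelated, and ignoring that inflates the dispersion of the linear
predictor by orders of magnitude — enough to turn a cohort of steady
decliners into a mixture of implausible explosive and recovering
trajectories. The bundled coefficient sets therefore carry a *synthetic
reconstructed* covariance built by `reconstruct_vcov()`: since
$cov(\hat\beta) = \sigma^2 (X'X)^{-1}$, the correlation structure of the
estimates is fixed by the design matrix alone, so we simulate a large
design matrix from the fitting cohort's published baseline distribution
(age 39 ± 7, TKV 1668 ± 873, 51.9% male), take the correlation matrix of
$(X'X)^{-1}$, and rescale it so the implied standard errors equal the
published ones exactly. The result reproduces the published marginal SEs
bit-exactly and the design-implied correlations, but it is not the
unpublished fitted matrix; users holding the true matrices can supply
them through the JSON coefficient files, which override everything else.

## Mortality

All-cause mortality uses a life table of annual death probabilities
$q_x$ by integer age and sex, loaded from CSV or generated synthetically.
The synthetic generator uses a Gompertz–Makeham hazard
$q_x = 1 - \exp\{-(a + b\,c^x)\}$ with defaults $a = 5\times10^{-5}$,
$b = 2.7\times10^{-5}$, $c = 1.098$ and a female hazard ratio of 0.55,
chosen once to approximate the adult age pattern of recent UK national
life tables (cumulative male mortality from age 39 to 65 of roughly
10%). Ages beyond the table plateau at the last row. Lifetime ESRD
incidence is mildly sensitive to the table: heavier mid-life mortality
removes slow progressors before they reach ESRD, so a few percentage
points of incidence ride on this choice; substitute a real national
table for applied work. No post-ESRD or cause-specific mortality is
modelled — the simulation ends at ESRD onset.

## Reproducibility design

Every random draw descends from one mandatory integer seed. Each patient
owns an RNG substream seeded by a deterministic hash of
`(seed, patient_id)`, with a fixed within-stream layout (coefficient
draws, then mortality uniforms). Consequences: cohort results are
invariant to patient ordering; any patient can be re-simulated alone and
match the cohort run bit for bit; and runs are byte-reproducible across
sessions. Quantile summaries (median, IQR, trajectory percentile bands)
use linear interpolation between order statistics (R type 7), stated
explicitly because IQR endpoints are compared across implementations.

## Numerical and boundary choices

* TKV is clamped below at 100 mL (the equations were fitted on kidneys
  ≥ 750 mL; below the floor the model logs a warning rather than
  extrapolating into vanishing volumes), and eGFR at 0.
* For small kidneys at ages past $\beta_T/|\delta| \approx 50$ years the
  TKV equation predicts shrinkage; TKV can settle at the floor where the
  predicted eGFR change is positive, so a small fraction of low-TKV
  baselines legitimately never reach ESRD and are horizon-censored.
* Patients already below eGFR 15 at baseline are returned as ESRD at age
  of entry with zero cycles.
* A linear-interpolation option for the age at ESRD within the crossing
  year exists for sensitivity analyses; the default is whole-cycle
  resolution, consistent with a fixed-increment model whose cohort means
  are insensitive to sub-year timing.
* Stage occupancy is credited to the stage at cycle start; credited years
  therefore equal completed progression cycles exactly (a conservation
  property the tests assert).

## What the synthetic generators do and do not emulate

The baseline generator reproduces published marginal moments under
truncation and nothing more: real ADPKD cohorts have correlated
baselines (larger kidneys go with lower eGFR and younger diagnosis),
non-normal TKV distributions (right-skewed), and eligibility filters
that truncate in covariate combinations, not margins. The life table is
a smooth two-parameter hazard, not an actual national table. Passing
tests therefore demonstrate internal correctness and faithfulness to the
published summary statistics — not validity in any particular clinical
population. The one distributional feature the defaults are known to
misplace is stage-1 time: with independent truncated-normal baselines
about a third of patients start above eGFR 90, so roughly a year of mean
pre-ESRD time sits in stage 1 that a correlated (or differently
truncated) baseline would assign to stage 2.

## Problem sizes

The base-case analyses in this package simulate 10,000 patients over a
lifetime horizon — about a second of compute — and that is the size used
by `scripts/acceptance.R` and the headline acceptance test. Unit and
property tests use cohorts of 25–500 patients and coefficient-draw
samples up to $10^5$, sizes at which Monte-Carlo error is far below the
tolerances asserted.

## Worked example

```{r example, eval = FALSE}
cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 10000), seed = 1)
outcomes <- simulate_cohort(cohort,
                            life_table = synthetic_uk_like_table(),
                            config = simulation_config(seed = 1))
age_at_esrd_summary(outcomes)
time_in_stages(outcomes)
cumulative_esrd_by_age(outcomes)
lifetime_esrd_incidence(outcomes)
```

## Known limitations

* Treatment effects, costs and utilities are out of scope: this is a
  natural-history model.
* Covariates limited to age, sex, TKV and eGFR; genotype, hypertension,
  proteinuria and extra-renal disease are not modelled.
* The reconstructed coefficient covariance matches published SEs and
  design-implied correlations, not the unpublished fitted matrix; second
  moments of simulated outcomes (SDs, IQRs, interval widths) inherit
  that approximation.
* Extrapolation beyond the fitting domain (baseline age > 50, TKV <
  750 mL, eGFR outside roughly 60–110) is flagged, not forbidden;
  interpret those runs with care.
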