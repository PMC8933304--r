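---
title: "Building a FRAX-style hip fracture probability model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a FRAX-style hip fracture probability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fraxbuildr)
library(dplyr)
```

Country-specific fracture-risk models are built from four ingredients: a
hip-fracture case series, population denominators, a life table, and — where
direct incidence of the other major osteoporotic fractures (MOF) is not
available — ratios of those fractures to hip fracture borrowed from a
reference population. This vignette explains how `fraxbuildr` turns those
ingredients into 10-year and lifetime fracture probabilities, which
assumptions are load-bearing, and what the packaged synthetic data do and
do not demonstrate.

## Case definition and deduplication

A hip fracture is an admission coded ICD-10 S72.0 (femoral neck), S72.1
(pertrochanteric) or S72.2 (subtrochanteric), at age 40 or older in
completed years at admission, with no trauma-based exclusion — high- and
low-energy fractures behave similarly with respect to bone fragility, and
trauma grading in records is inconsistent.

Hospital line lists contain repeat admissions for one fracture (transfers,
re-operations, rehabilitation), often recoded to a different S72 subcode.
`select_index_admissions()` therefore deduplicates *subcode-blind* within
patient: any hip admission within `window_days` (default **365 days**) of an
earlier retained admission is discarded, and the earliest admission defines
the case's age and calendar year. The window is a judgement call: long
enough to absorb any plausible same-fracture care episode, short enough
that a genuine second hip fracture a year or more later still counts. The
rule is greedy and idempotent — applying it twice changes nothing, which
the test suite asserts.

## Incidence and its uncertainty

Person-years are the sum of mid-year head counts over the study years (one
person-year per resident per calendar year). With annually projected
denominators this is the natural convention; whether an official analysis
summed or averaged its denominators rarely changes rates visibly, but the
convention is stated here so results are reproducible.

With `n` events over `PY` person-years the rate is `n/PY` (reported per
100,000), and the 95% interval is the exact Garwood construction from
chi-square quantiles. At national-registry counts for a small country —
single digits per stratum in places — a normal approximation would be
badly anti-conservative; the exact interval is asymmetric and remains valid
at `n = 0`, where the lower limit is 0 and the upper limit is
`χ²(0.975, 2)/(2·PY)`. By exact enumeration over the Poisson mass the
interval's coverage at means 1–20 ranges from about 95.7% to 98.8%:
conservative, never below nominal.

Rates are kept at full precision internally; `format_incidence()` rounds to
one decimal per 100,000 only at the reporting layer.

## Comparing population strata

Two resident strata (nationals vs expatriates) have very different age
structures, so crude rates are not comparable. `age_standardize()` applies
direct standardization using the national age distribution as the standard,
with the Fay–Feuer gamma interval — again chosen for validity with sparse
counts. The two standardized rates are compared with a z-test on the log
scale using delta-method standard errors. No exact test is canonical for
standardized rates; the log-scale z-test is standard practice, and the test
suite checks it against a parametric bootstrap that re-standardizes
Poisson-resampled counts under a pooled null (agreement within 0.005 on
the p-value). When a standardized rate is zero the function refuses and
points the user to an exact comparison on the raw counts.

## From bands to hazards

The probability engine needs hazards on single years of age, 40–105.

**Fracture.** `smooth_incidence()` fits a Poisson regression of band counts
on band-midpoint age with a log link and person-years offset. The default
shape is log-quadratic: hip incidence is close to exponential in age, so a
log-linear term captures the trend and the quadratic term allows gentle
curvature without overfitting nine bands. A natural-spline alternative
(`method = "spline"`, default 3 df) exists for richer data. Band midpoints
are the arithmetic centre of each half-open band (42.5 for [40, 45)); the
open 80+ band is assigned midpoint **85**. The fitted curve is evaluated at
ages 40–90 and held constant to 105 — extrapolating a quadratic on the log
scale beyond the last supporting data would be driven entirely by the
curvature term.

**MOF.** `mof_from_hip()` multiplies the hip hazard by `1 + r(age, sex)`,
where `r` is the ratio of other-MOF to hip incidence. Ratios are constant
within their bands and the last band extends upward. The construction
ignores that one person can sustain several fracture types; the modelled
event is the *first* MOF, and the additive combination slightly overstates
the joint hazard at ages where ratios are large. The packaged ratio table
(`synthetic_mof_hip_ratios.csv`) is an illustrative synthetic fixture with
the qualitative shape seen in reference populations (large ratios at
younger ages, declining toward 1 at 80+); it is **not** a published ratio
set and ships only so the full pipeline can run and be tested.

**Death.** `mortality_hazard()` converts annual death probabilities via
`m = −ln(1 − q)`, uses central rates directly when given, holds abridged
bands constant within band, and extends beyond the table by log-linear
(Gompertz) extrapolation from the last two bands. On a life table that is
genuinely Gompertz the extrapolated tail reproduces the generating curve,
which the tests verify; `q = 1` is rejected as an infinite hazard.

## Competing-risk probability

With piecewise-constant hazards `h_f` (fracture) and `h_d` (death) on
one-year intervals, the probability of a first fracture within a horizon is
summed in closed form: interval `k` contributes
`S_k · h_f/(h_f+h_d) · (1 − e^{−(h_f+h_d)})`, with `S_k` the probability of
entering the interval free of both events, and a zero combined hazard
contributing zero. Because the within-interval integral is exact there is
no step-size error; the only discretization is the one-year grid itself.
The same machinery gives the death-first and event-free probabilities, and
the three sum to one to machine precision — a property the tests check on
randomized hazard profiles, alongside agreement with an independent
discrete-event Monte-Carlo simulation (`monte_carlo_probability()`) within
three binomial standard errors.

"Lifetime" probability is the horizon to a closed terminal age of **105**
(configurable): hazard tables end somewhere, and past 105 survival is rare
enough that the truncation is immaterial at reporting precision.

These are population-average probabilities: no clinical risk factors, no
bone-density adjustment. A full clinical tool layers proprietary
relative-risk coefficients on top of exactly these baseline hazards; those
coefficients are unpublished and out of scope here.

## The synthetic registry

`synthetic_config()` defines the generator. Fracture events per
stratum-year are Poisson with mean `head count × h_f(band midpoint)`, where
`h_f(a) = a₀·e^{b·a}` with default scale `a₀ = 7.5e-7`/year and slope
`b = 0.11`/year — a log-linear fit by eye to Gulf-registry incidence
levels (tens per 100,000 in the late 50s rising to several hundred at
80+). The female:male hazard ratio defaults to 1.25 and the
expatriate:national ratio to 1.4. Mortality is Gompertz–Makeham,
`h_d(a) = α + β·e^{c·a}`, with sex-specific defaults giving plausible
adult death rates. Duplicate admissions are injected 1–90 days after the
index with probability 0.1 — well inside the 365-day window, so the dedup
rule is exercised unambiguously — and 5% decoy non-hip admissions exercise
the code filter.

Within closed bands the age at fracture is uniform over the five single
years (the true within-band distribution of cases is unknowable from
banded data; uniform is the neutral choice, and midpoint evaluation of the
hazard makes the discretization error second-order in band width). In the
open 80+ band, ages 80–100 are drawn with weights proportional to the
survival curve implied by the config's own mortality, so the band thins
with age the way a real population does.

The generator emulates: two strata with different rates and age
structures, age-increasing fracture and death hazards, duplicate
admissions, decoy codes, and census projection by a fixed growth factor.
It does **not** emulate secular trends, seasonality, ascertainment gaps,
post-fracture excess mortality, or refracture. Passing tests therefore
show the *estimation machinery* is correct under the stated statistical
structure — not that any real population satisfies that structure.

## Problem sizes and determinism

All randomness flows from a single seed per generated registry; identical
seed and configuration give byte-identical output, and `run_pipeline()`
writes a manifest with a configuration hash so two runs are comparable
file-by-file. The test suite's statistical checks use: exact enumeration
(not simulation) for interval coverage; 2,000 replicate registries for the
gamma-interval coverage check; 72 simulated strata for stratum-level
coverage; 20 randomized hazard profiles at 10⁵ subjects each for the
Monte-Carlo comparison; and a ~2.4-million-person-year national registry
for end-to-end recovery of 10-year probabilities at ages 60–80 — sizes at
which the checks have real power while the suite stays fast.

## Known limitations

* Rates are treated as incidence in the total population, not among
  prior-fracture-free survivors; at the event rates involved the
  distinction is small but real.
* The 80+ incidence is flattened to a constant beyond age 90; official
  tools may distribute it differently, so absolute probabilities at the
  oldest ages are convention-dependent.
* The MOF imputation inherits whatever bias the borrowed ratio table
  carries.
* The dedup window cannot distinguish a true second hip fracture within a
  year from a readmission.
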