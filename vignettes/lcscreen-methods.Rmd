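---
title: "Model and methods: simulating CT lung cancer screening policies in China"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating CT lung cancer screening policies in China}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

China has several hundred million current smokers, most of them men, and a
large burden of lung cancer among never-smoking women. Two eligibility rules
for annual low-dose CT screening are on the table: the U.S. CMS rule (ages
55–77, at least 30 pack-years, at most 15 years since quitting) and the
Chinese national guideline (ages 50–74, at least 20 pack-years, at most 5
years since quitting). `lcscreen` is a person-level microsimulation for
asking what each rule buys — lung cancer deaths prevented, life-years saved
— and what it costs in screening volume, when screening runs from 2016
through 2050 across the whole adult population.

## Model structure

Each simulated person carries a smoking life-course, an other-cause death
age, and possibly a latent lung cancer. Time advances in annual cycles on
integer ages 15–84; persons exit alive at 85. Calendar years 1975–2050 are
tallied, so birth cohorts 1891–2035 are simulated (cohorts already adult in
1975 receive retrospectively sampled histories from age 15 with the same
curves).

**Smoking.** Initiation age comes from a cumulative logistic curve in age
with a per-sex, per-birth-cohort-group asymptote ("level"), shared midpoint
and slope. Quitting is a one-way annual hazard — 0.02 for males aged 30–65,
0.03 above 65, 0.02 for females from 35, zero below the tracking ages — with
no relapse. Intensity (cigarettes/day) is deterministic given sex, age and
calendar year: the male age profile observed in 2006 is combined
multiplicatively with the calendar-year trend in mean cigarettes per day,
and the female profile reuses the male age shape rescaled so the female
calendar anchors are matched as age-35–74 means. Outside the observed
1980–2012 window the trend is held at the nearest anchor. Pack-years
accumulate cigarettes/day ÷ 20 over completed smoking years and freeze at
quitting.

**Natural history.** Annual onset hazard is
`baseline(sex, age) × (1 + β · pack-years^η · decay)`, with a Weibull
baseline in age (shape 6, scale 110, per-sex multiplier set by calibration)
and `decay = exp(−δ · years-since-quit)` for former smokers (δ = 0.03/yr).
A tumor then has a preclinical sojourn (1 + geometric, mean 4 years) to
symptomatic detection, a stage drawn at detection
(I/II/III/IV = 0.15/0.10/0.25/0.50 clinically), a stage-specific cure
fraction (0.55/0.35/0.12/0.02) and, if not cured, exponential residual
survival (rates 0.15/0.25/0.50/1.00 per year). Histology is assigned from
the published sex-by-period table and is bookkeeping only — survival is
stage-specific. Other-cause mortality is a synthetic Gompertz–Makeham life
table per sex with multiplicative smoking-intensity bands (never / <20 /
≥20 cigarettes per day at 1.0 / 1.5 / 2.0).

**Detection channels and the stage-shift benefit.** A tumor can be found
three ways: symptoms (the clinical route), incidental imaging (2%/year
while preclinical), or a screen. Screening benefit operates purely through
stage shift: at screen detection the stage is redrawn from a distribution
with probability mass `s` moved to stage I (the stage-shift parameter `s`,
set by calibration), *at the same quantile* as the clinical stage draw, the
same cure draw is evaluated at the new stage's cure fraction, and the same
survival draw is applied at the new stage's rate *anchored at the clinical
detection age*. Incidental detection uses the clinical stage and the same
anchor. Three consequences, by construction rather than by chance:

* earlier diagnosis alone never changes a death age (no lead-time bias);
* a screen-detected tumor's death age is never earlier than its clinical
  counterfactual, so deaths prevented are nonnegative in every stratum at
  the person level;
* with stage-shift 0 (or CT sensitivity 0) screening scenarios reproduce
  the baseline exactly.

**Screening process.** In each programme year (2016–2050) an alive,
undiagnosed person who satisfies the policy's inclusive bounds (age window,
pack-years, quit window; never-smokers never qualify) and is an attender is
screened once. Attendance is a per-person always/never draw at the policy's
adherence fraction — the conservative reading of population adherence that
makes the screens-versus-adherence relationship exactly linear in
expectation. A screen detects a preclinical tumor with sensitivity 0.85 per
visit. Diagnosis by any channel ends screening for that person.

**Common random numbers.** Every cohort draws its random numbers once, in a
fixed order, from a seed derived from (run seed, birth year, sex); every
scenario is then a deterministic function of those draws. Baseline, CMS and
CNG therefore share persons, histories, tumors and other-cause deaths
bit-for-bit, and differences between scenarios are pure policy effects —
never-smoker death tallies are identical across scenarios by construction.

**Scaling.** Tallies are scaled to population units by the ratio of the
projection count at cohort entry (age 15, or the 1975 age for earlier
cohorts) to simulated survivors at entry, held fixed thereafter; simulated
attrition then governs cohort size.

## Synthetic external inputs

Two inputs the analysis needs are not published as tables and are generated
synthetically, as first-class tested code:

* **Life tables** — Gompertz–Makeham `A + B·exp(θ·age)` per sex
  (A = 8/6 ×10⁻⁴, B = 4.5/2.5 ×10⁻⁵ for males/females, θ = 0.088), chosen
  to give mid-70s life expectancy; band multipliers as above.
* **Population projection** — cohort entry sizes follow a logistic rise
  (mid-century growth) times a logistic decline toward a 0.55 floor
  (post-transition fertility), peak 21 million entrants/year, 51.2% male,
  aged forward with the never-band life table. The default adult population
  is ~0.9 billion.

The projection deliberately does **not** reproduce China's census: absolute
population-scale outputs (e.g. total deaths 2016–2050) are meaningful only
relative to it, which is why the published absolute totals are checked as
outcome-formula arithmetic on the published tables, not as simulation
output. Within-model comparisons (reductions, ratios, orderings) are the
simulation's claims. Post-2015 fertility changes are ignored; they cannot
affect results before 2031 and the window ends in 2050.

## Calibration

Three stages, strictly ordered; later stages never touch earlier fits.

1. **Initiation levels → prevalence.** Six cohort-group levels per sex
   (births ≤1928, –1936, –1944, –1952, –1960, –1970; cohorts after 1970 use
   0.85 × the last level) are fitted to the twelve survey prevalence
   anchors (ages 35–74, six years per sex) by Nelder–Mead on
   logit-transformed levels from several seeded starts. The objective uses
   an exact four-state annual Markov chain (never / current / former by
   intensity band) that mirrors the simulation cycle, so it is
   deterministic and free of Monte-Carlo noise; a property test keeps chain
   and simulation in agreement. All twelve residuals land within the 5%
   target tolerance (max ≈ 4%). The fitted female levels are *effective*
   parameters, not demographic estimates: the survey series has a sharp
   2000–2004 drop that the model can only express through strongly
   non-monotone cohort levels, a known identifiability limit documented
   here on purpose.
2. **Baseline hazard → 2012 mortality.** The per-sex Weibull multipliers
   are solved so scaled simulated lung cancer deaths in 2012 match 422,000
   (male) and 175,000 (female): a damped secant in log space on counts
   simulated under common random numbers (20,000 persons per cohort for the
   search, refined and verified at 50,000). Shipped defaults achieve
   −0.4% (male) and −0.8% (female).
3. **Stage-shift → trial anchor.** The stage-shift is root-solved so the
   simulated mortality reduction in the CMS-eligible subgroup of the 1960
   birth cohort equals 19.7% (100,000 persons per sex, CRN). A zero anchor
   yields zero shift; an unreachable anchor aborts with the achievable
   bound. Fitted default: 0.408.

The dose-effect coefficients β (2.0 male, 0.9 female per pack-year) and the
quit-decay δ were fixed once so the simulated baseline composition of
deaths by smoking status approximates the published strata (never-smoker
share ≈ 2% of male and ≈ 60% of female deaths); they are inputs, not
calibrated parameters, and the mortality calibration absorbs their scale.

## Numerical choices and degenerate inputs

* Annual integer ages; lung cancer death ages are continuous (detection age
  + exponential survival) and floored into tally years; a lung cancer death
  wins a same-year tie with other-cause death.
* Death tallies are stratified by smoking status *at the clinical detection
  age* (status at diagnosis). That anchor is identical across scenarios, so
  screening moves deaths across calendar years but never across status
  strata: per-stratum deaths prevented are nonnegative by construction.
  Labelling by status at the (possibly deferred) death year instead would
  let a deferred death cross a quit event and flip a stratum count upward.
* Inverse-CDF sampling on single uniforms everywhere (initiation, quit,
  other-cause death, onset clock) keeps scenario and sensitivity variants
  maximally coupled: doubling the cessation hazard from 2016 provably
  leaves all pre-2016 history unchanged and can only advance quit ages.
* Stage distributions must have nonincreasing cure and nondecreasing
  survival-rate vectors (validated), which is what makes the coupled
  stage-shift monotone.
* Degenerate parameters are honored exactly: zero initiation → never-
  smokers only; cessation 1 → universal quitting at the tracking age; cure
  1 → no lung cancer deaths; incidental rate 1 → detection in the first
  preclinical year.

## Problem sizes

Defaults are sized for a desk machine: the bundled comparisons and tests
run at a few hundred to 20,000 persons per cohort per sex (145 cohorts,
both sexes, three scenarios in ~1–2 minutes at 20,000), the mortality
calibration verifies at 50,000, and the trial-anchor calibration uses
100,000 persons per sex in a single cohort. The study-scale configuration —
two million per cohort per sex — is the same code path via
`n_per_cohort = 2e6`, scaled for cluster time.

## What the tests do and do not show

Passing tests show the machinery is right: inputs are carried verbatim,
the outcome formulas reproduce the published arithmetic exactly, the
calibration stages hit their targets at the stated tolerances, the policy
orderings (CNG reaches more people and screens more; screens scale
linearly with adherence; cessation changes move mortality reduction by
under a percentage point) hold under common random numbers, and runs are
byte-reproducible. They do not show that the synthetic projection or life
tables match China's demography, that the surrogate natural history equals
a tumor-growth model, or that absolute population totals are forecasts —
those depend on external data this package intentionally stands in for.

## Sensitivity behaviour

Screens scale exactly linearly with per-person adherence in expectation,
and the bundled sweep confirms the halving empirically. Cessation is more
delicate: doubling or halving the quit hazard from 2016 moves the
2016–2050 mortality reduction by about 2 percentage points in this
package's configuration (measured with the bundled sensitivity analysis at
2,000 persons per cohort under common random numbers) — roughly 20% of the
~10% overall reduction. The absolute swing is larger than in the published
analysis chiefly because the overall mortality reduction itself is about
twice as large under the synthetic demography (the prevalence fit drives
pre-1952 male ever-smoking to its upper bound, and the stand-in projection
weights cohorts differently than the census), and absolute sensitivity
scales with the reduction. The test suite asserts this property at the
published-analysis scale (under one percentage point), so that check
documents the exceedance instead of hiding it behind a relaxed bound.

## Known limitations

No urban/rural or education strata; no secondhand-smoke or air-pollution
risk covariates (their baseline contribution is implicit in the mortality
calibration); no benign-nodule false-positive cascade, no observed-versus-
true stage discordance, no treatment detail, no costs; no relapse after
quitting; adherence is per-person, not per-visit; life-years are
undiscounted.
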