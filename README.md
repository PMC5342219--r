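# lcscreen

Person-level microsimulation of low-dose CT lung cancer screening policies
in China. The package simulates smoking life-courses (initiation, one-way
cessation, calendar- and age-dependent intensity, pack-years), lung cancer
natural history (an excess-hazard dose model on pack-years with preclinical
sojourn, stage at detection, stage-specific cure and survival), competing
other-cause mortality, and an annual screening process, for birth cohorts
1891–2035 observed over calendar years 1975–2050. It is written for
modellers and policy analysts who want to compare screening eligibility
rules — the U.S. CMS rule (ages 55–77, ≥30 pack-years, ≤15 years since
quitting) versus the Chinese national guideline (ages 50–74, ≥20
pack-years, ≤5 years since quitting) — on deaths prevented, life-years
saved, and screening burden.

## The model in brief

Annual lung cancer onset hazard for a person of sex *s* at age *a*:

    h(a) = h0_s(a) * (1 + beta_s * PY(a)^eta * d(a)),
    d(a) = exp(-delta * years_since_quit)  for former smokers, 1 otherwise

with a Weibull never-smoker baseline `h0_s` calibrated to GLOBOCAN 2012
death counts (422,000 male / 175,000 female), and pack-years `PY`
accumulated from survey-based cigarettes-per-day profiles. A tumor is
detected by symptoms, incidentally, or by a screen; screening benefit is a
pure stage shift: the screen-detection stage distribution moves probability
mass `s` to stage I, coupled quantile-by-quantile to the clinical draw and
anchored at the clinical detection age, so earlier diagnosis alone never
changes a death age and screening can only defer or remove deaths. The
shift `s` is calibrated so the mortality reduction in the CMS-eligible
subgroup of the 1960 birth cohort reproduces the NLST-based 19.7% anchor.
Scenarios run under common random numbers: baseline, CMS and CNG share
every person, history and tumor, so policy contrasts are noise-free.
Smoking initiation is calibrated to China Health and Nutrition Survey
prevalence (12 anchors, 1991–2006). Inputs the study used but did not
publish (life tables, the census population projection) are generated
synthetically — absolute population totals are therefore illustrative,
while calibration targets, ratios and policy orderings are the model's
claims. See `vignettes/lcscreen-methods.Rmd` for the full account.

## Worked example

```r
library(lcscreen)

params <- default_parameters()      # ships with calibrated values
cmp <- run_compare(params, n_per_cohort = 2000, seed = 1)
cmp
```

```
<lcpm_comparison> seed 1, n_per_cohort 2000, years 2016-2050
  cms: deaths prevented 2921263; MR 10.69% (m 12.27%, f 4.61%); LY saved 19443940 (6.7/death); screens 1330472881
  cng: deaths prevented 3050942; MR 11.17% (m 12.75%, f 5.09%); LY saved 27806142 (9.1/death); screens 2448785254
```

Read: under this package's synthetic demography (~27 million baseline lung
cancer deaths 2016–2050; absolute totals track the stand-in projection,
not the census), annual CT screening with the CMS rule prevents ~2.9
million deaths — a 10.7% reduction, much higher in males than females
because few women meet the pack-year thresholds — at ~6.7 life-years per
death prevented and 1.33 billion screens. The broader Chinese rule
prevents more deaths, especially in women and younger cohorts, but needs
~84% more screens. Per-sex detail, per-year series (eligibility, screens,
cumulative mortality reduction), per-birth-cohort reductions and
Table-style strata are in `cmp$summary`, `cmp$series`, `cmp$cohorts` and
`cmp$strata`, and can be written as CSV/JSON with
`run_compare(..., out_dir = "out")`.

Calibration from scratch (rather than using the shipped values):

```r
cal <- calibrate_lcpm(default_parameters(), seed = 1)
cal
#> <lcpm_calibration>
#>   prevalence: max |rel error| = 3.93% (within tolerance)
#>   2012 deaths: male 419895 (-0.50%), female 174310 (-0.39%)
#>   screening anchor: achieved 19.7% (target 19.7%), shift 0.409
```

A thin CLI covering `calibrate | simulate | compare | sensitivity` is in
`inst/scripts/lcpm.R`.

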