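# Shared fixtures, built once per test run. The default bundle ships with
# calibrated values, so tests against published anchors need no refitting.
PARAMS <- default_parameters()
LT <- generate_life_tables(PARAMS)
PROJ <- generate_population_projection(PARAMS, life_table = LT)

# parameters with a flat cigarettes/day profile (cpd constant in age & year),
# convenient for closed-form pack-year oracles
flat_cpd_params <- function(cpd = 20, params = PARAMS) {
  params$smoking$cpd_age_anchors <- list(age = c(20, 80), cpd = c(cpd, cpd))
  params$smoking$cpd_year_anchors$male <-
    list(year = c(1980, 2012), cpd = c(21.8, 21.8))
  params$smoking$cpd_year_anchors$female <-
    list(year = c(1998, 2003), cpd = c(cpd, cpd))
  params
}

make_history <- function(sex = "male", birth_year = 1950, init = NA,
                         quit = NA) {
  list(sex = sex, birth_year = birth_year, initiation_age = init,
       quit_age = quit)
}

# frozen Table-of-inputs fixture: every published number the default bundle
# must carry verbatim
published_inputs <- function() {
  list(
    prevalence_male = c("1991" = 0.66, "1993" = 0.65, "1997" = 0.62,
                        "2000" = 0.58, "2004" = 0.59, "2006" = 0.57),
    prevalence_female = c("1991" = 0.062, "1993" = 0.061, "1997" = 0.055,
                          "2000" = 0.053, "2004" = 0.041, "2006" = 0.035),
    cessation_male = c("40" = 0.02, "65" = 0.02, "70" = 0.03),
    cessation_female = c("40" = 0.02),
    cpd_male_2006 = c("37" = 16.56, "46" = 17.44, "55" = 15.76,
                      "66" = 13.2, "74" = 12.2),
    cpd_trend = c("1980" = 15.5, "1996" = 18.2, "2006" = 21.8,
                  "2012" = 22.3),
    cpd_female_qian = c("1998" = 12.3, "2003" = 15.8),
    lc_deaths_2012 = c(male = 422000, female = 175000),
    histology_male = rbind("1991-1995" = c(0.30, 0.54, 0.13, 0.03),
                           "1996-2000" = c(0.31, 0.52, 0.13, 0.04),
                           "2001-2005" = c(0.33, 0.52, 0.10, 0.05)),
    histology_female = rbind("1991-1995" = c(0.51, 0.32, 0.15, 0.02),
                             "1996-2000" = c(0.55, 0.32, 0.10, 0.03),
                             "2001-2005" = c(0.54, 0.34, 0.08, 0.04))
  )
}
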