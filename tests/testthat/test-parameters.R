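test_that("every published input number appears verbatim in the defaults", {
  pub <- published_inputs()
  tg <- PARAMS$targets
  for (s in c("male", "female")) {
    pv <- pub[[paste0("prevalence_", s)]]
    got <- tg[tg$kind == "prevalence" & tg$sex == s, ]
    expect_equal(got$value[match(names(pv), got$year)], unname(pv))
    hm <- pub[[paste0("histology_", s)]]
    for (per in rownames(hm)) {
      v <- PARAMS$natural_history$histology[[s]][[gsub("-", "-", per)]]
      expect_equal(unname(v), unname(hm[per, ]))
    }
  }
  expect_equal(cessation_rate("male", c(40, 65, 70), PARAMS),
               unname(pub$cessation_male))
  expect_equal(cessation_rate("female", 40, PARAMS),
               unname(pub$cessation_female))
  aa <- PARAMS$smoking$cpd_age_anchors
  expect_equal(setNames(aa$cpd, aa$age), pub$cpd_male_2006)
  ya <- PARAMS$smoking$cpd_year_anchors$male
  expect_equal(setNames(ya$cpd, ya$year), pub$cpd_trend)
  qa <- PARAMS$smoking$cpd_year_anchors$female
  expect_equal(setNames(qa$cpd, qa$year), pub$cpd_female_qian)
  mt <- tg[tg$kind == "mortality_count", ]
  expect_equal(setNames(mt$value, mt$sex), pub$lc_deaths_2012)
})

test_that("cessation schedule is tracked from age 30 (m) / 35 (f)", {
  expect_equal(cessation_rate("male", 25, PARAMS), 0)
  expect_equal(cessation_rate("male", 40, PARAMS), 0.02)
  expect_equal(cessation_rate("male", 70, PARAMS), 0.03)
  expect_equal(cessation_rate("female", c(30, 34), PARAMS), c(0, 0))
  # the sensitivity multiplier only acts from its switch-on year
  p2 <- PARAMS
  p2$smoking$cessation_multiplier <- 2
  expect_equal(cessation_rate("male", 40, p2, year = 2010), 0.02)
  expect_equal(cessation_rate("male", 40, p2, year = 2016), 0.04)
})

test_that("cigarettes per day returns anchors and interpolates linearly", {
  expect_equal(cigarettes_per_day("male", 46, 2006, PARAMS), 17.44)
  expect_equal(cigarettes_per_day("male", 55, 2006, PARAMS), 15.76)
  # independent straight-line interpolation oracle between age anchors
  w <- (50.5 - 46) / (55 - 46)
  expect_equal(cigarettes_per_day("male", 50.5, 2006, PARAMS),
               (1 - w) * 17.44 + w * 15.76)
  # nearest-anchor extrapolation outside the anchor ages / years
  expect_equal(cigarettes_per_day("male", 20, 2006, PARAMS), 16.56)
  expect_equal(cigarettes_per_day("male", 80, 2006, PARAMS), 12.2)
  expect_equal(cigarettes_per_day("male", 46, 2030, PARAMS),
               cigarettes_per_day("male", 46, 2012, PARAMS))
  expect_equal(cigarettes_per_day("male", 46, 1960, PARAMS),
               cigarettes_per_day("male", 46, 1980, PARAMS))
  expect_error(cigarettes_per_day("other", 46, 2006, PARAMS), "sex")
  expect_true(all(cigarettes_per_day("female", 35:74, 2003, PARAMS) >= 0))
  # female calendar anchors are matched as age-averaged means
  expect_equal(mean(cigarettes_per_day("female", 35:74, 2003, PARAMS)), 15.8,
               tolerance = 1e-9)
  expect_equal(mean(cigarettes_per_day("female", 35:74, 1998, PARAMS)), 12.3,
               tolerance = 1e-9)
})

test_that("histology distributions renormalise and map years to periods", {
  expect_equal(unname(histology_distribution("male", "2001-2005", PARAMS)),
               c(0.33, 0.52, 0.10, 0.05))
  expect_equal(unname(histology_distribution("female", "1996-2000", PARAMS)),
               c(0.55, 0.32, 0.10, 0.03))
  for (s in c("male", "female")) {
    for (per in c("1991-1995", "1996-2000", "2001-2005")) {
      expect_equal(sum(histology_distribution(s, per, PARAMS)), 1)
    }
  }
  # years before the first period use it; years at/after 2005 use the last
  expect_equal(histology_distribution("male", 1985, PARAMS),
               histology_distribution("male", "1991-1995", PARAMS))
  expect_equal(histology_distribution("male", 2030, PARAMS),
               histology_distribution("male", "2001-2005", PARAMS))
})

test_that("bundled policies match the two guidelines", {
  cms <- PARAMS$policies$cms
  expect_equal(c(cms$age_min, cms$age_max, cms$min_pack_years,
                 cms$max_years_since_quit), c(55, 77, 30, 15))
  cng <- PARAMS$policies$cng
  expect_equal(c(cng$age_min, cng$age_max, cng$min_pack_years,
                 cng$max_years_since_quit), c(50, 74, 20, 5))
  expect_equal(c(cms$start_year, cms$end_year, cms$adherence),
               c(2016, 2050, 1))
})

test_that("parameter bundles round-trip through JSON and validate", {
  path <- tempfile(fileext = ".json")
  save_parameters(PARAMS, path)
  p2 <- load_parameters(path)
  expect_equal(p2, PARAMS)
  # overriding adherence survives the round trip
  p3 <- PARAMS
  p3$policies$cms$adherence <- 0.7
  save_parameters(p3, path)
  expect_equal(load_parameters(path)$policies$cms$adherence, 0.7)
  # schema violations name the offending field
  broken <- PARAMS
  broken$smoking$cessation$male <- NULL
  expect_error(validate_parameters(broken), "cessation_schedule")
  broken <- PARAMS
  broken$natural_history$stage_clinical <- c(I = 0.5, II = 0.2, III = 0.2,
                                             IV = 0.2)
  expect_error(validate_parameters(broken), "stage_distribution_clinical")
  broken <- PARAMS
  broken$natural_history$cure <- c(I = 0.1, II = 0.3, III = 0.1, IV = 0)
  expect_error(validate_parameters(broken), "nonincreasing")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("initiation curve is a bounded cohort-level logistic", {
  f <- initiation_cdf("male", 1950, 15:60, PARAMS)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  # cohorts past the last break scale the last fitted level by late_ratio
  ip <- PARAMS$smoking$initiation$male
  expect_equal(initiation_cdf("male", 1990, 50, PARAMS),
               ip$late_ratio * initiation_cdf("male", 1965, 50, PARAMS))
})
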