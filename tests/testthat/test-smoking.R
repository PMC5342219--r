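test_that("pack-years follow the definition and freeze at quitting", {
  p20 <- flat_cpd_params(20)
  h <- make_history(init = 30)
  expect_equal(pack_years(h, 40, p20), 10)           # one pack/day for 10 y
  p10 <- flat_cpd_params(10)
  h2 <- make_history(init = 30, quit = 32)
  expect_equal(pack_years(h2, 50, p10), 1)           # half pack for 2 years
  expect_equal(pack_years(make_history(), 60, p20), 0)
  # frozen after quitting, nondecreasing before
  expect_equal(pack_years(h2, 32, p10), pack_years(h2, 80, p10))
  py <- pack_years(h, 16:84, PARAMS)
  expect_true(all(diff(py) >= 0))
})

test_that("pack-years match a brute-force year-by-year summation", {
  for (case in list(make_history("male", 1945, init = 18, quit = 47),
                    make_history("female", 1960, init = 22),
                    make_history("male", 1980, init = 25, quit = 31))) {
    for (age in c(30, 46, 60, 80)) {
      yrs <- seq_len(0)
      end <- min(age, ifelse(is.na(case$quit_age), Inf, case$quit_age)) - 1
      if (!is.na(case$initiation_age) && end >= case$initiation_age) {
        yrs <- case$initiation_age:end
      }
      oracle <- sum(vapply(yrs, function(t)
        cigarettes_per_day(case$sex, t, case$birth_year + t, PARAMS) / 20,
        numeric(1)))
      expect_equal(pack_years(case, age, PARAMS), oracle, tolerance = 1e-9)
    }
  }
})

test_that("smoking status and years since quit follow the annual cycle", {
  h <- make_history(init = 20, quit = 50)
  expect_equal(smoking_status(h, 53), "former")
  expect_equal(years_since_quit(h, 53), 3)
  h2 <- make_history(init = 20)
  expect_equal(smoking_status(h2, 53), "current")
  expect_true(is.na(years_since_quit(h2, 53)))
  h3 <- make_history()
  expect_equal(smoking_status(h3, 53), "never")
  expect_true(is.na(years_since_quit(h3, 53)))
  expect_equal(smoking_status(h, c(18, 20, 49, 50)),
               c("never", "current", "current", "former"))
})

test_that("degenerate initiation/cessation parameters behave as forced", {
  p0 <- PARAMS
  p0$smoking$initiation$male$levels <- rep(0, 6)
  p0$smoking$initiation$male$late_ratio <- 0
  set.seed(1)
  h <- sample_smoking_history("male", 1950, p0, n = 500)
  expect_true(all(is.na(h$initiation_age)))
  p1 <- PARAMS
  p1$smoking$cessation$male$rates <- c(1, 1)
  set.seed(2)
  h <- sample_smoking_history("male", 1950, p1, n = 500)
  sm <- !is.na(h$initiation_age)
  # quit in the first tracked smoking year: former by 31, or the year
  # after a late initiation
  expect_true(all(h$quit_age[sm] <= pmax(h$initiation_age[sm], 30) + 1))
  expect_true(all(h$quit_age[sm & h$initiation_age <= 30] == 31))
})

test_that("simulated prevalence reproduces the survey anchors", {
  pop <- simulate_smoking_cohorts(PARAMS, LT, 1917:1971, 4000, seed = 42,
                                  projection = PROJ)
  expect_equal(cross_sectional_prevalence(pop, "male", 1997), 0.62,
               tolerance = 0.035)
  expect_equal(cross_sectional_prevalence(pop, "male", 1991), 0.66,
               tolerance = 0.035)
  expect_equal(cross_sectional_prevalence(pop, "female", 2006), 0.035,
               tolerance = 0.12)
  # all never-smokers -> zero
  p0 <- PARAMS
  for (s in c("male", "female")) {
    p0$smoking$initiation[[s]]$levels <- rep(0, 6)
    p0$smoking$initiation[[s]]$late_ratio <- 0
  }
  pop0 <- simulate_smoking_cohorts(p0, LT, 1940:1950, 200, seed = 1)
  expect_equal(cross_sectional_prevalence(pop0, "male", 1995), 0)
  expect_error(cross_sectional_prevalence(pop0, "male", 1800), "alive")
})

test_that("state-chain expectation agrees with Monte-Carlo prevalence", {
  pop <- simulate_smoking_cohorts(PARAMS, LT, 1917:1971, 3000, seed = 9,
                                  projection = PROJ)
  for (case in list(c("male", 1991), c("male", 2006), c("female", 1997))) {
    sim <- cross_sectional_prevalence(pop, case[1], as.numeric(case[2]))
    chain <- expected_smoking_prevalence(PARAMS, LT, case[1],
                                         as.numeric(case[2]),
                                         projection = PROJ)
    n_eff <- 3000 * 40
    expect_lt(abs(sim - chain), 4 * sqrt(chain * (1 - chain) / n_eff) + 0.002)
  }
})

test_that("prevalence is monotone decreasing in the cessation rate", {
  hi <- PARAMS
  hi$smoking$cessation$male$rates <- c(0.06, 0.08)
  lo_prev <- expected_smoking_prevalence(PARAMS, LT, "male", 2000,
                                         projection = PROJ)
  hi_prev <- expected_smoking_prevalence(hi, LT, "male", 2000,
                                         projection = PROJ)
  expect_lt(hi_prev, lo_prev)
})

test_that("histories before the intervention year are frozen when cessation changes", {
  p2 <- PARAMS
  p2$smoking$cessation_multiplier <- 2    # doubled from 2016
  for (b in c(1950, 1975)) {
    set.seed(cohort_seed <- 1234 + b)
    h1 <- sample_smoking_history("male", b, PARAMS, n = 2000)
    set.seed(cohort_seed)
    h2 <- sample_smoking_history("male", b, p2, n = 2000)
    expect_equal(h1$initiation_age, h2$initiation_age)
    # quits that happened before 2016 are identical
    pre <- !is.na(h1$quit_age) & b + h1$quit_age <= 2016
    expect_equal(h1$quit_age[pre], h2$quit_age[pre])
    # doubled hazard can only advance quitting
    both <- !is.na(h1$quit_age) & !is.na(h2$quit_age)
    expect_true(all(h2$quit_age[both] <= h1$quit_age[both]))
  }
})
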