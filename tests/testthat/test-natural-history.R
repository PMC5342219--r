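test_that("onset hazard reduces to baseline without dose and scales with it", {
  nev <- make_history("male", 1950)
  expect_equal(lung_cancer_hazard(40:80, nev, PARAMS),
               baseline_hazard("male", 40:80, PARAMS))
  p0 <- PARAMS
  p0$natural_history$beta <- c(male = 0, female = 0)
  smoker <- make_history("male", 1950, init = 20)
  expect_equal(lung_cancer_hazard(60, smoker, p0),
               baseline_hazard("male", 60, p0))
  # strictly higher hazard for higher pack-years at positive beta
  light <- flat_cpd_params(10); heavy <- flat_cpd_params(20)
  expect_gt(lung_cancer_hazard(60, smoker, heavy),
            lung_cancer_hazard(60, smoker, light))
  # former smokers' excess decays toward baseline
  former <- make_history("male", 1950, init = 20, quit = 50)
  ex <- lung_cancer_hazard(c(51, 60, 75), former, PARAMS) /
    baseline_hazard("male", c(51, 60, 75), PARAMS) - 1
  expect_true(all(diff(ex) < 0))
})

test_that("tumor sampling respects forced-hazard and cure degeneracies", {
  person <- c(make_history("male", 1950, init = 20), oc_death_age = 80)
  p0 <- PARAMS
  p0$natural_history$baseline$male$mult <- 0
  set.seed(11)
  expect_null(sample_tumor(person, p0))
  # cure fraction one for all stages: no lung cancer death ever
  p1 <- PARAMS
  p1$natural_history$cure <- c(I = 1, II = 1, III = 1, IV = 1)
  p1$natural_history$baseline$male$mult <- 1   # force plenty of tumors
  set.seed(12)
  deaths <- 0
  for (i in 1:200) {
    tm <- sample_tumor(person, p1)
    if (!is.null(tm)) deaths <- deaths + is.finite(tm$lc_death_age_clinical)
  }
  expect_equal(deaths, 0)
  # structural invariants of sampled tumors
  set.seed(13)
  for (i in 1:100) {
    tm <- sample_tumor(person, PARAMS)
    if (is.null(tm)) next
    expect_lte(tm$onset_age, tm$clinical_detection_age)
    expect_lte(tm$clinical_detection_age, tm$lc_death_age_clinical)
    expect_true(tm$stage_clinical %in% c("I", "II", "III", "IV"))
  }
})

test_that("screen detection never worsens the outcome and collapses at zero shift", {
  tumor <- list(onset_age = 60, sojourn = 5, clinical_detection_age = 65,
                stage_clinical = "III", cured_clinical = FALSE,
                lc_death_age_clinical = 67,
                u_stage = 0.4, u_cure = 0.5, e_surv = 1)
  p0 <- PARAMS
  p0$natural_history$stage_shift <- 0
  nh <- p0$natural_history
  t0 <- tumor
  t0$stage_clinical <-
    c("I", "II", "III", "IV")[findInterval(t0$u_stage,
                                           cumsum(nh$stage_clinical),
                                           left.open = TRUE) + 1]
  st <- t0$stage_clinical
  t0$lc_death_age_clinical <- t0$clinical_detection_age +
    t0$e_surv / nh$surv_rate[[st]]
  out0 <- screen_detect_outcome(t0, 62, p0)
  expect_equal(out0$stage_screen, t0$stage_clinical)
  expect_equal(out0$lc_death_age_screen, t0$lc_death_age_clinical)
  # positive shift: stage weakly earlier, death weakly later, over quantiles
  for (u in seq(0.05, 0.95, by = 0.1)) {
    tm <- tumor; tm$u_stage <- u
    cs <- findInterval(u, cumsum(PARAMS$natural_history$stage_clinical),
                       left.open = TRUE) + 1
    out <- screen_detect_outcome(tm, 61, PARAMS)
    ss <- match(out$stage_screen, c("I", "II", "III", "IV"))
    expect_lte(ss, cs)
    if (!out$cured_screen) {
      expect_gte(out$lc_death_age_screen, tm$clinical_detection_age +
                   tm$e_surv / PARAMS$natural_history$surv_rate[[cs]])
    }
  }
  # certain cure at stage I removes the death
  p1 <- PARAMS
  p1$natural_history$cure[["I"]] <- 1
  p1$natural_history$stage_shift <- 1
  out <- screen_detect_outcome(tumor, 61, p1)
  expect_equal(out$stage_screen, "I")
  expect_true(out$cured_screen)
  expect_equal(out$lc_death_age_screen, Inf)
  expect_error(screen_detect_outcome(tumor, 66, PARAMS), "preclinical")
  expect_error(screen_detect_outcome(tumor, 59, PARAMS), "preclinical")
})

test_that("incidental detection fires with the closed-form geometric probability", {
  tumor <- list(onset_age = 60, clinical_detection_age = 70)
  p0 <- PARAMS
  p0$natural_history$incidental_rate <- 0
  expect_true(is.na(incidental_detection(tumor, p0)))
  p1 <- PARAMS
  p1$natural_history$incidental_rate <- 1
  expect_equal(incidental_detection(tumor, p1, u = 0.99), 60)
  p2 <- PARAMS
  p2$natural_history$incidental_rate <- 0.01
  set.seed(21)
  hits <- mean(!is.na(vapply(runif(40000), function(u)
    incidental_detection(tumor, p2, u = u), numeric(1))))
  expect_equal(hits, 1 - 0.99^10, tolerance = 0.12)
})

test_that("other-cause death honours forced rates and band dominance", {
  lt1 <- LT; lt1[, , ] <- 1
  expect_equal(oc_death_ages("male", 1950, Inf, Inf, PARAMS, lt1,
                             runif(10)), rep(15, 10))
  lt0 <- LT; lt0[, , ] <- 0
  expect_equal(oc_death_ages("male", 1950, Inf, Inf, PARAMS, lt0,
                             runif(10)), rep(85, 10))
  # heavier smoking band stochastically dominates in age at death
  set.seed(31)
  n <- 100000
  p20 <- flat_cpd_params(25)   # heavy band for all smokers
  p05 <- flat_cpd_params(5)    # light band
  u <- runif(n)
  d_heavy <- oc_death_ages("male", 1950, rep(20, n), rep(Inf, n), p20, LT, u)
  d_light <- oc_death_ages("male", 1950, rep(20, n), rep(Inf, n), p05, LT, u)
  cdf_h <- ecdf(d_heavy); cdf_l <- ecdf(d_light)
  grid <- 20:84
  expect_true(all(cdf_h(grid) >= cdf_l(grid) - 1e-12))
  expect_gt(mean(d_light), mean(d_heavy))
})

test_that("with screening disabled the engine ignores all policy fields", {
  pol_odd <- screening_policy("odd", 40, 80, 1, 99, adherence = 1)
  p2 <- PARAMS
  p2$natural_history$ct_sensitivity <- 0
  r <- simulate_scenarios(list(baseline = NULL, odd = pol_odd), p2, 400,
                          seed = 5, birth_years = seq(1930, 1990, 10),
                          life_table = LT, projection = PROJ)
  expect_identical(r$baseline$deaths, r$odd$deaths)
  expect_identical(r$baseline$person_years, r$odd$person_years)
})
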