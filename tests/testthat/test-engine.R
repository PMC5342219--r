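# shared mid-size run reused across engine tests (common random numbers)
ENGINE_RES <- simulate_scenarios(
  c(list(baseline = NULL), PARAMS$policies), PARAMS, 800, seed = 101,
  birth_years = seq(1930, 2000, 2), life_table = LT, projection = PROJ)

test_that("identical seeds give identical results; scenarios share persons", {
  r1 <- simulate_scenario(NULL, PARAMS, 300, seed = 17,
                          birth_years = seq(1940, 1980, 10),
                          life_table = LT, projection = PROJ)
  r2 <- simulate_scenario(NULL, PARAMS, 300, seed = 17,
                          birth_years = seq(1940, 1980, 10),
                          life_table = LT, projection = PROJ)
  expect_identical(r1$deaths, r2$deaths)
  expect_identical(r1$person_years, r2$person_years)
  # baseline inside a multi-policy run equals the standalone baseline
  r3 <- simulate_scenarios(list(baseline = NULL, cms = PARAMS$policies$cms),
                           PARAMS, 300, seed = 17,
                           birth_years = seq(1940, 1980, 10),
                           life_table = LT, projection = PROJ)
  expect_identical(r1$deaths, r3$baseline$deaths)
})

test_that("never-smoker death tallies are bit-identical across scenarios", {
  b <- ENGINE_RES$baseline
  for (pn in c("cms", "cng")) {
    expect_identical(b$deaths[, , , "never"],
                     ENGINE_RES[[pn]]$deaths[, , , "never"])
    expect_identical(b$person_years[, , , "never"],
                     ENGINE_RES[[pn]]$person_years[, , , "never"])
  }
})

test_that("screening can only prevent or defer lung cancer deaths", {
  b <- ENGINE_RES$baseline
  for (pn in c("cms", "cng")) {
    r <- ENGINE_RES[[pn]]
    # every (sex, status) stratum and overall
    for (s in c("male", "female")) {
      for (st in c("never", "current", "former")) {
        expect_gte(result_total(b, "deaths", 2016:2050, s, st),
                   result_total(r, "deaths", 2016:2050, s, st))
      }
    }
    expect_gte(life_years_saved(b, r), 0)
  }
  # and across independent seeds at small n
  for (sd in 1:4) {
    rr <- simulate_scenarios(list(baseline = NULL,
                                  cms = PARAMS$policies$cms),
                             PARAMS, 150, seed = sd,
                             birth_years = seq(1935, 1995, 5),
                             life_table = LT, projection = PROJ)
    expect_gte(result_total(rr$baseline, "deaths"),
               result_total(rr$cms, "deaths"))
  }
})

test_that("tallies are conserved and extensive in cohort size", {
  b <- ENGINE_RES$baseline
  # status strata sum to totals; cohort sums equal year sums
  expect_equal(result_total(b, "deaths", b$years, status = "never") +
                 result_total(b, "deaths", b$years, status = "current") +
                 result_total(b, "deaths", b$years, status = "former"),
               result_total(b, "deaths", b$years))
  expect_equal(sum(apply(b$deaths, 1, sum)), sum(apply(b$deaths, 2, sum)))
  # doubling n approximately doubles unscaled tallies
  rA <- simulate_scenario(NULL, PARAMS, 600, seed = 55,
                          birth_years = seq(1940, 1970, 10),
                          life_table = LT, scale = FALSE)
  rB <- simulate_scenario(NULL, PARAMS, 1200, seed = 55,
                          birth_years = seq(1940, 1970, 10),
                          life_table = LT, scale = FALSE)
  dA <- result_total(rA, "deaths", 1975:2050)
  dB <- result_total(rB, "deaths", 1975:2050)
  expect_equal(dB / dA, 2, tolerance = 5 / sqrt(dA))
})

test_that("population scaling is linear and the identity at unit factors", {
  r <- simulate_scenario(NULL, PARAMS, 400, seed = 23,
                         birth_years = seq(1950, 1990, 10),
                         life_table = LT, scale = FALSE)
  # a projection equal to the simulated alive-at-entry counts scales by one
  proj1 <- PROJ
  proj1$counts[, , ] <- 0
  for (bi in seq_along(r$birth_years)) {
    b <- r$birth_years[bi]
    ey <- max(1975, b + 15)
    for (si in 1:2) {
      proj1$counts[as.character(ey), as.character(ey - b), si] <-
        r$alive_entry[bi, si]
    }
  }
  s1 <- scale_results(r, proj1)
  expect_equal(s1$deaths, r$deaths)
  # doubling the projection doubles every tally
  proj2 <- proj1
  proj2$counts <- proj1$counts * 2
  s2 <- scale_results(r, proj2)
  expect_equal(s2$deaths, 2 * r$deaths)
  expect_equal(s2$person_years, 2 * r$person_years)
  # scale-then-sum equals sum-then-scale
  expect_equal(result_total(s2, "deaths", r$years),
               2 * result_total(r, "deaths", r$years))
  expect_error(scale_results(s2, proj1), "already scaled")
})

test_that("engine other-cause deaths match the standalone sampler", {
  # the engine's inlined column pass must equal oc_death_ages draw-for-draw
  n <- 5000; b <- 1950; sex <- "male"
  set.seed(lcscreen:::cohort_seed(77, b, sex))
  u_init <- runif(n); u_quit <- runif(n); u_oc <- runif(n)
  hh <- lcscreen:::sample_histories_core(sex, b, PARAMS, u_init, u_quit)
  ocd <- oc_death_ages(sex, b, hh$init, hh$quit, PARAMS, LT, u_oc)
  cr <- lcscreen:::cohort_run(n, sex, b, PARAMS, LT, list(baseline = NULL),
                              77, 1975, 2050, collect_persons = TRUE)
  expect_identical(cr$persons$ocd, ocd)
  expect_identical(cr$persons$init, hh$init)
})

test_that("zero CT sensitivity reproduces baseline deaths bit-for-bit", {
  p0 <- PARAMS
  p0$natural_history$ct_sensitivity <- 0
  r <- simulate_scenarios(list(baseline = NULL, cms = p0$policies$cms), p0,
                          400, seed = 3, birth_years = seq(1940, 1985, 5),
                          life_table = LT, projection = PROJ)
  expect_identical(r$baseline$deaths, r$cms$deaths)
  expect_gt(result_total(r$cms, "screens", 2016:2050), 0)
})

test_that("outcome ratios match a brute-force recomputation on small tables", {
  expect_equal(mortality_reduction(9257019, 8648191), 0.0658,
               tolerance = 1e-3)
  expect_equal(mortality_reduction(100, 100), 0)
  expect_error(mortality_reduction(0, 10), "zero baseline")
  set.seed(61)
  for (i in 1:20) {
    b <- matrix(rpois(6, 50) + 1, 2)
    s <- matrix(rpois(6, 45), 2)
    expect_equal(mortality_reduction(sum(b), sum(s)),
                 (sum(b) - sum(s)) / sum(b))
  }
  expect_equal(per_death(5798331, 721589), 8.0, tolerance = 0.005)
  expect_equal(per_death(6623148, 742563), 8.9, tolerance = 0.005)
  expect_error(per_death(10, 0), "undefined")
  expect_equal(life_years_saved(10, 10), 0)
})

test_that("screens per death prevented behave and CNG outscreens CMS", {
  b <- ENGINE_RES$baseline
  spd_cms <- screens_per_death_prevented(ENGINE_RES$cms, b)
  spd_cng <- screens_per_death_prevented(ENGINE_RES$cng, b)
  expect_gt(spd_cms, 0)
  expect_gt(result_total(ENGINE_RES$cng, "screens"),
            result_total(ENGINE_RES$cms, "screens"))
  # male ratio higher under the broader Chinese criteria
  expect_gt(screens_per_death_prevented(ENGINE_RES$cng, b, sex = "male"),
            screens_per_death_prevented(ENGINE_RES$cms, b, sex = "male"))
  p0 <- PARAMS$policies$cms; p0$adherence <- 0
  r0 <- simulate_scenarios(list(baseline = NULL, cms = p0), PARAMS, 200,
                           seed = 5, birth_years = seq(1945, 1975, 10),
                           life_table = LT, projection = PROJ)
  expect_equal(result_total(r0$cms, "screens"), 0)
  expect_error(screens_per_death_prevented(r0$cms, r0$baseline),
               "undefined")
})

test_that("simulated histology shares reproduce the period table", {
  h <- ENGINE_RES$baseline$histology
  for (s in c("male", "female")) {
    si <- ifelse(s == "male", 1, 2)
    for (per in colnames(h)) {
      cases <- h[, per, si]
      if (sum(cases) < 2000) next
      share <- cases / sum(cases)
      target <- histology_distribution(s, per, PARAMS)
      expect_true(all(abs(share - target) < 0.02),
                  info = paste(s, per, paste(round(share, 3),
                                             collapse = " ")))
    }
  }
})

test_that("results flatten to an ordered CSV with a seed header", {
  r <- simulate_scenario(PARAMS$policies$cms, PARAMS, 200, seed = 12,
                         birth_years = seq(1945, 1985, 10),
                         life_table = LT, projection = PROJ)
  tab <- result_table(r)
  expect_equal(names(tab), c("year", "sex", "smoking_status", "lc_deaths",
                             "person_years", "screens", "eligible"))
  expect_equal(nrow(tab), length(r$years) * 6)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results_csv(r, f1)
  write_results_csv(r, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1], "seed=12")
})
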