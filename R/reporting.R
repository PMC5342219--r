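# Scenario comparison and reporting: the headline baseline-vs-policy
# comparison under common random numbers, sensitivity sweeps, CSV/JSON
# emission, and the published-results tables used for arithmetic
# consistency checks.

#' Compare screening policies against the no-screening baseline
#'
#' Runs the baseline and each policy under common random numbers, scales to
#' the population projection, and assembles the headline outcomes: deaths
#' prevented, mortality reduction (overall and by sex), life-years saved
#' (and per death prevented), screens, screens per death prevented, deaths
#' by sex and smoking status, per-year eligibility and screen series, and
#' per-birth-cohort mortality reductions.
#'
#' @param params Calibrated parameter bundle.
#' @param n_per_cohort Simulated persons per cohort per sex.
#' @param seed Run seed.
#' @param policies Named list of policies to compare (default the bundled
#'   CMS and CNG rules).
#' @param years Outcome window.
#' @param out_dir Optional directory: writes per-scenario results CSVs, the
#'   strata/series tables and a JSON summary (seed recorded in every file).
#' @return An object of class `lcpm_comparison`.
#' @export
run_compare <- function(params, n_per_cohort = 20000, seed = 1,
                        policies = params$policies, years = 2016:2050,
                        out_dir = NULL) {
  res <- simulate_scenarios(c(list(baseline = NULL), policies), params,
                            n_per_cohort, seed)
  base <- res$baseline
  summary <- list(seed = seed, n_per_cohort = n_per_cohort,
                  years = range(years))
  strata <- list(); series <- list(); cohorts <- list()
  strata$baseline <- strata_table(base, years)
  for (pn in names(policies)) {
    r <- res[[pn]]
    prevented <- result_total(base, "deaths", years) -
      result_total(r, "deaths", years)
    ly <- life_years_saved(base, r, years)
    summary[[pn]] <- list(
      deaths_prevented = prevented,
      mortality_reduction = mortality_reduction(base, r, years),
      mortality_reduction_by_sex = sapply(SEXES, function(s)
        mortality_reduction(base, r, years, sex = s)),
      life_years_saved = ly,
      life_years_per_death = per_death(ly, prevented),
      screens = result_total(r, "screens", years),
      screens_per_death = screens_per_death_prevented(r, base, years),
      screens_per_death_by_sex = sapply(SEXES, function(s)
        screens_per_death_prevented(r, base, years, sex = s)),
      eligible_person_years = result_total(r, "eligible", years))
    strata[[pn]] <- strata_table(r, years)
    series[[pn]] <- year_series(r, base, years)
    cohorts[[pn]] <- cohort_reduction(r, base, years)
  }
  out <- structure(list(summary = summary, strata = strata, series = series,
                        cohorts = cohorts, results = res),
                   class = "lcpm_comparison")
  if (!is.null(out_dir)) write_comparison(out, out_dir)
  out
}

strata_table <- function(result, years) {
  d <- expand.grid(sex = SEXES, smoking_status = SMOKING_STATUSES,
                   stringsAsFactors = FALSE)
  d$lc_deaths <- mapply(function(s, st)
    result_total(result, "deaths", years, sex = s, status = st),
    d$sex, d$smoking_status)
  d
}

year_series <- function(result, baseline, years) {
  yrs <- intersect(years, result$years)
  d <- data.frame(year = yrs)
  for (s in SEXES) {
    d[[paste0("eligible_", s)]] <-
      sapply(yrs, function(y) result_total(result, "eligible", y, s))
    d[[paste0("screens_", s)]] <-
      sapply(yrs, function(y) result_total(result, "screens", y, s))
  }
  bd <- sapply(yrs, function(y) result_total(baseline, "deaths",
                                             min(yrs):y))
  sd <- sapply(yrs, function(y) result_total(result, "deaths", min(yrs):y))
  d$cumulative_mortality_reduction <- (bd - sd) / pmax(bd, 1e-12)
  d
}

cohort_reduction <- function(result, baseline, years) {
  b <- result$birth_years
  yi <- intersect(as.character(years), as.character(result$years))
  out <- data.frame(birth_year = b)
  for (s in SEXES) {
    si <- match(s, SEXES)
    bd <- rowSums(baseline$deaths[, yi, si, , drop = FALSE])
    sd <- rowSums(result$deaths[, yi, si, , drop = FALSE])
    out[[paste0("mortality_reduction_", s)]] <-
      ifelse(bd > 0, (bd - sd) / bd, NA_real_)
  }
  out
}

write_comparison <- function(cmp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (pn in names(cmp$results)) {
    write_results_csv(cmp$results[[pn]],
                      file.path(out_dir, paste0("results_", pn, ".csv")))
  }
  hdr <- sprintf("# lcscreen comparison seed=%d n_per_cohort=%d",
                 cmp$summary$seed, cmp$summary$n_per_cohort)
  wcsv <- function(d, f) {
    con <- file(file.path(out_dir, f), "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  }
  for (pn in names(cmp$strata)) {
    wcsv(cmp$strata[[pn]], paste0("strata_", pn, ".csv"))
  }
  for (pn in names(cmp$series)) {
    wcsv(cmp$series[[pn]], paste0("series_", pn, ".csv"))
    wcsv(cmp$cohorts[[pn]], paste0("cohorts_", pn, ".csv"))
  }
  jsonlite::write_json(cmp$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.lcpm_comparison <- function(x, ...) {
  cat(sprintf("<lcpm_comparison> seed %d, n_per_cohort %d, years %d-%d\n",
              x$summary$seed, x$summary$n_per_cohort,
              x$summary$years[1], x$summary$years[2]))
  for (pn in setdiff(names(x$summary),
                     c("seed", "n_per_cohort", "years"))) {
    s <- x$summary[[pn]]
    cat(sprintf(paste0("  %s: deaths prevented %.0f; MR %.2f%% ",
                       "(m %.2f%%, f %.2f%%); LY saved %.0f (%.1f/death); ",
                       "screens %.0f\n"),
                pn, s$deaths_prevented, 100 * s$mortality_reduction,
                100 * s$mortality_reduction_by_sex[["male"]],
                100 * s$mortality_reduction_by_sex[["female"]],
                s$life_years_saved, s$life_years_per_death, s$screens))
  }
  invisible(x)
}

#' Screening adherence sensitivity sweep
#'
#' Re-runs the comparison at several population adherence levels (per-person
#' always/never attendance) under the same seed, reporting screens and
#' mortality reduction per level.
#'
#' @param params Calibrated bundle.
#' @param levels Adherence fractions.
#' @param policy Policy name in `params$policies` to sweep.
#' @param n_per_cohort,seed,years As in [run_compare()].
#' @return `data.frame` with one row per adherence level.
#' @export
run_adherence_sweep <- function(params, levels = c(1, 0.8, 0.6, 0.4, 0.2),
                                policy = "cms", n_per_cohort = 20000,
                                seed = 1, years = 2016:2050) {
  out <- lapply(levels, function(a) {
    pol <- params$policies[[policy]]
    pol$adherence <- a
    pl <- stats::setNames(list(NULL, pol), c("baseline", policy))
    res <- simulate_scenarios(pl, params, n_per_cohort, seed)
    data.frame(adherence = a,
               screens = result_total(res[[policy]], "screens", years),
               deaths_prevented =
                 result_total(res$baseline, "deaths", years) -
                 result_total(res[[policy]], "deaths", years),
               mortality_reduction =
                 mortality_reduction(res$baseline, res[[policy]], years))
  })
  do.call(rbind, out)
}

#' Smoking cessation sensitivity
#'
#' Doubles/halves the annual cessation probability from the screening start
#' year onwards (histories before that year are untouched by construction)
#' and reports the 2016-2050 mortality reduction per policy per factor.
#'
#' @param params Calibrated bundle.
#' @param factors Multipliers on the cessation rate from 2016.
#' @param n_per_cohort,seed,years As in [run_compare()].
#' @return `data.frame`: factor x policy mortality reductions and screens.
#' @export
run_cessation_sensitivity <- function(params, factors = c(0.5, 1, 2),
                                      n_per_cohort = 20000, seed = 1,
                                      years = 2016:2050) {
  out <- list()
  for (f in factors) {
    p2 <- params
    p2$smoking$cessation_multiplier <- f
    res <- simulate_scenarios(c(list(baseline = NULL), params$policies),
                              p2, n_per_cohort, seed)
    for (pn in names(params$policies)) {
      out[[length(out) + 1]] <- data.frame(
        cessation_factor = f, policy = pn,
        mortality_reduction = mortality_reduction(res$baseline, res[[pn]],
                                                  years),
        screens = result_total(res[[pn]], "screens", years))
    }
  }
  do.call(rbind, out)
}

# ---- published results (arithmetic-consistency inputs) -------------------

#' Published scenario tables
#'
#' The published 2016-2050 lung cancer death counts by scenario, sex and
#' smoking status, total screens and life-years saved, bundled as plain-text
#' data. These are inputs to arithmetic consistency checks of the outcome
#' formulas, not model output.
#'
#' @return List with `strata` (data.frame), `screens` and `life_years`
#'   (named vectors).
#' @export
reported_results <- function() {
  strata <- utils::read.csv(system.file("extdata", "reported_strata.csv",
                                        package = "lcscreen"),
                            stringsAsFactors = FALSE)
  summ <- utils::read.csv(system.file("extdata", "reported_summary.csv",
                                      package = "lcscreen"),
                          stringsAsFactors = FALSE)
  v <- stats::setNames(summ$value, summ$name)
  list(strata = strata,
       screens = v[c("screens_cms", "screens_cng")],
       life_years = v[c("life_years_cms", "life_years_cng")])
}

#' Outcome formulas applied to the published tables
#'
#' Recomputes the headline outcomes from the published death-count strata:
#' total baseline deaths, deaths prevented per policy, sex-specific
#' mortality reductions (percent), life-years saved per death prevented,
#' the relative policy deltas in deaths prevented and screens (percent),
#' and the never-smoker share of baseline deaths (percent). Every number is
#' produced by the package's outcome operations on the published inputs.
#'
#' @return Named list of numbers.
#' @export
reported_outcome_summary <- function() {
  rr <- reported_results()
  tot <- function(scen, sex = NULL, status = NULL) {
    d <- rr$strata
    sel <- d$scenario == scen
    if (!is.null(sex)) sel <- sel & d$sex == sex
    if (!is.null(status)) sel <- sel & d$smoking_status == status
    sum(d$deaths[sel])
  }
  baseline_total <- tot("baseline")
  prevented_cms <- baseline_total - tot("cms")
  prevented_cng <- baseline_total - tot("cng")
  list(
    baseline_deaths = baseline_total,
    deaths_prevented_cms = prevented_cms,
    deaths_prevented_cng = prevented_cng,
    mortality_reduction_male_cms_pct =
      100 * mortality_reduction(tot("baseline", "male"), tot("cms", "male")),
    mortality_reduction_female_cng_pct =
      100 * mortality_reduction(tot("baseline", "female"),
                                tot("cng", "female")),
    life_years_per_death_cms =
      per_death(unname(rr$life_years["life_years_cms"]), prevented_cms),
    life_years_per_death_cng =
      per_death(unname(rr$life_years["life_years_cng"]), prevented_cng),
    deaths_prevented_delta_pct =
      100 * (prevented_cng - prevented_cms) / prevented_cms,
    screens_delta_pct =
      100 * (unname(rr$screens["screens_cng"]) -
               unname(rr$screens["screens_cms"])) /
      unname(rr$screens["screens_cms"]),
    never_smoker_share_pct =
      100 * (tot("baseline", status = "never")) / baseline_total
  )
}
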