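# Screening eligibility and the annual CT process. Eligibility bounds are
# inclusive: age_min <= age <= age_max, pack_years >= min_pack_years, and
# (current smoker OR years_since_quit <= max_years_since_quit). Never-smokers
# are never eligible. Adherence is a per-person always/never-attender draw.

#' Screening eligibility
#'
#' Evaluates the policy's eligibility rule for a person at a given age.
#'
#' @param policy An [screening_policy()].
#' @param person List/row with `sex`, `birth_year`, `initiation_age`,
#'   `quit_age`.
#' @param age Age in years.
#' @param year Calendar year (the age and the person's birth year determine
#'   it; accepted for interface symmetry and checked for consistency when
#'   possible).
#' @param params Parameter bundle (pack-years need the intensity inputs).
#' @return Logical.
#' @export
is_eligible <- function(policy, person, age, year = person$birth_year + age,
                        params = default_parameters()) {
  st <- smoking_status(person, age)
  if (st == "never") return(FALSE)
  if (age < policy$age_min || age > policy$age_max) return(FALSE)
  if (pack_years(person, age, params) < policy$min_pack_years) return(FALSE)
  if (st == "former" &&
      years_since_quit(person, age) > policy$max_years_since_quit) {
    return(FALSE)
  }
  TRUE
}

#' Run the annual screening process for one person
#'
#' Reference (person-at-a-time) implementation of the CT screening loop used
#' by the vectorized engine: one screen per eligible, adherent year while the
#' person is alive and not yet diagnosed; a screen detects the tumor when it
#' is preclinical and the CT sensitivity draw succeeds, after which
#' [screen_detect_outcome()] applies and the person exits screening.
#'
#' @param person List with `sex`, `birth_year`, `initiation_age`, `quit_age`,
#'   `oc_death_age` and optionally `tumor` (from [sample_tumor()]).
#' @param policy An [screening_policy()].
#' @param params Parameter bundle.
#' @return List with `events` (data.frame `year`, `age`, `result`) and the
#'   possibly updated `tumor`.
#' @export
run_screening <- function(person, policy, params) {
  adherent <- stats::runif(1) < policy$adherence
  events <- list()
  tumor <- person$tumor
  diag_age <- Inf
  if (!is.null(tumor)) {
    diag_age <- tumor$clinical_detection_age
    inc <- incidental_detection(tumor, params)
    if (!is.na(inc)) diag_age <- min(diag_age, inc)
  }
  if (adherent) {
    for (year in policy$start_year:policy$end_year) {
      age <- year - person$birth_year
      if (age < ENTRY_AGE || age >= EXIT_AGE) next
      if (age > person$oc_death_age || age >= diag_age) next
      if (!is_eligible(policy, person, age, year, params)) next
      detected <- !is.null(tumor) && age >= tumor$onset_age &&
        age < tumor$clinical_detection_age &&
        stats::runif(1) < params$natural_history$ct_sensitivity
      events[[length(events) + 1]] <- data.frame(
        year = year, age = age,
        result = if (detected) "detected" else "negative",
        stringsAsFactors = FALSE)
      if (detected) {
        tumor <- screen_detect_outcome(tumor, age, params)
        break
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(year = integer(), age = integer(), result = character())
  list(events = ev, tumor = tumor)
}

#' Tally screens from a scenario result
#'
#' @param result An `lcpm_result` from [simulate_scenario()].
#' @param by Grouping columns, a subset of `c("year", "sex")`.
#' @param years Calendar-year window.
#' @return A `data.frame` of screen counts.
#' @export
count_screens <- function(result, by = c("year", "sex"),
                          years = 2016:2050) {
  yi <- intersect(as.character(years), dimnames(result$screens)[[2]])
  d <- as.data.frame.table(result$screens[, yi, , drop = FALSE],
                           stringsAsFactors = FALSE)
  names(d) <- c("birth_year", "year", "sex", "screens")
  d$year <- as.integer(d$year)
  stats::aggregate(screens ~ ., data = d[, c(by, "screens")], FUN = sum)
}

#' Fraction of the adult population screened
#'
#' Divides yearly screen counts by the adult (ages 15-84) population.
#'
#' @param screens Named vector or `data.frame` (`year`, `screens`) of yearly
#'   screen counts in population units (i.e. from a scaled result).
#' @param adult_population Named vector of adult persons per year, e.g. from
#'   [adult_population()].
#' @return Named vector of fractions per year.
#' @export
eligible_fraction <- function(screens, adult_population) {
  if (is.data.frame(screens)) {
    screens <- stats::setNames(screens$screens, screens$year)
  }
  yrs <- names(screens)
  if (!all(yrs %in% names(adult_population))) {
    stop("adult population does not cover all screen years", call. = FALSE)
  }
  out <- screens / adult_population[yrs]
  stopifnot(all(out >= 0))
  out
}
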