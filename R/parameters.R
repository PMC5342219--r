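SEXES <- c("male", "female")
STAGES <- c("I", "II", "III", "IV")
HISTOLOGIES <- c("adenocarcinoma", "squamous", "small_cell", "large_other")
HIST_PERIODS <- c("1991-1995", "1996-2000", "2001-2005")
SMOKING_STATUSES <- c("never", "current", "former")

check_sex <- function(sex) {
  if (!all(sex %in% SEXES)) {
    stop("invalid sex label: ", paste(setdiff(sex, SEXES), collapse = ", "),
         " (expected 'male' or 'female')", call. = FALSE)
  }
  sex
}

#' Default model parameters
#'
#' Builds the full parameter bundle for the China lung cancer screening
#' microsimulation: the published smoking inputs (prevalence calibration
#' anchors, cessation rates, cigarettes-per-day profiles), the lung cancer
#' natural-history surrogate (Weibull baseline hazard, pack-year excess-risk
#' dose model, preclinical sojourn, stage distribution, stage-specific cure
#' and survival), synthetic other-cause mortality inputs, the two screening
#' policies (CMS and the Chinese national guideline), and the calibration
#' target table.
#'
#' Free parameters (smoking initiation curve levels, per-sex baseline hazard
#' multipliers, and the screen stage-shift) default to values produced by
#' [calibrate_lcpm()] run against the default targets, so that the bundle is
#' usable out of the box; re-running the staged calibration reproduces them.
#'
#' @return An object of class `lcpm_params` (a validated nested list with
#'   components `smoking`, `natural_history`, `other_cause`, `policies`,
#'   `projection`, and `targets`).
#' @seealso [cigarettes_per_day()], [histology_distribution()],
#'   [load_parameters()], [calibrate_lcpm()]
#' @export
default_parameters <- function() {
  p <- list(
    smoking = list(
      cessation = list(
        male = list(
          track_from = 30,
          age_breaks = c(30, 66),         # rate band lower edges
          rates = c(0.02, 0.03)           # 30-65: 0.02, >65: 0.03
        ),
        female = list(
          track_from = 35,
          age_breaks = 35,
          rates = 0.02                    # age >35 band
        )
      ),
      cessation_multiplier = 1,
      cessation_multiplier_from = 2016,
      # male cigarettes/day by age, survey year 2006 (urban/rural average)
      cpd_age_anchors = list(age = c(37, 46, 55, 66, 74),
                             cpd = c(16.56, 17.44, 15.76, 13.2, 12.2)),
      # calendar trend in mean cigarettes/day
      cpd_year_anchors = list(
        male = list(year = c(1980, 1996, 2006, 2012),
                    cpd = c(15.5, 18.2, 21.8, 22.3)),
        female = list(year = c(1998, 2003), cpd = c(12.3, 15.8))
      ),
      cpd_year_range = c(1980, 2012),     # hold flat outside observed years
      initiation = list(
        male = list(
          group_breaks = c(1928, 1936, 1944, 1952, 1960, 1970),
          levels = c(1, 1, 1, 1, 0.804339, 0.792641),
          late_ratio = 0.85,
          midpoint = 21, slope = 0.45
        ),
        female = list(
          group_breaks = c(1928, 1936, 1944, 1952, 1960, 1970),
          levels = c(0.00014, 0.481325, 0.022531, 0.002263, 0.070389,
                     0.032725),
          late_ratio = 0.85,
          midpoint = 23, slope = 0.35
        )
      )
    ),
    natural_history = list(
      baseline = list(
        male   = list(shape = 6, scale = 110, mult = 0.04156774),
        female = list(shape = 6, scale = 110, mult = 0.15740858)
      ),
      beta = c(male = 2.0, female = 0.9),  # excess-risk coefficient per pack-year^eta
      eta = 1,
      quit_decay = 0.03,                   # per-year decay of excess risk after quit
      sojourn_mean = 4,                    # mean preclinical years (support >= 1)
      incidental_rate = 0.02,              # annual non-screening imaging detection
      stage_clinical = c(I = 0.15, II = 0.10, III = 0.25, IV = 0.50),
      stage_shift = 0.408379,              # screen-detection shift toward stage I
      cure = c(I = 0.55, II = 0.35, III = 0.12, IV = 0.02),
      surv_rate = c(I = 0.15, II = 0.25, III = 0.50, IV = 1.00),
      ct_sensitivity = 0.85,
      histology = list(
        male = list(
          "1991-1995" = c(adenocarcinoma = 0.30, squamous = 0.54,
                          small_cell = 0.13, large_other = 0.03),
          "1996-2000" = c(adenocarcinoma = 0.31, squamous = 0.52,
                          small_cell = 0.13, large_other = 0.04),
          "2001-2005" = c(adenocarcinoma = 0.33, squamous = 0.52,
                          small_cell = 0.10, large_other = 0.05)
        ),
        female = list(
          "1991-1995" = c(adenocarcinoma = 0.51, squamous = 0.32,
                          small_cell = 0.15, large_other = 0.02),
          "1996-2000" = c(adenocarcinoma = 0.55, squamous = 0.32,
                          small_cell = 0.10, large_other = 0.03),
          "2001-2005" = c(adenocarcinoma = 0.54, squamous = 0.34,
                          small_cell = 0.08, large_other = 0.04)
        )
      )
    ),
    other_cause = list(
      makeham_a = c(male = 8e-4, female = 6e-4),
      gompertz_b = c(male = 4.5e-5, female = 2.5e-5),
      gompertz_theta = c(male = 0.088, female = 0.088),
      band_multipliers = c(never = 1.0, light = 1.5, heavy = 2.0),
      heavy_cpd = 20                       # cigarettes/day cutoff for heavy band
    ),
    policies = list(
      cms = screening_policy("cms", age_min = 55, age_max = 77,
                             min_pack_years = 30, max_years_since_quit = 15),
      cng = screening_policy("cng", age_min = 50, age_max = 74,
                             min_pack_years = 20, max_years_since_quit = 5)
    ),
    projection = list(
      base_cohort_size = 2.1e7,   # peak persons entering at age 15 per year
      rise_mid = 1945, rise_slope = 0.06,
      decline_mid = 2010, decline_slope = 0.08, decline_floor = 0.55,
      male_fraction = 0.512
    ),
    targets = default_targets()
  )
  validate_parameters(canonicalize_parameters(p))
}

#' Screening policy constructor
#'
#' Declarative eligibility rule for an annual CT screening programme: an age
#' window, a minimum cumulative pack-year exposure, and a maximum number of
#' years since quitting for former smokers (current smokers always satisfy the
#' quit-window condition; never-smokers are never eligible). All bounds are
#' inclusive.
#'
#' @param name Policy label, e.g. `"cms"` or `"cng"`.
#' @param age_min,age_max Inclusive age window in years.
#' @param min_pack_years Minimum pack-years smoked.
#' @param max_years_since_quit Maximum years since quitting for former smokers.
#' @param interval Years between screens (annual = 1; the only supported value).
#' @param start_year,end_year Calendar years the programme is active.
#' @param adherence Fraction of the eligible population that attends
#'   (modelled per person: an always/never attender draw at first eligibility).
#' @return An object of class `lcpm_policy`.
#' @export
screening_policy <- function(name, age_min, age_max, min_pack_years,
                             max_years_since_quit, interval = 1,
                             start_year = 2016, end_year = 2050,
                             adherence = 1) {
  stopifnot(age_min <= age_max, min_pack_years >= 0,
            adherence >= 0, adherence <= 1, interval == 1,
            start_year <= end_year)
  structure(list(name = as.character(name), age_min = age_min,
                 age_max = age_max, min_pack_years = min_pack_years,
                 max_years_since_quit = max_years_since_quit,
                 interval = interval, start_year = start_year,
                 end_year = end_year, adherence = adherence),
            class = "lcpm_policy")
}

#' @export
print.lcpm_policy <- function(x, ...) {
  cat(sprintf(
    "<screening policy '%s'> ages %d-%d, >=%g pack-years, <=%g years since quit,\n  annual %d-%d, adherence %.0f%%\n",
    x$name, x$age_min, x$age_max, x$min_pack_years, x$max_years_since_quit,
    x$start_year, x$end_year, 100 * x$adherence))
  invisible(x)
}

#' Default calibration target table
#'
#' The published calibration targets: CHNS current-smoking prevalence for ages
#' 35-74 at six survey years per sex, GLOBOCAN 2012 lung cancer death counts
#' per sex, the histology shares by sex and diagnosis period, and the NLST
#' screening-effectiveness anchor (percent mortality reduction in the
#' CMS-eligible subgroup of the 1960 birth cohort).
#'
#' @return A `data.frame` with columns `name`, `kind`, `sex`, `year`,
#'   `period`, `subtype`, `value`, `weight`, `rel_tolerance`.
#' @export
default_targets <- function() {
  prev_years <- c(1991, 1993, 1997, 2000, 2004, 2006)
  prev_male <- c(0.66, 0.65, 0.62, 0.58, 0.59, 0.57)
  prev_female <- c(0.062, 0.061, 0.055, 0.053, 0.041, 0.035)
  prev <- data.frame(
    name = paste0("prevalence_", rep(SEXES, each = 6), "_",
                  rep(prev_years, 2)),
    kind = "prevalence",
    sex = rep(SEXES, each = 6),
    year = rep(prev_years, 2),
    period = NA_character_, subtype = NA_character_,
    value = c(prev_male, prev_female),
    weight = 1, rel_tolerance = 0.05,
    stringsAsFactors = FALSE
  )
  mort <- data.frame(
    name = c("lc_deaths_2012_male", "lc_deaths_2012_female"),
    kind = "mortality_count", sex = SEXES, year = 2012,
    period = NA_character_, subtype = NA_character_,
    value = c(422000, 175000), weight = 1, rel_tolerance = 0.02,
    stringsAsFactors = FALSE
  )
  hist_vals <- list(
    male = rbind("1991-1995" = c(0.30, 0.54, 0.13, 0.03),
                 "1996-2000" = c(0.31, 0.52, 0.13, 0.04),
                 "2001-2005" = c(0.33, 0.52, 0.10, 0.05)),
    female = rbind("1991-1995" = c(0.51, 0.32, 0.15, 0.02),
                   "1996-2000" = c(0.55, 0.32, 0.10, 0.03),
                   "2001-2005" = c(0.54, 0.34, 0.08, 0.04))
  )
  hist <- do.call(rbind, lapply(SEXES, function(s) {
    m <- hist_vals[[s]]
    data.frame(
      name = paste0("histology_", s, "_", rep(rownames(m), each = 4), "_",
                    rep(HISTOLOGIES, 3)),
      kind = "histology_share", sex = s, year = NA_real_,
      period = rep(rownames(m), each = 4),
      subtype = rep(HISTOLOGIES, 3),
      value = as.vector(t(m)), weight = 1, rel_tolerance = 0.05,
      stringsAsFactors = FALSE
    )
  }))
  nlst <- data.frame(
    name = "nlst_anchor_1960_cohort", kind = "screening_effectiveness",
    sex = NA_character_, year = 1960, period = NA_character_,
    subtype = NA_character_, value = 19.7, weight = 1, rel_tolerance = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- rbind(prev, mort, hist, nlst)
  rownames(out) <- NULL
  out
}

#' Annual smoking cessation probability
#'
#' Cessation is tracked from age 30 for males and age 35 for females and is
#' zero below those ages. An optional multiplier (used by the cessation
#' sensitivity analysis) applies only from `cessation_multiplier_from`
#' onwards, so histories before that calendar year are unaffected.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Integer age(s).
#' @param params Parameter bundle.
#' @param year Calendar year(s) (only used for the multiplier switch-on).
#' @return Vector of annual quit probabilities.
#' @export
cessation_rate <- function(sex, age, params, year = NULL) {
  check_sex(sex)
  cs <- params$smoking$cessation[[sex]]
  r <- rep(0, length(age))
  for (i in seq_along(cs$age_breaks)) {
    hi <- if (i < length(cs$age_breaks)) cs$age_breaks[i + 1] - 1 else Inf
    sel <- age >= cs$age_breaks[i] & age <= hi
    r[sel] <- cs$rates[i]
  }
  if (!is.null(year) && params$smoking$cessation_multiplier != 1) {
    on <- year >= params$smoking$cessation_multiplier_from
    r <- ifelse(on, pmin(1, r * params$smoking$cessation_multiplier), r)
  }
  r
}

cpd_trend <- function(sex, year, params) {
  sm <- params$smoking
  y <- pmin(pmax(year, sm$cpd_year_range[1]), sm$cpd_year_range[2])
  ng <- sm$cpd_year_anchors$male
  ng_at <- function(yy) stats::approx(ng$year, ng$cpd, xout = yy, rule = 2)$y
  if (sex == "male") return(ng_at(y))
  qa <- sm$cpd_year_anchors$female
  out <- numeric(length(y))
  lo <- y < qa$year[1]; hi <- y > qa$year[length(qa$year)]
  mid <- !lo & !hi
  if (any(mid)) out[mid] <- stats::approx(qa$year, qa$cpd, xout = y[mid])$y
  # outside the female anchors, carry the male calendar shape
  if (any(lo)) out[lo] <- qa$cpd[1] * ng_at(y[lo]) / ng_at(qa$year[1])
  if (any(hi)) out[hi] <- qa$cpd[length(qa$cpd)] *
      ng_at(y[hi]) / ng_at(qa$year[length(qa$year)])
  out
}

#' Cigarettes smoked per day by current smokers
#'
#' Combines the male age profile observed in 2006 with the calendar-year trend
#' in mean cigarettes per day, multiplicatively:
#' `cpd(male, age, year) = age_profile(age) * trend_male(year) / trend_male(2006)`,
#' so the 2006 age anchors are returned exactly. The female age shape reuses
#' the male profile normalised to a mean of one over ages 35-74 and is scaled
#' by the female calendar trend, so the female anchors are matched as
#' age-averaged means. Between anchors values are linearly interpolated;
#' outside the anchor range the nearest anchor is carried; calendar years are
#' clamped to the observed 1980-2012 window.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age(s) in years, `>= 15`.
#' @param year Calendar year(s).
#' @param params Parameter bundle (default [default_parameters()] smoking block
#'   is required; pass the full bundle).
#' @return Cigarettes per day (nonnegative numeric).
#' @export
cigarettes_per_day <- function(sex, age, year, params) {
  check_sex(sex)
  stopifnot(all(age >= 15))
  aa <- params$smoking$cpd_age_anchors
  prof <- stats::approx(aa$age, aa$cpd, xout = age, rule = 2)$y
  if (sex == "male") {
    norm <- cpd_trend("male", 2006, params)
    return(prof * cpd_trend("male", year, params) / norm)
  }
  rel <- prof / mean(stats::approx(aa$age, aa$cpd, xout = 35:74, rule = 2)$y)
  rel * cpd_trend("female", year, params)
}

period_of_year <- function(year) {
  p <- rep(HIST_PERIODS[3], length(year))
  p[year <= 2000] <- HIST_PERIODS[2]
  p[year <= 1995] <- HIST_PERIODS[1]
  p
}

#' Histology distribution of lung cancer cases
#'
#' Probability over the four histological subtypes (adenocarcinoma, squamous
#' cell, small cell, large cell/other) by sex and diagnosis period. Years
#' before 1991 use the earliest period; years at or after 2001 use the latest.
#' The printed percentages are renormalised to sum exactly to one.
#'
#' @param sex `"male"` or `"female"`.
#' @param period A period label (`"1991-1995"`, `"1996-2000"`, `"2001-2005"`)
#'   or a calendar year, which is mapped to its period.
#' @param params Parameter bundle.
#' @return Named probability vector over the four subtypes, summing to 1.
#' @export
histology_distribution <- function(sex, period, params) {
  check_sex(sex)
  if (is.numeric(period)) period <- period_of_year(period)
  if (!period %in% HIST_PERIODS) {
    stop("unknown histology period: ", period, call. = FALSE)
  }
  v <- params$natural_history$histology[[sex]][[period]]
  v / sum(v)
}

#' Cumulative smoking initiation curve
#'
#' Probability that a person of the given sex and birth cohort has initiated
#' smoking by each age: a logistic curve in age with a cohort-group level
#' (asymptote), shared midpoint and slope. The level for cohorts born after
#' the last group break is `late_ratio` times the last fitted level.
#'
#' @param sex `"male"` or `"female"`.
#' @param birth_year Birth cohort.
#' @param age Vector of ages.
#' @param params Parameter bundle.
#' @return Vector of cumulative initiation probabilities.
#' @export
initiation_cdf <- function(sex, birth_year, age, params) {
  check_sex(sex)
  ip <- params$smoking$initiation[[sex]]
  lv <- c(ip$levels, ip$late_ratio * ip$levels[length(ip$levels)])
  g <- findInterval(birth_year, ip$group_breaks) + 1
  lv[g] * stats::plogis(ip$slope * (age - ip$midpoint))
}

# ---- bundle I/O and validation ------------------------------------------

# rebuild proper leaf types from a plain (e.g. JSON-decoded) nested list
canonicalize_parameters <- function(p) {
  num <- function(x) {
    y <- unlist(x)
    storage.mode(y) <- "double"
    y
  }
  for (s in SEXES) {
    cs <- p$smoking$cessation[[s]]
    cs$track_from <- as.numeric(cs$track_from)
    cs$age_breaks <- num(cs$age_breaks); cs$rates <- num(cs$rates)
    p$smoking$cessation[[s]] <- cs
    ip <- p$smoking$initiation[[s]]
    ip$group_breaks <- num(ip$group_breaks); ip$levels <- num(ip$levels)
    ip$late_ratio <- as.numeric(ip$late_ratio)
    ip$midpoint <- as.numeric(ip$midpoint); ip$slope <- as.numeric(ip$slope)
    p$smoking$initiation[[s]] <- ip
    b <- p$natural_history$baseline[[s]]
    p$natural_history$baseline[[s]] <-
      list(shape = as.numeric(b$shape), scale = as.numeric(b$scale),
           mult = as.numeric(b$mult))
    for (per in HIST_PERIODS) {
      v <- num(p$natural_history$histology[[s]][[per]])
      names(v) <- HISTOLOGIES
      p$natural_history$histology[[s]][[per]] <- v
    }
  }
  p$smoking$cpd_age_anchors <- lapply(p$smoking$cpd_age_anchors, num)
  p$smoking$cpd_year_anchors <- lapply(p$smoking$cpd_year_anchors,
                                       function(a) lapply(a, num))
  p$smoking$cpd_year_range <- num(p$smoking$cpd_year_range)
  p$smoking$cessation_multiplier <- as.numeric(p$smoking$cessation_multiplier)
  p$smoking$cessation_multiplier_from <-
    as.numeric(p$smoking$cessation_multiplier_from)
  nh <- p$natural_history
  for (f in c("beta")) { v <- num(nh[[f]]); names(v) <- SEXES; nh[[f]] <- v }
  for (f in c("stage_clinical", "cure", "surv_rate")) {
    v <- num(nh[[f]]); names(v) <- STAGES; nh[[f]] <- v
  }
  for (f in c("eta", "quit_decay", "sojourn_mean", "incidental_rate",
              "stage_shift", "ct_sensitivity")) {
    nh[[f]] <- as.numeric(nh[[f]])
  }
  p$natural_history <- nh
  oc <- p$other_cause
  for (f in c("makeham_a", "gompertz_b", "gompertz_theta")) {
    v <- num(oc[[f]]); names(v) <- SEXES; oc[[f]] <- v
  }
  v <- num(oc$band_multipliers); names(v) <- c("never", "light", "heavy")
  oc$band_multipliers <- v
  oc$heavy_cpd <- as.numeric(oc$heavy_cpd)
  p$other_cause <- oc
  p$policies <- lapply(p$policies, function(pol) {
    do.call(screening_policy, lapply(unclass(pol), function(x)
      if (is.character(x)) x else as.numeric(x)))
  })
  p$projection <- lapply(p$projection, as.numeric)
  tg <- as.data.frame(p$targets, stringsAsFactors = FALSE)
  for (f in c("year", "value", "weight", "rel_tolerance")) {
    tg[[f]] <- as.numeric(tg[[f]])
  }
  for (f in c("name", "kind", "sex", "period", "subtype")) {
    tg[[f]] <- as.character(tg[[f]])
  }
  p$targets <- tg
  structure(p, class = "lcpm_params")
}

#' Validate a parameter bundle
#'
#' Checks structural completeness and the domain invariants: probabilities in
#' `[0, 1]`, nonnegative cigarettes-per-day and pack-year thresholds, stage
#' distributions summing to one, cure fractions nonincreasing and survival
#' rates nondecreasing with stage (which guarantees the stage-shift benefit is
#' never harmful), and the cessation tracking ages. Errors name the offending
#' field.
#'
#' @param params Parameter bundle (possibly freshly loaded from file).
#' @return The validated bundle, invisibly classed as `lcpm_params`.
#' @export
validate_parameters <- function(params) {
  need <- function(cond, field, what) {
    if (!isTRUE(cond)) stop("invalid parameters: ", field, " ", what,
                            call. = FALSE)
  }
  for (top in c("smoking", "natural_history", "other_cause", "policies",
                "projection", "targets")) {
    need(!is.null(params[[top]]), top, "is missing")
  }
  sm <- params$smoking
  need(!is.null(sm$cessation), "cessation_schedule", "is missing")
  for (s in SEXES) {
    cs <- sm$cessation[[s]]
    need(!is.null(cs), "cessation_schedule", paste("is missing for", s))
    need(all(cs$rates >= 0 & cs$rates <= 1), "cessation_schedule",
         "rates must be probabilities in [0,1]")
    need(min(cs$age_breaks) >= cs$track_from, "cessation_schedule",
         "bands must start at the tracking age")
    ip <- sm$initiation[[s]]
    need(!is.null(ip), "initiation_params", paste("is missing for", s))
    need(all(ip$levels >= 0 & ip$levels <= 1), "initiation_params",
         "levels must lie in [0,1]")
    need(ip$slope > 0, "initiation_params", "slope must be positive")
  }
  need(sm$cessation$male$track_from == 30 || sm$cessation$male$track_from >= 15,
       "cessation_schedule", "male tracking age out of range")
  need(all(unlist(sm$cpd_age_anchors$cpd) >= 0), "cpd_age_profile",
       "cigarettes/day must be nonnegative")
  nh <- params$natural_history
  need(abs(sum(nh$stage_clinical) - 1) < 1e-8, "stage_distribution_clinical",
       "must sum to 1")
  need(all(nh$cure >= 0 & nh$cure <= 1), "survival_params",
       "cure fractions must lie in [0,1]")
  need(!is.unsorted(rev(nh$cure)), "survival_params",
       "cure fractions must be nonincreasing with stage")
  need(!is.unsorted(nh$surv_rate), "survival_params",
       "survival rates must be nondecreasing with stage")
  need(nh$quit_decay >= 0, "quit_decay", "must be nonnegative")
  need(all(nh$beta >= 0), "smoking_effect_params", "beta must be nonnegative")
  need(nh$stage_shift >= 0 && nh$stage_shift <= 1, "stage_distribution_screen",
       "stage_shift must lie in [0,1]")
  need(nh$ct_sensitivity >= 0 && nh$ct_sensitivity <= 1, "ct_sensitivity",
       "must lie in [0,1]")
  need(nh$sojourn_mean >= 1, "sojourn_mean", "must be at least one year")
  need(nh$incidental_rate >= 0 && nh$incidental_rate <= 1,
       "incidental_detection_rate", "must lie in [0,1]")
  for (s in SEXES) {
    for (per in HIST_PERIODS) {
      v <- nh$histology[[s]][[per]]
      need(!is.null(v) && length(v) == 4, "histology",
           paste("missing for", s, per))
      need(abs(sum(v) - 1) <= 0.02, "histology",
           paste("row", s, per, "must sum to 1 within 0.02"))
    }
  }
  for (pol in params$policies) {
    need(inherits(pol, "lcpm_policy"), "policies",
         "entries must be lcpm_policy objects")
  }
  tg <- params$targets
  need(is.data.frame(tg) && all(c("name", "kind", "value", "weight") %in%
                                  names(tg)), "targets", "table malformed")
  need(all(tg$value >= 0), "targets", "values must be nonnegative")
  need(all(tg$weight > 0), "targets", "weights must be positive")
  invisible(params)
}

#' @export
print.lcpm_params <- function(x, ...) {
  cat("<lcpm_params> China lung cancer screening model parameter bundle\n")
  cat(sprintf("  policies: %s\n", paste(names(x$policies), collapse = ", ")))
  cat(sprintf("  calibration targets: %d rows\n", nrow(x$targets)))
  cat(sprintf("  baseline hazard mult (m/f): %.4g / %.4g; stage shift: %.3f\n",
              x$natural_history$baseline$male$mult,
              x$natural_history$baseline$female$mult,
              x$natural_history$stage_shift))
  invisible(x)
}

#' Save / load a parameter bundle
#'
#' Parameters round-trip through JSON at full double precision:
#' `load_parameters(save_parameters(b, path))` reproduces `b` exactly.
#' Loading validates the bundle and reports the offending field on schema
#' violations.
#'
#' @param params Parameter bundle.
#' @param path File path (JSON).
#' @return `load_parameters` returns the validated `lcpm_params` bundle;
#'   `save_parameters` returns `path` invisibly.
#' @export
save_parameters <- function(params, path) {
  stopifnot(inherits(params, "lcpm_params"))
  jsonlite::write_json(unclass_policies(params), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_policies <- function(params) {
  p <- unclass(params)
  p$policies <- lapply(p$policies, unclass)
  p
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_parameters(canonicalize_parameters(raw))
}
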