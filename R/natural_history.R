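# Lung cancer natural history: a parametric surrogate with explicit
# detection channels. Annual onset hazard is a Weibull never-smoker baseline
# times a proportional excess term in pack-years that decays exponentially
# after quitting. A tumor then has a preclinical sojourn to symptomatic
# (clinical) detection, a stage drawn at detection, a stage-specific cure
# fraction and exponential residual survival. Screen detection redraws the
# stage from a distribution shifted toward stage I using the SAME quantile
# draw, and anchors the survival clock at the clinical detection age, so
# earlier diagnosis alone never changes a death age (no lead-time bias) and
# screening can only delay or remove a lung cancer death.

#' Annual lung cancer onset hazard
#'
#' `hazard = baseline(sex, age) * (1 + beta * pack_years^eta * decay)` with
#' `decay = exp(-quit_decay * years_since_quit)` for former smokers and 1
#' otherwise; never-smokers are at exactly the baseline. The baseline is a
#' Weibull hazard in age, `mult * (shape/scale) * (age/scale)^(shape-1)`,
#' per sex, with `mult` set by calibration to the 2012 mortality target.
#'
#' @param age Age(s) in years.
#' @param history A history list (`sex`, `birth_year`, `initiation_age`,
#'   `quit_age`).
#' @param params Parameter bundle.
#' @return Annual hazard(s) of lung cancer onset.
#' @export
lung_cancer_hazard <- function(age, history, params) {
  nh <- params$natural_history
  py <- pack_years(history, age, params)
  st <- smoking_status(history, age)
  ysq <- years_since_quit(history, age)
  decay <- ifelse(st == "former", exp(-nh$quit_decay * ysq), 1)
  baseline_hazard(history$sex, age, params) *
    (1 + nh$beta[[history$sex]] * py^nh$eta * decay)
}

#' @rdname lung_cancer_hazard
#' @param sex `"male"` or `"female"`.
#' @export
baseline_hazard <- function(sex, age, params) {
  check_sex(sex)
  b <- params$natural_history$baseline[[sex]]
  b$mult * (b$shape / b$scale) * (age / b$scale)^(b$shape - 1)
}

# first index (stage) whose cumulative probability exceeds u; vectorized in u
stage_quantile <- function(probs, u) {
  findInterval(u, cumsum(probs), left.open = TRUE) + 1L
}

# stage distribution at screen detection: mass moved toward stage I by the
# stage-shift parameter; shift 0 reproduces the clinical distribution
screen_stage_probs <- function(nh) {
  p <- (1 - nh$stage_shift) * nh$stage_clinical
  p[1] <- p[1] + nh$stage_shift
  p
}

#' Sample a latent tumor for one person
#'
#' Onset is drawn from the annual hazard (inverse-CDF on an exponential
#' clock); tumors arising at age 85 or beyond, or entirely outside the
#' simulated life, are absent. The tumor carries its detection-channel
#' quantile draws (`u_stage`, `u_cure`, `e_surv`) so that
#' [screen_detect_outcome()] is coupled to the clinical counterfactual.
#'
#' @param person List/row with `sex`, `birth_year`, `initiation_age`,
#'   `quit_age`, `oc_death_age`.
#' @param params Parameter bundle.
#' @return A `Tumor` list (onset_age, histology, sojourn,
#'   clinical_detection_age, stage_clinical, cured_clinical,
#'   lc_death_age_clinical, u_stage, u_cure, e_surv) or `NULL` when no tumor
#'   arises before age 85 or other-cause death.
#' @export
sample_tumor <- function(person, params) {
  stopifnot(!is.null(person$oc_death_age))
  nh <- params$natural_history
  h <- list(sex = person$sex, birth_year = person$birth_year,
            initiation_age = person$initiation_age,
            quit_age = person$quit_age)
  haz <- lung_cancer_hazard(AGES, h, params)
  e <- stats::rexp(1)
  idx <- findInterval(e, cumsum(haz), left.open = TRUE) + 1L
  draws <- list(u_soj = stats::runif(1), u_hist = stats::runif(1),
                u_stage = stats::runif(1), u_cure = stats::runif(1),
                e_surv = stats::rexp(1))
  if (idx > length(AGES)) return(NULL)
  onset <- AGES[idx]
  if (onset >= min(EXIT_AGE, person$oc_death_age)) return(NULL)
  sojourn <- 1 + stats::qgeom(draws$u_soj, 1 / nh$sojourn_mean)
  clin_age <- onset + sojourn
  hist_p <- histology_distribution(person$sex,
                                   period_of_year(person$birth_year + clin_age),
                                   params)
  stage_c <- stage_quantile(nh$stage_clinical, draws$u_stage)
  cured_c <- unname(draws$u_cure < nh$cure[stage_c])
  lc_death <- if (cured_c) Inf else
    unname(clin_age + draws$e_surv / nh$surv_rate[stage_c])
  list(onset_age = onset,
       histology = HISTOLOGIES[stage_quantile(hist_p, draws$u_hist)],
       sojourn = sojourn,
       clinical_detection_age = clin_age,
       stage_clinical = STAGES[stage_c],
       cured_clinical = cured_c,
       lc_death_age_clinical = lc_death,
       u_stage = draws$u_stage, u_cure = draws$u_cure, e_surv = draws$e_surv)
}

#' Outcome of a screen detection
#'
#' The stage is redrawn from the screen-detection distribution at the same
#' quantile as the clinical stage (so it is never later), the cure fraction
#' of the (weakly earlier) stage is applied to the same cure draw, and
#' residual survival uses the same exponential draw with the new stage's
#' rate, anchored at the clinical detection age. Consequently the returned
#' lung cancer death age is never earlier than the clinical one.
#'
#' @param tumor A tumor from [sample_tumor()].
#' @param detect_age Age at the detecting screen; must lie in
#'   `[onset_age, clinical_detection_age)`.
#' @param params Parameter bundle.
#' @return The tumor updated with `stage_screen`, `cured_screen`,
#'   `lc_death_age_screen`, `screen_detection_age`.
#' @export
screen_detect_outcome <- function(tumor, detect_age, params) {
  if (detect_age < tumor$onset_age ||
      detect_age >= tumor$clinical_detection_age) {
    stop("screen detection age outside the preclinical window", call. = FALSE)
  }
  nh <- params$natural_history
  stage_s <- stage_quantile(screen_stage_probs(nh), tumor$u_stage)
  cured_s <- unname(tumor$u_cure < nh$cure[stage_s])
  tumor$stage_screen <- STAGES[stage_s]
  tumor$cured_screen <- cured_s
  tumor$screen_detection_age <- detect_age
  tumor$lc_death_age_screen <- if (cured_s) Inf else
    unname(tumor$clinical_detection_age + tumor$e_surv / nh$surv_rate[stage_s])
  tumor
}

#' Incidental (non-screening) imaging detection
#'
#' Each preclinical year the tumor may be found on imaging done for
#' unrelated reasons, with the annual `incidental_detection_rate`. An
#' incidental finding is handled through the clinical route (clinical stage,
#' survival anchored at the clinical detection age), so it changes the
#' diagnosis age - ending screening eligibility - but not the death age.
#'
#' @param tumor A tumor from [sample_tumor()].
#' @param params Parameter bundle.
#' @param u Optional uniform draw.
#' @return Detection age (integer) or `NA` if it never fires before clinical
#'   detection.
#' @export
incidental_detection <- function(tumor, params, u = stats::runif(1)) {
  rate <- params$natural_history$incidental_rate
  if (rate <= 0) return(NA_real_)
  delay <- stats::qgeom(u, rate)
  age <- tumor$onset_age + delay
  if (age < tumor$clinical_detection_age) age else NA_real_
}

#' Other-cause death age
#'
#' Sequential annual Bernoulli draws from the life table, with the
#' smoking-intensity band following the person's history: never-smokers use
#' the never band; current smokers the band of their current cigarettes/day;
#' former smokers keep the band held at quitting. Implemented as an
#' inverse-CDF on one uniform per person, which is distributionally
#' identical and keeps scenario comparisons coupled. Persons surviving age
#' 84 exit at the cap and are returned as 85.
#'
#' @param sex `"male"` or `"female"`.
#' @param birth_year Birth cohort.
#' @param init,quit Initiation / quit ages (`Inf` for absent).
#' @param params Parameter bundle.
#' @param life_table An `lcpm_life_table`.
#' @param u_oc Uniform draw(s), one per person.
#' @param ages Age grid (defaults to the full 15-84 range; the engine may
#'   truncate it when later years are not tallied).
#' @return Integer age at other-cause death (one past the last grid age =
#'   survived the grid, i.e. 85 = exit alive on the full grid).
#' @export
oc_death_ages <- function(sex, birth_year, init, quit, params, life_table,
                          u_oc, ages = AGES) {
  n <- length(u_oc)
  na <- length(ages)
  cpd_t <- cigarettes_per_day(sex, ages, birth_year + ages, params)
  heavy_t <- cpd_t >= params$other_cause$heavy_cpd
  m_nev <- life_table_probs(life_table, sex, ages, "never")
  m_lgt <- life_table_probs(life_table, sex, ages, "light")
  m_hvy <- life_table_probs(life_table, sex, ages, "heavy")
  # former smokers keep the band of their last smoked year
  bq <- pmin(pmax(quit - ENTRY_AGE, 1), na)
  heavyQ <- heavy_t[bq] & is.finite(quit)
  logu <- log(u_oc)
  ls <- numeric(n)
  surv <- integer(n)
  for (j in seq_len(na)) {
    a <- ages[j]
    cur_j <- init <= a & a < quit
    post_j <- a >= quit
    m_cur <- if (heavy_t[j]) m_hvy[j] else m_lgt[j]
    m_j <- m_nev[j] + cur_j * (m_cur - m_nev[j]) +
      post_j * (m_lgt[j] + heavyQ * (m_hvy[j] - m_lgt[j]) - m_nev[j])
    ls <- ls + log1p(-pmin(m_j, 0.999999))
    surv <- surv + (ls >= logu)
  }
  ages[1] + surv
}
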