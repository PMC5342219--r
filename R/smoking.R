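# Smoking life-courses: initiation, cessation, intensity, pack-years.
#
# A history is (initiation_age, quit_age) with NA/Inf meaning "absent";
# intensity comes from cigarettes_per_day() so pack-years depend on sex,
# age and calendar year. The annual cycle is: status during year t is
# current iff initiation_age <= t < quit_age; the quit hazard at age t acts
# on smokers and makes them former from age t+1; other-cause death during
# year t uses the smoking-intensity band held during t.

ENTRY_AGE <- 15L
EXIT_AGE <- 85L        # simulation cap: persons exit alive at their 85th year
AGES <- ENTRY_AGE:(EXIT_AGE - 1L)

#' Sample smoking life-courses
#'
#' Draws initiation and quit ages for `n` persons of one sex and birth
#' cohort. Initiation age is the first integer age at which the cohort's
#' cumulative initiation curve crosses a uniform draw (persons whose draw
#' exceeds the curve's plateau never initiate). Quitting is a one-way annual
#' hazard from the cessation schedule, tracked from age 30 (males) or 35
#' (females); there is no relapse. Sampling is inverse-CDF on single uniforms,
#' so scenario changes that alter the hazard only after some calendar year
#' (e.g. the cessation sensitivity multiplier) leave earlier history frozen.
#'
#' @param sex `"male"` or `"female"`.
#' @param birth_year Birth cohort (single value).
#' @param params Parameter bundle.
#' @param n Number of persons.
#' @param u_init,u_quit Optional uniform draws (length `n`); drawn from the
#'   current RNG stream when omitted.
#' @return A `data.frame` with columns `initiation_age` and `quit_age`
#'   (`NA` = never smoked / never quit).
#' @export
sample_smoking_history <- function(sex, birth_year, params, n = 1,
                                   u_init = NULL, u_quit = NULL) {
  check_sex(sex)
  if (is.null(u_init)) u_init <- stats::runif(n)
  if (is.null(u_quit)) u_quit <- stats::runif(n)
  h <- sample_histories_core(sex, birth_year, params, u_init, u_quit)
  data.frame(initiation_age = ifelse(is.finite(h$init), h$init, NA),
             quit_age = ifelse(is.finite(h$quit), h$quit, NA))
}

# vectorized core; returns init/quit as numeric with Inf for "absent"
sample_histories_core <- function(sex, birth_year, params, u_init, u_quit) {
  n <- length(u_init)
  Fa <- initiation_cdf(sex, birth_year, AGES, params)
  # initiation age: first age with F(age) >= u; plateau -> never
  idx <- findInterval(u_init, Fa, left.open = TRUE) + 1L
  init <- ifelse(idx > length(AGES), Inf, AGES[pmin(idx, length(AGES))])
  init[u_init > Fa[length(Fa)]] <- Inf
  # quit: hazard q(t) from max(init, track_from); shared survival curve
  q <- cessation_rate(sex, AGES, params, year = birth_year + AGES)
  S <- cumprod(1 - q)                      # P(still smoking at end of age t)
  S0 <- c(1, S)                            # S0[k] = survival through AGES[k-1]
  t0 <- pmax(init, params$smoking$cessation[[sex]]$track_from)
  s_entry <- S0[pmin(pmax(t0 - ENTRY_AGE, 0), length(AGES)) + 1L]
  s_entry[!is.finite(init)] <- 1
  thr <- (1 - u_quit) * s_entry
  # quit event at first age t with S(t) <= thr; former from t+1
  k <- findInterval(-thr, -S, left.open = TRUE) + 1L
  quit_event <- ifelse(k > length(AGES), Inf, AGES[pmin(k, length(AGES))])
  quit <- quit_event + 1
  quit[!is.finite(init)] <- Inf
  quit[quit <= init] <- init[quit <= init] + 1  # guard (cannot occur with t0>=init)
  list(init = init, quit = quit)
}

#' Cumulative pack-years at a given age
#'
#' One pack-year is one pack (20 cigarettes) per day smoked for one year.
#' Pack-years at age `a` accumulate `cigarettes_per_day / 20` over each
#' completed smoking year before `a`, freeze at the quit age, and are zero
#' for never-smokers.
#'
#' @param history A list/row with `sex`, `birth_year`, `initiation_age`,
#'   `quit_age` (`NA` allowed for the ages).
#' @param age Age(s) in years, `>= 15`.
#' @param params Parameter bundle.
#' @return Pack-years (numeric, nondecreasing in `age`).
#' @export
pack_years <- function(history, age, params) {
  stopifnot(all(age >= ENTRY_AGE))
  init <- history$initiation_age
  if (is.null(init) || is.na(init) || !is.finite(init)) return(0 * age)
  quit <- history$quit_age
  if (is.null(quit) || is.na(quit)) quit <- Inf
  yrs <- seq(init, min(max(age), quit - 1, EXIT_AGE - 1))
  if (length(yrs) == 0 || yrs[1] > min(max(age), quit - 1)) return(0 * age)
  cpd <- cigarettes_per_day(history$sex, yrs, history$birth_year + yrs, params)
  cum <- cumsum(cpd / 20)
  vapply(age, function(a) {
    k <- min(a, quit) - init         # completed smoking years before age a
    if (k <= 0) 0 else cum[min(k, length(cum))]
  }, numeric(1))
}

#' Smoking status and years since quit
#'
#' Status at age `a`: `"never"` before initiation, `"current"` from the
#' initiation age up to (excluding) the quit age, `"former"` after.
#'
#' @inheritParams pack_years
#' @return `smoking_status`: one of `"never"`, `"current"`, `"former"` (per
#'   age). `years_since_quit`: `age - quit_age` for former smokers, `NA`
#'   otherwise.
#' @export
smoking_status <- function(history, age) {
  init <- history$initiation_age
  if (is.null(init) || is.na(init)) return(rep("never", length(age)))
  quit <- history$quit_age
  if (is.null(quit) || is.na(quit)) quit <- Inf
  ifelse(age < init, "never", ifelse(age < quit, "current", "former"))
}

#' @rdname smoking_status
#' @export
years_since_quit <- function(history, age) {
  st <- smoking_status(history, age)
  quit <- history$quit_age
  ifelse(st == "former", age - quit, NA_real_)
}

#' Simulate smoking-only cohorts
#'
#' Samples smoking histories and other-cause death ages (no lung cancer) for
#' a set of birth cohorts, for computing cross-sectional smoking prevalence.
#' Cohort weights are persons-represented-per-simulated-person taken from the
#' population projection at cohort entry (age 15, or the 1975 age for cohorts
#' already older then).
#'
#' @param params Parameter bundle.
#' @param life_table Life table from [generate_life_tables()].
#' @param birth_years Vector of birth cohorts.
#' @param n Persons per cohort per sex.
#' @param seed Integer seed (per-cohort substreams are derived from it).
#' @param sexes Sexes to simulate.
#' @param projection Optional [generate_population_projection()] output for
#'   cohort weights (weight 1 when omitted).
#' @return A `data.frame`: `sex`, `birth_year`, `initiation_age`, `quit_age`,
#'   `oc_death_age`, `weight`.
#' @export
simulate_smoking_cohorts <- function(params, life_table, birth_years, n, seed,
                                     sexes = SEXES, projection = NULL) {
  out <- vector("list", length(birth_years) * length(sexes))
  k <- 0
  for (sex in sexes) {
    for (b in birth_years) {
      set.seed(cohort_seed(seed, b, sex))
      u_init <- stats::runif(n); u_quit <- stats::runif(n)
      u_oc <- stats::runif(n)
      h <- sample_histories_core(sex, b, params, u_init, u_quit)
      ocd <- oc_death_ages(sex, b, h$init, h$quit, params, life_table, u_oc)
      w <- 1
      if (!is.null(projection)) {
        entry_year <- max(1975, b + ENTRY_AGE)
        entry_age <- entry_year - b
        alive_entry <- mean(ocd >= entry_age)
        w <- projection_count(projection, entry_year, entry_age, sex) /
          (n * max(alive_entry, 1e-12))
      }
      k <- k + 1
      out[[k]] <- data.frame(sex = sex, birth_year = b,
                             initiation_age = ifelse(is.finite(h$init),
                                                     h$init, NA),
                             quit_age = ifelse(is.finite(h$quit), h$quit, NA),
                             oc_death_age = ocd, weight = w,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-sectional current-smoking prevalence
#'
#' Weighted fraction of alive persons in the age range who are current
#' smokers in the given calendar year, over simulated cohorts (persons dying
#' during age `a` count as alive in that year, matching the annual cycle).
#'
#' @param pop Simulated population (e.g. [simulate_smoking_cohorts()] output).
#' @param sex `"male"` or `"female"`.
#' @param year Calendar year.
#' @param age_range Integer ages included (default the CHNS sampling frame
#'   35-74).
#' @return Prevalence in `[0, 1]`.
#' @export
cross_sectional_prevalence <- function(pop, sex, year, age_range = 35:74) {
  check_sex(sex)
  age <- year - pop$birth_year
  sel <- pop$sex == sex & age >= min(age_range) & age <= max(age_range) &
    pop$oc_death_age >= age
  if (!any(sel)) stop("no alive persons in the requested stratum", call. = FALSE)
  a <- age[sel]
  init <- pop$initiation_age[sel]; quit <- pop$quit_age[sel]
  init[is.na(init)] <- Inf; quit[is.na(quit)] <- Inf
  cur <- init <= a & a < quit
  w <- if (is.null(pop$weight)) rep(1, sum(sel)) else pop$weight[sel]
  sum(w * cur) / sum(w)
}

# ---- exact expectation of prevalence (used by calibration) ---------------

# Four-state annual Markov chain (never / current / former-light /
# former-heavy) mirroring the simulation cycle exactly, vectorized over
# cohorts. Returns P(state, alive) at the requested age per cohort.
smoking_state_chain <- function(sex, birth_years, target_ages, params,
                                life_table) {
  nb <- length(birth_years)
  stopifnot(length(target_ages) == nb)
  ages <- AGES
  Fm <- outer_initiation(sex, birth_years, c(ages, EXIT_AGE), params)
  m_nev <- life_table_probs(life_table, sex, ages, "never")
  m_lgt <- life_table_probs(life_table, sex, ages, "light")
  m_hvy <- life_table_probs(life_table, sex, ages, "heavy")
  heavy_cut <- params$other_cause$heavy_cpd
  v <- cbind(never = 1 - Fm[, 1], current = Fm[, 1], fl = 0, fh = 0)
  out <- matrix(NA_real_, nb, 4, dimnames = list(NULL, colnames(v)))
  alive_entry <- rep(NA_real_, nb)
  entry_ages <- pmax(ENTRY_AGE, 1975 - birth_years)
  for (k in seq_along(ages)) {
    t <- ages[k]
    rec <- target_ages == t
    if (any(rec)) out[rec, ] <- v[rec, , drop = FALSE]
    ent <- entry_ages == t
    if (any(ent)) alive_entry[ent] <- rowSums(v[ent, , drop = FALSE])
    cpd_t <- cigarettes_per_day(sex, t, birth_years + t, params)
    hv <- cpd_t >= heavy_cut
    m_cur <- ifelse(hv, m_hvy[k], m_lgt[k])
    # deaths during year t by band held during t
    v[, 1] <- v[, 1] * (1 - m_nev[k])
    v[, 2] <- v[, 2] * (1 - m_cur)
    v[, 3] <- v[, 3] * (1 - m_lgt[k])
    v[, 4] <- v[, 4] * (1 - m_hvy[k])
    # transitions effective at age t+1
    denom <- pmax(1 - Fm[, k], 1e-15)
    h_init <- pmin(pmax((Fm[, k + 1] - Fm[, k]) / denom, 0), 1)
    q <- cessation_rate(sex, t, params, year = birth_years + t)
    new_cur <- v[, 1] * h_init
    quits <- v[, 2] * q
    v[, 1] <- v[, 1] - new_cur
    v[, 2] <- v[, 2] - quits + new_cur
    v[, 3] <- v[, 3] + quits * !hv
    v[, 4] <- v[, 4] + quits * hv
  }
  rec <- target_ages == EXIT_AGE  # not used in practice; guard
  if (any(rec)) out[rec, ] <- v[rec, , drop = FALSE]
  list(states = out, alive_entry = alive_entry)
}

outer_initiation <- function(sex, birth_years, ages, params) {
  ip <- params$smoking$initiation[[sex]]
  lv <- c(ip$levels, ip$late_ratio * ip$levels[length(ip$levels)])
  g <- findInterval(birth_years, ip$group_breaks) + 1
  outer(lv[g], stats::plogis(ip$slope * (ages - ip$midpoint)))
}

#' Expected current-smoking prevalence
#'
#' Deterministic expectation of [cross_sectional_prevalence()] under the
#' model, computed by an exact four-state annual Markov chain (never /
#' current / former by intensity band) that mirrors the simulation cycle,
#' weighted across cohorts by the projection entry sizes. Used as the
#' calibration objective for the initiation parameters, avoiding Monte-Carlo
#' noise in the optimizer.
#'
#' @inheritParams cross_sectional_prevalence
#' @param params Parameter bundle.
#' @param life_table Life table.
#' @param projection Optional population projection for cohort weights.
#' @return Expected prevalence in `[0, 1]`.
#' @export
expected_smoking_prevalence <- function(params, life_table, sex, year,
                                        age_range = 35:74, projection = NULL) {
  expected_prevalence_multi(params, life_table, sex, year, age_range,
                            projection)[[1]]
}

#' @rdname expected_smoking_prevalence
#' @param years Calendar years (the multi-year variant shares one chain pass
#'   across all of them).
#' @export
expected_prevalence_multi <- function(params, life_table, sex, years,
                                      age_range = 35:74, projection = NULL) {
  check_sex(sex)
  ages <- age_range[age_range >= ENTRY_AGE & age_range < EXIT_AGE]
  grid <- expand.grid(age = ages, year = years)
  births <- grid$year - grid$age
  res <- smoking_state_chain(sex, births, grid$age, params, life_table)
  w <- rep(1, length(births))
  if (!is.null(projection)) {
    entry_year <- pmax(1975, births + ENTRY_AGE)
    w <- projection_count(projection, entry_year, entry_year - births, sex) /
      pmax(res$alive_entry, 1e-12)
  }
  alive <- rowSums(res$states)
  num <- tapply(w * res$states[, "current"], grid$year, sum)
  den <- tapply(w * alive, grid$year, sum)
  as.numeric(num[as.character(years)] / den[as.character(years)])
}
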