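# Vectorized annual-cycle microsimulation engine. Each (sex, birth cohort)
# is simulated as a block of n persons on an integer age grid 15..84; all
# random draws for a cohort are made once, in a fixed order, from a seed
# derived from (run seed, cohort, sex), and every scenario (baseline or any
# screening policy) is a deterministic function of those draws. That gives
# exact common random numbers: scenarios share persons, histories, tumors
# and other-cause deaths, and differ only through screen detection.

cohort_seed <- function(seed, birth_year, sex) {
  base <- as.numeric(seed) %% 2147483647
  v <- (base + birth_year * 131 + ifelse(sex == "female", 7919, 0)) * 48271
  as.integer(v %% 2147483647)
}

STATUS_CODES <- c(never = 1L, current = 2L, former = 3L)

# one cohort, all scenarios; returns per-policy tallies on the year grid
cohort_run <- function(n, sex, birth_year, params, life_table, policies,
                       seed, year_min = 1975, year_max = 2050,
                       collect_persons = FALSE) {
  nh <- params$natural_history
  max_age <- min(EXIT_AGE - 1L, year_max - birth_year)
  ages <- ENTRY_AGE:max_age
  na <- length(ages)
  years <- year_min:year_max
  ny <- length(years)

  # --- draws: fixed order and sizes given (n, cohort) ---------------------
  set.seed(cohort_seed(seed, birth_year, sex))
  u_init <- stats::runif(n); u_quit <- stats::runif(n)
  u_oc <- stats::runif(n)
  e_onset <- stats::rexp(n); u_soj <- stats::runif(n)
  u_hist <- stats::runif(n); u_stage <- stats::runif(n)
  u_cure <- stats::runif(n); e_surv <- stats::rexp(n)
  u_incid <- stats::runif(n); u_adh <- stats::runif(n)
  sw_sel <- birth_year + ages >= 2016 & birth_year + ages <= 2050
  sw_ages <- ages[sw_sel]
  U_sens <- if (length(sw_ages)) {
    matrix(stats::runif(n * length(sw_ages)), n)
  } else NULL

  # --- smoking histories and person-level disease quantities --------------
  hh <- sample_histories_core(sex, birth_year, params, u_init, u_quit)
  init <- hh$init; quit <- hh$quit
  cpd_t <- cigarettes_per_day(sex, ages, birth_year + ages, params)
  heavy_t <- cpd_t >= params$other_cause$heavy_cpd
  m_nev <- life_table_probs(life_table, sex, ages, "never")
  m_lgt <- life_table_probs(life_table, sex, ages, "light")
  m_hvy <- life_table_probs(life_table, sex, ages, "heavy")
  bq <- pmin(pmax(quit - ENTRY_AGE, 1), na)
  heavyQ <- heavy_t[bq] & is.finite(quit)
  base_t <- baseline_hazard(sex, ages, params)
  beta <- nh$beta[[sex]]
  # single pass over the age grid: smoking status, pack-years, other-cause
  # survival and the cumulative lung cancer hazard, all column-wise
  cur <- matrix(FALSE, n, na); post <- matrix(FALSE, n, na)
  PY <- matrix(0, n, na)
  py <- numeric(n); ls <- numeric(n); ch <- numeric(n)
  oc_surv <- integer(n); pre_onset <- integer(n)
  logu <- log(u_oc)
  for (j in seq_len(na)) {
    a <- ages[j]
    cur_j <- init <= a & a < quit
    post_j <- a >= quit
    cur[, j] <- cur_j; post[, j] <- post_j; PY[, j] <- py
    m_cur <- if (heavy_t[j]) m_hvy[j] else m_lgt[j]
    m_j <- m_nev[j] + cur_j * (m_cur - m_nev[j]) +
      post_j * (m_lgt[j] + heavyQ * (m_hvy[j] - m_lgt[j]) - m_nev[j])
    ls <- ls + log1p(-pmin(m_j, 0.999999))
    oc_surv <- oc_surv + (ls >= logu)
    exc_j <- if (nh$eta == 1) py else py^nh$eta
    dec_j <- 1 - post_j + post_j * exp(-nh$quit_decay * pmax(a - quit, 0))
    ch <- ch + base_t[j] * (1 + beta * exc_j * dec_j)
    pre_onset <- pre_onset + (ch < e_onset)
    py <- py + cur_j * (cpd_t[j] / 20)
  }
  ocd <- ages[1] + oc_surv
  oi <- pre_onset + 1L
  onset <- ifelse(oi <= na, ages[pmin(oi, na)], Inf)
  sojourn <- 1 + stats::qgeom(u_soj, 1 / nh$sojourn_mean)
  clin_age <- onset + sojourn
  inc_delay <- if (nh$incidental_rate > 0) {
    stats::qgeom(u_incid, nh$incidental_rate)
  } else Inf
  inc_age <- onset + inc_delay
  diag0 <- pmin(clin_age, ifelse(inc_age < clin_age, inc_age, Inf))
  stage_c <- stage_quantile(nh$stage_clinical, u_stage)
  cured_c <- u_cure < nh$cure[stage_c]
  lc_clin <- ifelse(cured_c, Inf, clin_age + e_surv / nh$surv_rate[stage_c])

  # histology tallies of cases diagnosed before death/exit
  hist_counts <- matrix(0L, 4, 3, dimnames = list(HISTOLOGIES, HIST_PERIODS))
  case <- is.finite(onset) & diag0 <= pmin(ocd, max_age)
  if (any(case)) {
    dy <- birth_year + diag0[case]
    per <- period_of_year(dy)
    for (p in unique(per)) {
      hp <- histology_distribution(sex, p, params)
      hidx <- stage_quantile(hp, u_hist[case][per == p])
      hist_counts[, p] <- hist_counts[, p] + tabulate(hidx, 4)
    }
  }

  entry_age <- max(ENTRY_AGE, 1975 - birth_year)

  tally <- function(lc_death) {
    cause_lc <- lc_death < ocd + 1
    fa <- floor(lc_death)
    death_age <- ifelse(cause_lc, fa, ocd)       # ocd == max_age+1 => censored
    deaths <- matrix(0, ny, 3)
    sel <- cause_lc & fa <= max_age
    if (any(sel)) {
      dy <- birth_year + fa[sel]
      ok <- dy >= year_min & dy <= year_max
      if (any(ok)) {
        # stratify by smoking status at the (scenario-invariant) clinical
        # detection age, so screening moves deaths across years, never
        # across status strata
        ca <- clin_age[sel][ok]
        st <- ifelse(init[sel][ok] > ca, 1L,
                     ifelse(ca < quit[sel][ok], 2L, 3L))
        idx <- (st - 1L) * ny + (dy[ok] - year_min + 1L)
        deaths <- matrix(tabulate(idx, 3L * ny), ny, 3)
      }
    }
    py <- matrix(0, ny, 3)
    for (j in seq_len(na)) {
      y <- birth_year + ages[j]
      if (y < year_min || y > year_max) next
      alive_j <- death_age >= ages[j]
      ncur <- sum(alive_j & cur[, j])
      nfor <- sum(alive_j & post[, j])
      yi <- y - year_min + 1L
      py[yi, ] <- py[yi, ] + c(sum(alive_j) - ncur - nfor, ncur, nfor)
    }
    list(deaths = deaths, py = py, death_age = death_age)
  }

  base_tally <- tally(lc_clin)
  alive_entry <- sum(base_tally$death_age >= entry_age)

  screen_p <- screen_stage_probs(nh)
  stage_s_all <- stage_quantile(screen_p, u_stage)
  cured_s_all <- u_cure < nh$cure[stage_s_all]
  lc_s_all <- ifelse(cured_s_all, Inf,
                     clin_age + e_surv / nh$surv_rate[stage_s_all])

  out <- vector("list", length(policies))
  names(out) <- names(policies)
  persons <- NULL
  if (collect_persons) {
    persons <- list(init = init, quit = quit, ocd = ocd, onset = onset,
                    clin_age = clin_age, lc_clin = lc_clin)
  }
  for (pn in names(policies)) {
    pol <- policies[[pn]]
    if (is.null(pol)) {
      out[[pn]] <- list(deaths = base_tally$deaths, py = base_tally$py,
                        screens = numeric(ny), eligible = numeric(ny))
      if (collect_persons) persons[[paste0("lc_", pn)]] <- lc_clin
      next
    }
    keep <- birth_year + sw_ages >= pol$start_year &
      birth_year + sw_ages <= pol$end_year
    aS <- sw_ages[keep]
    screens <- numeric(ny); eligible <- numeric(ny)
    lc_scen <- lc_clin
    ever_elig <- rep(FALSE, n)
    if (length(aS)) {
      jj <- match(aS, ages)
      aSM <- matrix(aS, n, length(aS), byrow = TRUE)
      in_win <- aS >= pol$age_min & aS <= pol$age_max
      former_ok <- post[, jj, drop = FALSE] &
        (aSM - quit) <= pol$max_years_since_quit
      elig <- (cur[, jj, drop = FALSE] | former_ok) &
        matrix(in_win, n, length(aS), byrow = TRUE) &
        PY[, jj, drop = FALSE] >= pol$min_pack_years
      undiag <- aSM < diag0 & aSM <= ocd
      mask_e <- elig & undiag
      adherent <- u_adh < pol$adherence
      det <- mask_e & adherent & aSM >= onset &
        U_sens[, keep, drop = FALSE] < nh$ct_sensitivity
      any_det <- rowSums(det) > 0
      sda <- rep(Inf, n)
      if (any(any_det)) {
        sda[any_det] <- aS[max.col(det[any_det, , drop = FALSE] + 0,
                                   ties.method = "first")]
      }
      scr <- mask_e & adherent & aSM <= sda
      eligm <- mask_e & aSM <= sda
      ever_elig <- rowSums(mask_e) > 0
      yi <- birth_year + aS - year_min + 1L
      oky <- yi >= 1 & yi <= ny
      screens[yi[oky]] <- colSums(scr)[oky]
      eligible[yi[oky]] <- colSums(eligm)[oky]
      lc_scen[any_det] <- lc_s_all[any_det]
    }
    tl <- tally(lc_scen)
    out[[pn]] <- list(deaths = tl$deaths, py = tl$py, screens = screens,
                      eligible = eligible)
    if (collect_persons) {
      persons[[paste0("lc_", pn)]] <- lc_scen
      persons[[paste0("ever_elig_", pn)]] <- ever_elig
    }
  }
  list(tallies = out, alive_entry = alive_entry, hist_counts = hist_counts,
       persons = persons)
}

#' Simulate one or several scenarios under common random numbers
#'
#' Runs the microsimulation over birth cohorts 1891-2035 (persons ages 15-84
#' during 1975-2050) for each policy in `policies` (a `NULL` element is the
#' no-screening baseline), drawing each cohort's random numbers once so that
#' all scenarios share identical persons. Results are optionally scaled to
#' the population projection.
#'
#' @param policies Named list of [screening_policy()] objects and/or `NULL`
#'   (baseline).
#' @param params Parameter bundle.
#' @param n_per_cohort Simulated persons per birth cohort per sex.
#' @param seed Integer run seed.
#' @param years Calendar-year tally window.
#' @param birth_years Birth cohorts to simulate.
#' @param life_table,projection Synthetic inputs (regenerated from `params`
#'   when omitted).
#' @param scale Scale tallies to population units using the projection.
#' @return For `simulate_scenarios`, a named list of `lcpm_result` objects;
#'   `simulate_scenario` returns a single `lcpm_result`. Each result holds
#'   arrays `deaths` and `person_years` `[cohort, year, sex, status]`, and
#'   `screens`, `eligible` `[cohort, year, sex]`.
#' @export
simulate_scenarios <- function(policies, params, n_per_cohort, seed,
                               years = 1975:2050,
                               birth_years = (min(years) - EXIT_AGE + 1):
                                 (max(years) - ENTRY_AGE),
                               life_table = NULL, projection = NULL,
                               scale = TRUE) {
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  if (scale && is.null(projection)) {
    projection <- generate_population_projection(params,
                                                 life_table = life_table)
  }
  year_min <- min(years); year_max <- max(years)
  birth_years <- birth_years[birth_years + ENTRY_AGE <= year_max]
  nb <- length(birth_years); ny <- year_max - year_min + 1
  dn <- list(birth_years, year_min:year_max, SEXES, SMOKING_STATUSES)
  mk <- function() array(0, c(nb, ny, 2, 3), dimnames = dn)
  res <- lapply(policies, function(p) {
    structure(list(
      birth_years = birth_years, years = year_min:year_max,
      deaths = mk(), person_years = mk(),
      screens = array(0, c(nb, ny, 2), dimnames = dn[1:3]),
      eligible = array(0, c(nb, ny, 2), dimnames = dn[1:3]),
      histology = array(0, c(4, 3, 2),
                        dimnames = list(HISTOLOGIES, HIST_PERIODS, SEXES)),
      alive_entry = matrix(n_per_cohort, nb, 2, dimnames = dn[c(1, 3)]),
      meta = list(seed = seed, n_per_cohort = n_per_cohort,
                  policy = if (is.null(p)) "baseline" else p$name,
                  scaled = FALSE)), class = "lcpm_result")
  })
  for (si in 1:2) {
    sex <- SEXES[si]
    for (bi in seq_len(nb)) {
      b <- birth_years[bi]
      cr <- cohort_run(n_per_cohort, sex, b, params, life_table, policies,
                       seed, year_min, year_max)
      for (pn in names(policies)) {
        t <- cr$tallies[[pn]]
        res[[pn]]$deaths[bi, , si, ] <- t$deaths
        res[[pn]]$person_years[bi, , si, ] <- t$py
        res[[pn]]$screens[bi, , si] <- t$screens
        res[[pn]]$eligible[bi, , si] <- t$eligible
        res[[pn]]$alive_entry[bi, si] <- cr$alive_entry
        res[[pn]]$histology[, , si] <- res[[pn]]$histology[, , si] +
          cr$hist_counts
      }
    }
  }
  if (scale) res <- lapply(res, scale_results, projection = projection)
  res
}

#' @rdname simulate_scenarios
#' @param policy A single [screening_policy()] or `NULL` for baseline.
#' @export
simulate_scenario <- function(policy, params, n_per_cohort, seed, ...) {
  nm <- if (is.null(policy)) "baseline" else policy$name
  pl <- stats::setNames(list(policy), nm)
  simulate_scenarios(pl, params, n_per_cohort, seed, ...)[[1]]
}

#' Scale a result to population units
#'
#' Multiplies every tally by the persons-represented ratio of its cohort:
#' the projection count at cohort entry (age 15, or the 1975 age for cohorts
#' already adult then) divided by the simulated persons alive at entry.
#'
#' @param result An `lcpm_result`.
#' @param projection An `lcpm_projection` covering all cohorts.
#' @return The scaled `lcpm_result` (with `meta$scaled = TRUE` and a
#'   `scale_factor` matrix `[cohort, sex]`).
#' @export
scale_results <- function(result, projection) {
  if (isTRUE(result$meta$scaled)) stop("result is already scaled",
                                       call. = FALSE)
  b <- result$birth_years
  entry_year <- pmax(1975, b + ENTRY_AGE)
  entry_age <- entry_year - b
  if (min(entry_year) < min(projection$years) ||
      max(entry_age) > max(projection$ages)) {
    stop("projection does not cover all cohort entries", call. = FALSE)
  }
  f <- sapply(SEXES, function(s) {
    projection_count(projection, entry_year, entry_age, s) /
      pmax(result$alive_entry[, s], 1)
  })
  for (nm in c("deaths", "person_years")) {
    for (si in 1:2) {
      result[[nm]][, , si, ] <- result[[nm]][, , si, ] *
        as.vector(f[, si])
    }
  }
  for (nm in c("screens", "eligible")) {
    for (si in 1:2) result[[nm]][, , si] <- result[[nm]][, , si] *
        as.vector(f[, si])
  }
  result$scale_factor <- f
  result$meta$scaled <- TRUE
  result
}

#' @export
print.lcpm_result <- function(x, ...) {
  cat(sprintf("<lcpm_result> policy '%s', %d cohorts x %d years, %s\n",
              x$meta$policy, length(x$birth_years), length(x$years),
              if (x$meta$scaled) "population-scaled" else "unscaled"))
  cat(sprintf("  lung cancer deaths 2016-2050: %.0f; screens: %.0f\n",
              result_total(x, "deaths", 2016:2050),
              result_total(x, "screens", 2016:2050)))
  invisible(x)
}

#' Sum a result tally over a selection
#'
#' @param result An `lcpm_result`.
#' @param what One of `"deaths"`, `"person_years"`, `"screens"`,
#'   `"eligible"`.
#' @param years Calendar years to include.
#' @param sex Optional sex restriction.
#' @param status Optional smoking-status restriction (deaths/person-years).
#' @return Numeric total.
#' @export
result_total <- function(result, what = "deaths", years = 2016:2050,
                         sex = NULL, status = NULL) {
  a <- result[[what]]
  yi <- intersect(as.character(years), dimnames(a)[[2]])
  if (length(dim(a)) == 4) {
    a <- a[, yi, , , drop = FALSE]
    if (!is.null(status)) a <- a[, , , status, drop = FALSE]
    if (!is.null(sex)) a <- a[, , sex, , drop = FALSE]
  } else {
    a <- a[, yi, , drop = FALSE]
    if (!is.null(sex)) a <- a[, , sex, drop = FALSE]
  }
  sum(a)
}

# ---- outcome measures ----------------------------------------------------

#' Lung cancer mortality reduction of a scenario versus baseline
#'
#' `(baseline deaths - scenario deaths) / baseline deaths` over the year
#' window and stratum. Dispatches on the input type: two `lcpm_result`
#' objects, or two plain death totals.
#'
#' @param baseline,scenario `lcpm_result` objects (scaled identically) or
#'   numeric death totals.
#' @param years Calendar-year window (default the 2016-2050 headline window).
#' @param sex,status Optional stratum restriction.
#' @return Fraction of baseline deaths prevented.
#' @export
mortality_reduction <- function(baseline, scenario, years = 2016:2050,
                                sex = NULL, status = NULL) {
  if (is.numeric(baseline)) {
    if (any(baseline <= 0)) stop("zero baseline deaths in stratum",
                                 call. = FALSE)
    return((baseline - scenario) / baseline)
  }
  b <- result_total(baseline, "deaths", years, sex, status)
  s <- result_total(scenario, "deaths", years, sex, status)
  if (b <= 0) stop("zero baseline deaths in stratum", call. = FALSE)
  (b - s) / b
}

#' Life-years saved by a scenario versus baseline
#'
#' Scenario person-years minus baseline person-years over the window;
#' positive when screening defers deaths.
#'
#' @inheritParams mortality_reduction
#' @return Life-years (numeric).
#' @export
life_years_saved <- function(baseline, scenario, years = 2016:2050,
                             sex = NULL) {
  if (is.numeric(baseline)) return(scenario - baseline)
  result_total(scenario, "person_years", years, sex) -
    result_total(baseline, "person_years", years, sex)
}

#' Life-years saved per death prevented
#'
#' @param ly Life-years saved.
#' @param deaths_prevented Deaths prevented (must be positive).
#' @return Ratio.
#' @export
per_death <- function(ly, deaths_prevented) {
  if (deaths_prevented <= 0) {
    stop("undefined: no deaths prevented in this stratum", call. = FALSE)
  }
  ly / deaths_prevented
}

#' Screening CT exams per death prevented
#'
#' @param result Scenario `lcpm_result` (or total screens, numeric).
#' @param baseline Baseline `lcpm_result` (or total baseline deaths).
#' @param years Calendar-year window.
#' @param sex Optional sex restriction.
#' @return Ratio of screens to deaths prevented.
#' @export
screens_per_death_prevented <- function(result, baseline, years = 2016:2050,
                                        sex = NULL) {
  scr <- result_total(result, "screens", years, sex)
  prevented <- result_total(baseline, "deaths", years, sex) -
    result_total(result, "deaths", years, sex)
  if (prevented <= 0) {
    stop("undefined: no deaths prevented in this stratum", call. = FALSE)
  }
  scr / prevented
}

#' Flatten a result to a data frame / write it as CSV
#'
#' One row per (year, sex, smoking status) with deaths, person-years and the
#' (status-independent) screens and eligible counts attached to each year and
#' sex. The CSV carries a header comment recording the seed and scale so
#' reruns are verifiably identical.
#'
#' @param result An `lcpm_result`.
#' @param path CSV path.
#' @return `as.data.frame` method: the flat table. `write_results_csv`:
#'   `path`, invisibly.
#' @export
result_table <- function(result) {
  d <- as.data.frame.table(apply(result$deaths, 2:4, sum),
                           stringsAsFactors = FALSE)
  names(d) <- c("year", "sex", "smoking_status", "lc_deaths")
  p <- as.data.frame.table(apply(result$person_years, 2:4, sum),
                           stringsAsFactors = FALSE)
  d$person_years <- p$Freq
  scr <- apply(result$screens, c(2, 3), sum)
  eli <- apply(result$eligible, c(2, 3), sum)
  d$screens <- scr[cbind(d$year, d$sex)]
  d$eligible <- eli[cbind(d$year, d$sex)]
  d$year <- as.integer(d$year)
  d[order(d$year, d$sex, d$smoking_status), , drop = FALSE]
}

#' @rdname result_table
#' @export
write_results_csv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lcscreen results policy=%s seed=%d n_per_cohort=%d scaled=%s",
                     result$meta$policy, result$meta$seed,
                     result$meta$n_per_cohort, result$meta$scaled), con)
  utils::write.csv(result_table(result), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
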