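# Staged calibration of the model's free parameters to the printed targets:
#   1. smoking initiation curve levels -> CHNS prevalence anchors
#      (deterministic objective via the exact state-chain expectation);
#   2. per-sex baseline hazard multipliers -> GLOBOCAN 2012 death counts
#      (common-random-number secant on simulated scaled deaths);
#   3. screen stage-shift -> NLST mortality-reduction anchor in the
#      CMS-eligible subgroup of the 1960 birth cohort (uniroot, CRN).
# The stages are strictly ordered: later stages never touch earlier fits.

#' Weighted relative squared-error calibration loss
#'
#' `sum(weight * ((output - value) / value)^2)` over the target table; zero
#' iff every target is hit exactly, invariant to target order.
#'
#' @param targets Target table ([default_targets()] layout).
#' @param outputs Named numeric vector of model outputs, names matching
#'   `targets$name`.
#' @return Scalar loss.
#' @export
calibration_loss <- function(targets, outputs) {
  miss <- setdiff(targets$name, names(outputs))
  if (length(miss)) {
    stop("missing model output for target(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  o <- unlist(outputs[targets$name])
  sum(targets$weight * ((o - targets$value) / targets$value)^2)
}

prevalence_outputs <- function(params, life_table, projection, targets,
                               age_range = 35:74) {
  tg <- targets[targets$kind == "prevalence", , drop = FALSE]
  out <- numeric(nrow(tg))
  for (s in unique(tg$sex)) {
    sel <- tg$sex == s
    out[sel] <- expected_prevalence_multi(params, life_table, s,
                                          tg$year[sel], age_range,
                                          projection)
  }
  stats::setNames(out, tg$name)
}

#' Calibrate the smoking initiation curves
#'
#' Fits the cohort-group levels of the cumulative initiation curve (per sex)
#' to the current-smoking prevalence targets, minimising
#' [calibration_loss()] with Nelder-Mead on logit-transformed levels from a
#' small set of seeded starting points. The objective is the deterministic
#' state-chain prevalence ([expected_smoking_prevalence()]), so the fit is
#' exactly reproducible. If the evaluation budget is exhausted before every
#' target is inside its relative tolerance the best fit found is returned,
#' with per-target residuals attached either way (attribute `"residuals"`,
#' plus `"converged"`).
#'
#' @param params Parameter bundle (its targets are used unless `targets` is
#'   given).
#' @param targets Optional target table.
#' @param life_table,projection Synthetic inputs (regenerated when omitted).
#' @param budget Nelder-Mead evaluation budget per start.
#' @param age_range Ages over which prevalence is computed (CHNS frame).
#' @param seed Seed for the extra latin-hypercube starting points.
#' @return Updated `lcpm_params` with fitted initiation levels.
#' @export
calibrate_initiation <- function(params, targets = NULL, life_table = NULL,
                                 projection = NULL, budget = 500,
                                 age_range = 35:74, seed = 1) {
  if (is.null(targets)) targets <- params$targets
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  if (is.null(projection)) {
    projection <- generate_population_projection(params,
                                                 life_table = life_table)
  }
  for (s in SEXES) {
    tg <- targets[targets$kind == "prevalence" & targets$sex == s, ,
                  drop = FALSE]
    if (!nrow(tg)) next
    lv0 <- params$smoking$initiation[[s]]$levels
    obj <- function(x) {
      p2 <- params
      p2$smoking$initiation[[s]]$levels <- stats::plogis(x)
      calibration_loss(tg, prevalence_outputs(p2, life_table, projection,
                                              tg, age_range))
    }
    x0 <- stats::qlogis(pmin(pmax(lv0, 1e-4), 1 - 1e-4))
    ctr <- mean(x0)
    starts <- list(x0, rep(ctr, length(lv0)), rep(ctr - 1, length(lv0)))
    if (requireNamespace("lhs", quietly = TRUE)) {
      set.seed(seed)
      grid <- lhs::randomLHS(2, length(lv0))
      for (i in 1:2) {
        starts[[length(starts) + 1]] <- ctr + (grid[i, ] - 0.5) * 3
      }
    }
    best <- NULL
    for (st in starts) {
      fit <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = budget))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    params$smoking$initiation[[s]]$levels <- stats::plogis(best$par)
  }
  tgp <- targets[targets$kind == "prevalence", , drop = FALSE]
  out <- prevalence_outputs(params, life_table, projection, tgp, age_range)
  resid <- data.frame(target = tgp$name, value = tgp$value,
                      model = as.numeric(out[tgp$name]),
                      rel_error = as.numeric(out[tgp$name]) / tgp$value - 1)
  attr(params, "residuals") <- resid
  attr(params, "converged") <-
    all(abs(resid$rel_error) <= tgp$rel_tolerance)
  params
}

deaths_in_year <- function(params, life_table, projection, year, n, seed) {
  res <- simulate_scenarios(list(baseline = NULL), params, n, seed,
                            years = year:year,
                            birth_years = (year - EXIT_AGE + 1):
                              (year - ENTRY_AGE),
                            life_table = life_table,
                            projection = projection, scale = TRUE)$baseline
  c(male = result_total(res, "deaths", year, "male"),
    female = result_total(res, "deaths", year, "female"))
}

#' Calibrate the baseline lung cancer hazard to mortality counts
#'
#' Adjusts the per-sex baseline hazard multipliers until the
#' population-scaled simulated lung cancer deaths in the target year match
#' the mortality-count targets (GLOBOCAN 2012). The solve is a damped secant
#' iteration in log space on simulated counts under common random numbers
#' (the same seed and person draws at every evaluation, so the objective is
#' a fixed monotone function), run at `n_calib` persons per cohort and then
#' refined and verified at `n_final`.
#'
#' @inheritParams calibrate_initiation
#' @param seed Run seed for the simulation draws.
#' @param n_calib,n_final Persons per cohort per sex for the search and the
#'   final refinement.
#' @param tol Relative tolerance on each sex's death count.
#' @param max_iter Maximum secant iterations at `n_calib`.
#' @return Updated `lcpm_params`; attribute `"mortality_fit"` holds the
#'   achieved scaled counts and relative errors at `n_final`.
#' @export
calibrate_natural_history <- function(params, targets = NULL, seed = 1,
                                      life_table = NULL, projection = NULL,
                                      n_calib = 20000, n_final = 50000,
                                      tol = 0.005, max_iter = 8) {
  if (is.null(targets)) targets <- params$targets
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  if (is.null(projection)) {
    projection <- generate_population_projection(params,
                                                 life_table = life_table)
  }
  tg <- targets[targets$kind == "mortality_count", , drop = FALSE]
  stopifnot(nrow(tg) == 2)
  year <- unique(tg$year)
  target <- stats::setNames(tg$value, tg$sex)[SEXES]
  get_mult <- function(p) c(male = p$natural_history$baseline$male$mult,
                            female = p$natural_history$baseline$female$mult)
  set_mult <- function(p, m) {
    p$natural_history$baseline$male$mult <- m[["male"]]
    p$natural_history$baseline$female$mult <- m[["female"]]
    p
  }
  mult <- get_mult(params)
  step <- function(mult, d, mult_prev = NULL, d_prev = NULL) {
    # damped log-space update; counts floored and step factors clamped so a
    # stray zero-count evaluation cannot derail the iteration
    ratio <- target / pmax(d, 0.5)
    slope <- rep(1, 2)
    if (!is.null(mult_prev)) {
      dd <- log(pmax(d, 0.5)) - log(pmax(d_prev, 0.5))
      dm <- log(mult) - log(mult_prev)
      ok <- abs(dd) > 1e-12 & abs(dm) > 1e-12
      slope[ok] <- pmin(pmax(dm[ok] / dd[ok], 0.1), 10)
    }
    mult * pmin(pmax(ratio^slope, 0.05), 20)
  }
  hist_m <- list(); hist_d <- list()
  for (it in seq_len(max_iter)) {
    d <- deaths_in_year(set_mult(params, mult), life_table, projection,
                        year, n_calib, seed)
    if (all(abs(d / target - 1) < tol)) break
    hist_m[[it]] <- mult; hist_d[[it]] <- d
    mult <- if (it == 1) step(mult, d) else
      step(mult, d, hist_m[[it - 1]], hist_d[[it - 1]])
  }
  # refine at the verification size (fresh Monte-Carlo realization),
  # keeping the best evaluated point per sex
  evals <- list()
  cur <- mult
  prev_m <- NULL; prev_d <- NULL
  for (it in 1:3) {
    d <- deaths_in_year(set_mult(params, cur), life_table, projection, year,
                        n_final, seed)
    evals[[it]] <- list(mult = cur, d = d)
    if (all(abs(d / target - 1) < tol)) break
    nxt <- step(cur, d, prev_m, prev_d)
    prev_m <- cur; prev_d <- d
    cur <- nxt
  }
  err <- sapply(evals, function(e) abs(e$d / target - 1))  # 2 x n_evals
  best <- apply(err, 1, which.min)
  mult_best <- c(male = evals[[best[1]]]$mult[["male"]],
                 female = evals[[best[2]]]$mult[["female"]])
  d_best <- c(male = evals[[best[1]]]$d[["male"]],
              female = evals[[best[2]]]$d[["female"]])
  params <- set_mult(params, mult_best)
  attr(params, "mortality_fit") <- data.frame(
    sex = SEXES, target = as.numeric(target[SEXES]),
    model = as.numeric(d_best[SEXES]),
    rel_error = as.numeric(d_best[SEXES] / target[SEXES] - 1),
    n_per_cohort = n_final, seed = seed, year = year)
  params
}

#' Mortality reduction in the screening-eligible subgroup of one cohort
#'
#' Simulates a single birth cohort (both sexes) with and without the policy
#' under common random numbers and returns the percent lung cancer mortality
#' reduction restricted to persons who ever meet the eligibility criteria,
#' with deaths counted over the screening era.
#'
#' @param params Parameter bundle.
#' @param policy Screening policy (default the bundled CMS rule).
#' @param birth_year Birth cohort (1960 for the NLST-era anchor).
#' @param n Persons per sex.
#' @param seed Run seed.
#' @param years Death-count window.
#' @param life_table Optional life table.
#' @return Percent mortality reduction (0-100 scale).
#' @export
eligible_subgroup_reduction <- function(params, policy = params$policies$cms,
                                        birth_year = 1960, n = 100000,
                                        seed = 1, years = 2016:2050,
                                        life_table = NULL) {
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  base_d <- 0; scen_d <- 0
  for (sex in SEXES) {
    cr <- cohort_run(n, sex, birth_year, params, life_table,
                     list(baseline = NULL, pol = policy), seed,
                     year_min = min(years), year_max = max(years),
                     collect_persons = TRUE)
    pp <- cr$persons
    ever <- pp$ever_elig_pol
    count <- function(lc) {
      cause <- lc < pp$ocd + 1
      fa <- floor(lc)
      dy <- birth_year + fa
      sum(ever & cause & fa < EXIT_AGE & dy >= min(years) & dy <= max(years))
    }
    base_d <- base_d + count(pp$lc_baseline)
    scen_d <- scen_d + count(pp$lc_pol)
  }
  if (base_d == 0) stop("no baseline deaths in the eligible subgroup",
                        call. = FALSE)
  100 * (base_d - scen_d) / base_d
}

#' Calibrate the screening stage-shift to an effectiveness anchor
#'
#' Solves for the stage-shift parameter so that the simulated percent
#' mortality reduction in the policy-eligible subgroup of the anchor birth
#' cohort matches the trial anchor (19.7% for the 1960 cohort under CMS
#' criteria). The root-solve runs under common random numbers, so the
#' response is a deterministic nondecreasing function of the shift; an
#' anchor of zero yields a zero shift (screen stages collapse to the
#' clinical distribution), and an anchor above the model's maximum benefit
#' is reported as infeasible with the achievable bound.
#'
#' @inheritParams eligible_subgroup_reduction
#' @param anchor Target percent mortality reduction.
#' @param tol Absolute tolerance on the stage-shift parameter.
#' @return Updated `lcpm_params`; attribute `"nlst_fit"` records the
#'   achieved reduction.
#' @export
calibrate_screening_benefit <- function(params, anchor = 19.7,
                                        policy = params$policies$cms,
                                        birth_year = 1960, n = 100000,
                                        seed = 1, tol = 0.004,
                                        life_table = NULL) {
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  f <- function(theta) {
    p2 <- params
    p2$natural_history$stage_shift <- theta
    eligible_subgroup_reduction(p2, policy, birth_year, n, seed,
                                life_table = life_table) - anchor
  }
  if (anchor <= 0) {
    params$natural_history$stage_shift <- 0
    attr(params, "nlst_fit") <- data.frame(anchor = anchor, achieved = 0,
                                           stage_shift = 0, n = n, seed = seed)
    return(params)
  }
  f1 <- f(1)
  if (f1 < 0) {
    stop(sprintf(paste0("infeasible anchor: maximum achievable mortality ",
                        "reduction is %.1f%% (anchor %.1f%%); raise CT ",
                        "sensitivity, stage-I cure fraction or sojourn time"),
                 f1 + anchor, anchor), call. = FALSE)
  }
  root <- stats::uniroot(f, c(0, 1), f.upper = f1, tol = tol)
  params$natural_history$stage_shift <- root$root
  attr(params, "nlst_fit") <- data.frame(
    anchor = anchor, achieved = root$f.root + anchor,
    stage_shift = root$root, n = n, seed = seed)
  params
}

#' Full staged calibration
#'
#' Runs the three calibration stages in order - initiation levels to the
#' prevalence targets, baseline hazard multipliers to the mortality-count
#' targets, stage-shift to the screening-effectiveness anchor - and returns
#' the calibrated bundle together with the per-stage fit reports. Later
#' stages never modify earlier fits.
#'
#' @param params Starting parameter bundle.
#' @param seed Run seed (sub-seeds for stages 2 and 3 are derived from it).
#' @param budget Stage-1 optimizer budget.
#' @param n_calib,n_final Stage-2 cohort sizes.
#' @param nlst_n Stage-3 persons per sex.
#' @param targets Optional replacement target table.
#' @return A list of class `lcpm_calibration`: `params` (calibrated bundle),
#'   `prevalence` (residual table), `mortality` (fit table), `nlst` (fit
#'   table), `converged` (stage-1 tolerance flag).
#' @export
calibrate_lcpm <- function(params, seed = 1, budget = 400, n_calib = 20000,
                           n_final = 50000, nlst_n = 100000, targets = NULL) {
  if (!is.null(targets)) params$targets <- targets
  life_table <- generate_life_tables(params)
  projection <- generate_population_projection(params,
                                               life_table = life_table)
  p1 <- calibrate_initiation(params, life_table = life_table,
                             projection = projection, budget = budget,
                             seed = seed)
  prev_resid <- attr(p1, "residuals"); conv <- attr(p1, "converged")
  p2 <- calibrate_natural_history(p1, seed = seed + 1,
                                  life_table = life_table,
                                  projection = projection,
                                  n_calib = n_calib, n_final = n_final)
  mort_fit <- attr(p2, "mortality_fit")
  anchor <- params$targets$value[params$targets$kind ==
                                   "screening_effectiveness"][1]
  p3 <- calibrate_screening_benefit(p2, anchor = anchor, n = nlst_n,
                                    seed = seed + 2,
                                    life_table = life_table)
  structure(list(params = p3, prevalence = prev_resid, mortality = mort_fit,
                 nlst = attr(p3, "nlst_fit"), converged = conv),
            class = "lcpm_calibration")
}

#' @export
print.lcpm_calibration <- function(x, ...) {
  cat("<lcpm_calibration>\n")
  cat(sprintf("  prevalence: max |rel error| = %.2f%% (%s)\n",
              100 * max(abs(x$prevalence$rel_error)),
              if (isTRUE(x$converged)) "within tolerance" else "NOT converged"))
  cat(sprintf("  2012 deaths: male %.0f (%.2f%%), female %.0f (%.2f%%)\n",
              x$mortality$model[1], 100 * x$mortality$rel_error[1],
              x$mortality$model[2], 100 * x$mortality$rel_error[2]))
  cat(sprintf("  screening anchor: achieved %.1f%% (target %.1f%%), shift %.3f\n",
              x$nlst$achieved, x$nlst$anchor, x$nlst$stage_shift))
  invisible(x)
}
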