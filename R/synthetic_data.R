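# Synthetic stand-ins for the external inputs the model needs but whose
# primary sources are not bundled: other-cause life tables and the Chinese
# population projection. Both are smooth parametric constructions, pure in
# (params, seed); they aim for demographic plausibility, not census fidelity,
# so absolute population-scale outputs are meaningful only relative to them.

#' Synthetic other-cause mortality life table
#'
#' Gompertz-Makeham annual death probabilities by sex,
#' `m(age) = A + B * exp(theta * age)`, stratified into smoking-intensity
#' bands (never / light `<20` cpd / heavy `>=20` cpd) by multiplicative
#' factors. Probabilities are capped at 1; rates are monotone in age above
#' 40 by construction.
#'
#' @param params Parameter bundle (uses the `other_cause` block).
#' @param seed Unused (the construction is deterministic); accepted so all
#'   generators share the `(params, seed)` signature.
#' @return An `lcpm_life_table`: array `[sex, age 15-84, band]` of annual
#'   probabilities.
#' @export
generate_life_tables <- function(params, seed = NULL) {
  oc <- params$other_cause
  ages <- AGES
  bands <- names(oc$band_multipliers)
  arr <- array(NA_real_, c(2, length(ages), 3),
               dimnames = list(SEXES, ages, bands))
  for (s in SEXES) {
    base <- oc$makeham_a[[s]] + oc$gompertz_b[[s]] *
      exp(oc$gompertz_theta[[s]] * ages)
    for (b in bands) arr[s, , b] <- pmin(base * oc$band_multipliers[[b]], 1)
  }
  structure(arr, class = "lcpm_life_table", ages = ages)
}

life_table_probs <- function(life_table, sex, ages, band) {
  life_table[sex, as.character(ages), band]
}

#' Life expectancy implied by a life table
#'
#' Expected years lived from `from_age`, with deaths mid-year and survival
#' censored at the simulation exit age of 85, computed analytically from the
#' annual probabilities.
#'
#' @param life_table An `lcpm_life_table`.
#' @param sex `"male"` or `"female"`.
#' @param from_age Starting age (default 15).
#' @param band Smoking-intensity band.
#' @return Expected years lived (numeric).
#' @export
life_expectancy <- function(life_table, sex, from_age = 15, band = "never") {
  ages <- from_age:(EXIT_AGE - 1)
  m <- life_table_probs(life_table, sex, ages, band)
  S_prev <- c(1, cumprod(1 - m))[seq_along(ages)]  # alive entering age t
  pmf <- S_prev * m
  surv_all <- prod(1 - m)
  sum(pmf * (ages - from_age + 0.5)) + surv_all * (EXIT_AGE - from_age)
}

#' Write / read a life table as CSV
#'
#' Plain-text exchange format: columns `sex`, `age`, `band`,
#' `annual_probability`.
#'
#' @param life_table An `lcpm_life_table`.
#' @param path CSV path.
#' @return `read_life_table` returns an `lcpm_life_table`.
#' @export
write_life_table <- function(life_table, path) {
  d <- as.data.frame.table(unclass(life_table), stringsAsFactors = FALSE)
  names(d) <- c("sex", "age", "band", "annual_probability")
  d$age <- as.integer(d$age)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ages <- sort(unique(d$age))
  bands <- c("never", "light", "heavy")
  arr <- array(NA_real_, c(2, length(ages), 3),
               dimnames = list(SEXES, ages, bands))
  arr[cbind(d$sex, as.character(d$age), d$band)] <- d$annual_probability
  structure(arr, class = "lcpm_life_table", ages = ages)
}

#' Synthetic population projection
#'
#' Stand-in for the census projection used to scale simulated cohorts to
#' population counts. Cohort sizes at entry (age 15) follow a smooth logistic
#' rise (20th-century growth) followed by a logistic decline toward a floor
#' (post-transition fertility); cohorts are split by sex and aged forward
#' with the never-band synthetic life table. Deliberately not a census match:
#' with default parameters the adult population is of order one billion.
#'
#' @param params Parameter bundle (uses the `projection` block and the
#'   `other_cause` block through the life table).
#' @param seed Unused; accepted for the common generator signature.
#' @param life_table Optional life table (regenerated if omitted).
#' @return An `lcpm_projection`: list with `years` (1975-2050), `ages`
#'   (15-84) and a `counts` array `[year, age, sex]`.
#' @export
generate_population_projection <- function(params, seed = NULL,
                                           life_table = NULL) {
  pr <- params$projection
  if (is.null(life_table)) life_table <- generate_life_tables(params)
  years <- 1975:2050
  ages <- AGES
  counts <- array(0, c(length(years), length(ages), 2),
                  dimnames = list(years, ages, SEXES))
  entry_size <- function(birth) {
    pr$base_cohort_size *
      stats::plogis(pr$rise_slope * (birth - pr$rise_mid)) *
      (pr$decline_floor + (1 - pr$decline_floor) *
         (1 - stats::plogis(pr$decline_slope * (birth - pr$decline_mid))))
  }
  for (s in SEXES) {
    frac <- if (s == "male") pr$male_fraction else 1 - pr$male_fraction
    m <- life_table_probs(life_table, s, ages, "never")
    S <- c(1, cumprod(1 - m))                # survival from 15 to each age
    for (yi in seq_along(years)) {
      births <- years[yi] - ages
      counts[yi, , s] <- entry_size(births) * frac * S[ages - ENTRY_AGE + 1]
    }
  }
  structure(list(years = years, ages = ages, counts = counts),
            class = "lcpm_projection")
}

projection_count <- function(projection, year, age, sex) {
  yi <- pmin(pmax(year, projection$years[1]),
             projection$years[length(projection$years)]) -
    projection$years[1] + 1
  ai <- age - projection$ages[1] + 1
  si <- ifelse(sex == "male", 1, 2)
  projection$counts[cbind(yi, ai, si)]
}

#' Adult population by calendar year
#'
#' Total persons ages 15-84 in the projection, optionally by sex; the
#' denominator of the screens-per-adult eligibility fraction.
#'
#' @param projection An `lcpm_projection`.
#' @param years Calendar years (default all).
#' @param sex Optional sex restriction.
#' @return Named numeric vector of persons per year.
#' @export
adult_population <- function(projection, years = projection$years, sex = NULL) {
  yi <- match(years, projection$years)
  stopifnot(!anyNA(yi))
  sub <- projection$counts[yi, , , drop = FALSE]
  out <- if (is.null(sex)) apply(sub, 1, sum) else
    apply(sub[, , sex, drop = FALSE], 1, sum)
  stats::setNames(out, years)
}

#' Write a projection as CSV (year, age, sex, count)
#' @param projection An `lcpm_projection`.
#' @param path CSV path.
#' @export
write_projection <- function(projection, path) {
  d <- as.data.frame.table(projection$counts, stringsAsFactors = FALSE)
  names(d) <- c("year", "age", "sex", "count")
  d$year <- as.integer(d$year); d$age <- as.integer(d$age)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  years <- sort(unique(d$year)); ages <- sort(unique(d$age))
  counts <- array(0, c(length(years), length(ages), 2),
                  dimnames = list(years, ages, SEXES))
  counts[cbind(as.character(d$year), as.character(d$age), d$sex)] <- d$count
  structure(list(years = years, ages = ages, counts = counts),
            class = "lcpm_projection")
}

#' Fully specified test persons
#'
#' Samples a small cohort of persons (sex, birth year, smoking history,
#' other-cause death age) for unit tests.
#'
#' @param n Number of persons (`>= 1`).
#' @param sex_mix Proportion male.
#' @param seed Integer seed.
#' @param params Parameter bundle.
#' @param birth_years Range to draw birth cohorts from.
#' @return A `data.frame` of persons.
#' @export
generate_test_cohort <- function(n, sex_mix = 0.5, seed = 1,
                                 params = default_parameters(),
                                 birth_years = 1940:1990) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  lt <- generate_life_tables(params)
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < sex_mix, "male", "female")
  birth <- sample(birth_years, n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    h <- sample_smoking_history(sex[i], birth[i], params, n = 1)
    init <- ifelse(is.na(h$initiation_age), Inf, h$initiation_age)
    quit <- ifelse(is.na(h$quit_age), Inf, h$quit_age)
    ocd <- oc_death_ages(sex[i], birth[i], init, quit, params, lt,
                         stats::runif(1))
    out[[i]] <- data.frame(id = i, sex = sex[i], birth_year = birth[i],
                           initiation_age = h$initiation_age,
                           quit_age = h$quit_age, oc_death_age = ocd,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Perturb calibration targets
#'
#' Multiplies target values by `1 + rel_noise * u`, `u ~ Uniform(-1, 1)`,
#' for exercising calibration failure paths; `rel_noise = 0` returns the
#' targets unchanged.
#'
#' @param targets Target table ([default_targets()] layout).
#' @param rel_noise Relative noise amplitude.
#' @param seed Integer seed.
#' @return Perturbed target table.
#' @export
perturb_targets <- function(targets, rel_noise, seed = 1) {
  set.seed(seed)
  targets$value <- targets$value *
    (1 + rel_noise * stats::runif(nrow(targets), -1, 1))
  targets
}
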