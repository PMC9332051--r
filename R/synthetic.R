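#' Generate synthetic survey records
#'
#' Emulates the statistical structure of a national health-survey extract
#' used to seed the assessment: individual adults aged 20--79 with a
#' diabetes flag drawn per age band at the band's prevalence, years since
#' diagnosis drawn from the band's fitted duration distribution (truncated
#' so nobody was diagnosed before age 18), a positive survey weight whose
#' band totals are proportional to the bands' weight mass, and a
#' social-security flag. Ages are uniform within bands (the model only uses
#' band membership). No attempt is made to mimic a complex survey design
#' (strata, PSUs); weights are a plain positive scale factor.
#'
#' @param profiles Validated age-profile tibble.
#' @param n Number of records (>= 1).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param p_social_security Probability of the social-security flag
#'   (default 0.5).
#' @param durations Optional named list of `ckd_duration` per band; fitted
#'   from `profiles` when omitted.
#' @return Tibble with columns `age_years`, `age_band`, `has_t2dm`,
#'   `years_since_diagnosis` (`NA` for non-diabetic records),
#'   `survey_weight`, `has_social_security`.
#' @examples
#' srv <- generate_survey(load_age_profiles(), 1000, seed = 7)
#' mean(srv$has_t2dm)
#' @export
generate_survey <- function(profiles, n, seed, p_social_security = 0.5,
                            durations = NULL) {
  # structural validation on a clamped copy: the generator itself accepts
  # degenerate prevalence (including 0) for stress scenarios
  original_prevalence <- setNames(profiles$prevalence, profiles$age_band)
  clamped <- profiles
  clamped$prevalence <- pmin(pmax(profiles$prevalence, 1e-9), 1 - 1e-9)
  profiles <- validate_age_profiles(clamped)
  profiles$prevalence <- unname(original_prevalence[profiles$age_band])
  if (!is.numeric(n) || n < 1) {
    abort("n must be a positive count", class = "ckd_argument_error")
  }
  n <- as.integer(n)
  if (any(profiles$prevalence < 0 | profiles$prevalence >= 1)) {
    abort("Prevalence must be a fraction in [0, 1)", class = "ckd_argument_error")
  }
  if (is.null(durations)) durations <- fit_band_durations(clamped)
  set.seed(as.integer(seed))

  band_p <- profiles$weight_mass / sum(profiles$weight_mass)
  band_idx <- sample.int(nrow(profiles), n, replace = TRUE, prob = band_p)
  age <- profiles$age_min[band_idx] +
    floor(runif(n) * (profiles$age_max[band_idx] - profiles$age_min[band_idx] + 1))
  has_t2dm <- runif(n) < profiles$prevalence[band_idx]

  dur <- rep(NA_real_, n)
  for (b in seq_len(nrow(profiles))) {
    idx <- which(band_idx == b & has_t2dm)
    if (length(idx) == 0) next
    draws <- durations[[profiles$age_band[b]]]$sampler(length(idx))
    # diagnosis is an adult-onset event here: cap at age - 18
    dur[idx] <- pmin(draws, age[idx] - 18)
  }

  base_w <- profiles$weight_mass[band_idx] / (n * band_p[band_idx])
  weight <- base_w * rgamma(n, shape = 4, rate = 4)

  tibble::tibble(
    age_years = as.integer(age),
    age_band = profiles$age_band[band_idx],
    has_t2dm = has_t2dm,
    years_since_diagnosis = dur,
    survey_weight = weight,
    has_social_security = runif(n) < p_social_security
  )
}

#' Generate a geometric total-population projection
#'
#' Yearly adult population over the horizon growing at a constant annual
#' rate. The default annual rate is the one whose compound effect over 16
#' years is 22% total growth, the published projection this generator
#' stands in for.
#'
#' @param base_2016 Population at the start year (> 0).
#' @param annual_growth Annual growth fraction in (-0.05, 0.05); default
#'   `growth_rate_for_total(0.22, 16)`.
#' @param horizon Years beyond the start year (default 16).
#' @param start_year First calendar year (default 2016).
#' @return Tibble (`year`, `population`).
#' @examples
#' pop <- generate_population(100)
#' pop$population[17]  # 122: 22% above base
#' @export
generate_population <- function(base_2016,
                                annual_growth = growth_rate_for_total(0.22, 16),
                                horizon = 16, start_year = 2016) {
  if (!is.numeric(base_2016) || base_2016 <= 0) {
    abort("base_2016 must be positive", class = "ckd_argument_error")
  }
  if (annual_growth <= -0.05 || annual_growth >= 0.05) {
    abort("annual_growth must lie in (-0.05, 0.05)", class = "ckd_argument_error")
  }
  years <- start_year:(start_year + horizon)
  tibble::tibble(
    year = as.integer(years),
    population = base_2016 * (1 + annual_growth)^(seq_along(years) - 1)
  )
}

#' Annual growth rate matching a total compound growth
#'
#' Solves `(1 + g)^years = 1 + total_growth` for `g`.
#'
#' @param total_growth Total compound growth fraction over the period.
#' @param years Number of annual steps.
#' @return The annual growth fraction.
#' @examples
#' growth_rate_for_total(0.22, 16)
#' @export
growth_rate_for_total <- function(total_growth, years) {
  (1 + total_growth)^(1 / years) - 1
}

#' Generate a constant incidence-rate schedule
#'
#' Yearly type 2 diabetes incidence among non-diabetic adults, constant over
#' the horizon. Incidence values for the original projection were taken
#' from external literature and are not published with the model; this
#' synthetic schedule (optionally calibrated with [calibrate_incidence()])
#' stands in for them.
#'
#' @param rate Annual incidence fraction, strictly inside (0, 0.05).
#' @param horizon Years beyond the start year (default 16).
#' @param start_year First calendar year covered (default 2016; the schedule
#'   runs from the year after, since incidence accrues after baseline).
#' @return Tibble (`year`, `rate`) for `horizon` years after `start_year`.
#' @export
generate_incidence <- function(rate, horizon = 16, start_year = 2016) {
  if (!is.numeric(rate) || rate <= 0 || rate >= 0.05) {
    abort("rate must lie strictly inside (0, 0.05)", class = "ckd_argument_error")
  }
  tibble::tibble(
    year = as.integer((start_year + 1):(start_year + horizon)),
    rate = rep(rate, horizon)
  )
}

#' Calibrate a constant incidence rate to a target cohort trajectory
#'
#' One-dimensional root-find for the constant annual incidence rate under
#' which [cohort_series()] on a given population projection reaches the
#' target final-year cohort exactly.
#'
#' @param prev_2016 Baseline prevalent diabetic persons.
#' @param population Tibble (`year`, `population`) over the horizon.
#' @param target_cohort Tibble (`year`, `cohort`) to match; only years
#'   shared with `population` are used.
#' @return The calibrated rate (fraction).
#' @examples
#' pop <- generate_population(4e7)
#' target <- load_cohort_sizes()
#' calibrate_incidence(target$cohort[1], pop, target)
#' @export
calibrate_incidence <- function(prev_2016, population, target_cohort) {
  years <- intersect(population$year, target_cohort$year)
  if (length(years) < 2) {
    abort("Population and target must share at least two years",
          class = "ckd_argument_error")
  }
  target_final <- target_cohort$cohort[target_cohort$year == max(years)]
  horizon <- length(years) - 1
  start_year <- min(years)
  mismatch <- function(rate) {
    inc <- generate_incidence(rate, horizon = horizon, start_year = start_year)
    series <- cohort_series(prev_2016, inc,
                            population[population$year %in% years, ])
    series$cohort[nrow(series)] - target_final
  }
  uniroot(mismatch, c(1e-6, 0.05 - 1e-6), tol = 1e-10)$root
}

#' Write a synthetic survey to CSV
#'
#' @param survey Tibble from [generate_survey()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path)
  invisible(path)
}
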