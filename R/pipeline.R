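#' Build a yearly diabetic cohort series from incidence and population
#'
#' Accrues the diabetic cohort from a baseline prevalent count: for every
#' year after baseline, the population at risk is the total adult population
#' that year minus the baseline prevalent cases, new cases are the year's
#' incidence rate times the population at risk, and the cohort is the
#' baseline plus cumulative new cases. This is the accounting used when
#' cohort sizes are derived from a population projection and an incidence
#' schedule rather than supplied directly.
#'
#' @param prev_2016 Baseline prevalent diabetic persons (at the first year
#'   of `population`).
#' @param incidence Tibble (`year`, `rate`), annual incidence among
#'   non-diabetic adults, covering every year after baseline.
#' @param population Tibble (`year`, `population`), total adults 20--79.
#' @return Tibble (`year`, `cohort`).
#' @examples
#' pop <- generate_population(1e6, 0, horizon = 3)
#' inc <- generate_incidence(0.01, horizon = 3)
#' cohort_series(1e5, inc, pop)  # adds 9,000 new cases each year
#' @export
cohort_series <- function(prev_2016, incidence, population) {
  stopifnot(is.numeric(prev_2016), prev_2016 > 0)
  years <- sort(population$year)
  rate <- setNames(incidence$rate, incidence$year)
  pop <- setNames(population$population, population$year)
  missing_years <- setdiff(as.character(years[-1]), names(rate))
  if (length(missing_years) > 0) {
    abort(sprintf("Incidence schedule missing year(s): %s",
                  paste(missing_years, collapse = ", ")),
          class = "ckd_configuration_error")
  }
  cohort <- numeric(length(years))
  cohort[1] <- prev_2016
  for (i in seq_along(years)[-1]) {
    yr <- as.character(years[i])
    at_risk <- pop[[yr]] - prev_2016
    if (at_risk < 0) {
      abort(sprintf("Negative population at risk in %s", yr),
            class = "ckd_computation_error")
    }
    cohort[i] <- cohort[i - 1] + rate[[yr]] * at_risk
  }
  tibble::tibble(year = as.integer(years), cohort = cohort)
}

#' Run the full health-needs assessment
#'
#' End-to-end annual-cycle projection of the diabetic cohort through the
#' five nephropathy states. Per age band, prevalent baseline patients are
#' initialized by propagating a pure-normoalbuminuria vector through their
#' completed years since diagnosis (mixed analytically over the band's
#' fitted duration distribution); the baseline cohort is allocated to bands
#' proportionally to survey weight mass and split into a glycemic-controlled
#' stratum (transition bounds selected by `rate_policy_controlled`) and an
#' uncontrolled stratum (`rate_policy_uncontrolled`). Each subsequent year,
#' the cohort-size increment enters as incident patients at pure
#' normoalbuminuria on January 1 and transitions with everyone else at year
#' end. Deaths are retained as a state, so yearly state counts always sum to
#' the accumulated cohort.
#'
#' By default the baseline initialization carries death mass accrued before
#' the start year (the baseline cohort then includes patients already lost
#' to cardiovascular death); with `condition_on_survival = TRUE` in the
#' scenario, the entry mix is renormalized over the alive states instead.
#'
#' This is the deterministic analytic-expectation engine; use
#' [simulate_cohort()] for Monte-Carlo dispersion summaries.
#'
#' @param scenario A `ckd_scenario` (see [load_scenario()]).
#' @param profiles Age-profile tibble; default shipped values.
#' @param table Transition-bound tibble; default shipped values.
#' @param durations Optional named list of `ckd_duration` per age band;
#'   fitted from `profiles` via [fit_band_durations()] when omitted.
#' @param max_duration_years Cap for the completed-years discretization.
#' @return A `ckd_projection`: tibble (`year`, `cohort_size`, `state`,
#'   `count`, `share_pct`) with provenance attributes.
#' @examples
#' proj <- run_assessment(load_scenario())
#' stage_distribution(proj, 2022)
#' @export
run_assessment <- function(scenario = load_scenario(),
                           profiles = load_age_profiles(),
                           table = load_transition_table(),
                           durations = NULL,
                           max_duration_years = 60) {
  stopifnot(inherits(scenario, "ckd_scenario"))
  profiles <- validate_age_profiles(profiles)
  table <- validate_transition_table(table)
  if (is.null(durations)) durations <- fit_band_durations(profiles)
  missing_bands <- setdiff(profiles$age_band, names(durations))
  if (length(missing_bands) > 0) {
    abort(sprintf("No duration distribution for band(s): %s",
                  paste(missing_bands, collapse = ", ")),
          class = "ckd_configuration_error")
  }

  years <- scenario$start_year:(scenario$start_year + scenario$horizon_years)
  cs <- scenario$cohort_sizes
  cohort <- setNames(cs$cohort, cs$year)[as.character(years)]
  if (any(diff(cohort) < 0)) {
    abort("Cohort sizes must be non-decreasing over the horizon (cases accumulate)",
          class = "ckd_computation_error")
  }

  M_ctrl <- build_matrix(table, scenario$rate_policy_controlled)
  M_unc <- build_matrix(table, scenario$rate_policy_uncontrolled)
  f_ctrl <- scenario$control_fraction
  f_unc <- 1 - f_ctrl
  band_w <- profiles$weight_mass / sum(profiles$weight_mass)

  entry_mix <- function(M) {
    mix <- Reduce(`+`, purrr::map2(
      band_w, profiles$age_band,
      function(w, band) {
        w * initialize_from_distribution(durations[[band]], M,
                                         max_years = max_duration_years)
      }
    ))
    if (isTRUE(scenario$condition_on_survival)) {
      mix["DEATH_CV"] <- 0
      mix <- mix / sum(mix)
    }
    mix
  }

  state_ctrl <- entry_mix(M_ctrl) * f_ctrl * cohort[1]
  state_unc <- entry_mix(M_unc) * f_unc * cohort[1]
  e_normo <- c(1, 0, 0, 0, 0)

  occupancy <- matrix(NA_real_, length(years), 5,
                      dimnames = list(years, CKD_STATE_CODES))
  occupancy[1, ] <- state_ctrl + state_unc
  for (i in seq_along(years)[-1]) {
    entrants <- cohort[i] - cohort[i - 1]
    state_ctrl <- as.numeric((state_ctrl + f_ctrl * entrants * e_normo) %*% M_ctrl)
    state_unc <- as.numeric((state_unc + f_unc * entrants * e_normo) %*% M_unc)
    occupancy[i, ] <- state_ctrl + state_unc
  }

  out <- tibble::tibble(
    year = rep(as.integer(years), each = 5),
    cohort_size = rep(as.numeric(cohort), each = 5),
    state = rep(CKD_STATE_CODES, length(years)),
    count = as.numeric(t(occupancy))
  )
  out$share_pct <- out$count / out$cohort_size * 100
  new_projection(
    out,
    scenario = scenario,
    provenance = list(
      seed = scenario$seed,
      policies = c(controlled = scenario$rate_policy_controlled,
                   uncontrolled = scenario$rate_policy_uncontrolled),
      control_fraction = f_ctrl,
      condition_on_survival = isTRUE(scenario$condition_on_survival),
      param_hash = params_hash(profiles, table, cs)
    )
  )
}

new_projection <- function(df, scenario = NULL, provenance = NULL) {
  structure(
    as_tibble(df),
    scenario = scenario,
    provenance = provenance,
    class = c("ckd_projection", class(as_tibble(df)))
  )
}

# md5 over a canonical text serialization of the parameter tables.
params_hash <- function(profiles, table, cohort_sizes) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(c(
    apply(as.data.frame(profiles), 1, paste, collapse = ","),
    apply(as.data.frame(table), 1, paste, collapse = ","),
    apply(as.data.frame(cohort_sizes), 1, paste, collapse = ",")
  ), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a projection table from state counts
#'
#' Builds a `ckd_projection` from a long table of per-year state counts
#' (for instance, published reference counts), recomputing shares from the
#' counts.
#'
#' @param counts Tibble with columns `year`, `cohort_size`, `state`,
#'   `count`.
#' @return A `ckd_projection`.
#' @examples
#' ref <- readr::read_csv(ckd_example("reference_projection.csv"),
#'                        show_col_types = FALSE)
#' as_projection(ref)
#' @export
as_projection <- function(counts) {
  need <- c("year", "cohort_size", "state", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("Projection needs column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ckd_schema_error")
  }
  check_state_codes(counts$state)
  out <- as_tibble(counts[, need])
  out$year <- as.integer(out$year)
  out$share_pct <- out$count / out$cohort_size * 100
  out <- dplyr::arrange(out, .data$year, match(.data$state, CKD_STATE_CODES))
  new_projection(out)
}

#' Stage distribution for one calendar year
#'
#' Percentage of the accumulated diabetic cohort in each health state in a
#' given year (deaths included in the denominator).
#'
#' @param projection A `ckd_projection`.
#' @param year Calendar year within the projection horizon.
#' @return Tibble (`state`, `count`, `share_pct`).
#' @export
stage_distribution <- function(projection, year) {
  if (!year %in% projection$year) {
    abort(sprintf("Year %s is outside the projection horizon (%d-%d)",
                  year, min(projection$year), max(projection$year)),
          class = "ckd_argument_error")
  }
  rows <- projection[projection$year == year, , drop = FALSE]
  tibble::tibble(
    state = rows$state,
    count = rows$count,
    share_pct = rows$count / rows$cohort_size * 100
  )
}

#' Growth of progressed-state counts between two years
#'
#' Percent change of each non-normoalbuminuria state count between two
#' years of a projection; the headline growth figures of the assessment.
#'
#' @param projection A `ckd_projection`.
#' @param y0,y1 Calendar years, `y0 < y1`, both within the horizon.
#' @return Tibble (`state`, `count_y0`, `count_y1`, `growth_pct`); growth is
#'   `NA` where the baseline count is zero (undefined).
#' @export
growth_summary <- function(projection, y0, y1) {
  if (!is.numeric(y0) || !is.numeric(y1) || y0 >= y1) {
    abort("Need y0 < y1", class = "ckd_argument_error")
  }
  for (y in c(y0, y1)) {
    if (!y %in% projection$year) {
      abort(sprintf("Year %s is outside the projection horizon", y),
            class = "ckd_argument_error")
    }
  }
  states <- setdiff(CKD_STATE_CODES, "NORMO")
  a <- projection[projection$year == y0 & projection$state %in% states, ]
  b <- projection[projection$year == y1 & projection$state %in% states, ]
  a <- a[match(states, a$state), ]
  b <- b[match(states, b$state), ]
  tibble::tibble(
    state = states,
    count_y0 = a$count,
    count_y1 = b$count,
    growth_pct = ifelse(a$count == 0, NA_real_,
                        (b$count - a$count) / a$count * 100)
  )
}

#' Write a projection table to CSV
#'
#' One row per year and state with columns `year`, `cohort_size`, `state`,
#' `count`, `share_pct`. Counts are rounded to whole persons and shares to
#' 0.01% at write time only; a `#`-prefixed provenance header records the
#' seed and parameter hash.
#'
#' @param projection A `ckd_projection`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, path) {
  prov <- attr(projection, "provenance")
  header <- sprintf(
    "# ckdneeds projection | seed=%s | params_md5=%s | policies=%s | written=%s",
    prov$seed %||% "NA", prov$param_hash %||% "NA",
    paste(prov$policies %||% "NA", collapse = "/"),
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  out <- as_tibble(projection)[, c("year", "cohort_size", "state", "count",
                                   "share_pct")]
  out$count <- round(out$count)
  out$share_pct <- round(out$share_pct, 2)
  writeLines(c(header, paste(names(out), collapse = ",")), path)
  readr::write_csv(out, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read a projection table written by [write_projection()]
#'
#' @param path CSV path.
#' @return A `ckd_projection`; the provenance header line is parsed back
#'   into the `provenance` attribute.
#' @export
read_projection <- function(path) {
  first <- readLines(path, n = 1)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  prov <- NULL
  if (startsWith(first, "#")) {
    get_field <- function(key) {
      m <- regmatches(first, regexec(paste0(key, "=([^ |]+)"), first))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    prov <- list(seed = as.integer(get_field("seed")),
                 param_hash = get_field("params_md5"))
  }
  proj <- as_projection(df[, c("year", "cohort_size", "state", "count")])
  attr(proj, "provenance") <- prov
  proj
}
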