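#' Path to a shipped default parameter file
#'
#' The package ships its default parameter set as plain-text data files:
#' annual transition-probability intervals (`transition_probabilities.csv`),
#' age-group diabetes prevalence and years-since-diagnosis summaries
#' (`age_profiles.csv`), the yearly diabetic cohort sizes for the population
#' without social security (`cohort_sizes.csv`), the default scenario
#' (`scenario_default.yml`), and the published projection used as a
#' consistency reference (`reference_projection.csv`).
#'
#' @param file File name within the package's `extdata` directory. With no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' ckd_example()
#' ckd_example("transition_probabilities.csv")
#' @export
ckd_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ckdneeds")))
  }
  path <- system.file("extdata", file, package = "ckdneeds")
  if (identical(path, "")) {
    abort(sprintf("No shipped parameter file named '%s'", file),
          class = "ckd_io_error")
  }
  path
}

#' Load an annual transition-probability table
#'
#' Reads the seven annual transition-probability intervals of the nephropathy
#' progression model. The file stores probabilities as percentages (as they
#' are conventionally reported); they are converted to fractions once, at
#' load time. The shipped default carries the UKPDS-derived intervals, e.g.
#' normoalbuminuria to microalbuminuria 1.9--2.2% per year and end-stage
#' renal disease to death 14--24.4% per year.
#'
#' @param path CSV file with columns `from_state`, `to_state`, `p_min_pct`,
#'   `p_max_pct`. Defaults to the shipped table.
#' @return A validated tibble with columns `from_state`, `to_state`, `p_min`,
#'   `p_max` (annual probabilities as fractions in `[0, 1]`).
#' @examples
#' load_transition_table()
#' @seealso [build_matrix()] to turn the intervals into a transition matrix.
#' @export
load_transition_table <- function(path = ckd_example("transition_probabilities.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("from_state", "to_state", "p_min_pct", "p_max_pct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Transition table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ckd_schema_error")
  }
  tab <- tibble::tibble(
    from_state = as.character(raw$from_state),
    to_state = as.character(raw$to_state),
    p_min = raw$p_min_pct / 100,
    p_max = raw$p_max_pct / 100
  )
  validate_transition_table(tab)
}

#' Validate a transition-probability table
#'
#' Checks that a table of annual transition bounds is complete and usable:
#' exactly the seven admissible progression pairs are present, bounds are
#' ordered probabilities, and for every originating state the outgoing upper
#' bounds sum to less than one, so matrix construction can never produce a
#' negative stay probability.
#'
#' @param table Tibble with columns `from_state`, `to_state`, `p_min`,
#'   `p_max` (fractions).
#' @return The table, invisibly unchanged, ordered canonically.
#' @export
validate_transition_table <- function(table) {
  check_state_codes(table$from_state, "from_state")
  check_state_codes(table$to_state, "to_state")
  if (any(table$from_state == table$to_state)) {
    abort("Self-loop transitions must not be stored; stay probabilities are derived",
          class = "ckd_validation_error")
  }
  key <- paste(table$from_state, table$to_state)
  want <- paste(CKD_TRANSITION_PAIRS$from_state, CKD_TRANSITION_PAIRS$to_state)
  missing_pairs <- setdiff(want, key)
  if (length(missing_pairs) > 0) {
    abort(sprintf("Transition table is missing pair(s): %s",
                  paste(missing_pairs, collapse = "; ")),
          class = "ckd_completeness_error")
  }
  extra <- setdiff(key, want)
  if (length(extra) > 0 || nrow(table) != nrow(CKD_TRANSITION_PAIRS)) {
    abort(sprintf("Transition table has unexpected pair(s): %s",
                  paste(extra, collapse = "; ")),
          class = "ckd_validation_error")
  }
  bad <- !(table$p_min >= 0 & table$p_min <= table$p_max & table$p_max <= 1)
  if (any(bad)) {
    abort(sprintf(
      "Invalid bounds (need 0 <= p_min <= p_max <= 1) for %s -> %s: [%g, %g]",
      table$from_state[bad][1], table$to_state[bad][1],
      table$p_min[bad][1], table$p_max[bad][1]
    ), class = "ckd_validation_error")
  }
  sums <- tapply(table$p_max, table$from_state, sum)
  if (any(sums >= 1)) {
    abort(sprintf(
      "Outgoing upper bounds for state %s sum to %g (must be < 1)",
      names(sums)[which(sums >= 1)][1], max(sums)
    ), class = "ckd_validation_error")
  }
  table[order(match(key, want)), , drop = FALSE]
}

#' Write a transition-probability table
#'
#' Inverse of [load_transition_table()]: probabilities are written back as
#' percentages so the file diffs cleanly against published tables.
#'
#' @param table Validated transition table (fractions).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(table, path) {
  table <- validate_transition_table(table)
  out <- tibble::tibble(
    from_state = table$from_state,
    to_state = table$to_state,
    p_min_pct = table$p_min * 100,
    p_max_pct = table$p_max * 100
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Load age-group diabetes profiles
#'
#' Reads the per-age-band summaries driving cohort initialization: total
#' diabetes prevalence (diagnosed and undiagnosed), survey weight mass, and
#' the median and interquartile range of years since diagnosis among the
#' population without social security. The shipped default reproduces the
#' 2016 national survey summaries for six bands covering ages 20--79.
#' Prevalence is converted from percent to fraction at load time.
#'
#' @param path CSV file with columns `age_min`, `age_max`, `prevalence_pct`,
#'   `weight_mass`, `duration_median`, `duration_q25`, `duration_q75`.
#' @return A validated tibble with columns `age_band` (label), `age_min`,
#'   `age_max`, `prevalence` (fraction), `weight_mass`, `duration_median`,
#'   `duration_q25`, `duration_q75`.
#' @examples
#' load_age_profiles()
#' @export
load_age_profiles <- function(path = ckd_example("age_profiles.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("age_min", "age_max", "prevalence_pct", "weight_mass",
            "duration_median", "duration_q25", "duration_q75")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Age profile table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ckd_schema_error")
  }
  prof <- tibble::tibble(
    age_band = sprintf("%d-%d", as.integer(raw$age_min), as.integer(raw$age_max)),
    age_min = as.integer(raw$age_min),
    age_max = as.integer(raw$age_max),
    prevalence = raw$prevalence_pct / 100,
    weight_mass = raw$weight_mass,
    duration_median = raw$duration_median,
    duration_q25 = raw$duration_q25,
    duration_q75 = raw$duration_q75
  )
  validate_age_profiles(prof)
}

#' Validate age-group profiles
#'
#' Requires six non-overlapping age bands jointly covering ages 20--79,
#' prevalence fractions strictly inside (0, 1), positive weight mass, and
#' duration medians lying within their interquartile ranges.
#'
#' @param profiles Tibble as returned by [load_age_profiles()].
#' @return The profiles, ordered by age, invisibly unchanged otherwise.
#' @export
validate_age_profiles <- function(profiles) {
  profiles <- profiles[order(profiles$age_min), , drop = FALSE]
  if (nrow(profiles) != 6) {
    abort(sprintf("Expected 6 age bands, found %d", nrow(profiles)),
          class = "ckd_validation_error")
  }
  if (profiles$age_min[1] != 20 || profiles$age_max[6] != 79) {
    abort("Age bands must cover ages 20-79", class = "ckd_validation_error")
  }
  if (any(profiles$age_max < profiles$age_min)) {
    abort("Age band with age_max < age_min", class = "ckd_validation_error")
  }
  if (any(profiles$age_min[-1] != profiles$age_max[-6] + 1)) {
    abort("Age bands must be non-overlapping and contiguous",
          class = "ckd_validation_error")
  }
  if (any(profiles$prevalence <= 0 | profiles$prevalence >= 1)) {
    abort("Prevalence must lie strictly between 0 and 100 percent",
          class = "ckd_validation_error")
  }
  if (any(profiles$weight_mass <= 0)) {
    abort("Weight mass must be positive", class = "ckd_validation_error")
  }
  bad <- !(profiles$duration_q25 <= profiles$duration_median &
             profiles$duration_median <= profiles$duration_q75)
  if (any(bad)) {
    abort(sprintf(
      "Duration median outside IQR for band %s: median %g, IQR [%g, %g]",
      profiles$age_band[bad][1], profiles$duration_median[bad][1],
      profiles$duration_q25[bad][1], profiles$duration_q75[bad][1]
    ), class = "ckd_validation_error")
  }
  if (any(profiles$duration_q25 < 0)) {
    abort("Durations must be non-negative", class = "ckd_validation_error")
  }
  profiles
}

#' Write age-group profiles
#'
#' Inverse of [load_age_profiles()]; prevalence is written back as percent.
#'
#' @param profiles Validated profile tibble (prevalence as fraction).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_age_profiles <- function(profiles, path) {
  profiles <- validate_age_profiles(profiles)
  out <- tibble::tibble(
    age_min = profiles$age_min,
    age_max = profiles$age_max,
    prevalence_pct = profiles$prevalence * 100,
    weight_mass = profiles$weight_mass,
    duration_median = profiles$duration_median,
    duration_q25 = profiles$duration_q25,
    duration_q75 = profiles$duration_q75
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Load yearly diabetic cohort sizes
#'
#' @param path Two-column CSV (`year`, `cohort`). Defaults to the shipped
#'   2016--2032 series for the diabetic population without social security.
#' @return A tibble with columns `year` (integer) and `cohort` (persons).
#' @export
load_cohort_sizes <- function(path = ckd_example("cohort_sizes.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("year", "cohort") %in% names(raw))) {
    abort("Cohort size file needs columns 'year' and 'cohort'",
          class = "ckd_schema_error")
  }
  if (any(raw$cohort <= 0)) {
    abort("Cohort sizes must be positive", class = "ckd_validation_error")
  }
  tibble::tibble(year = as.integer(raw$year), cohort = as.numeric(raw$cohort))
}

# Scenario defaults mirror the shipped scenario file; used for fill-in when a
# user config omits optional fields.
scenario_defaults <- function() {
  list(
    start_year = 2016L,
    horizon_years = 16L,
    control_fraction = 0.187,
    rate_policy_controlled = "min",
    rate_policy_uncontrolled = "max",
    n_sim = "auto",
    error_bound = 10000,
    seed = 20160101L,
    condition_on_survival = FALSE
  )
}

#' Load an assessment scenario
#'
#' Reads a hierarchical YAML scenario configuration and fills omitted
#' optional fields with the shipped defaults: assessment start 2016, a
#' 16-year horizon, an 18.7% glycemic-control fraction (HbA1c < 7), minimum
#' transition rates for controlled patients and maximum rates for
#' uncontrolled patients, a Monte-Carlo error bound of 10,000 persons, and
#' baseline initialization that carries pre-baseline death mass forward (set
#' `condition_on_survival: true` to renormalize the baseline cohort over the
#' alive states instead).
#'
#' Cohort sizes may be given inline (`cohort_sizes:` mapping year to persons)
#' or via `cohort_sizes_file:` naming a CSV relative to the scenario file.
#'
#' @param path YAML scenario file; defaults to the shipped scenario.
#' @return A `ckd_scenario` object (a validated named list, with a
#'   `cohort_sizes` tibble covering `start_year` to `start_year +
#'   horizon_years`).
#' @examples
#' sc <- load_scenario()
#' sc$control_fraction
#' @export
load_scenario <- function(path = ckd_example("scenario_default.yml")) {
  raw <- yaml::read_yaml(path)
  defaults <- scenario_defaults()
  required <- c("start_year", "horizon_years", "control_fraction")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    abort(sprintf("Scenario is missing required field(s): %s",
                  paste(missing_req, collapse = ", ")),
          class = "ckd_schema_error")
  }
  sc <- utils::modifyList(defaults, raw[!vapply(raw, is.null, logical(1))])

  if (!is.null(sc[["cohort_sizes"]])) {
    cs <- tibble::tibble(
      year = as.integer(names(sc[["cohort_sizes"]])),
      cohort = as.numeric(unlist(sc[["cohort_sizes"]], use.names = FALSE))
    )
  } else {
    file <- sc[["cohort_sizes_file"]] %||% "cohort_sizes.csv"
    candidate <- file.path(dirname(path), file)
    if (!file.exists(candidate)) candidate <- ckd_example(file)
    cs <- load_cohort_sizes(candidate)
  }
  sc$cohort_sizes <- cs[order(cs$year), , drop = FALSE]
  sc$cohort_sizes_file <- NULL
  validate_scenario(sc)
}

#' Validate a scenario configuration
#'
#' @param scenario Named list of scenario fields including a `cohort_sizes`
#'   tibble.
#' @return The scenario as a `ckd_scenario` object.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  if (sc$horizon_years < 1) {
    abort("horizon_years must be at least 1", class = "ckd_validation_error")
  }
  if (sc$control_fraction < 0 || sc$control_fraction > 1) {
    abort(sprintf("control_fraction must be in [0, 1], got %g",
                  sc$control_fraction), class = "ckd_validation_error")
  }
  for (field in c("rate_policy_controlled", "rate_policy_uncontrolled")) {
    if (!sc[[field]] %in% c("min", "max", "midpoint")) {
      abort(sprintf("%s must be one of min, max, midpoint (got '%s')",
                    field, sc[[field]]), class = "ckd_validation_error")
    }
  }
  if (!identical(sc$n_sim, "auto") &&
      (!is.numeric(sc$n_sim) || sc$n_sim < 1)) {
    abort("n_sim must be 'auto' or a positive count",
          class = "ckd_validation_error")
  }
  if (sc$error_bound <= 0) {
    abort("error_bound must be positive persons", class = "ckd_validation_error")
  }
  if (any(sc$cohort_sizes$cohort <= 0)) {
    abort("Cohort sizes must be positive", class = "ckd_validation_error")
  }
  years <- sc$start_year:(sc$start_year + sc$horizon_years)
  missing_years <- setdiff(years, sc$cohort_sizes$year)
  if (length(missing_years) > 0) {
    abort(sprintf("Cohort sizes missing for year(s): %s",
                  paste(missing_years, collapse = ", ")),
          class = "ckd_validation_error")
  }
  sc$start_year <- as.integer(sc$start_year)
  sc$horizon_years <- as.integer(sc$horizon_years)
  sc$seed <- as.integer(sc$seed)
  sc$cohort_sizes <- sc$cohort_sizes[sc$cohort_sizes$year %in% years, ,
                                     drop = FALSE]
  structure(sc, class = "ckd_scenario")
}

#' Write a scenario configuration
#'
#' Inverse of [load_scenario()]; cohort sizes are written inline so the file
#' round-trips without companion files.
#'
#' @param scenario A `ckd_scenario`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  out <- unclass(scenario)
  cs <- out$cohort_sizes
  out$cohort_sizes <- as.list(setNames(cs$cohort, as.character(cs$year)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.ckd_scenario <- function(x, ...) {
  cat("<ckd_scenario>\n")
  cat(sprintf("  years: %d-%d (horizon %d)\n", x$start_year,
              x$start_year + x$horizon_years, x$horizon_years))
  cat(sprintf("  control fraction: %.1f%% (policy %s); uncontrolled policy %s\n",
              x$control_fraction * 100, x$rate_policy_controlled,
              x$rate_policy_uncontrolled))
  cat(sprintf("  baseline cohort: %s persons\n",
              format(x$cohort_sizes$cohort[1], big.mark = ",")))
  cat(sprintf("  seed: %d; n_sim: %s; error bound: %s persons\n", x$seed,
              as.character(x$n_sim), format(x$error_bound, big.mark = ",")))
  invisible(x)
}
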