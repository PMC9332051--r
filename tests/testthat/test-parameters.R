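test_that("shipped defaults reproduce the published parameter set", {
  # transition bounds (fractions after load-time percent conversion)
  tab <- default_table
  key <- paste(tab$from_state, tab$to_state)
  bounds <- setNames(asplit(cbind(tab$p_min, tab$p_max), 1), key)
  expect_equal(bounds[["NORMO MICRO"]], c(0.019, 0.022), ignore_attr = TRUE)
  expect_equal(bounds[["MICRO MACRO"]], c(0.025, 0.032), ignore_attr = TRUE)
  expect_equal(bounds[["MACRO ESRD"]], c(0.015, 0.030), ignore_attr = TRUE)
  expect_equal(bounds[["NORMO DEATH_CV"]], c(0.013, 0.015), ignore_attr = TRUE)
  expect_equal(bounds[["MICRO DEATH_CV"]], c(0.026, 0.034), ignore_attr = TRUE)
  expect_equal(bounds[["MACRO DEATH_CV"]], c(0.036, 0.057), ignore_attr = TRUE)
  expect_equal(bounds[["ESRD DEATH_CV"]], c(0.140, 0.244), ignore_attr = TRUE)

  # age-group profiles
  prof <- default_profiles
  expect_equal(prof$prevalence * 100, c(3.3, 3.2, 13.8, 26.9, 36.5, 25.5))
  expect_equal(prof$duration_median, c(2, 5, 5, 9, 10, 15))
  expect_equal(prof$weight_mass,
               c(65962, 127191, 562243, 946925, 1185025, 263384))
  p7079 <- prof[prof$age_band == "70-79", ]
  expect_equal(p7079$prevalence, 0.255)
  expect_equal(c(p7079$duration_q25, p7079$duration_q75), c(10, 22))
  p2029 <- prof[prof$age_band == "20-29", ]
  expect_equal(c(p2029$duration_q25, p2029$duration_median, p2029$duration_q75),
               c(1, 2, 2))

  # scenario
  sc <- default_scenario
  expect_identical(sc$start_year, 2016L)
  expect_identical(sc$horizon_years, 16L)
  expect_equal(sc$control_fraction, 0.187)
  expect_equal(sc$cohort_sizes$cohort[sc$cohort_sizes$year == 2016], 5449204)
  expect_equal(sc$cohort_sizes$cohort[sc$cohort_sizes$year == 2032], 10217299)
})

test_that("five states are defined with a single absorbing death state", {
  st <- ckd_states()
  expect_equal(nrow(st), 5)
  expect_identical(st$code[st$absorbing], "DEATH_CV")
  expect_false(st$absorbing[st$code == "ESRD"])
})

test_that("transition-table validation rejects malformed input", {
  inverted <- default_table
  inverted$p_min[1] <- 0.03
  inverted$p_max[1] <- 0.02
  expect_error(validate_transition_table(inverted), class = "ckd_validation_error")

  incomplete <- default_table[default_table$to_state != "DEATH_CV" |
                                default_table$from_state != "MICRO", ]
  expect_error(validate_transition_table(incomplete),
               class = "ckd_completeness_error")

  renamed <- default_table
  renamed$from_state[1] <- "NORMAL"
  expect_error(validate_transition_table(renamed), class = "ckd_parse_error")

  heavy <- default_table
  heavy$p_max[heavy$from_state == "ESRD"] <- 1.0
  expect_error(validate_transition_table(heavy), class = "ckd_validation_error")
})

test_that("outgoing upper-bound sums leave positive stay probability", {
  sums <- tapply(default_table$p_max, default_table$from_state, sum)
  expect_true(all(1 - sums > 0))
})

test_that("age-profile validation rejects inconsistent bands", {
  bad_iqr <- default_profiles
  bad_iqr$duration_q25[3] <- 5
  bad_iqr$duration_q75[3] <- 3
  bad_iqr$duration_median[3] <- 4
  expect_error(validate_age_profiles(bad_iqr), class = "ckd_validation_error")

  overlapping <- default_profiles
  overlapping$age_min[2] <- 25
  expect_error(validate_age_profiles(overlapping), class = "ckd_validation_error")

  out_of_range <- default_profiles
  out_of_range$prevalence[1] <- 1.2
  expect_error(validate_age_profiles(out_of_range), class = "ckd_validation_error")
})

test_that("scenario validation enforces field ranges and fills defaults", {
  expect_error(make_scenario(control_fraction = 1.5),
               class = "ckd_validation_error")
  expect_error(make_scenario(rate_policy_uncontrolled = "maximal"),
               class = "ckd_validation_error")
  expect_error(make_scenario(error_bound = -1), class = "ckd_validation_error")

  # omitting optional fields falls back to documented defaults
  minimal <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(
    start_year = 2016, horizon_years = 2, control_fraction = 0.2,
    cohort_sizes = list(`2016` = 100, `2017` = 110, `2018` = 120)
  ), minimal)
  sc <- load_scenario(minimal)
  expect_identical(sc$seed, 20160101L)
  expect_identical(sc$rate_policy_uncontrolled, "max")
  expect_false(sc$condition_on_survival)

  # missing required field names the field
  broken <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(start_year = 2016, horizon_years = 2), broken)
  expect_error(load_scenario(broken), "control_fraction",
               class = "ckd_schema_error")
})

test_that("parameter files round-trip through write and reload", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(default_table, tmp)
  expect_equal(load_transition_table(tmp), default_table)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_age_profiles(default_profiles, tmp2)
  expect_equal(load_age_profiles(tmp2), default_profiles)

  tmp3 <- withr::local_tempfile(fileext = ".yml")
  write_scenario(default_scenario, tmp3)
  sc2 <- load_scenario(tmp3)
  expect_equal(unclass(sc2), unclass(default_scenario))
})
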