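max_matrix <- build_matrix(default_table, "max")
min_matrix <- build_matrix(default_table, "min")
pure_normo <- c(1, 0, 0, 0, 0)

test_that("matrix rows follow directly from the selected bounds", {
  expect_equal(max_matrix["NORMO", ],
               c(NORMO = 0.963, MICRO = 0.022, MACRO = 0, ESRD = 0,
                 DEATH_CV = 0.015))
  expect_equal(max_matrix["ESRD", ],
               c(NORMO = 0, MICRO = 0, MACRO = 0, ESRD = 0.756,
                 DEATH_CV = 0.244))
  expect_equal(min_matrix["MICRO", "MICRO"], 1 - 0.025 - 0.026)
  mid <- build_matrix(default_table, "midpoint")
  expect_equal(mid["NORMO", "MICRO"], (0.019 + 0.022) / 2)
})

test_that("matrices are row-stochastic with an absorbing death state", {
  for (policy in c("min", "max", "midpoint")) {
    M <- build_matrix(default_table, policy)
    expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0))
    expect_equal(unname(M["DEATH_CV", ]), c(0, 0, 0, 0, 1))
    # only admissible pairs are nonzero off-diagonal
    off <- which(M > 0 & row(M) != col(M), arr.ind = TRUE)
    pairs <- paste(rownames(M)[off[, 1]], colnames(M)[off[, 2]])
    admissible <- paste(ckdneeds:::CKD_TRANSITION_PAIRS$from_state,
                        ckdneeds:::CKD_TRANSITION_PAIRS$to_state)
    expect_true(all(pairs %in% admissible))
  }
})

test_that("matrix construction refuses rows that would go negative", {
  # a single large exit probability is fine (stay probability stays positive)
  heavy <- default_table
  heavy$p_min[heavy$from_state == "ESRD"] <- 0.9
  heavy$p_max[heavy$from_state == "ESRD"] <- 0.9
  expect_silent(build_matrix(heavy, "max"))
  # two exits summing to >= 1 are rejected before any matrix is built
  heavier <- default_table
  heavier$p_max[heavier$from_state == "MACRO"] <- c(0.5, 0.51)
  expect_error(build_matrix(heavier, "max"), class = "ckd_validation_error")
})

test_that("propagation conserves mass and matches closed forms", {
  # identity matrix freezes any occupancy
  frozen <- build_matrix(zero_table(), "max")
  traj <- propagate(c(10, 20, 30, 5, 35), frozen, 4)
  for (i in 1:5) {
    expect_equal(unlist(traj[i, -1]), c(NORMO = 10, MICRO = 20, MACRO = 30,
                                        ESRD = 5, DEATH_CV = 35))
  }

  one <- propagate(pure_normo, max_matrix, 1)
  expect_equal(unlist(one[2, -1]),
               c(NORMO = 0.963, MICRO = 0.022, MACRO = 0, ESRD = 0,
                 DEATH_CV = 0.015))

  ten <- propagate(pure_normo, max_matrix, 10)
  expect_equal(ten$NORMO[11], 0.963^10, tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    v <- runif(5)
    traj <- propagate(v, max_matrix, 20)
    sums <- rowSums(traj[, -1])
    expect_equal(sums, rep(sum(v), 21), tolerance = 1e-9 * sum(v))
  }

  expect_error(propagate(pure_normo, max_matrix, -1),
               class = "ckd_argument_error")
})

test_that("duration-based initialization is matrix powering with floor()", {
  expect_equal(initialize_from_duration(0, max_matrix),
               c(NORMO = 1, MICRO = 0, MACRO = 0, ESRD = 0, DEATH_CV = 0))
  expect_equal(unname(initialize_from_duration(1, max_matrix)),
               c(0.963, 0.022, 0, 0, 0.015))
  expect_equal(initialize_from_duration(15, max_matrix)[["NORMO"]], 0.963^15,
               tolerance = 1e-12)
  # fractional years truncate to completed cycles
  expect_equal(initialize_from_duration(1.9, max_matrix),
               initialize_from_duration(1, max_matrix))
  expect_error(initialize_from_duration(-1, max_matrix),
               class = "ckd_argument_error")
})

test_that("distribution-mixed initialization equals the sampled average", {
  fit <- fit_from_quantiles(10, c(5, 13))
  analytic <- initialize_from_distribution(fit, max_matrix)
  draws <- sample_durations(fit, 50000, seed = 21)
  sampled <- Reduce(`+`, lapply(floor(draws), function(d) {
    unname(initialize_from_duration(d, max_matrix))
  })) / length(draws)
  expect_equal(unname(analytic), sampled, tolerance = 0.005)
  expect_equal(sum(analytic), 1, tolerance = 1e-9)
})

test_that("sample-size rule matches its formula and rounding", {
  # bound 10,000 persons on a 5,449,204-person cohort at worst-case p
  n <- required_n(10000, 5449204)
  expect_identical(n, 80000L)
  expect_identical(n %% 10000L, 0L)
  # realized scaled SE is below the bound at n, above it one rounding step
  # earlier
  se <- function(n) 5449204 * sqrt(0.25 / n)
  expect_lt(se(n), 10000)
  expect_gt(se(n - 10000L), 10000)

  expect_identical(required_n(5449204 / 2, 5449204), 10000L)
  expect_identical(required_n(100, 1000, worst_case_p = 0), 10000L)
  expect_error(required_n(6e6, 5449204), class = "ckd_argument_error")
  expect_error(required_n(0, 100), class = "ckd_argument_error")
})

test_that("simulated one-year transitions match their binomial law", {
  n <- 100000
  sim <- simulate_cohort(rep("NORMO", n), max_matrix, 1, seed = 42)
  micro <- sim$counts$count[sim$counts$step == 1 & sim$counts$state == "MICRO"]
  expected <- n * 0.022
  sd4 <- 4 * sqrt(n * 0.022 * (1 - 0.022))
  expect_lt(abs(micro - expected), sd4)
})

test_that("an identity matrix freezes every simulated individual", {
  frozen <- build_matrix(zero_table(), "max")
  init <- rep(c("NORMO", "MACRO"), each = 500)
  sim <- simulate_cohort(init, frozen, 5, seed = 1)
  for (s in 0:5) {
    cnt <- sim$counts[sim$counts$step == s, ]
    expect_equal(cnt$count[cnt$state == "NORMO"], 500)
    expect_equal(cnt$count[cnt$state == "MACRO"], 500)
  }
})

test_that("Monte-Carlo means agree with analytic expectation", {
  n <- 200000
  sim <- simulate_cohort(rep("NORMO", n), max_matrix, 16, seed = 8)
  analytic <- propagate(n * pure_normo, max_matrix, 16)
  for (state in ckd_states()$code) {
    exp_counts <- analytic[[state]]
    got <- sim$counts$count[sim$counts$state == state]
    se <- sqrt(pmax(exp_counts * (1 - exp_counts / n), 1))
    expect_true(all(abs(got - exp_counts) < 5 * se),
                info = sprintf("state %s deviates beyond 5 SE", state))
  }
})

test_that("simulation is reproducible and rejects empty cohorts", {
  a <- simulate_cohort(rep("NORMO", 200), max_matrix, 3, seed = 13)
  b <- simulate_cohort(rep("NORMO", 200), max_matrix, 3, seed = 13)
  expect_identical(a$counts, b$counts)
  expect_identical(a$summary, b$summary)
  expect_error(simulate_cohort(character(0), max_matrix, 3, seed = 1),
               class = "ckd_argument_error")
})

test_that("simulation quantiles are ordered and centered on the mean", {
  sim <- simulate_cohort(rep("NORMO", 20000), max_matrix, 5, seed = 3)
  s <- sim$summary
  expect_true(all(s$q2.5 <= s$q25 & s$q25 <= s$q50 &
                    s$q50 <= s$q75 & s$q75 <= s$q97.5))
  # the block-quantile envelope brackets the mean wherever occupancy is
  # large enough for the blocks to resolve it (for near-empty states the
  # block counts are almost all zero and the envelope degenerates)
  populated <- s$mean >= 100
  expect_true(any(populated))
  expect_true(all(s$mean[populated] >= s$q2.5[populated] &
                    s$mean[populated] <= s$q97.5[populated]))
})

test_that("death mass is monotone and eventually absorbs everything", {
  traj <- propagate(pure_normo, max_matrix, 500)
  expect_true(all(diff(traj$DEATH_CV) >= 0))
  expect_equal(traj$DEATH_CV[501], 1, tolerance = 1e-6)

  # max-rate deaths dominate min-rate deaths pointwise in time
  dmax <- propagate(pure_normo, max_matrix, 30)$DEATH_CV
  dmin <- propagate(pure_normo, min_matrix, 30)$DEATH_CV
  expect_true(all(dmax >= dmin))
})

test_that("empirical one-step frequencies recover the matrix entries", {
  # ~1e6 person-years: 100,000 individuals over 10 years from a mixed start
  init <- rep(c("NORMO", "MICRO", "MACRO", "ESRD"), times = c(4, 3, 2, 1) * 10000)
  sim <- simulate_cohort(init, max_matrix, 10, seed = 17,
                         keep_trajectories = TRUE)
  st <- sim$trajectories
  from <- as.vector(st[, -ncol(st)])
  to <- as.vector(st[, -1])
  pairs <- ckdneeds:::CKD_TRANSITION_PAIRS
  for (i in seq_len(nrow(pairs))) {
    f <- match(pairs$from_state[i], ckd_states()$code)
    t_ <- match(pairs$to_state[i], ckd_states()$code)
    exposure <- sum(from == f)
    hits <- sum(from == f & to == t_)
    p <- max_matrix[pairs$from_state[i], pairs$to_state[i]]
    # seven simultaneous two-sided comparisons: Bonferroni-adjusted 99%
    # family confidence interval
    ci_half <- qnorm(1 - 0.01 / 14) * sqrt(p * (1 - p) / exposure)
    expect_lt(abs(hits / exposure - p), ci_half + 1 / exposure)
  }
})

test_that("expected sojourn in ESRD matches the geometric closed form", {
  # single exit rate p: expected sojourn 1/p years (~4.10 at p = 0.244)
  n <- 20000
  sim <- simulate_cohort(rep("ESRD", n), max_matrix, 80, seed = 23,
                         keep_trajectories = TRUE)
  st <- sim$trajectories
  years_alive <- rowSums(st == 4)  # cycles spent in ESRD before absorption
  expect_true(all(st[, ncol(st)] == 5))  # everyone absorbed by 80 years
  closed_form <- 1 / 0.244
  se <- sd(years_alive) / sqrt(n)
  expect_lt(abs(mean(years_alive) - closed_form), 4 * se)
})

test_that("simulation results export to CSV and JSON", {
  sim <- simulate_cohort(rep("NORMO", 500), max_matrix, 3, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_setequal(unique(back$statistic),
                  c("count", "mean", "var", "q2.5", "q25", "q50", "q75", "q97.5"))
  total <- back$value[back$statistic == "count" & back$step == 3]
  expect_equal(sum(total), 500)

  js <- withr::local_tempfile(fileext = ".json")
  write_simulation(sim, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_sim, 500)
})
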