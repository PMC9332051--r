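#' Build an annual transition matrix from probability bounds
#'
#' Constructs the 5x5 one-year transition matrix of the nephropathy chain.
#' Each of the seven admissible off-diagonal transitions is set to the bound
#' selected by `policy` — the lower bound (`"min"`), upper bound (`"max"`),
#' or interval midpoint (`"midpoint"`, offered for sensitivity analysis) —
#' and each diagonal entry is the complement of its row's outgoing
#' probabilities, so rows are exactly stochastic. Cardiovascular death is
#' absorbing by construction. The reported annual rates are treated directly
#' as one-cycle transition probabilities (no hazard conversion), matching
#' their origin as annual probabilities in a discrete-time chain; competing
#' risks within a cycle are resolved by direct row construction, which is
#' valid because outgoing sums stay well below one.
#'
#' @param table Validated transition-bound tibble (see
#'   [load_transition_table()]).
#' @param policy One of `"min"`, `"max"`, `"midpoint"`.
#' @return A 5x5 row-stochastic matrix with states as dimnames and a
#'   `policy` attribute.
#' @examples
#' M <- build_matrix(load_transition_table(), "max")
#' M["NORMO", ]  # stay 0.963, to MICRO 0.022, to DEATH_CV 0.015
#' @export
build_matrix <- function(table, policy = c("max", "min", "midpoint")) {
  policy <- match.arg(policy)
  table <- validate_transition_table(table)
  p <- switch(policy,
    min = table$p_min,
    max = table$p_max,
    midpoint = (table$p_min + table$p_max) / 2
  )
  M <- matrix(0, 5, 5, dimnames = list(CKD_STATE_CODES, CKD_STATE_CODES))
  for (i in seq_len(nrow(table))) {
    M[table$from_state[i], table$to_state[i]] <- p[i]
  }
  out_sums <- rowSums(M)
  if (any(out_sums >= 1)) {
    bad <- CKD_STATE_CODES[which(out_sums >= 1)][1]
    abort(sprintf(
      "Outgoing probabilities for state %s sum to %g under policy '%s' (must be < 1)",
      bad, out_sums[bad], policy
    ), class = "ckd_construction_error")
  }
  diag(M) <- 1 - out_sums
  attr(M, "policy") <- policy
  M
}

#' Propagate a state vector through annual cycles
#'
#' Analytic expectation propagation: the initial occupancy vector is
#' repeatedly left-multiplied by the one-year transition matrix. Because
#' death is retained as a model state, total mass is conserved at every
#' step.
#'
#' @param init Numeric length-5 occupancy vector (probabilities or persons),
#'   optionally named by state code.
#' @param matrix 5x5 transition matrix from [build_matrix()].
#' @param n_years Number of annual cycles (non-negative integer).
#' @return A tibble with `step` (0 to `n_years`) and one column per state;
#'   row 0 is `init`.
#' @examples
#' M <- build_matrix(load_transition_table(), "max")
#' propagate(c(1, 0, 0, 0, 0), M, 3)
#' @export
propagate <- function(init, matrix, n_years) {
  init <- as_state_vector(init)
  if (!is.numeric(n_years) || n_years < 0) {
    abort("n_years must be a non-negative count", class = "ckd_argument_error")
  }
  n_years <- as.integer(n_years)
  out <- matrix(NA_real_, n_years + 1, 5,
                dimnames = list(NULL, CKD_STATE_CODES))
  out[1, ] <- init
  cur <- init
  for (i in seq_len(n_years)) {
    cur <- as.numeric(cur %*% matrix)
    out[i + 1, ] <- cur
  }
  dplyr::bind_cols(tibble::tibble(step = 0:n_years), as_tibble(out))
}

as_state_vector <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, CKD_STATE_CODES])
  if (length(x) != 5 || any(!is.finite(x)) || any(x < 0)) {
    abort("A state vector is 5 finite non-negative numbers",
          class = "ckd_argument_error")
  }
  if (!is.null(names(x))) x <- x[CKD_STATE_CODES]
  setNames(as.numeric(x), CKD_STATE_CODES)
}

#' Initialize a prevalent patient from elapsed disease duration
#'
#' A patient diagnosed `duration_years` ago is assumed to have entered the
#' chain at normoalbuminuria at diagnosis; the occupancy mix at model entry
#' is obtained by propagating a pure-normoalbuminuria vector through
#' `floor(duration_years)` completed annual cycles. Death mass accumulated
#' before entry is retained in the returned vector; whether the pipeline
#' keeps or renormalizes it is a separate, explicit choice.
#'
#' @param duration_years Non-negative years since diagnosis.
#' @param matrix 5x5 transition matrix.
#' @return Named length-5 probability vector.
#' @examples
#' M <- build_matrix(load_transition_table(), "max")
#' initialize_from_duration(0, M)   # pure normoalbuminuria
#' initialize_from_duration(15, M)  # NORMO component 0.963^15
#' @export
initialize_from_duration <- function(duration_years, matrix) {
  if (!is.numeric(duration_years) || duration_years < 0) {
    abort("duration_years must be non-negative", class = "ckd_argument_error")
  }
  steps <- floor(duration_years)
  res <- propagate(c(1, 0, 0, 0, 0), matrix, steps)
  as_state_vector(res[nrow(res), CKD_STATE_CODES])
}

#' Expected entry mix for a duration distribution
#'
#' Analytic counterpart of sampling durations and averaging
#' [initialize_from_duration()] over them: the distribution of completed
#' years since diagnosis is discretized exactly (`P(floor(D) = d)` from the
#' fitted CDF) and the occupancy vectors after `d` cycles are mixed with
#' those probabilities.
#'
#' @param dist A `ckd_duration` distribution.
#' @param matrix 5x5 transition matrix.
#' @param max_years Discretization cap; tail mass beyond it is assigned to
#'   the cap (default 60 completed years).
#' @return Named length-5 probability vector.
#' @export
initialize_from_distribution <- function(dist, matrix, max_years = 60) {
  stopifnot(inherits(dist, "ckd_duration"))
  pm <- completed_year_probs(dist, max_years)
  traj <- propagate(c(1, 0, 0, 0, 0), matrix, max_years)
  mix <- as.numeric(pm %*% as.matrix(traj[, CKD_STATE_CODES]))
  as_state_vector(mix)
}

#' Monte-Carlo sample size for a bounded count error
#'
#' Smallest number of simulated individuals such that the binomial standard
#' error of a state count, scaled to the cohort, stays below a given bound:
#' the least `n` with `cohort_size * sqrt(p (1 - p) / n) < error_bound`,
#' evaluated at a worst-case occupancy probability (1/2 by default) and
#' rounded up to the next 10,000.
#'
#' @param error_bound Tolerated standard error, in persons (> 0).
#' @param cohort_size Real cohort the simulation is scaled to (> bound).
#' @param worst_case_p Occupancy probability maximizing the variance
#'   (default 0.5).
#' @return Integer sample size (a multiple of 10,000, at least 10,000).
#' @examples
#' required_n(10000, 5449204)  # 80,000 simulated individuals
#' @export
required_n <- function(error_bound, cohort_size, worst_case_p = 0.5) {
  if (!is.numeric(error_bound) || error_bound <= 0) {
    abort("error_bound must be positive", class = "ckd_argument_error")
  }
  if (!is.numeric(cohort_size) || cohort_size <= 0) {
    abort("cohort_size must be positive", class = "ckd_argument_error")
  }
  if (error_bound >= cohort_size) {
    abort("error_bound must be smaller than the cohort size (bound is vacuous)",
          class = "ckd_argument_error")
  }
  if (worst_case_p < 0 || worst_case_p > 1) {
    abort("worst_case_p must be in [0, 1]", class = "ckd_argument_error")
  }
  variance <- worst_case_p * (1 - worst_case_p)
  n_raw <- if (variance == 0) 1 else
    ceiling(cohort_size^2 * variance / error_bound^2)
  as.integer(max(1, ceiling(n_raw / 10000)) * 10000)
}

#' Simulate individual patient trajectories
#'
#' Individual-level Monte-Carlo counterpart of [propagate()]: each simulated
#' patient draws its next state every year from the categorical distribution
#' given by its current matrix row. Draws are made year by year (one uniform
#' per individual per year, individuals in their input order), so a fixed
#' seed yields identical output. Per-year state counts are aggregated, and
#' mean, variance and occupancy quantiles are estimated across contiguous
#' blocks of individuals (block totals rescaled to the full sample).
#'
#' @param init_states Character vector of starting state codes, one per
#'   individual.
#' @param matrix 5x5 transition matrix.
#' @param n_years Number of annual cycles.
#' @param seed Integer seed.
#' @param n_blocks Number of bootstrap-style blocks for the dispersion
#'   summaries (default 50).
#' @param keep_trajectories Keep the full individual-by-year state matrix
#'   (integer codes); needed for transition-frequency diagnostics.
#' @return A `ckd_simulation` object: list with `counts` (tibble: `step`,
#'   `state`, `count`), `summary` (tibble: `step`, `state`, `mean`, `var`
#'   and quantiles `q2.5`, `q25`, `q50`, `q75`, `q97.5` across scaled
#'   blocks), `n_sim`, `seed`, and optionally `trajectories`.
#' @examples
#' M <- build_matrix(load_transition_table(), "max")
#' sim <- simulate_cohort(rep("NORMO", 1000), M, 5, seed = 1)
#' tidy(sim)
#' @export
simulate_cohort <- function(init_states, matrix, n_years, seed,
                            n_blocks = 50, keep_trajectories = FALSE) {
  if (length(init_states) < 1) {
    abort("At least one individual is required", class = "ckd_argument_error")
  }
  check_state_codes(init_states, "initial state")
  n <- length(init_states)
  n_years <- as.integer(n_years)
  set.seed(as.integer(seed))

  cum <- t(apply(matrix, 1, cumsum))
  states <- matrix(NA_integer_, n, n_years + 1)
  states[, 1] <- match(init_states, CKD_STATE_CODES)
  for (year in seq_len(n_years)) {
    u <- runif(n)
    cur <- states[, year]
    nxt <- integer(n)
    for (s in 1:5) {
      idx <- which(cur == s)
      if (length(idx) == 0) next
      nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    states[, year + 1] <- nxt
  }

  block <- rep(seq_len(n_blocks), length.out = n)
  counts_long <- purrr::map_dfr(0:n_years, function(step) {
    st <- states[, step + 1]
    tibble::tibble(
      step = step,
      state = CKD_STATE_CODES,
      count = tabulate(st, nbins = 5)
    )
  })
  summary_long <- purrr::map_dfr(0:n_years, function(step) {
    st <- states[, step + 1]
    purrr::map_dfr(1:5, function(s) {
      bc <- tapply((st == s), block, sum)
      bc[is.na(bc)] <- 0
      scaled <- as.numeric(bc) * n_blocks  # block totals rescaled to n
      qs <- quantile(scaled, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      tibble::tibble(
        step = step, state = CKD_STATE_CODES[s],
        mean = mean(scaled), var = var(scaled),
        q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q97.5 = qs[5]
      )
    })
  })
  structure(
    list(
      counts = counts_long,
      summary = summary_long,
      n_sim = n, n_years = n_years, seed = as.integer(seed),
      policy = attr(matrix, "policy"),
      trajectories = if (keep_trajectories) states else NULL
    ),
    class = "ckd_simulation"
  )
}

#' @export
print.ckd_simulation <- function(x, ...) {
  cat(sprintf(
    "<ckd_simulation> %s individuals, %d annual cycles, seed %d%s\n",
    format(x$n_sim, big.mark = ","), x$n_years, x$seed,
    if (!is.null(x$policy)) sprintf(", policy %s", x$policy) else ""
  ))
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Export simulation results
#'
#' Long-format CSV (`step`, `state`, `statistic`, `value`) or JSON of the
#' per-year summaries.
#'
#' @param sim A `ckd_simulation`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "ckd_simulation"))
  long <- tidyr::pivot_longer(sim$summary, -c("step", "state"),
                              names_to = "statistic", values_to = "value")
  counts <- dplyr::mutate(sim$counts, statistic = "count",
                          value = as.numeric(.data$count))
  long <- dplyr::bind_rows(
    long, counts[, c("step", "state", "statistic", "value")]
  )
  long <- dplyr::arrange(long, .data$step, .data$state, .data$statistic)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(n_sim = sim$n_sim, n_years = sim$n_years, seed = sim$seed,
           results = long),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(long, path)
  }
  invisible(path)
}
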