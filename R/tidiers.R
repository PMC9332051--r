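#' Tidy a projection table
#'
#' @param x A `ckd_projection`.
#' @param ... Unused.
#' @return A plain tibble (`year`, `cohort_size`, `state`, `count`,
#'   `share_pct`).
#' @export
tidy.ckd_projection <- function(x, ...) {
  as_tibble(unclass(x)[c("year", "cohort_size", "state", "count", "share_pct")])
}

#' One-row summary of a projection
#'
#' @param x A `ckd_projection`.
#' @param ... Unused.
#' @return Tibble with the horizon, baseline and final cohort sizes, and the
#'   final-year share outside normoalbuminuria.
#' @export
glance.ckd_projection <- function(x, ...) {
  y0 <- min(x$year)
  y1 <- max(x$year)
  final <- x[x$year == y1, ]
  tibble::tibble(
    start_year = y0,
    end_year = y1,
    n_years = y1 - y0 + 1L,
    cohort_start = x$cohort_size[x$year == y0][1],
    cohort_end = final$cohort_size[1],
    progressed_share_end = 100 - final$share_pct[final$state == "NORMO"]
  )
}

#' Tidy a Monte-Carlo simulation
#'
#' @param x A `ckd_simulation`.
#' @param ... Unused.
#' @return The per-year, per-state summary tibble (mean, variance and
#'   occupancy quantiles across scaled blocks).
#' @export
tidy.ckd_simulation <- function(x, ...) {
  x$summary
}

#' One-row summary of a simulation
#'
#' @param x A `ckd_simulation`.
#' @param ... Unused.
#' @return Tibble with `n_sim`, `n_years`, `seed` and the matrix policy.
#' @export
glance.ckd_simulation <- function(x, ...) {
  tibble::tibble(
    n_sim = x$n_sim,
    n_years = x$n_years,
    seed = x$seed,
    policy = x$policy %||% NA_character_
  )
}

#' Tidy a fitted duration distribution
#'
#' @param x A `ckd_duration`.
#' @param ... Unused.
#' @return One-row tibble with the kind, band, and fitted parameters or
#'   bandwidth.
#' @export
tidy.ckd_duration <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, age_band = x$age_band %||% NA_character_),
    as_tibble(purrr::map(x$params, ~.x))
  )
}
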