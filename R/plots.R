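#' Plot a projection as stacked stage shares over time
#'
#' Stacked-area view of the cohort's stage distribution (deaths included)
#' across the projection horizon.
#'
#' @param object A `ckd_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckd_projection <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(df$state, levels = rev(CKD_STATE_CODES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$share_pct,
                                   fill = .data$state)) +
    ggplot2::geom_area(alpha = 0.9) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "Year", y = "Share of cohort (%)", fill = "State",
                  title = "Projected stage distribution of the diabetic cohort") +
    ggplot2::theme_minimal()
}

#' Bar chart of the stage distribution in one year
#'
#' @param projection A `ckd_projection`.
#' @param year Calendar year within the horizon.
#' @return A ggplot object.
#' @export
plot_stage_distribution <- function(projection, year) {
  df <- stage_distribution(projection, year)
  df$state <- factor(df$state, levels = CKD_STATE_CODES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$share_pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Share of cohort (%)",
                  title = sprintf("Stage distribution, %d", year)) +
    ggplot2::theme_minimal()
}

#' Plot growth of progressed states between two years
#'
#' @param projection A `ckd_projection`.
#' @param y0,y1 Calendar years, `y0 < y1`.
#' @return A ggplot object.
#' @export
plot_growth <- function(projection, y0, y1) {
  df <- growth_summary(projection, y0, y1)
  df$state <- factor(df$state, levels = setdiff(CKD_STATE_CODES, "NORMO"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$growth_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = sprintf("Growth %d-%d (%%)", y0, y1),
                  title = "Growth of progressed CKD states") +
    ggplot2::theme_minimal()
}

#' Plot Monte-Carlo occupancy with uncertainty ribbons
#'
#' Per-state mean occupancy over time with 2.5--97.5% block-quantile
#' ribbons.
#'
#' @param object A `ckd_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckd_simulation <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(df$state, levels = CKD_STATE_CODES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "Years from start", y = "Individuals",
                  title = "Simulated state occupancy") +
    ggplot2::theme_minimal()
}
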