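# Shared fixtures: shipped defaults loaded once, plus the published
# reference projection used for consistency checks.

default_table <- load_transition_table()
default_profiles <- load_age_profiles()
default_scenario <- load_scenario()

reference_projection <- function() {
  ref <- readr::read_csv(ckd_example("reference_projection.csv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(share_printed = readr::col_character()))
  as_projection(ref[, c("year", "cohort_size", "state", "count")])
}

reference_printed_shares <- function() {
  readr::read_csv(ckd_example("reference_projection.csv"),
                  show_col_types = FALSE,
                  col_types = readr::cols(share_printed = readr::col_character()))
}

# Tolerance implied by the number of printed decimals: half a unit in the
# last printed place, never tighter than 0.1 percentage points.
printed_tolerance <- function(printed) {
  decimals <- ifelse(grepl("\\.", printed),
                     nchar(sub(".*\\.", "", printed)), 0)
  pmax(0.1, 0.5 * 10^(-decimals))
}

# A transition table with every rate zero: the frozen chain.
zero_table <- function() {
  tab <- default_table
  tab$p_min <- 0
  tab$p_max <- 0
  tab
}

make_scenario <- function(...) {
  args <- list(...)
  sc <- unclass(default_scenario)
  for (nm in names(args)) sc[[nm]] <- args[[nm]]
  validate_scenario(sc)
}
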