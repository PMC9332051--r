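#' Health states of the diabetic nephropathy progression model
#'
#' The model follows patients with type 2 diabetes through five renal health
#' states defined by the albuminuria marker: normoalbuminuria, early renal
#' involvement (microalbuminuria), overt nephropathy (macroalbuminuria),
#' end-stage renal disease requiring renal replacement therapy, and death
#' associated with cardiovascular risk. Cardiovascular death is the single
#' absorbing state; end-stage renal disease is not absorbing (patients on
#' renal replacement continue to face an annual death probability).
#'
#' @return A tibble with one row per state: `code` (stable identifier, in
#'   progression order), `albuminuria_band` (clinical descriptor), and
#'   `absorbing` (logical).
#' @examples
#' ckd_states()
#' @export
ckd_states <- function() {
  tibble::tibble(
    code = CKD_STATE_CODES,
    albuminuria_band = c(
      "< 30 mg/g",
      "30-300 mg/24 h",
      ">= 300 mg/g",
      "renal replacement",
      "cardiovascular death"
    ),
    absorbing = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# State codes in progression order; used for matrix/tibble ordering everywhere.
CKD_STATE_CODES <- c("NORMO", "MICRO", "MACRO", "ESRD", "DEATH_CV")

# The seven admissible one-year transitions (no skips; single absorbing state).
CKD_TRANSITION_PAIRS <- data.frame(
  from_state = c("NORMO", "MICRO", "MACRO", "NORMO", "MICRO", "MACRO", "ESRD"),
  to_state   = c("MICRO", "MACRO", "ESRD", "DEATH_CV", "DEATH_CV", "DEATH_CV",
                 "DEATH_CV"),
  stringsAsFactors = FALSE
)

as_state_factor <- function(x) {
  factor(as.character(x), levels = CKD_STATE_CODES)
}

check_state_codes <- function(x, what = "state") {
  bad <- setdiff(unique(as.character(x)), CKD_STATE_CODES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s name(s): %s (expected one of %s)",
      what, paste(bad, collapse = ", "), paste(CKD_STATE_CODES, collapse = ", ")
    ), class = "ckd_parse_error")
  }
  invisible(x)
}
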