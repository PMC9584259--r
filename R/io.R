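#' Read and write rosters and assignments as delimited text
#'
#' Rosters are comma-separated with a header row and columns `patient_id`,
#' `group`, one column per feature, and optionally `show_prob` (and
#' `show_prob_pred`). Assignments carry `patient_id`, `slot` (1-based) and
#' `priority`.
#'
#' @param path File path.
#' @return `read_roster` / `read_assignment` return tibbles; the writers
#'   return `path` invisibly.
#' @export
read_roster <- function(path) {
  roster <- readr::read_csv(path, show_col_types = FALSE)
  if (!"patient_id" %in% names(roster)) {
    abort("roster file must have a patient_id column",
          class = "fairbook_input_error")
  }
  roster$patient_id <- as.character(roster$patient_id)
  if (anyDuplicated(roster$patient_id) > 0) {
    abort("roster patient_id values must be unique",
          class = "fairbook_input_error")
  }
  if ("show_prob" %in% names(roster) &&
      any(roster$show_prob < 0 | roster$show_prob > 1, na.rm = TRUE)) {
    abort("show_prob values must lie in [0, 1]",
          class = "fairbook_input_error")
  }
  roster
}

#' @rdname read_roster
#' @param roster Roster tibble.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster, path)
  invisible(path)
}

#' @rdname read_roster
#' @export
read_assignment <- function(path) {
  asg <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("patient_id", "slot")
  if (!all(required %in% names(asg))) {
    abort("assignment file must have patient_id and slot columns",
          class = "fairbook_input_error")
  }
  assignment(as.character(asg$patient_id), asg$slot,
             priority = if ("priority" %in% names(asg)) asg$priority else NULL)
}

#' @rdname read_roster
#' @param assignment Assignment tibble.
#' @export
write_assignment <- function(assignment, path) {
  readr::write_csv(assignment[c("patient_id", "slot", "priority")], path)
  invisible(path)
}

#' Export an expected outcome as structured text
#'
#' Writes the evaluation mode, the three aggregate expectations and the
#' per-patient expected waits as YAML.
#'
#' @param outcome An `expected_outcome`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_expected_outcome <- function(outcome, path) {
  stopifnot(inherits(outcome, "expected_outcome"))
  yaml::write_yaml(list(
    mode = outcome$mode,
    n_samples = if (is.na(outcome$n_samples)) NULL else outcome$n_samples,
    seed = if (is.na(outcome$seed)) NULL else outcome$seed,
    expected_idle = outcome$idle,
    expected_overtime = outcome$overtime,
    total_expected_wait = sum(outcome$patients$expected_wait),
    patients = lapply(seq_len(nrow(outcome$patients)), function(i) {
      as.list(outcome$patients[i, c("patient_id", "slot", "expected_wait")])
    })
  ), path)
  invisible(path)
}
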