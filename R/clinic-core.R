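#' Define a clinic session's slot grid
#'
#' A clinic session is a sequence of equally spaced appointment slots with a
#' fixed slot duration. Internally all times are integer minutes from the
#' session start, which keeps the day recursion exact; `session_start` is a
#' clock-time label used only for printing.
#'
#' @param n_slots Number of appointment slots (positive integer).
#' @param slot_duration Slot duration in minutes (positive).
#' @param capacity Maximum number of patients bookable into one slot.
#'   Defaults to 2 (double-booking).
#' @param session_start Clock-time label such as `"09:00"`.
#'
#' @return An object of class `slot_grid`.
#' @examples
#' slot_grid(4, 30) # a 9:00-11:00 session of four 30-minute slots
#' @export
slot_grid <- function(n_slots, slot_duration = 30, capacity = 2,
                      session_start = "09:00") {
  stopifnot(length(n_slots) == 1, n_slots >= 1, n_slots == round(n_slots),
            length(slot_duration) == 1, slot_duration > 0,
            length(capacity) == 1, capacity >= 1, capacity == round(capacity))
  structure(
    list(
      n_slots = as.integer(n_slots),
      slot_duration = as.numeric(slot_duration),
      capacity = as.integer(capacity),
      session_start = session_start,
      session_length = as.numeric(n_slots) * as.numeric(slot_duration)
    ),
    class = "slot_grid"
  )
}

#' @export
print.slot_grid <- function(x, ...) {
  cat(sprintf(
    "<slot_grid> %d slots x %g min from %s (capacity %d/slot, session %g min)\n",
    x$n_slots, x$slot_duration, x$session_start, x$capacity, x$session_length
  ))
  invisible(x)
}

# Slot start times in minutes from session start, 1-based slot index.
slot_starts <- function(grid) (seq_len(grid$n_slots) - 1) * grid$slot_duration

#' Construct an assignment of patients to slots
#'
#' An assignment books every rostered patient into exactly one slot, with a
#' within-slot priority giving the service order among patients sharing a
#' slot. Priority defaults to order of appearance and must never be derived
#' from group labels.
#'
#' @param patient_id Character vector of patient identifiers.
#' @param slot Integer vector of 1-based slot indices, same length.
#' @param priority Optional integer vector of within-slot service priorities
#'   (lower is served first). Defaults to order of appearance within slot.
#'
#' @return A tibble with columns `patient_id`, `slot`, `priority`.
#' @examples
#' assignment(c("a", "d", "e", "c", "b"), c(1, 2, 2, 3, 4))
#' @export
assignment <- function(patient_id, slot, priority = NULL) {
  stopifnot(length(patient_id) == length(slot))
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    slot = as.integer(slot)
  )
  if (is.null(priority)) {
    out <- out |>
      dplyr::group_by(.data$slot) |>
      dplyr::mutate(priority = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    stopifnot(length(priority) == nrow(out))
    out$priority <- as.integer(priority)
  }
  out
}

#' Validate an assignment against a roster and slot grid
#'
#' Checks the structural invariants: every rostered patient booked exactly
#' once, no unknown patients, slot indices on the grid, and no slot over
#' capacity.
#'
#' @param assignment Assignment tibble (see [assignment()]).
#' @param roster Roster data frame with a `patient_id` column.
#' @param grid A [slot_grid()].
#'
#' @return The assignment, invisibly, if valid; otherwise an error.
#' @export
validate_assignment <- function(assignment, roster, grid) {
  stopifnot(is.data.frame(assignment), is.data.frame(roster),
            inherits(grid, "slot_grid"))
  unknown <- setdiff(assignment$patient_id, roster$patient_id)
  if (length(unknown) > 0) {
    abort(sprintf("roster mismatch: assignment references unknown patient(s) %s",
                  paste(unknown, collapse = ", ")),
          class = "fairbook_roster_mismatch")
  }
  missing <- setdiff(roster$patient_id, assignment$patient_id)
  if (length(missing) > 0 || anyDuplicated(assignment$patient_id) > 0) {
    abort("roster mismatch: every rostered patient must appear exactly once",
          class = "fairbook_roster_mismatch")
  }
  if (any(assignment$slot < 1L | assignment$slot > grid$n_slots)) {
    abort(sprintf("invalid assignment: slot index outside 1..%d", grid$n_slots),
          class = "fairbook_invalid_assignment")
  }
  load <- table(factor(assignment$slot, levels = seq_len(grid$n_slots)))
  if (any(load > grid$capacity)) {
    bad <- names(load)[load > grid$capacity]
    abort(sprintf("invalid assignment: slot(s) %s exceed capacity %d",
                  paste(bad, collapse = ", "), grid$capacity),
          class = "fairbook_invalid_assignment")
  }
  invisible(assignment)
}

# Assignment rows in service order: by slot, then within-slot priority,
# stable in appearance order for ties.
service_order <- function(assignment) {
  order(assignment$slot, assignment$priority)
}

#' Simulate one clinic day deterministically
#'
#' Runs the deterministic day recursion for a fixed show/no-show realization:
#' shown patients are served in (slot, priority) order, each service takes
#' exactly one slot duration, a patient's service starts at the later of
#' their slot start and the provider becoming free, and their wait is that
#' start minus the slot start. No-shows consume no provider time and wait
#' zero. Provider idle is the non-serving time between session start and the
#' later of session end and last completion; overtime is any serving past
#' session end.
#'
#' @param assignment Assignment tibble.
#' @param grid A [slot_grid()].
#' @param shows Show indicators: either a named 0/1 (or logical) vector
#'   keyed by `patient_id`, or a data frame with columns `patient_id` and
#'   `show`. Must cover exactly the booked patients.
#' @param roster Optional roster for validation; defaults to the patients in
#'   `shows`.
#'
#' @return A `day_outcome` object: per-patient waits plus idle and overtime
#'   (all minutes). Access the per-patient table with [tidy()] and the
#'   aggregates with [glance()].
#' @examples
#' grid <- slot_grid(4, 30)
#' asg <- assignment(c("a", "d", "e", "c", "b"), c(1, 2, 2, 3, 4))
#' shows <- c(a = 1, d = 1, e = 1, c = 1, b = 1)
#' simulate_day(asg, grid, shows)
#' @export
simulate_day <- function(assignment, grid, shows, roster = NULL) {
  show_vec <- as_show_vector(shows)
  if (is.null(roster)) {
    roster <- tibble::tibble(patient_id = names(show_vec))
  }
  validate_assignment(assignment, roster, grid)
  if (!setequal(names(show_vec), assignment$patient_id)) {
    abort("roster mismatch: show vector must cover exactly the booked patients",
          class = "fairbook_roster_mismatch")
  }
  ord <- service_order(assignment)
  a_ord <- (assignment$slot[ord] - 1) * grid$slot_duration
  s_ord <- matrix(show_vec[assignment$patient_id[ord]], nrow = 1)
  storage.mode(s_ord) <- "integer"
  res <- cpp_day_eval(a_ord, grid$slot_duration, grid$session_length, s_ord)
  patients <- tibble::tibble(
    patient_id = assignment$patient_id[ord],
    slot = assignment$slot[ord],
    priority = assignment$priority[ord],
    shown = as.logical(s_ord[1, ]),
    wait = res$wait[1, ]
  )
  structure(
    list(patients = patients, idle = res$idle[1], overtime = res$overtime[1],
         grid = grid),
    class = "day_outcome"
  )
}

#' @export
print.day_outcome <- function(x, ...) {
  cat(sprintf("<day_outcome> %d patients (%d shown): total wait %g min, idle %g min, overtime %g min\n",
              nrow(x$patients), sum(x$patients$shown),
              sum(x$patients$wait), x$idle, x$overtime))
  print(x$patients)
  invisible(x)
}

#' @rdname simulate_day
#' @param x A `day_outcome`.
#' @param ... Unused.
#' @export
tidy.day_outcome <- function(x, ...) x$patients

#' @rdname simulate_day
#' @export
glance.day_outcome <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_shown = sum(x$patients$shown),
    total_wait = sum(x$patients$wait),
    idle = x$idle,
    overtime = x$overtime
  )
}

# Normalize `shows` into a named 0/1 integer vector.
as_show_vector <- function(shows) {
  if (is.data.frame(shows)) {
    stopifnot(all(c("patient_id", "show") %in% names(shows)))
    out <- setNames(as.integer(shows$show), as.character(shows$patient_id))
  } else {
    if (is.null(names(shows))) {
      abort("`shows` must be named by patient_id or be a data frame")
    }
    out <- setNames(as.integer(shows), names(shows))
  }
  if (!all(out %in% c(0L, 1L))) abort("show indicators must be 0/1")
  out
}

#' Label slots as desirable or undesirable
#'
#' A slot is undesirable when it is overbooked (holds two or more patients)
#' or immediately follows an overbooked slot; these slots carry longer
#' expected waits. Patients inherit their slot's label.
#'
#' @inheritParams validate_assignment
#' @return A tibble with one row per slot: `slot`, `n_patients`,
#'   `desirable` (logical).
#' @examples
#' grid <- slot_grid(4, 30)
#' asg <- assignment(c("a", "d", "e", "c", "b"), c(1, 2, 2, 3, 4))
#' classify_slots(asg, grid) # slots 2 (overbooked) and 3 (after it) undesirable
#' @export
classify_slots <- function(assignment, grid) {
  load <- as.integer(table(factor(assignment$slot, levels = seq_len(grid$n_slots))))
  overbooked <- load >= 2L
  after <- c(FALSE, overbooked[-length(overbooked)])
  tibble::tibble(
    slot = seq_len(grid$n_slots),
    n_patients = load,
    desirable = !(overbooked | after)
  )
}
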