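#' The packaged worked-example clinic day
#'
#' A five-patient, four-slot session (30-minute slots, 9:00-11:00) with one
#' double-booked slot: patient `a` alone in slot 1, the two
#' lowest-show-probability patients `d` and `e` double-booked in slot 2,
#' `c` in the slot right after the overbooked one, and `b` in the last
#' slot. When everyone shows up, the second-served overbooked patient and
#' the patient in the following slot each wait 30 minutes; the first-slot
#' patient never waits, and the last-slot patient waits only when `c`, `d`
#' and `e` all show. The roster's show probabilities are illustrative
#' synthetic values.
#'
#' @return A list with elements `roster` (tibble), `assignment` (tibble)
#'   and `grid` ([slot_grid()]).
#' @examples
#' ex <- example_day()
#' simulate_day(ex$assignment, ex$grid,
#'              setNames(rep(1, 5), ex$roster$patient_id))
#' @export
example_day <- function() {
  roster <- read_roster(system.file("extdata", "example_roster.csv",
                                    package = "fairbook", mustWork = TRUE))
  asg <- read_assignment(system.file("extdata", "example_assignment.csv",
                                     package = "fairbook", mustWork = TRUE))
  list(roster = roster, assignment = asg, grid = slot_grid(4, 30))
}
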