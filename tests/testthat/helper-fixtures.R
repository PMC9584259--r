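# Shared fixtures and independent reference implementations used across the
# suite. The reference day recursion below is deliberately written from the
# definition (event-by-event, data-frame based) rather than reusing any
# package internals, so that package results can be cross-checked against it.

# The packaged five-patient worked example: four 30-min slots, slot 2
# double-booked, priorities a; d,e; c; b.
worked_example <- function() example_day()

all_show <- function(roster) setNames(rep(1L, nrow(roster)), roster$patient_id)

# Independent reference: serve shown patients in (slot, priority) order;
# each service lasts exactly the slot duration.
ref_day <- function(assignment, grid, shows) {
  df <- assignment[order(assignment$slot, assignment$priority), ]
  dur <- grid$slot_duration
  free_at <- 0
  waits <- setNames(numeric(nrow(df)), df$patient_id)
  n_shown <- 0
  for (i in seq_len(nrow(df))) {
    id <- df$patient_id[i]
    if (shows[[id]] == 1) {
      slot_start <- (df$slot[i] - 1) * dur
      start <- max(slot_start, free_at)
      waits[id] <- start - slot_start
      free_at <- start + dur
      n_shown <- n_shown + 1
    }
  }
  sess <- grid$session_length
  list(waits = waits,
       idle = max(sess, free_at) - dur * n_shown,
       overtime = max(0, free_at - sess),
       last_completion = free_at)
}

# Independent reference for exact expectations: probability-weighted
# average of ref_day over all 2^n show vectors.
ref_expected <- function(assignment, grid, p) {
  ids <- assignment$patient_id
  n <- length(ids)
  waits <- setNames(numeric(n), ids)
  idle <- 0
  overtime <- 0
  for (r in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(r))[seq_len(n)]
    shows <- setNames(bits, ids)
    pr <- prod(ifelse(bits == 1, p[ids], 1 - p[ids]))
    day <- ref_day(assignment, grid, shows)
    waits <- waits + pr * day$waits[ids]
    idle <- idle + pr * day$idle
    overtime <- overtime + pr * day$overtime
  }
  list(waits = waits, idle = idle, overtime = overtime)
}

# Random small instance for optimizer / evaluator property tests.
random_instance <- function(n, m, capacity = 2, two_groups = TRUE) {
  roster <- tibble::tibble(
    patient_id = sprintf("r%02d", seq_len(n)),
    group = if (two_groups) {
      sample(c("B", "nonB"), n, replace = TRUE, prob = c(0.4, 0.6))
    } else {
      rep("B", n)
    }
  )
  p <- setNames(round(runif(n, 0.2, 0.98), 3), roster$patient_id)
  list(roster = roster, grid = slot_grid(m, 30, capacity = capacity), p = p)
}

random_assignment <- function(n, m, capacity = 2) {
  pool <- rep(seq_len(m), capacity)
  assignment(sprintf("r%02d", seq_len(n)), sample(pool)[seq_len(n)])
}
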