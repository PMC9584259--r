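#' Cost weights for the schedule-cost function
#'
#' Schedule cost is the weighted sum of total expected patient wait,
#' expected provider idle time, and expected provider overtime; schedule
#' quality is its negation. The weight vector is a clinic policy choice;
#' defaults weigh the three components equally.
#'
#' @param w_wait,w_idle,w_overtime Nonnegative weights, not all zero.
#' @return A `cost_weights` object.
#' @export
cost_weights <- function(w_wait = 1, w_idle = 1, w_overtime = 1) {
  if (any(c(w_wait, w_idle, w_overtime) < 0)) {
    abort("configuration error: cost weights must be nonnegative",
          class = "fairbook_config_error")
  }
  if (w_wait + w_idle + w_overtime == 0) {
    abort("configuration error: cost weights must not all be zero",
          class = "fairbook_config_error")
  }
  structure(list(w_wait = w_wait, w_idle = w_idle, w_overtime = w_overtime),
            class = "cost_weights")
}

# All 2^n show vectors as a 0/1 integer matrix (row r = binary digits of
# r - 1, column j = patient j's indicator).
enumerate_shows <- function(n) {
  m <- 2L^n
  S <- matrix(0L, nrow = m, ncol = n)
  r <- seq_len(m) - 1L
  for (j in seq_len(n)) {
    S[, j] <- bitwAnd(r, bitwShiftL(1L, j - 1L)) > 0L
  }
  storage.mode(S) <- "integer"
  S
}

# Probability of each show vector under independent Bernoulli(p_j) draws.
show_vector_weights <- function(S, p) {
  w <- rep(1, nrow(S))
  for (j in seq_along(p)) {
    w <- w * ifelse(S[, j] == 1L, p[j], 1 - p[j])
  }
  w
}

# Align a show-probability vector with the assignment's patients.
align_probs <- function(show_probs, assignment) {
  if (!is.null(names(show_probs))) {
    missing <- setdiff(assignment$patient_id, names(show_probs))
    if (length(missing) > 0) {
      abort(sprintf("show_probs missing patient(s): %s",
                    paste(missing, collapse = ", ")))
    }
    show_probs <- show_probs[assignment$patient_id]
  }
  stopifnot(length(show_probs) == nrow(assignment),
            all(show_probs >= 0 & show_probs <= 1))
  unname(show_probs)
}

new_expected_outcome <- function(patients, idle, overtime, mode, n_samples = NA,
                                 seed = NA, se = NULL) {
  structure(
    list(patients = patients, idle = idle, overtime = overtime,
         mode = mode, n_samples = n_samples, seed = seed, se = se),
    class = "expected_outcome"
  )
}

#' Exact expected outcome of an assignment
#'
#' Enumerates all `2^n` show vectors, runs the deterministic day recursion
#' on each, and weights outcomes by their Bernoulli probabilities. Exact but
#' exponential in the roster size: beyond `cutoff` patients use
#' [expected_outcome_mc()].
#'
#' @param assignment Assignment tibble.
#' @param grid A [slot_grid()].
#' @param show_probs Per-patient show probabilities: a vector named by
#'   `patient_id`, or aligned with the assignment's rows.
#' @param cutoff Maximum roster size for exact enumeration (default 20,
#'   about a million outcomes).
#'
#' @return An `expected_outcome`: per-patient expected waits plus expected
#'   idle and overtime, all in minutes. [tidy()] returns the per-patient
#'   table, [glance()] the aggregates.
#' @examples
#' grid <- slot_grid(1, 30)
#' asg <- assignment(c("x", "y"), c(1, 1))
#' expected_outcome_exact(asg, grid, c(x = 0.5, y = 0.5))
#' @export
expected_outcome_exact <- function(assignment, grid, show_probs, cutoff = 20) {
  n <- nrow(assignment)
  if (n > cutoff) {
    abort(sprintf(
      "instance too large for exact enumeration (%d > %d patients); use expected_outcome_mc()",
      n, cutoff), class = "fairbook_size_error")
  }
  p <- align_probs(show_probs, assignment)
  ord <- service_order(assignment)
  a_ord <- (assignment$slot[ord] - 1) * grid$slot_duration
  # column j of the enumeration indexes assignment row j; reorder columns
  # into service order before the recursion
  S <- enumerate_shows(n)
  w <- show_vector_weights(S, p)
  res <- cpp_expected_eval(a_ord, grid$slot_duration, grid$session_length,
                           S, w, as.integer(ord - 1L))
  patients <- tibble::tibble(
    patient_id = assignment$patient_id[ord],
    slot = assignment$slot[ord],
    show_prob = p[ord],
    expected_wait = res$wait
  )
  new_expected_outcome(patients, res$idle, res$overtime, mode = "exact")
}

#' Monte-Carlo expected outcome of an assignment
#'
#' Empirical mean of the day recursion over seeded Bernoulli show-vector
#' draws; agrees with [expected_outcome_exact()] up to sampling error and is
#' reproducible given the seed.
#'
#' @inheritParams expected_outcome_exact
#' @param n_samples Number of simulated days (default 10000).
#' @param seed Integer seed.
#'
#' @return An `expected_outcome` carrying Monte-Carlo standard errors of the
#'   three aggregates in its `se` element.
#' @export
expected_outcome_mc <- function(assignment, grid, show_probs,
                                n_samples = 10000, seed = 1) {
  stopifnot(n_samples >= 1)
  n <- nrow(assignment)
  p <- align_probs(show_probs, assignment)
  ord <- service_order(assignment)
  a_ord <- (assignment$slot[ord] - 1) * grid$slot_duration
  p_ord <- p[ord]
  S <- with_seed(seed, {
    matrix(rbinom(n_samples * n, 1, rep(p_ord, each = n_samples)),
           nrow = n_samples, ncol = n)
  })
  storage.mode(S) <- "integer"
  res <- cpp_day_eval(a_ord, grid$slot_duration, grid$session_length, S)
  total_wait <- rowSums(res$wait)
  patients <- tibble::tibble(
    patient_id = assignment$patient_id[ord],
    slot = assignment$slot[ord],
    show_prob = p_ord,
    expected_wait = colMeans(res$wait)
  )
  se <- c(total_wait = sd(total_wait) / sqrt(n_samples),
          idle = sd(res$idle) / sqrt(n_samples),
          overtime = sd(res$overtime) / sqrt(n_samples))
  new_expected_outcome(patients, mean(res$idle), mean(res$overtime),
                       mode = "mc", n_samples = n_samples, seed = seed,
                       se = se)
}

#' Expected outcome with automatic mode selection
#'
#' Uses exact enumeration up to `cutoff` patients, Monte Carlo beyond.
#'
#' @inheritParams expected_outcome_mc
#' @inheritParams expected_outcome_exact
#' @param mode `"auto"`, `"exact"` or `"mc"`.
#' @return An `expected_outcome`.
#' @export
expected_outcome <- function(assignment, grid, show_probs,
                             mode = c("auto", "exact", "mc"), cutoff = 20,
                             n_samples = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (nrow(assignment) <= cutoff) "exact" else "mc"
  }
  if (mode == "exact") {
    expected_outcome_exact(assignment, grid, show_probs, cutoff = cutoff)
  } else {
    expected_outcome_mc(assignment, grid, show_probs,
                        n_samples = n_samples, seed = seed)
  }
}

#' @export
print.expected_outcome <- function(x, ...) {
  cat(sprintf(
    "<expected_outcome> (%s) E[total wait] %.3f, E[idle] %.3f, E[overtime] %.3f min\n",
    x$mode, sum(x$patients$expected_wait), x$idle, x$overtime))
  print(x$patients)
  invisible(x)
}

#' @rdname expected_outcome_exact
#' @param x An `expected_outcome`.
#' @param ... Unused.
#' @export
tidy.expected_outcome <- function(x, ...) x$patients

#' @rdname expected_outcome_exact
#' @export
glance.expected_outcome <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_patients = nrow(x$patients),
    total_expected_wait = sum(x$patients$expected_wait),
    expected_idle = x$idle,
    expected_overtime = x$overtime,
    n_samples = x$n_samples
  )
}

#' Scalar schedule cost of an expected outcome
#'
#' `w_wait * sum(expected waits) + w_idle * E[idle] + w_overtime *
#' E[overtime]`. The lower the cost, the higher the schedule quality.
#'
#' @param outcome An `expected_outcome`.
#' @param weights A [cost_weights()].
#' @return Nonnegative scalar cost (weighted minutes).
#' @export
schedule_cost <- function(outcome, weights = cost_weights()) {
  stopifnot(inherits(outcome, "expected_outcome"),
            inherits(weights, "cost_weights"))
  weights$w_wait * sum(outcome$patients$expected_wait) +
    weights$w_idle * outcome$idle +
    weights$w_overtime * outcome$overtime
}

#' Plot per-patient expected waits
#'
#' @param object An `expected_outcome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expected_outcome <- function(object, ...) {
  df <- object$patients
  df$patient_id <- factor(df$patient_id, levels = df$patient_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id,
                                   y = .data$expected_wait)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patient (service order)",
                  y = "expected wait (min)",
                  title = sprintf("Expected waits (%s evaluation)", object$mode)) +
    ggplot2::theme_minimal()
}
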