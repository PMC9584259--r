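#' Wait-time disparity between patient groups
#'
#' Signed percent difference between the two groups' mean waits. The wait
#' entering the group means is, by default, the *show-conditional* expected
#' wait `E[wait | shows] = E[wait] / p`: the average wait a patient
#' experiences when they actually attend, which is what clinic wait-time
#' records measure. (On the unconditional scale a group's low show rate
#' deflates its mean wait even under group-blind scheduling, masking or
#' fabricating disparity.) The denominator is the average of the two group
#' means, a symmetric choice that stays stable when one group's mean is
#' near zero; the other group's mean or the overall mean can be selected
#' instead.
#'
#' @param outcome An `expected_outcome` (per-patient expected waits and
#'   show probabilities).
#' @param roster Roster with `patient_id` and `group` columns; both groups
#'   must be nonempty.
#' @param group_b Label of the group whose mean wait enters with positive
#'   sign (default `"B"`); positive disparity means this group waits longer.
#' @param denominator `"average"` (default), `"other"` (the non-`group_b`
#'   mean) or `"overall"` (mean wait of all patients).
#' @param conditional Use show-conditional waits (default `TRUE`).
#' @return Signed percent; `0` by convention when both group means are zero.
#' @examples
#' # group means 30 and 10 minutes give +100% under the average denominator
#' @export
wait_disparity <- function(outcome, roster, group_b = "B",
                           denominator = c("average", "other", "overall"),
                           conditional = TRUE) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(outcome, "expected_outcome"))
  df <- dplyr::left_join(outcome$patients,
                         dplyr::select(roster, "patient_id", "group"),
                         by = "patient_id")
  groups <- unique(df$group)
  if (!(group_b %in% groups) || length(groups) < 2) {
    abort("undefined metric: wait disparity needs both groups nonempty",
          class = "fairbook_undefined_metric")
  }
  df$w <- if (conditional) {
    ifelse(df$show_prob > 0, df$expected_wait / df$show_prob, 0)
  } else {
    df$expected_wait
  }
  mean_b <- mean(df$w[df$group == group_b])
  mean_o <- mean(df$w[df$group != group_b])
  if (mean_b == 0 && mean_o == 0) return(0)
  den <- switch(denominator,
                average = (mean_b + mean_o) / 2,
                other = mean_o,
                overall = mean(df$w))
  if (den <= 0) {
    abort("undefined metric: disparity denominator is not positive",
          class = "fairbook_undefined_metric")
  }
  100 * (mean_b - mean_o) / den
}

#' Statistical-parity gap at a wait threshold
#'
#' Difference between the two groups' probabilities of waiting longer than
#' a threshold, conditional on showing up, with probabilities taken over
#' the show-vector distribution:
#' `P(wait > t | group B, shown) - P(wait > t | other group, shown)`.
#' Exact enumeration is used up to `cutoff` patients; seeded Monte Carlo
#' beyond.
#'
#' @inheritParams expected_outcome_exact
#' @param roster Roster with `group` labels; both groups must be nonempty.
#' @param wait_threshold Wait threshold in minutes (default 0: any wait).
#' @param group_b Group entering with positive sign (default `"B"`).
#' @param n_samples,seed Monte-Carlo controls for rosters above `cutoff`.
#' @return Signed fraction in `[-1, 1]`.
#' @export
statistical_parity_gap <- function(assignment, grid, show_probs, roster,
                                   wait_threshold = 0, group_b = "B",
                                   cutoff = 20, n_samples = 10000, seed = 1) {
  n <- nrow(assignment)
  p <- align_probs(show_probs, assignment)
  ord <- service_order(assignment)
  a_ord <- (assignment$slot[ord] - 1) * grid$slot_duration
  if (n <= cutoff) {
    S_ord <- enumerate_shows(n)[, ord, drop = FALSE]
    w <- show_vector_weights(S_ord, p[ord])
  } else {
    S_ord <- with_seed(seed, {
      matrix(rbinom(n_samples * n, 1, rep(p[ord], each = n_samples)),
             nrow = n_samples)
    })
    storage.mode(S_ord) <- "integer"
    w <- rep(1 / n_samples, n_samples)
  }
  res <- cpp_day_eval(a_ord, grid$slot_duration, grid$session_length, S_ord)
  # P(shown and wait > t) per patient, in service order
  exceed <- drop(crossprod(w, (S_ord == 1L) * (res$wait > wait_threshold)))
  shown_prob <- drop(crossprod(w, S_ord))
  ids <- assignment$patient_id[ord]
  groups <- roster$group[match(ids, roster$patient_id)]
  if (!(group_b %in% groups) || length(unique(groups)) < 2) {
    abort("undefined metric: parity gap needs both groups nonempty",
          class = "fairbook_undefined_metric")
  }
  cond_prob <- function(sel) {
    denom <- sum(shown_prob[sel])
    if (denom == 0) 0 else sum(exceed[sel]) / denom
  }
  cond_prob(groups == group_b) - cond_prob(groups != group_b)
}

#' Optimality gap relative to a reference cost
#'
#' Percent excess of a method's schedule cost over a reference (typically
#' the cost-minimizing method on the same instance):
#' `100 * (cost_method - cost_reference) / cost_reference`.
#'
#' @param cost_method Schedule cost of the method under study.
#' @param cost_reference Reference schedule cost (> 0).
#' @return Percent gap; nonnegative whenever the reference is the optimum
#'   of the same instance under the same weights.
#' @export
optimality_gap <- function(cost_method, cost_reference) {
  if (!is.finite(cost_reference) || cost_reference <= 0) {
    abort("undefined metric: optimality gap needs a positive reference cost",
          class = "fairbook_undefined_metric")
  }
  100 * (cost_method - cost_reference) / cost_reference
}

#' Fairness report for one assignment
#'
#' One-row tibble with group mean expected waits, the signed wait
#' disparity, the statistical-parity gap at the configured threshold, the
#' schedule cost, and (when a reference cost is supplied) the optimality
#' gap.
#'
#' @inheritParams statistical_parity_gap
#' @param weights A [cost_weights()].
#' @param reference_cost Optional positive reference cost for the
#'   optimality gap.
#' @return A tibble with one row.
#' @export
fairness_report <- function(assignment, grid, show_probs, roster,
                            weights = cost_weights(), wait_threshold = 0,
                            group_b = "B", reference_cost = NULL,
                            cutoff = 20, n_samples = 10000, seed = 1) {
  out <- expected_outcome(assignment, grid, show_probs, cutoff = cutoff,
                          n_samples = n_samples, seed = seed)
  df <- dplyr::left_join(out$patients,
                         dplyr::select(roster, "patient_id", "group"),
                         by = "patient_id")
  cw <- ifelse(df$show_prob > 0, df$expected_wait / df$show_prob, 0)
  mean_b <- mean(cw[df$group == group_b])
  mean_o <- mean(cw[df$group != group_b])
  cost <- schedule_cost(out, weights)
  tibble::tibble(
    mean_wait_B = mean_b,
    mean_wait_other = mean_o,
    disparity_pct = wait_disparity(out, roster, group_b = group_b),
    parity_gap = statistical_parity_gap(assignment, grid, show_probs, roster,
                                        wait_threshold = wait_threshold,
                                        group_b = group_b, cutoff = cutoff,
                                        n_samples = n_samples, seed = seed),
    schedule_cost = cost,
    expected_idle = out$idle,
    expected_overtime = out$overtime,
    optimality_gap_pct = if (is.null(reference_cost)) NA_real_ else
      optimality_gap(cost, reference_cost)
  )
}
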