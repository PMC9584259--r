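#' Objective specification for schedule optimization
#'
#' Three objective variants correspond to the intervention menu on the
#' optimization component:
#'
#' * `"TRADITIONAL"` — minimize schedule cost (total expected wait + idle +
#'   overtime, weighted).
#' * `"RACE_AWARE"` — replace the wait term by `n` times the largest group
#'   mean expected wait, so the optimizer minimizes the waiting of the group
#'   expected to wait longer. Requires group labels.
#' * `"RACE_UNAWARE"` — replace the wait term by `n` times the largest
#'   individual expected wait (min-max over patients), never reading group
#'   labels.
#'
#' The idle and overtime terms are retained in all variants (the fairness
#' variants alter only what the wait term minimizes); the fair wait terms
#' are scaled by `n` so their units stay comparable to the total-wait term.
#'
#' @param variant One of `"TRADITIONAL"`, `"RACE_AWARE"`, `"RACE_UNAWARE"`.
#' @param weights A [cost_weights()].
#' @param constraints List of [quota_constraint()] objects (possibly empty).
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(variant = c("TRADITIONAL", "RACE_AWARE", "RACE_UNAWARE"),
                           weights = cost_weights(), constraints = list()) {
  variant <- match.arg(variant)
  stopifnot(inherits(weights, "cost_weights"), is.list(constraints))
  if (length(constraints) > 0) {
    stopifnot(all(vapply(constraints, inherits, TRUE, "quota_constraint")))
  }
  structure(list(variant = variant, weights = weights,
                 constraints = constraints),
            class = "objective_spec")
}

#' Quota constraint on desirable slots
#'
#' Restricts feasible schedules so that a minimum fraction of the
#' *desirable* slots (slots neither overbooked nor immediately after an
#' overbooked slot) goes to each protected group (`kind = "group"`), or to
#' patients whose predicted no-show risk is in the highest third of the
#' roster (`kind = "risk"`, group-blind).
#'
#' @param kind `"group"` or `"risk"`.
#' @param minima For `"group"`: a named numeric vector of minimum desirable
#'   -slot fractions per group (e.g. `c(B = 0.2, nonB = 0.6)`). For
#'   `"risk"`: a single minimum fraction for the top no-show-risk tercile.
#' @return A `quota_constraint` object.
#' @export
quota_constraint <- function(kind = c("group", "risk"), minima) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(minima), all(minima >= 0), all(minima <= 1))
  if (kind == "group" && is.null(names(minima))) {
    abort("group quota minima must be named by group label",
          class = "fairbook_config_error")
  }
  if (kind == "risk") stopifnot(length(minima) == 1)
  structure(list(kind = kind, minima = minima), class = "quota_constraint")
}

# Flag the top no-show-risk tercile: the ceil(n/3) patients with the lowest
# predicted show probability, boundary ties resolved by patient_id order.
risk_tercile_flags <- function(patient_id, show_probs) {
  n <- length(show_probs)
  ord <- order(show_probs, patient_id)
  flags <- logical(n)
  flags[ord[seq_len(ceiling(n / 3))]] <- TRUE
  flags
}

# Attained desirable-slot fractions for one constraint given slot loads.
# `slots` is the roster-aligned slot vector. Returns a tibble of
# (level, attained, minimum); fractions NA when no slot is desirable.
quota_attained <- function(slots, n_slots, constraint, groups = NULL,
                           show_probs = NULL, patient_id = NULL) {
  load <- tabulate(slots, nbins = n_slots)
  overbooked <- load >= 2L
  desirable <- !(overbooked | c(FALSE, overbooked[-n_slots]))
  ndes <- sum(desirable)
  if (constraint$kind == "group") {
    levels <- names(constraint$minima)
    attained <- vapply(levels, function(g) {
      if (ndes == 0) return(NA_real_)
      sum(desirable[slots[groups == g]]) / ndes
    }, numeric(1))
  } else {
    if (is.null(show_probs)) {
      abort("risk quota requires show probabilities",
            class = "fairbook_config_error")
    }
    hi <- risk_tercile_flags(patient_id %||% as.character(seq_along(slots)),
                             show_probs)
    levels <- "top_risk_tercile"
    attained <- if (ndes == 0) NA_real_ else sum(desirable[slots[hi]]) / ndes
  }
  tibble::tibble(kind = constraint$kind, level = levels,
                 attained = unname(attained),
                 minimum = unname(constraint$minima))
}

#' Check a quota constraint for an assignment
#'
#' Computes the fraction of desirable slots held by each group (group
#' quota) or by top-risk-tercile patients (risk quota) and compares it to
#' the configured minima. When no slot is desirable, fractions are
#' undefined (`NA`) and the constraint is reported unsatisfied.
#'
#' @inheritParams validate_assignment
#' @param constraint A [quota_constraint()].
#' @param show_probs Predicted show probabilities (needed for risk quotas),
#'   named by `patient_id` or aligned with the roster rows.
#' @return A list with elements `satisfied` (logical) and `fractions`
#'   (tibble of attained vs minimum fractions per level).
#' @export
check_quota <- function(assignment, grid, roster, constraint,
                        show_probs = NULL) {
  stopifnot(inherits(constraint, "quota_constraint"))
  idx <- match(roster$patient_id, assignment$patient_id)
  slots <- assignment$slot[idx]
  groups <- if ("group" %in% names(roster)) roster$group else NULL
  p <- if (!is.null(show_probs)) align_probs(show_probs, roster) else NULL
  fr <- quota_attained(slots, grid$n_slots, constraint,
                       groups = groups, show_probs = p,
                       patient_id = roster$patient_id)
  satisfied <- all(!is.na(fr$attained) & fr$attained >= fr$minimum - 1e-12)
  list(satisfied = satisfied, fractions = fr)
}

# ---- internal fast evaluation context -------------------------------------
#
# Precomputes the show-vector matrix and its probability weights once per
# instance so that repeated objective evaluations during search only pay
# for a column reorder and the C++ recursion. Exact enumeration up to
# `cutoff` patients, common-random-number Monte Carlo beyond.

make_eval_ctx <- function(grid, show_probs, groups = NULL, weights = cost_weights(),
                          variant = "TRADITIONAL", constraints = list(),
                          patient_id = NULL, cutoff = 20,
                          n_samples = 2000, seed = 1) {
  n <- length(show_probs)
  if (n <= cutoff) {
    S <- enumerate_shows(n)
    w <- show_vector_weights(S, show_probs)
  } else {
    S <- with_seed(seed, {
      matrix(rbinom(n_samples * n, 1, rep(show_probs, each = n_samples)),
             nrow = n_samples)
    })
    storage.mode(S) <- "integer"
    w <- rep(1 / n_samples, n_samples)
  }
  gi <- if (is.null(groups)) rep(0L, n) else as.integer(factor(groups)) - 1L
  list(n = n, S = S, w = w, grid = grid, p = show_probs, groups = groups,
       weights = weights, variant = variant, constraints = constraints,
       patient_id = patient_id %||% as.character(seq_len(n)),
       variant_code = match(variant, c("TRADITIONAL", "RACE_AWARE",
                                       "RACE_UNAWARE")) - 1L,
       wts = c(weights$w_wait, weights$w_idle, weights$w_overtime),
       group_idx = gi,
       n_groups = max(gi) + 1L)
}

# Expected waits / idle / overtime for a roster-aligned slot vector under
# canonical (roster-order) within-slot priority.
ctx_expectations <- function(ctx, slots) {
  ord <- order(slots, seq_along(slots))
  a_ord <- (slots[ord] - 1) * ctx$grid$slot_duration
  res <- cpp_expected_eval(a_ord, ctx$grid$slot_duration,
                           ctx$grid$session_length,
                           ctx$S, ctx$w, as.integer(ord - 1L))
  ewait <- numeric(ctx$n)
  ewait[ord] <- res$wait
  list(ewait = ewait, idle = res$idle, overtime = res$overtime)
}

# The fair variants replace the total-wait term with n times the worst
# show-conditional expected wait (per patient or per group): E[wait]/p is
# the waiting a patient faces when they do attend, so a group's low show
# rate cannot mask the waits imposed on its attendees.
compose_objective <- function(ewait, idle, overtime, variant, weights,
                              groups = NULL, show_probs = NULL) {
  n <- length(ewait)
  cond_wait <- function() {
    if (is.null(show_probs)) {
      abort("fair objectives need show probabilities for conditional waits")
    }
    ifelse(show_probs > 0, ewait / show_probs, 0)
  }
  wait_term <- switch(
    variant,
    TRADITIONAL = sum(ewait),
    RACE_UNAWARE = n * max(cond_wait()),
    RACE_AWARE = {
      if (is.null(groups)) {
        abort("configuration error: RACE_AWARE objective requires group labels",
              class = "fairbook_config_error")
      }
      n * max(tapply(cond_wait(), groups, mean))
    }
  )
  weights$w_wait * wait_term + weights$w_idle * idle +
    weights$w_overtime * overtime
}

# Total quota shortfall (0 when feasible); undefined fractions count as
# full shortfall.
ctx_shortfall <- function(ctx, slots) {
  if (length(ctx$constraints) == 0) return(0)
  sum(vapply(ctx$constraints, function(con) {
    fr <- quota_attained(slots, ctx$grid$n_slots, con, groups = ctx$groups,
                         show_probs = ctx$p, patient_id = ctx$patient_id)
    sum(pmax(0, fr$minimum - dplyr::coalesce(fr$attained, 0)))
  }, numeric(1)))
}

ctx_objective <- function(ctx, slots, penalty = 0) {
  obj <- cpp_objective(ctx$S, ctx$w, ctx$grid$slot_duration,
                       ctx$grid$session_length, as.integer(slots),
                       ctx$grid$n_slots, ctx$variant_code, ctx$wts,
                       ctx$group_idx, ctx$n_groups, ctx$p)
  if (penalty > 0) obj <- obj + penalty * ctx_shortfall(ctx, slots)
  obj
}

# ---- public objective -----------------------------------------------------

#' Objective value of an assignment under an objective specification
#'
#' Evaluates the expected outcome (exactly when the roster is small enough,
#' by Monte Carlo otherwise) and composes the variant's objective: schedule
#' cost for `TRADITIONAL`; the idle/overtime terms plus `n` times the
#' worst group mean expected wait (`RACE_AWARE`) or the worst individual
#' expected wait (`RACE_UNAWARE`).
#'
#' @inheritParams expected_outcome_exact
#' @param roster Roster (used for group labels under `RACE_AWARE` only).
#' @param spec An [objective_spec()].
#' @param ... Passed to [expected_outcome()].
#' @return Scalar objective value.
#' @export
objective_value <- function(assignment, grid, show_probs, roster = NULL,
                            spec = objective_spec(), ...) {
  out <- expected_outcome(assignment, grid, show_probs, ...)
  ewait <- out$patients$expected_wait
  groups <- NULL
  if (spec$variant == "RACE_AWARE") {
    if (is.null(roster) || !("group" %in% names(roster))) {
      abort("configuration error: RACE_AWARE objective requires group labels",
            class = "fairbook_config_error")
    }
    groups <- roster$group[match(out$patients$patient_id, roster$patient_id)]
  }
  compose_objective(ewait, out$idle, out$overtime, spec$variant,
                    spec$weights, groups, out$patients$show_prob)
}

# slot vector (roster order) -> assignment tibble with canonical priority
slots_to_assignment <- function(patient_id, slots) {
  assignment(patient_id, slots)
}

infeasibility_error <- function(constraints) {
  kinds <- vapply(constraints, function(x) x$kind, character(1))
  abort(sprintf(
    "infeasible: no capacity-feasible assignment satisfies the %s quota constraint(s)",
    paste(unique(kinds), collapse = " + ")),
    class = "fairbook_infeasible")
}

#' Exhaustive-enumeration optimal assignment (oracle)
#'
#' Enumerates every capacity-feasible assignment (within-slot priority
#' canonicalized to roster order), filters by the objective's quota constraints,
#' evaluates the exact objective, and returns the minimizer. Ties are broken
#' lexicographically on the roster-ordered slot encoding, which is
#' group-blind. Intended as the correctness reference on small instances.
#'
#' @param roster Roster tibble (`patient_id`, optionally `group`).
#' @param grid A [slot_grid()].
#' @param show_probs Predicted show probabilities, named or roster-aligned.
#' @param spec An [objective_spec()].
#' @param max_patients,max_slots Enumeration guards (defaults 7 and 5).
#' @return The optimal assignment tibble, with the attained objective in
#'   attribute `"objective"`.
#' @export
optimize_oracle <- function(roster, grid, show_probs, spec = objective_spec(),
                            max_patients = 7, max_slots = 5) {
  n <- nrow(roster)
  m <- grid$n_slots
  if (n > max_patients || m > max_slots) {
    abort(sprintf(
      "full enumeration limited to %d patients and %d slots (got %d, %d); use optimize_heuristic()",
      max_patients, max_slots, n, m), class = "fairbook_size_error")
  }
  p <- align_probs(show_probs, roster)
  groups <- if (spec$variant == "RACE_AWARE" || has_group_quota(spec)) {
    if (!("group" %in% names(roster))) {
      abort("configuration error: group labels required by the objective or constraints",
            class = "fairbook_config_error")
    }
    roster$group
  } else NULL
  ctx <- make_eval_ctx(grid, p, groups = groups, weights = spec$weights,
                       variant = spec$variant, constraints = spec$constraints,
                       patient_id = roster$patient_id)
  # all m^n slot vectors in lexicographic order (patient 1 most significant)
  r <- seq_len(m^n) - 1L
  A <- matrix(0L, nrow = m^n, ncol = n)
  for (j in seq_len(n)) {
    A[, j] <- (r %/% m^(n - j)) %% m + 1L
  }
  feasible <- rep(TRUE, nrow(A))
  for (s in seq_len(m)) {
    feasible <- feasible & rowSums(A == s) <= grid$capacity
  }
  A <- A[feasible, , drop = FALSE]
  best_obj <- Inf
  best_slots <- NULL
  any_capacity_feasible <- nrow(A) > 0
  for (i in seq_len(nrow(A))) {
    slots <- A[i, ]
    if (length(spec$constraints) > 0 && ctx_shortfall(ctx, slots) > 1e-12) next
    obj <- ctx_objective(ctx, slots)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_slots <- slots
    }
  }
  if (is.null(best_slots)) {
    if (any_capacity_feasible && length(spec$constraints) > 0) {
      infeasibility_error(spec$constraints)
    }
    abort("infeasible: no capacity-feasible assignment exists",
          class = "fairbook_infeasible")
  }
  out <- slots_to_assignment(roster$patient_id, best_slots)
  attr(out, "objective") <- best_obj
  attr(out, "spec") <- spec
  out
}

has_group_quota <- function(spec) {
  any(vapply(spec$constraints, function(x) x$kind == "group", logical(1)))
}

# Greedy initial assignment: the n_slots highest-show-probability patients
# get one slot each in slot order; remaining (lowest-probability) patients
# are placed one at a time into the penalized-objective-minimizing slot.
greedy_initial <- function(ctx, capacity, penalty) {
  n <- ctx$n
  m <- ctx$grid$n_slots
  ord <- order(-ctx$p, seq_len(n))
  slots <- integer(n)
  first <- ord[seq_len(min(n, m))]
  slots[first] <- seq_along(first)
  rest <- if (n > m) ord[(m + 1):n] else integer(0)
  for (i in rest) {
    load <- tabulate(slots[slots > 0], nbins = m)
    open <- which(load < capacity)
    best <- open[1]
    best_obj <- Inf
    for (s in open) {
      slots[i] <- s
      obj <- ctx_objective(ctx, slots, penalty)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- s
      }
    }
    slots[i] <- best
  }
  slots
}

local_search <- function(ctx, slots, capacity, penalty, max_passes) {
  # constraint-free search runs entirely in C++; the penalized
  # (quota-constrained) path stays in R where the quota arithmetic lives
  if (penalty == 0) {
    res <- cpp_local_search(ctx$S, ctx$w, ctx$grid$slot_duration,
                            ctx$grid$session_length, as.integer(slots),
                            ctx$grid$n_slots, as.integer(capacity),
                            ctx$variant_code, ctx$wts, ctx$group_idx,
                            ctx$n_groups, ctx$p, as.integer(max_passes))
    return(list(slots = as.integer(res$slots), obj = res$obj))
  }
  local_search_r(ctx, slots, capacity, penalty, max_passes)
}

local_search_r <- function(ctx, slots, capacity, penalty, max_passes) {
  m <- ctx$grid$n_slots
  n <- ctx$n
  obj <- ctx_objective(ctx, slots, penalty)
  pass <- 0
  repeat {
    if (pass >= max_passes) break
    pass <- pass + 1
    improved <- FALSE
    # single-patient moves
    for (i in seq_len(n)) {
      load <- tabulate(slots, nbins = m)
      for (s in seq_len(m)) {
        if (s == slots[i] || load[s] >= capacity) next
        cand <- slots
        cand[i] <- s
        cobj <- ctx_objective(ctx, cand, penalty)
        if (cobj < obj - 1e-9) {
          slots <- cand
          obj <- cobj
          improved <- TRUE
          load <- tabulate(slots, nbins = m)
        }
      }
    }
    # pairwise swaps
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (slots[i] == slots[j]) next
        cand <- slots
        cand[c(i, j)] <- slots[c(j, i)]
        cobj <- ctx_objective(ctx, cand, penalty)
        if (cobj < obj - 1e-9) {
          slots <- cand
          obj <- cobj
          improved <- TRUE
        }
      }
    }
    # slot-content swaps
    for (s1 in seq_len(m - 1)) {
      for (s2 in (s1 + 1):m) {
        cand <- slots
        cand[slots == s1] <- s2
        cand[slots == s2] <- s1
        if (identical(cand, slots)) next
        cobj <- ctx_objective(ctx, cand, penalty)
        if (cobj < obj - 1e-9) {
          slots <- cand
          obj <- cobj
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(slots = slots, obj = obj)
}

random_feasible_slots <- function(n, m, capacity) {
  pool <- rep(seq_len(m), capacity)
  sample(pool)[seq_len(n)]
}

#' Heuristic optimal assignment (multi-start local search)
#'
#' Scales the optimizer beyond enumeration: a greedy initial assignment
#' (one slot per patient in decreasing predicted show probability, then
#' cost-minimizing placement of the overbooked remainder) is improved by
#' local search over single-patient moves and pairwise swaps, with seeded
#' random restarts. Quota constraints are enforced through a large
#' feasibility penalty during search and verified on the returned
#' assignment; an assignment violating its constraints is never returned.
#'
#' @inheritParams optimize_oracle
#' @param seed Integer seed controlling scan order and restarts.
#' @param n_restarts Number of random restarts after the greedy start.
#' @param max_passes Maximum improvement passes per start; `0` returns the
#'   greedy initial assignment unimproved.
#' @param n_samples Monte-Carlo sample count used when the roster exceeds
#'   the exact-enumeration cutoff.
#' @return The best assignment found, with the attained objective in
#'   attribute `"objective"`.
#' @export
optimize_heuristic <- function(roster, grid, show_probs,
                               spec = objective_spec(), seed = 1,
                               n_restarts = 20, max_passes = 50,
                               n_samples = 2000) {
  n <- nrow(roster)
  m <- grid$n_slots
  if (n > m * grid$capacity) {
    abort("infeasible: more patients than total slot capacity",
          class = "fairbook_infeasible")
  }
  p <- align_probs(show_probs, roster)
  groups <- if (spec$variant == "RACE_AWARE" || has_group_quota(spec)) {
    if (!("group" %in% names(roster))) {
      abort("configuration error: group labels required by the objective or constraints",
            class = "fairbook_config_error")
    }
    roster$group
  } else NULL
  ctx <- make_eval_ctx(grid, p, groups = groups, weights = spec$weights,
                       variant = spec$variant, constraints = spec$constraints,
                       patient_id = roster$patient_id, n_samples = n_samples,
                       seed = seed)
  penalty <- if (length(spec$constraints) > 0) 1e7 else 0
  result <- with_seed(seed, {
    slots0 <- greedy_initial(ctx, grid$capacity, penalty)
    if (max_passes == 0) {
      list(slots = slots0, obj = ctx_objective(ctx, slots0, penalty))
    } else {
      best <- local_search(ctx, slots0, grid$capacity, penalty, max_passes)
      for (k in seq_len(n_restarts)) {
        start <- random_feasible_slots(n, m, grid$capacity)
        cand <- local_search(ctx, start, grid$capacity, penalty, max_passes)
        if (cand$obj < best$obj - 1e-9) best <- cand
      }
      best
    }
  })
  if (length(spec$constraints) > 0 &&
      ctx_shortfall(ctx, result$slots) > 1e-9) {
    infeasibility_error(spec$constraints)
  }
  out <- slots_to_assignment(roster$patient_id, result$slots)
  attr(out, "objective") <- ctx_objective(ctx, result$slots)
  attr(out, "spec") <- spec
  out
}
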