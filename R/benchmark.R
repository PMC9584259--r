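#' Configure a method-comparison experiment
#'
#' Defines the replicated-clinic-day experiment comparing scheduling
#' methods. Each method pairs a show-model regime with an objective
#' variant:
#'
#' * `SOTA` — FULL model, TRADITIONAL objective (the cost-minimizing
#'   state of the art);
#' * `NO_ML` — no model (constant population show rate), TRADITIONAL;
#' * `NO_SES` — history-features-only model, TRADITIONAL;
#' * `RACE_AWARE` — FULL model, min-max group-mean-wait objective;
#' * `RACE_UNAWARE` — FULL model, min-max individual-wait objective.
#'
#' Show models are fit once on a training population of `n_train` patients
#' drawn from the same generator, then applied to every replicated day.
#' Defaults give a 10-slot, 12-patient day with capacity 2, which keeps
#' exact expectation evaluation (2^12 outcomes) feasible while forcing two
#' overbooks.
#'
#' @param population A [population_config()] (its `n_patients` is ignored;
#'   `n_train` and `n_patients_day` control sizes here).
#' @param n_slots,slot_duration,capacity Clinic-day grid parameters.
#' @param n_patients_day Patients per replicated day.
#' @param weights [cost_weights()] used both inside the TRADITIONAL
#'   objective and for all cost reporting.
#' @param methods Character vector of method names (subset of the five
#'   above; `SOTA` is needed for optimality gaps).
#' @param n_days Number of replicated clinic days (>= 1).
#' @param n_train Training-population size for model fitting.
#' @param n_restarts,max_passes Search budget for the per-day heuristic
#'   optimizer.
#' @param seed Master seed; every downstream draw is derived from it.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(population = population_config(),
                              n_slots = 10, slot_duration = 30, capacity = 2,
                              n_patients_day = 12,
                              weights = cost_weights(),
                              methods = c("SOTA", "NO_ML", "NO_SES",
                                          "RACE_AWARE", "RACE_UNAWARE"),
                              n_days = 200, n_train = 2000,
                              n_restarts = 1, max_passes = 50,
                              seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_days >= 1, n_patients_day >= 1,
            n_patients_day <= n_slots * capacity,
            inherits(population, "population_config"),
            inherits(weights, "cost_weights"))
  structure(
    list(population = population, n_slots = n_slots,
         slot_duration = slot_duration, capacity = capacity,
         n_patients_day = n_patients_day, weights = weights,
         methods = methods, n_days = as.integer(n_days),
         n_train = as.integer(n_train), n_restarts = n_restarts,
         max_passes = max_passes, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Aggregate disparity across replicated days as a ratio of averages: the
# percent difference between the day-averaged group mean waits. Averaging
# per-day percent differences instead would be biased on small rosters,
# where the bounded per-day ratio saturates whenever the minority group
# happens to draw no delayed patient.
pooled_disparity <- function(mean_wait_B, mean_wait_nonB) {
  keep <- !is.na(mean_wait_B) & !is.na(mean_wait_nonB)
  mb <- mean(mean_wait_B[keep])
  mo <- mean(mean_wait_nonB[keep])
  if (mb == 0 && mo == 0) return(0)
  100 * (mb - mo) / ((mb + mo) / 2)
}

# Leave-one-day-out jackknife standard error of the pooled disparity.
pooled_disparity_se <- function(mean_wait_B, mean_wait_nonB) {
  keep <- !is.na(mean_wait_B) & !is.na(mean_wait_nonB)
  mb <- mean_wait_B[keep]
  mo <- mean_wait_nonB[keep]
  k <- length(mb)
  if (k < 2) return(NA_real_)
  reps <- vapply(seq_len(k), function(i) {
    pooled_disparity(mb[-i], mo[-i])
  }, numeric(1))
  sqrt((k - 1) / k * sum((reps - mean(reps))^2))
}

method_regime <- function(method) {
  switch(method,
         SOTA = "FULL", NO_ML = "NONE", NO_SES = "NO_SES",
         RACE_AWARE = "FULL", RACE_UNAWARE = "FULL")
}

method_variant <- function(method) {
  switch(method,
         SOTA = "TRADITIONAL", NO_ML = "TRADITIONAL", NO_SES = "TRADITIONAL",
         RACE_AWARE = "RACE_AWARE", RACE_UNAWARE = "RACE_UNAWARE")
}

#' Run the method comparison over replicated clinic days
#'
#' For each replicated day: draw a fresh roster from the population
#' generator, predict show probabilities with each method's (pre-fit)
#' model, optimize the day's schedule under the method's objective, then
#' evaluate the *true* expected outcome of the chosen schedule under the
#' generator's latent show probabilities — so differences in prediction
#' quality surface as realized cost and waits. Per-day optimality gaps are
#' taken against `SOTA`'s cost on the same day. The summary disparity per
#' method is the percent difference between the day-averaged group mean
#' show-conditional waits (a ratio of averages, with a jackknife standard
#' error); per-day disparities are also reported in the day table, but on
#' 12-patient rosters they are individually noisy and bounded, so their
#' plain mean is a biased aggregate. Days drawing a single group
#' contribute `NA` to the disparity columns.
#'
#' Fully reproducible from the master seed.
#'
#' @param config An [experiment_config()].
#' @return A `method_comparison` object; [tidy()] returns the per-day
#'   results, [glance()] (or `$summary`) the per-method aggregate table
#'   with Monte-Carlo standard errors.
#' @export
run_comparison <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- with_seed(config$seed, {
    list(train = sample.int(2^30, 1),
         days = sample.int(2^30, config$n_days),
         opt = matrix(sample.int(2^30, config$n_days * length(config$methods)),
                      nrow = config$n_days))
  })
  grid <- slot_grid(config$n_slots, config$slot_duration, config$capacity)

  # fit each required regime once on the training population
  train_pop_cfg <- config$population
  train_pop_cfg$n_patients <- config$n_train
  train_roster <- generate_population(train_pop_cfg, seed = seeds$train,
                                      id_prefix = "tr")
  regimes <- unique(vapply(config$methods, method_regime, character(1)))
  models <- lapply(setNames(regimes, regimes), function(rg) {
    fit_show_model(attr(train_roster, "history"), train_roster, regime = rg)
  })

  day_pop_cfg <- config$population
  day_pop_cfg$n_patients <- config$n_patients_day

  days <- purrr::map_dfr(seq_len(config$n_days), function(d) {
    roster <- generate_population(day_pop_cfg, seed = seeds$days[d],
                                  id_prefix = sprintf("d%d_", d))
    true_p <- setNames(roster$show_prob, roster$patient_id)
    purrr::imap_dfr(setNames(config$methods, config$methods), function(method, nm) {
      res <- tryCatch({
        model <- models[[method_regime(method)]]
        pred <- predict_show_prob(model, roster)
        spec <- objective_spec(method_variant(method), weights = config$weights)
        mi <- match(method, config$methods)
        asg <- optimize_heuristic(roster, grid, pred, spec,
                                  seed = seeds$opt[d, mi],
                                  n_restarts = config$n_restarts,
                                  max_passes = config$max_passes)
        out <- expected_outcome(asg, grid, true_p, seed = seeds$opt[d, mi])
        disp <- tryCatch(wait_disparity(out, roster),
                         fairbook_undefined_metric = function(e) NA_real_)
        grp <- roster$group[match(out$patients$patient_id, roster$patient_id)]
        cw <- ifelse(out$patients$show_prob > 0,
                     out$patients$expected_wait / out$patients$show_prob, 0)
        tibble::tibble(
          day = d, method = method,
          cost = schedule_cost(out, config$weights),
          disparity_pct = disp,
          mean_wait_B = mean(cw[grp == "B"]),
          mean_wait_nonB = mean(cw[grp == "nonB"])
        )
      }, error = function(e) {
        abort(sprintf("day %d, method %s: %s", d, method, conditionMessage(e)),
              parent = e)
      })
      res
    })
  })

  if ("SOTA" %in% config$methods) {
    sota <- days |>
      dplyr::filter(.data$method == "SOTA") |>
      dplyr::select("day", sota_cost = "cost")
    days <- days |>
      dplyr::left_join(sota, by = "day") |>
      dplyr::mutate(gap_pct = 100 * (.data$cost - .data$sota_cost) / .data$sota_cost) |>
      dplyr::select(-"sota_cost")
  } else {
    days$gap_pct <- NA_real_
  }

  mc_se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  summary <- days |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_gap_pct = mean(.data$gap_pct),
      se_gap_pct = mc_se(.data$gap_pct),
      mean_disparity_pct = pooled_disparity(.data$mean_wait_B,
                                            .data$mean_wait_nonB),
      se_disparity_pct = pooled_disparity_se(.data$mean_wait_B,
                                             .data$mean_wait_nonB),
      mean_cost = mean(.data$cost),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$method, config$methods))
  class(summary) <- c("comparison_table", class(summary))

  structure(list(days = days, summary = summary, config = config),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d methods x %d days\n",
              length(x$config$methods), x$config$n_days))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @rdname run_comparison
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @export
tidy.method_comparison <- function(x, ...) x$days

#' @rdname run_comparison
#' @export
glance.method_comparison <- function(x, ...) tibble::as_tibble(x$summary)

#' Plot the method comparison: disparity against schedule quality
#'
#' Scatter of each method's mean signed wait disparity (x) against its
#' mean optimality gap (y, inverted so higher is better quality), with
#' Monte-Carlo standard-error bars.
#'
#' @param object A `method_comparison` or its summary `comparison_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.method_comparison <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' @rdname autoplot.method_comparison
#' @export
autoplot.comparison_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_disparity_pct,
                                   y = -.data$mean_gap_pct,
                                   label = .data$method)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = -(.data$mean_gap_pct + 2 * .data$se_gap_pct),
      ymax = -(.data$mean_gap_pct - 2 * .data$se_gap_pct)), width = 0.2) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$mean_disparity_pct - 2 * .data$se_disparity_pct,
      xmax = .data$mean_disparity_pct + 2 * .data$se_disparity_pct),
      height = 0.02) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(x = "mean wait-time disparity (%)",
                  y = "schedule quality (- optimality gap %)") +
    ggplot2::theme_minimal()
}
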