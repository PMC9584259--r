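#' Fit a show-probability model under a feature regime
#'
#' The prediction stage of the pipeline. Three regimes correspond to the
#' intervention menu on the machine-learning component:
#'
#' * `"FULL"` — logistic regression of the per-visit show indicator on all
#'   SES features plus running history summaries (past shows, past visits).
#' * `"NO_SES"` — the same fit with every SES feature excluded; predictions
#'   are invariant to SES values by construction.
#' * `"NONE"` — no model: every patient is assigned the overall mean show
#'   rate of the history.
#'
#' History summaries are computed causally within the training table: the
#' row for a patient's visit *t* sees only visits before *t*.
#'
#' @param history History table (`patient_id`, `visit`, `show`), e.g. from
#'   [generate_history()].
#' @param roster Roster providing each patient's feature values.
#' @param regime One of `"FULL"`, `"NO_SES"`, `"NONE"`.
#' @param ses Character vector of SES feature names (default
#'   [ses_features()]).
#'
#' @return A `show_model` object with elements `regime`, `coef` (named
#'   coefficient vector; `NONE` stores the population rate instead) and the
#'   training fit. Supports [tidy()], [glance()], [predict_show_prob()].
#' @export
fit_show_model <- function(history, roster, regime = c("FULL", "NO_SES", "NONE"),
                           ses = ses_features()) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(history))
  if (nrow(history) == 0 && regime != "NONE") {
    abort("nonempty history required for FULL / NO_SES regimes",
          class = "fairbook_fit_error")
  }
  if (regime == "NONE") {
    rate <- if (nrow(history) > 0) mean(history$show) else 0.5
    return(structure(list(regime = regime, rate = rate, coef = NULL,
                          features = character(), fit = NULL,
                          n_obs = nrow(history)),
                     class = "show_model"))
  }
  if (length(unique(history$show)) < 2) {
    abort(paste("degenerate history: all visits have the same show outcome;",
                "a logistic model cannot be fit"),
          class = "fairbook_fit_error")
  }
  train <- history |>
    dplyr::arrange(.data$patient_id, .data$visit) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(past_shows = dplyr::lag(cumsum(.data$show), default = 0L),
                  past_visits = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(roster, "patient_id", dplyr::all_of(ses)),
      by = "patient_id"
    )
  feats <- switch(regime,
                  FULL = c(ses, history_features()),
                  NO_SES = history_features())
  form <- stats::reformulate(feats, response = "show")
  fit <- glm(form, family = binomial(), data = train)
  structure(
    list(regime = regime, rate = mean(history$show),
         coef = stats::coef(fit), features = feats, fit = fit,
         n_obs = nrow(train)),
    class = "show_model"
  )
}

#' @export
print.show_model <- function(x, ...) {
  if (x$regime == "NONE") {
    cat(sprintf("<show_model> regime NONE: constant population show rate %.4f\n",
                x$rate))
  } else {
    cat(sprintf("<show_model> regime %s: logistic fit on %d visits\n",
                x$regime, x$n_obs))
    print(round(x$coef, 4))
  }
  invisible(x)
}

#' Predict show probabilities for a roster
#'
#' @param model A `show_model` from [fit_show_model()].
#' @param roster Roster providing the features the regime requires (the
#'   history features here are the patient's full-history summaries).
#'
#' @return Numeric vector of probabilities in `[0, 1]`, one per roster row;
#'   the `NONE` regime returns its stored constant for every patient.
#' @export
predict_show_prob <- function(model, roster) {
  stopifnot(inherits(model, "show_model"), is.data.frame(roster))
  if (model$regime == "NONE") {
    return(rep(model$rate, nrow(roster)))
  }
  missing <- setdiff(model$features, names(roster))
  if (length(missing) > 0) {
    abort(sprintf("missing required feature(s): %s",
                  paste(missing, collapse = ", ")),
          class = "fairbook_input_error")
  }
  x <- as.matrix(roster[model$features])
  lp <- drop(model$coef[["(Intercept)"]] + x %*% model$coef[model$features])
  unname(plogis(lp))
}

#' Append model predictions to a roster
#'
#' @inheritParams predict_show_prob
#' @param column Name of the prediction column to add.
#' @return The roster with a predicted show-probability column.
#' @export
augment_show_prob <- function(roster, model, column = "show_prob_pred") {
  roster[[column]] <- predict_show_prob(model, roster)
  roster
}

#' @rdname fit_show_model
#' @param x A `show_model`.
#' @param ... Unused.
#' @export
tidy.show_model <- function(x, ...) {
  if (x$regime == "NONE") {
    return(tibble::tibble(term = "rate", estimate = x$rate,
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_show_model
#' @export
glance.show_model <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    n_obs = x$n_obs,
    rate = x$rate,
    deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance,
    aic = if (is.null(x$fit)) NA_real_ else x$fit$aic
  )
}

#' Persist a show model as structured text
#'
#' Writes / reads the regime, the population rate and the coefficient vector
#' as YAML; a read-back model predicts identically to the original.
#'
#' @param model A `show_model`.
#' @param path File path.
#' @return `write_show_model` returns `path` invisibly; `read_show_model`
#'   returns a `show_model`.
#' @export
write_show_model <- function(model, path) {
  stopifnot(inherits(model, "show_model"))
  writeLines(yaml::as.yaml(
    list(regime = model$regime, rate = model$rate,
         features = as.list(model$features),
         coef = as.list(model$coef)),
    precision = 15
  ), path)
  invisible(path)
}

#' @rdname write_show_model
#' @export
read_show_model <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(
    list(regime = doc$regime, rate = doc$rate,
         coef = unlist(doc$coef), features = unlist(doc$features) %||% character(),
         fit = NULL, n_obs = NA_integer_),
    class = "show_model"
  )
}
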