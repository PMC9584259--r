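#' Configure the synthetic clinic population
#'
#' The generator emulates a clinic population in which socio-economic (SES)
#' features are shifted between a binary group label (`"B"` / `"nonB"`) and
#' the latent show probability is a logistic function of the SES features
#' alone. Group therefore influences attendance only through its correlated
#' features, so group-differential outcomes downstream emerge as proxy
#' effects rather than being injected directly.
#'
#' The default parameters give group B (30% of patients) a mean show
#' probability near 0.70 against 0.85 for group nonB, and an overall show
#' rate near 0.80.
#'
#' @param n_patients Number of patients to draw.
#' @param fraction_group_B Probability a patient belongs to group B
#'   (default 0.30).
#' @param income_shift Difference in mean standardized income index for
#'   group B relative to nonB (default -1.5; both groups have unit SD).
#' @param employed_prob Length-2 named vector of employment probabilities,
#'   `c(nonB = , B = )`.
#' @param married_prob Length-2 named vector of marriage probabilities.
#' @param show_coef Named numeric: logistic intercept and coefficients on
#'   `income_index`, `employed`, `married` defining the latent show
#'   probability.
#' @param history_length Number of past appointments generated per patient
#'   (default 8).
#'
#' @return A `population_config` list.
#' @export
population_config <- function(n_patients = 1000,
                              fraction_group_B = 0.30,
                              income_shift = -1.5,
                              employed_prob = c(nonB = 0.90, B = 0.70),
                              married_prob = c(nonB = 0.55, B = 0.40),
                              show_coef = c(intercept = 0.95,
                                            income_index = 0.5,
                                            employed = 0.8,
                                            married = 0.3),
                              history_length = 8) {
  stopifnot(n_patients >= 1,
            fraction_group_B > 0, fraction_group_B < 1,
            all(c("nonB", "B") %in% names(employed_prob)),
            all(c("nonB", "B") %in% names(married_prob)),
            all(c("intercept", ses_features()) %in% names(show_coef)),
            history_length >= 0)
  structure(
    list(n_patients = as.integer(n_patients),
         fraction_group_B = fraction_group_B,
         income_shift = income_shift,
         employed_prob = employed_prob,
         married_prob = married_prob,
         show_coef = show_coef,
         history_length = as.integer(history_length)),
    class = "population_config"
  )
}

#' Generate a synthetic patient roster
#'
#' Draws group labels Bernoulli(`fraction_group_B`), SES features from
#' group-shifted distributions, and sets each patient's latent true show
#' probability to the logistic of the configured linear predictor. When
#' `history_length > 0` an attendance history is drawn from the true show
#' probabilities and summarized into `past_shows` / `past_visits` roster
#' columns (the history features available to prediction models).
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @param id_prefix Prefix for generated patient identifiers.
#'
#' @return A roster tibble with columns `patient_id`, `group`, the SES
#'   features, the history features, and the latent `show_prob`. The full
#'   history table is attached as attribute `"history"` (see
#'   [generate_history()]).
#' @examples
#' roster <- generate_population(population_config(n_patients = 50), seed = 1)
#' dplyr::count(roster, group)
#' @export
generate_population <- function(config = population_config(), seed = 1,
                                id_prefix = "p") {
  stopifnot(inherits(config, "population_config"))
  roster <- with_seed(seed, {
    n <- config$n_patients
    group <- ifelse(runif(n) < config$fraction_group_B, "B", "nonB")
    income_index <- rnorm(n, mean = ifelse(group == "B", config$income_shift, 0))
    employed <- as.numeric(runif(n) < config$employed_prob[group])
    married <- as.numeric(runif(n) < config$married_prob[group])
    b <- config$show_coef
    lp <- b[["intercept"]] + b[["income_index"]] * income_index +
      b[["employed"]] * employed + b[["married"]] * married
    p <- plogis(lp)
    if (any(p <= 0 | p >= 1 | !is.finite(p))) {
      abort("configuration error: show-model coefficients yield degenerate probabilities",
            class = "fairbook_config_error")
    }
    tibble::tibble(
      patient_id = sprintf("%s%0*d", id_prefix, nchar(n), seq_len(n)),
      group = group,
      income_index = income_index,
      employed = employed,
      married = married,
      show_prob = p
    )
  })
  history <- generate_history(roster, config$history_length, seed = seed + 1L)
  roster <- add_history_features(roster, history)
  attr(roster, "history") <- history
  roster
}

#' Generate an attendance history table
#'
#' Draws `history_length` independent past-visit show indicators per patient
#' from each patient's true show probability.
#'
#' @param roster Roster with `patient_id` and `show_prob` columns.
#' @param history_length Number of past appointments per patient (>= 0).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `patient_id`, `visit` (1-based past
#'   appointment index) and `show` (0/1); `n_patients * history_length`
#'   rows, empty when `history_length` is 0.
#' @export
generate_history <- function(roster, history_length, seed = 1) {
  stopifnot(is.data.frame(roster), history_length >= 0)
  if (history_length == 0) {
    return(tibble::tibble(patient_id = character(), visit = integer(),
                          show = integer()))
  }
  with_seed(seed, {
    tidyr::expand_grid(
      patient_id = roster$patient_id,
      visit = seq_len(history_length)
    ) |>
      dplyr::left_join(dplyr::select(roster, "patient_id", "show_prob"),
                       by = "patient_id") |>
      dplyr::mutate(show = rbinom(dplyr::n(), 1, .data$show_prob)) |>
      dplyr::select("patient_id", "visit", "show")
  })
}

#' Summarize an attendance history into roster features
#'
#' Adds `past_shows` (number of attended past visits) and `past_visits`
#' (number of past visits) columns to the roster.
#'
#' @param roster Roster tibble.
#' @param history History table from [generate_history()].
#' @return The roster with history feature columns appended.
#' @export
add_history_features <- function(roster, history) {
  summ <- history |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(past_shows = sum(.data$show),
                     past_visits = dplyr::n(), .groups = "drop")
  roster |>
    dplyr::select(-dplyr::any_of(history_features())) |>
    dplyr::left_join(summ, by = "patient_id") |>
    dplyr::mutate(past_shows = dplyr::coalesce(.data$past_shows, 0L),
                  past_visits = dplyr::coalesce(.data$past_visits, 0L))
}
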