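# broom-style tidiers for the engine's result objects.

#' Tidy a diagnosis into its belief table
#'
#' One row per disorder hypothesis with its status and confirmed-symptom
#' fraction.
#'
#' @param x A `vriksha_diagnosis`.
#' @param ... Unused.
#' @return A tibble with columns `disorder_id`, `status`,
#'   `confirmed_fraction`, `n_yes`, `n_no`, `n_symptoms`.
#' @method tidy vriksha_diagnosis
#' @export
tidy.vriksha_diagnosis <- function(x, ...) {
  tibble(
    disorder_id = x$belief$disorder_id,
    status = x$belief$status,
    confirmed_fraction = x$belief$confirmed_fraction,
    n_yes = lengths(x$belief$yes_facts),
    n_no = lengths(x$belief$no_facts),
    n_symptoms = x$belief$n_symptoms
  )
}

#' @rdname tidy.vriksha_diagnosis
#' @method glance vriksha_diagnosis
#' @export
glance.vriksha_diagnosis <- function(x, ...) {
  tibble(
    primary = x$primary,
    n_confirmed = length(x$confirmed),
    n_questions = length(x$question_log),
    n_hypotheses_evaluated = length(x$evaluated),
    stop_at_first = x$stop_at_first,
    exhaustive = x$exhaustive
  )
}

#' Tidy evaluation metrics into the confusion table
#'
#' @param x A `vriksha_metrics`.
#' @param ... Unused.
#' @return `tidy()`: the confusion tibble (`true_disorder_id`, `predicted`,
#'   `n`); `glance()`: a one-row summary.
#' @method tidy vriksha_metrics
#' @export
tidy.vriksha_metrics <- function(x, ...) {
  x$confusion
}

#' @rdname tidy.vriksha_metrics
#' @method glance vriksha_metrics
#' @export
glance.vriksha_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    mean_questions = x$mean_questions,
    n_cases = x$n_cases
  )
}
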