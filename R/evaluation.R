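# Synthetic-case generation and accuracy harness.
#
# Each case starts from the indicator vector of its true disorder ("yes"
# exactly on that disorder's symptoms) and flips every entry independently
# with probability noise_rate — a stand-in for imperfect field observation
# by the person answering the questions. The harness runs the full
# backward-chaining engine on each case and reports accuracy, mean
# question count and a confusion table.

#' Generate one synthetic diagnostic case
#'
#' @param kb A valid `vriksha_kb`.
#' @param disorder_id True disorder the case is built from.
#' @param noise_rate Independent flip probability per symptom, in `[0, 1]`.
#'   At 0 the vector is exactly the disorder's indicator; at 1 it is the
#'   deterministic complement.
#' @param seed Integer seed; the same seed reproduces the same case.
#' @return A `vriksha_case`: list with `true_disorder_id`, `answer_vector`
#'   (named "yes"/"no" over every KB symptom), `noise_rate`, `seed`.
#' @export
generate_case <- function(kb, disorder_id, noise_rate = 0, seed = 1L) {
  if (!is.numeric(noise_rate) || length(noise_rate) != 1 ||
    is.na(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    abort("noise_rate must be a single number in [0, 1]",
      class = "vriksha_range_error"
    )
  }
  body <- disorder_body(kb, disorder_id)
  sids <- kb$symptoms$id
  base <- ifelse(sids %in% body, "yes", "no")
  flip <- withr::with_seed(as.integer(seed), runif(length(sids)) < noise_rate)
  vec <- ifelse(flip, ifelse(base == "yes", "no", "yes"), base)
  names(vec) <- sids
  structure(
    list(
      true_disorder_id = disorder_id, answer_vector = vec,
      noise_rate = noise_rate, seed = as.integer(seed)
    ),
    class = "vriksha_case"
  )
}

# Fixed arithmetic expansion of a master seed into per-case seeds: kept
# within double precision and below 2^31 so set.seed() accepts them.
expand_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) * 10007 + seq_len(n)) %% 2147483647)
}

#' Generate a suite of synthetic cases from a master seed
#'
#' Builds `n_per_disorder` cases for each requested disorder. The master
#' seed expands into per-case seeds by fixed arithmetic, so a suite is
#' fully reproducible from `(kb, disorder_ids, noise_rate, n_per_disorder,
#' master_seed)`. If any disorder's symptom set is nested inside
#' another's, the ambiguity (the inner rule fires on the outer indicator)
#' is reported as a warning; see [detect_nested_rules()].
#'
#' @inheritParams generate_case
#' @param disorder_ids Disorders to generate cases for (default: all).
#' @param n_per_disorder Cases per disorder.
#' @param master_seed Master integer seed.
#' @return List of `vriksha_case` objects.
#' @export
generate_cases <- function(kb, noise_rate = 0, n_per_disorder = 1,
                           master_seed = 1L, disorder_ids = kb$disorders$id) {
  nested <- detect_nested_rules(kb)
  if (nrow(nested) > 0) {
    warn(c(
      "Knowledge base contains nested rules; noise-free cases for the outer disorder also satisfy the inner rule:",
      setNames(
        sprintf("'%s' is a subset of '%s'", nested$inner, nested$outer),
        rep("!", nrow(nested))
      )
    ))
  }
  grid <- expand.grid(
    rep = seq_len(n_per_disorder), disorder_id = disorder_ids,
    stringsAsFactors = FALSE
  )
  seeds <- expand_seeds(master_seed, nrow(grid))
  purrr::map(seq_len(nrow(grid)), function(i) {
    generate_case(kb, grid$disorder_id[[i]], noise_rate = noise_rate, seed = seeds[[i]])
  })
}

#' Detect nested rule bodies
#'
#' Finds ordered pairs of disorders where one symptom set is a strict
#' subset of another. On such KBs a single-disorder indicator vector for
#' the outer disorder also fires the inner rule, so noise-free recovery of
#' the outer disorder as primary is not guaranteed.
#'
#' @param kb A valid `vriksha_kb`.
#' @return Tibble with columns `inner`, `outer`.
#' @export
detect_nested_rules <- function(kb) {
  ids <- kb$disorders$id
  bodies <- kb$disorders$symptom_ids
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i != j && length(bodies[[i]]) < length(bodies[[j]]) &&
        all(bodies[[i]] %in% bodies[[j]])) {
        pairs <- c(pairs, list(tibble(inner = ids[[i]], outer = ids[[j]])))
      }
    }
  }
  if (length(pairs) == 0) {
    tibble(inner = character(), outer = character())
  } else {
    purrr::list_rbind(pairs)
  }
}

#' Evaluate the engine over a suite of synthetic cases
#'
#' Runs [diagnose()] with a scripted provider on each case
#' (`stop_at_first = FALSE`, so every hypothesis is scored) and scores
#' the primary conclusion against the case's true disorder. Cases whose
#' vector satisfies no rule count as incorrect with predicted `"none"`.
#' Deterministic given the cases.
#'
#' @param kb A valid `vriksha_kb`.
#' @param cases Non-empty list of `vriksha_case` objects.
#' @return A `vriksha_metrics`: list with `accuracy`, `mean_questions`,
#'   `confusion` (tibble of true -> predicted counts), `cases` (per-case
#'   tibble incl. the per-case seeds for replay) and `n_cases`.
#' @export
evaluate_cases <- function(kb, cases) {
  if (length(cases) == 0) {
    abort("Case list must be non-empty", class = "vriksha_contract_error")
  }
  rows <- purrr::map(cases, function(cs) {
    d <- diagnose(kb, scripted_provider(cs$answer_vector), stop_at_first = FALSE)
    predicted <- if (is.na(d$primary)) "none" else d$primary
    tibble(
      true_disorder_id = cs$true_disorder_id,
      predicted = predicted,
      correct = identical(predicted, cs$true_disorder_id),
      n_questions = length(d$question_log),
      n_confirmed = length(d$confirmed),
      noise_rate = cs$noise_rate,
      seed = cs$seed
    )
  }) |> purrr::list_rbind()
  confusion <- rows |>
    dplyr::count(.data$true_disorder_id, .data$predicted, name = "n") |>
    dplyr::arrange(.data$true_disorder_id, .data$predicted)
  structure(
    list(
      accuracy = mean(rows$correct),
      mean_questions = mean(rows$n_questions),
      confusion = confusion,
      cases = rows,
      n_cases = nrow(rows)
    ),
    class = "vriksha_metrics"
  )
}

#' Serialize metrics
#'
#' `write_metrics()` writes the full metrics object as JSON (bit-identical
#' for identical metrics); `write_confusion_csv()` writes the confusion
#' table as CSV.
#'
#' @param m A `vriksha_metrics`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(m, path) {
  jsonlite::write_json(
    list(
      accuracy = m$accuracy,
      mean_questions = m$mean_questions,
      n_cases = m$n_cases,
      confusion = m$confusion,
      cases = m$cases
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_confusion_csv <- function(m, path) {
  readr::write_csv(m$confusion, path)
  invisible(path)
}

#' @export
print.vriksha_metrics <- function(x, ...) {
  cat(sprintf(
    "<vriksha_metrics> %d case(s): accuracy %.3f, mean questions %.1f\n",
    x$n_cases, x$accuracy, x$mean_questions
  ))
  print(x$confusion)
  invisible(x)
}
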