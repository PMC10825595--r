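# Backward-chaining inference engine.
#
# The engine treats each disorder as a goal and works backwards from it:
# to conclude the disorder, every symptom in its conjunctive rule body must
# be a "yes" fact. Facts are acquired through an answer provider (a user
# dialogue or a scripted vector) and memoized in working memory, so a
# symptom shared by several hypotheses is asked at most once per session.
# A "no" on any symptom rejects the hypothesis immediately (unless running
# exhaustively) and the engine moves to the next goal in taxonomy order.

TRACE_KINDS <- c(
  "goal_selected", "question_asked", "fact_recorded",
  "belief_updated", "hypothesis_concluded"
)

#' Create an empty working memory
#'
#' Working memory holds the session's memoized symptom facts and the
#' ordered log of questions actually asked. It is an environment, mutated
#' in place by [evaluate_hypothesis()] so facts persist across hypotheses.
#'
#' @return A `vriksha_wm` environment with fields `facts` (named character
#'   vector of "yes"/"no"), `provenance` (named character) and
#'   `question_log` (character).
#' @export
new_working_memory <- function() {
  wm <- new.env(parent = emptyenv())
  wm$facts <- character()
  wm$provenance <- character()
  wm$question_log <- character()
  class(wm) <- "vriksha_wm"
  wm
}

new_session <- function(kb, wm = new_working_memory()) {
  s <- new.env(parent = emptyenv())
  s$kb <- kb
  s$wm <- wm
  s$trace <- list()
  s$ordinal <- 0L
  s$goal <- NULL
  s$pending_symptom <- NULL
  class(s) <- "vriksha_session"
  s
}

trace_add <- function(session, kind, disorder_id = NA_character_,
                      symptom_id = NA_character_, value = NA_character_) {
  session$ordinal <- session$ordinal + 1L
  session$trace[[session$ordinal]] <- list(
    ordinal = session$ordinal, kind = kind, disorder_id = disorder_id,
    symptom_id = symptom_id, value = value
  )
  invisible(session)
}

trace_tibble <- function(session) {
  if (length(session$trace) == 0) {
    return(tibble(
      ordinal = integer(), kind = character(), disorder_id = character(),
      symptom_id = character(), value = character()
    ))
  }
  purrr::map(session$trace, as_tibble) |> purrr::list_rbind()
}

#' Build a scripted answer provider from a named answer vector
#'
#' @param answers Named character vector (or named list) mapping symptom id
#'   to `"yes"`/`"no"`. Need not cover the whole KB; asking for a missing
#'   symptom is a provider error.
#' @return A provider function `f(symptom_id, state)` usable with
#'   [diagnose()]; its facts carry provenance `"scripted"`.
#' @export
scripted_provider <- function(answers) {
  answers <- unlist(answers)
  if (is.null(names(answers)) || any(!nzchar(names(answers)))) {
    abort("Scripted answers must be a named vector of 'yes'/'no'",
      class = "vriksha_contract_error"
    )
  }
  f <- function(symptom_id, state = NULL) {
    if (!symptom_id %in% names(answers)) {
      abort(sprintf("Scripted answers do not cover symptom '%s'", symptom_id),
        class = "vriksha_provider_error"
      )
    }
    answers[[symptom_id]]
  }
  attr(f, "provenance") <- "scripted"
  f
}

check_answer_value <- function(value, symptom_id) {
  if (!is.character(value) || length(value) != 1 || !value %in% c("yes", "no")) {
    abort(
      sprintf(
        "Answer provider must return 'yes' or 'no' for symptom '%s'",
        symptom_id
      ),
      class = "vriksha_provider_error"
    )
  }
  value
}

#' Evaluate a single disorder hypothesis
#'
#' Backward-chains on one goal: walks the disorder's symptoms in listed
#' order, reusing any fact already in working memory and asking the answer
#' provider only for unknown ones. Returns `"rejected"` at the first "no"
#' (the hypothesis's remaining symptoms are not asked, unless `exhaustive`)
#' and `"confirmed"` iff every symptom is answered "yes". Working memory is
#' updated in place, so later hypotheses sharing symptoms re-ask nothing.
#'
#' @param kb A valid `vriksha_kb`.
#' @param disorder_id Goal disorder; unknown ids raise a lookup error.
#' @param wm Working memory from [new_working_memory()]; mutated in place.
#' @param answers Answer provider: function of `(symptom_id, state)`
#'   returning `"yes"` or `"no"`, or a named answer vector (wrapped via
#'   [scripted_provider()]).
#' @param exhaustive If `TRUE`, keep asking the hypothesis's remaining
#'   symptoms even after a rejecting "no".
#' @param .session Internal session object (trace accumulator); created
#'   fresh when absent.
#' @return `"confirmed"` or `"rejected"`.
#' @export
evaluate_hypothesis <- function(kb, disorder_id, wm = new_working_memory(),
                                answers, exhaustive = FALSE, .session = NULL) {
  if (is.character(answers) || is.list(answers)) answers <- scripted_provider(answers)
  provenance <- attr(answers, "provenance") %||% "user_answer"
  session <- .session %||% new_session(kb, wm = wm)
  body <- disorder_body(kb, disorder_id)
  session$goal <- disorder_id
  status <- "confirmed"
  for (sid in body) {
    if (sid %in% names(wm$facts)) {
      value <- wm$facts[[sid]]
    } else {
      session$pending_symptom <- sid
      trace_add(session, "question_asked", disorder_id, sid)
      value <- tryCatch(
        check_answer_value(answers(sid, session), sid),
        error = function(e) {
          if (inherits(e, "vriksha_provider_error")) {
            abort(conditionMessage(e), class = "vriksha_provider_error", parent = e)
          }
          abort(sprintf("Answer provider failed on symptom '%s'", sid),
            class = "vriksha_provider_error", parent = e
          )
        }
      )
      session$pending_symptom <- NULL
      wm$facts[[sid]] <- value
      wm$provenance[[sid]] <- provenance
      wm$question_log <- c(wm$question_log, sid)
      trace_add(session, "fact_recorded", disorder_id, sid, value)
    }
    trace_add(session, "belief_updated", disorder_id, sid, value)
    if (value == "no") {
      status <- "rejected"
      if (!exhaustive) break
    }
  }
  session$goal <- NULL
  trace_add(session, "hypothesis_concluded", disorder_id, value = status)
  status
}

#' Run a full backward-chaining diagnostic session
#'
#' Iterates disorder hypotheses in taxonomy order (internal vata, pitta,
#' kapha, then external causes in KB order), evaluating each with
#' [evaluate_hypothesis()] over a shared working memory. With
#' `stop_at_first = TRUE` the session halts at the first confirmed
#' disorder; otherwise every hypothesis is scored so the belief state can
#' report all matches. The session is deterministic: identical KB and
#' answer function yield an identical diagnosis and trace.
#'
#' @inheritParams evaluate_hypothesis
#' @param stop_at_first Halt at the first confirmed disorder.
#' @return A `vriksha_diagnosis`: list with `confirmed` (ordered disorder
#'   ids), `primary` (first confirmed or `NA`), `belief` (tibble), `trace`
#'   (tibble of `TraceEntry` rows), `facts`, `question_log`, `treatments`
#'   (treatments of the primary disorder) and the session flags.
#' @export
#' @examples
#' kb <- example_kb()
#' vata <- disorder_body(kb, "vata")
#' answers <- setNames(ifelse(kb$symptoms$id %in% vata, "yes", "no"), kb$symptoms$id)
#' diagnose(kb, answers)$primary
diagnose <- function(kb, answers, stop_at_first = FALSE, exhaustive = FALSE) {
  if (is.character(answers) || is.list(answers)) answers <- scripted_provider(answers)
  session <- new_session(kb)
  wm <- session$wm
  hypothesis_order <- kb_taxonomy(kb)$disorder_id
  confirmed <- character()
  evaluated <- character()
  failure <- NULL
  for (did in hypothesis_order) {
    trace_add(session, "goal_selected", did)
    status <- tryCatch(
      evaluate_hypothesis(kb, did,
        wm = wm, answers = answers,
        exhaustive = exhaustive, .session = session
      ),
      vriksha_provider_error = function(e) e
    )
    if (inherits(status, "condition")) {
      failure <- status
      break
    }
    evaluated <- c(evaluated, did)
    if (status == "confirmed") {
      confirmed <- c(confirmed, did)
      if (stop_at_first) break
    }
  }
  trace_tbl <- trace_tibble(session)
  if (!is.null(failure)) {
    abort(
      c("Diagnostic session failed: the answer provider raised an error.",
        i = conditionMessage(failure)
      ),
      class = "vriksha_session_error", parent = failure,
      trace_tbl = trace_tbl, working_memory = wm
    )
  }
  primary <- if (length(confirmed) > 0) confirmed[[1]] else NA_character_
  structure(
    list(
      confirmed = confirmed,
      primary = primary,
      belief = belief_from_facts(kb, wm$facts),
      trace = trace_tbl,
      facts = tibble(
        symptom_id = names(wm$facts),
        value = unname(wm$facts),
        provenance = unname(wm$provenance[names(wm$facts)])
      ),
      question_log = wm$question_log,
      evaluated = evaluated,
      treatments = if (!is.na(primary)) kb_treatments_for(kb, primary) else kb$treatments[0, ],
      stop_at_first = stop_at_first,
      exhaustive = exhaustive
    ),
    class = "vriksha_diagnosis"
  )
}

#' Diagnose by direct rule matching over a complete answer vector
#'
#' The dialogue-free oracle: given an answer for every symptom in the KB,
#' returns exactly the disorders whose entire symptom list maps to "yes".
#' Pure and independent of the backward chainer; used to cross-check it.
#'
#' @param kb A valid `vriksha_kb`.
#' @param full_vector Named character vector of `"yes"`/`"no"` covering
#'   every symptom in the KB; an incomplete vector is a contract error.
#' @return Character vector of satisfied disorder ids, in KB order.
#' @export
brute_force_diagnose <- function(kb, full_vector) {
  missing <- setdiff(kb$symptoms$id, names(full_vector))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "Answer vector must cover every symptom; missing: %s",
        paste(missing, collapse = ", ")
      ),
      class = "vriksha_contract_error"
    )
  }
  bad <- !full_vector %in% c("yes", "no")
  if (any(bad)) {
    abort("Answer vector entries must be 'yes' or 'no'",
      class = "vriksha_contract_error"
    )
  }
  hit <- purrr::map_lgl(kb$disorders$symptom_ids, function(body) {
    all(full_vector[body] == "yes")
  })
  kb$disorders$id[hit]
}

#' Explain why the current question is being asked
#'
#' Mid-session justification: names the goal disorder under test and the
#' remaining unconfirmed symptoms of its rule that motivate the pending
#' question. Valid only while a question is pending.
#'
#' @param state The session state passed to the answer provider (its
#'   second argument).
#' @return A character string.
#' @export
explain_why <- function(state) {
  if (!inherits(state, "vriksha_session") || is.null(state$pending_symptom)) {
    abort("No question is pending; 'why' explanations are only available mid-question.",
      class = "vriksha_state_error"
    )
  }
  kb <- state$kb
  goal <- state$goal
  body <- disorder_body(kb, goal)
  d <- kb_disorder(kb, goal)
  known_yes <- intersect(body, names(state$wm$facts)[state$wm$facts == "yes"])
  remaining <- setdiff(body, names(state$wm$facts))
  labels <- function(ids) paste(purrr::map_chr(ids, symptom_label, kb = kb), collapse = "; ")
  paste0(
    sprintf(
      "Current goal: testing the hypothesis that the plant has %s ('%s', %s/%s).\n",
      d$name, goal, d$category, d$subcategory
    ),
    sprintf(
      "To conclude this disorder, all of its symptoms must be present: %s.\n",
      labels(body)
    ),
    if (length(known_yes) > 0) {
      sprintf("Already confirmed: %s.\n", labels(known_yes))
    } else {
      "No symptom of this disorder has been confirmed yet.\n"
    },
    sprintf(
      "Asking now about '%s'; still to verify after it: %s.",
      symptom_label(kb, state$pending_symptom),
      if (length(setdiff(remaining, state$pending_symptom)) > 0) {
        labels(setdiff(remaining, state$pending_symptom))
      } else {
        "none"
      }
    )
  )
}

#' Explain how a diagnosis was reached
#'
#' Linearizes the reasoning trace: each hypothesis in the order it was
#' considered, with the facts that decided it — every "yes" for a
#' confirmed disorder, the deciding "no" for a rejected one.
#'
#' @param x A `vriksha_diagnosis`, or a trace tibble (e.g. re-read from a
#'   saved trace file) for replaying saved sessions.
#' @param ... Unused.
#' @return A single multi-line character string.
#' @export
explain_how <- function(x, ...) UseMethod("explain_how")

#' @export
explain_how.vriksha_diagnosis <- function(x, ...) {
  explain_how(x$trace, ...)
}

#' @export
explain_how.data.frame <- function(x, ...) {
  n_q <- sum(x$kind == "question_asked")
  lines <- sprintf("Reasoning trace (%d question(s) asked):", n_q)
  concluded <- which(x$kind == "hypothesis_concluded")
  for (i in concluded) {
    did <- x$disorder_id[[i]]
    status <- x$value[[i]]
    considered <- x[seq_len(i - 1), ]
    used <- considered[considered$kind == "belief_updated" &
      considered$disorder_id == did, ]
    facts_txt <- paste(sprintf("%s=%s", used$symptom_id, used$value), collapse = ", ")
    if (identical(status, "confirmed")) {
      lines <- c(lines, sprintf(
        "- Hypothesis '%s': CONFIRMED — every symptom present (%s).", did, facts_txt
      ))
    } else {
      deciding <- used$symptom_id[used$value == "no"]
      lines <- c(lines, sprintf(
        "- Hypothesis '%s': REJECTED — decided by %s=no (facts considered: %s).",
        did, if (length(deciding) > 0) deciding[[1]] else "?", facts_txt
      ))
    }
  }
  paste(lines, collapse = "\n")
}

#' Write / read a reasoning trace as JSON lines
#'
#' One trace entry per line, for audit and replay (see the `replay` CLI
#' subcommand). Serialization is deterministic: identical sessions produce
#' byte-identical files.
#'
#' @param x A `vriksha_diagnosis` or a trace tibble.
#' @param path Output file.
#' @return `path` invisibly; `read_trace()` returns the trace tibble.
#' @export
write_trace <- function(x, path) {
  tr <- if (inherits(x, "vriksha_diagnosis")) x$trace else as_tibble(x)
  lines <- purrr::map_chr(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE, na = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  purrr::map(lines, function(l) {
    e <- jsonlite::fromJSON(l)
    tibble(
      ordinal = as.integer(e$ordinal), kind = e$kind,
      disorder_id = e$disorder_id %||% NA_character_,
      symptom_id = e$symptom_id %||% NA_character_,
      value = e$value %||% NA_character_
    )
  }) |> purrr::list_rbind()
}

#' @export
print.vriksha_diagnosis <- function(x, ...) {
  cat("<vriksha_diagnosis>\n")
  if (length(x$confirmed) > 0) {
    cat(sprintf(
      "  confirmed: %s (primary: %s)\n",
      paste(x$confirmed, collapse = ", "), x$primary
    ))
  } else {
    cat("  confirmed: none\n")
  }
  cat(sprintf(
    "  questions asked: %d; hypotheses evaluated: %d\n",
    length(x$question_log), length(x$evaluated)
  ))
  invisible(x)
}
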