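# Interactive session layer: renders the KB's questions, parses free-text
# yes/no answers (re-prompting on anything else), supports a "why" command
# that prints the engine's current line of reasoning, and ends with a
# belief statement naming what the plant was classified as having.

#' Parse a free-text yes/no answer
#'
#' Case-insensitive; accepts `y`, `yes`, `n`, `no` after trimming
#' whitespace. Anything else — including the empty string — is `"invalid"`.
#'
#' @param raw Raw answer text.
#' @return `"yes"`, `"no"` or `"invalid"`.
#' @export
#' @examples
#' parse_answer("  YES ")
#' parse_answer("maybe")
parse_answer <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw)) {
    return("invalid")
  }
  t <- tolower(trimws(raw))
  if (t %in% c("y", "yes")) {
    "yes"
  } else if (t %in% c("n", "no")) {
    "no"
  } else {
    "invalid"
  }
}

#' IO channels for diagnostic sessions
#'
#' A channel is a list of two functions: `ask(prompt)` returning the raw
#' answer text and `say(text)` emitting output. `scripted_channel()` replays
#' a fixed sequence of raw answers (exhausting it aborts the session);
#' `terminal_channel()` reads from standard input for live use.
#'
#' @param raw_answers Character vector of raw answer texts, consumed in order.
#' @return A channel list with elements `ask`, `say` and (for scripted
#'   channels) `n_asked()`.
#' @export
scripted_channel <- function(raw_answers) {
  raw_answers <- as.character(raw_answers)
  i <- 0L
  said <- character()
  list(
    ask = function(prompt) {
      i <<- i + 1L
      if (i > length(raw_answers)) {
        abort("Scripted channel exhausted: no answer left for the next question.",
          class = c("vriksha_provider_error", "vriksha_channel_exhausted")
        )
      }
      raw_answers[[i]]
    },
    say = function(text) {
      said <<- c(said, text)
      invisible(NULL)
    },
    n_asked = function() i,
    said = function() said
  )
}

#' @rdname scripted_channel
#' @export
terminal_channel <- function() {
  list(
    ask = function(prompt) {
      cat(prompt, "")
      if (interactive()) {
        readline()
      } else {
        ans <- readLines(con = "stdin", n = 1)
        if (length(ans) == 0) {
          abort("End of input reached.",
            class = c("vriksha_provider_error", "vriksha_channel_exhausted")
          )
        }
        ans
      }
    },
    say = function(text) cat(text, "\n", sep = "")
  )
}

#' Run a full diagnostic dialogue
#'
#' Drives [diagnose()] through an IO channel: each engine question is
#' rendered with its KB question text, the raw reply is parsed with
#' [parse_answer()], invalid replies are re-prompted up to `max_reprompts`
#' times before the session aborts cleanly, and the reply `why` prints the
#' current reasoning ([explain_why()]) without consuming the re-prompt
#' budget. The finished session emits and returns the belief statement.
#'
#' @param kb A valid `vriksha_kb`.
#' @param channel An IO channel ([scripted_channel()] or
#'   [terminal_channel()]).
#' @param max_reprompts Re-prompts allowed per question before aborting.
#' @param stop_at_first,exhaustive Passed to [diagnose()].
#' @return List with `diagnosis` (a `vriksha_diagnosis`) and `transcript`
#'   (a `vriksha_transcript`: tibble of turns plus the final statement).
#'   On an exhausted re-prompt budget an error of class
#'   `vriksha_session_aborted` is raised carrying the partial transcript
#'   in its `transcript` field.
#' @export
#' @examples
#' kb <- example_kb()
#' vata <- disorder_body(kb, "vata")
#' raw <- ifelse(kb$symptoms$id %in% vata, "yes", "no")
#' # answers arrive in engine question order, which here follows the KB
#' res <- run_session(kb, scripted_channel(raw))
#' res$diagnosis$primary
run_session <- function(kb, channel, max_reprompts = 3, stop_at_first = FALSE,
                        exhaustive = FALSE) {
  turns <- list()
  provider <- function(symptom_id, state) {
    q <- symptom_question(kb, symptom_id)
    invalid_seen <- 0L
    repeat {
      raw <- channel$ask(q)
      if (identical(tolower(trimws(raw)), "why")) {
        channel$say(explain_why(state))
        next
      }
      parsed <- parse_answer(raw)
      if (parsed != "invalid") {
        turns[[length(turns) + 1]] <<- tibble(
          question_text = q, raw_answer = raw, parsed_value = parsed
        )
        return(parsed)
      }
      invalid_seen <- invalid_seen + 1L
      if (invalid_seen > max_reprompts) {
        abort(
          sprintf(
            "Re-prompt budget exhausted on question '%s' after %d invalid answers.",
            q, invalid_seen
          ),
          class = c("vriksha_provider_error", "vriksha_reprompt_exhausted")
        )
      }
      channel$say("Please answer 'yes' or 'no' (or 'why' for the reasoning).")
    }
  }
  turn_tibble <- function() {
    if (length(turns) == 0) {
      tibble(
        question_text = character(), raw_answer = character(),
        parsed_value = character()
      )
    } else {
      purrr::list_rbind(turns)
    }
  }
  diagnosis <- tryCatch(
    diagnose(kb, provider, stop_at_first = stop_at_first, exhaustive = exhaustive),
    vriksha_session_error = function(e) e
  )
  if (inherits(diagnosis, "condition")) {
    partial <- structure(
      list(turns = turn_tibble(), final_statement = NA_character_),
      class = "vriksha_transcript"
    )
    abort("Diagnostic session aborted before completion.",
      class = "vriksha_session_aborted", parent = diagnosis,
      transcript = partial, trace_tbl = diagnosis$trace_tbl
    )
  }
  statement <- render_belief_statement(diagnosis, kb)
  channel$say(statement)
  transcript <- structure(
    list(turns = turn_tibble(), final_statement = statement),
    class = "vriksha_transcript"
  )
  list(diagnosis = diagnosis, transcript = transcript)
}

#' Render the final belief statement
#'
#' Names every confirmed disorder with its taxonomy path (category >
#' subcategory), flags the primary one, and lists the primary disorder's
#' treatments. When nothing is confirmed the statement says so explicitly
#' and — as a labelled extension beyond the all-or-nothing rule — ranks
#' the nearest hypotheses by confirmed-symptom fraction.
#'
#' @param d A `vriksha_diagnosis`.
#' @param kb The KB the diagnosis was made against.
#' @return A deterministic multi-line character string.
#' @export
render_belief_statement <- function(d, kb) {
  tax <- kb_taxonomy(kb)
  path_of <- function(did) {
    row <- tax[tax$disorder_id == did, ]
    sprintf("%s > %s", row$category, row$subcategory)
  }
  if (length(d$confirmed) > 0) {
    lines <- "Belief statement: the plant has been classified as having:"
    for (did in d$confirmed) {
      nm <- kb_disorder(kb, did)$name
      tag <- if (identical(did, d$primary)) " [primary]" else ""
      lines <- c(lines, sprintf("- %s ('%s', %s)%s", nm, did, path_of(did), tag))
    }
    tr <- kb_treatments_for(kb, d$primary)
    if (nrow(tr) > 0) {
      lines <- c(lines, sprintf(
        "Recommended treatment for %s:", kb_disorder(kb, d$primary)$name
      ))
      for (i in seq_len(nrow(tr))) {
        ing <- tr$ingredients[[i]]
        lines <- c(lines, sprintf(
          "- %s%s", tr$description[[i]],
          if (length(ing) > 0) sprintf(" (ingredients: %s)", paste(ing, collapse = ", ")) else ""
        ))
      }
    }
  } else {
    lines <- c(
      "Belief statement: no disorder could be identified.",
      "No hypothesis had all of its symptoms confirmed.",
      "Nearest hypotheses by confirmed-symptom fraction (partial matches, not diagnoses):"
    )
    bs <- d$belief[match(tax$disorder_id, d$belief$disorder_id), ]
    ord <- order(-bs$confirmed_fraction, seq_len(nrow(bs)))
    top <- bs[ord, ][seq_len(min(3, nrow(bs))), ]
    for (i in seq_len(nrow(top))) {
      lines <- c(lines, sprintf(
        "- %s: %d of %d symptoms confirmed (%.2f)",
        top$disorder_id[[i]],
        length(top$yes_facts[[i]]), top$n_symptoms[[i]],
        top$confirmed_fraction[[i]]
      ))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.vriksha_transcript <- function(x, ...) {
  cat(sprintf("<vriksha_transcript> %d turn(s)\n", nrow(x$turns)))
  for (i in seq_len(nrow(x$turns))) {
    cat(sprintf(
      "  Q%d: %s -> %s\n", i, x$turns$question_text[[i]], x$turns$parsed_value[[i]]
    ))
  }
  if (!is.na(x$final_statement)) cat(x$final_statement, "\n", sep = "")
  invisible(x)
}

#' Export a transcript as JSON
#'
#' @param transcript A `vriksha_transcript`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  jsonlite::write_json(
    list(
      turns = transcript$turns,
      final_statement = transcript$final_statement
    ),
    path,
    auto_unbox = TRUE, na = "null", pretty = TRUE
  )
  invisible(path)
}
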