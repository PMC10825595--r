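# Graded belief tracking. Each disorder hypothesis carries a status
# (open / confirmed / rejected) and a confirmed-symptom fraction in [0, 1].
# Conclusions are strictly conjunctive: only fraction 1 confirms; any "no"
# on a disorder's symptom rejects it regardless of how many others matched.

#' Create a fresh belief state over a KB's disorders
#'
#' One row per disorder, all hypotheses open with confirmed fraction 0.
#'
#' @param kb A valid `vriksha_kb`.
#' @return Tibble with columns `disorder_id`, `symptom_ids` (list), `yes_facts`
#'   (list), `no_facts` (list), `n_symptoms`, `confirmed_fraction`, `status`.
#' @export
new_belief_state <- function(kb) {
  n <- nrow(kb$disorders)
  tibble(
    disorder_id = kb$disorders$id,
    symptom_ids = kb$disorders$symptom_ids,
    yes_facts = rep(list(character()), n),
    no_facts = rep(list(character()), n),
    n_symptoms = lengths(kb$disorders$symptom_ids),
    confirmed_fraction = 0,
    status = rep("open", n)
  )
}

#' Construct a symptom fact
#'
#' @param symptom_id Symptom identifier.
#' @param value `"yes"` or `"no"`.
#' @param provenance `"user_answer"` or `"scripted"`.
#' @return A `vriksha_fact` (named list).
#' @export
new_fact <- function(symptom_id, value, provenance = "user_answer") {
  if (!value %in% c("yes", "no")) {
    abort(sprintf("Fact value must be 'yes' or 'no', got '%s'", value),
      class = "vriksha_contract_error"
    )
  }
  if (!provenance %in% c("user_answer", "scripted")) {
    abort("Fact provenance must be 'user_answer' or 'scripted'",
      class = "vriksha_contract_error"
    )
  }
  structure(list(symptom_id = symptom_id, value = value, provenance = provenance),
    class = "vriksha_fact"
  )
}

belief_status <- function(n_yes, n_no, n_symptoms) {
  dplyr::case_when(
    n_no > 0 ~ "rejected",
    n_yes == n_symptoms ~ "confirmed",
    .default = "open"
  )
}

#' Fold one fact into a belief state
#'
#' Recomputes the disorder's confirmed fraction and status after recording
#' the fact. The fact must concern one of the disorder's own symptoms;
#' a fact for an unrelated symptom is a contract violation. Adding a
#' yes-fact never decreases the confirmed fraction; any no-fact rejects
#' the hypothesis regardless of the fraction.
#'
#' @param bs Belief state from [new_belief_state()].
#' @param disorder_id Disorder whose hypothesis the fact bears on.
#' @param fact A [new_fact()].
#' @return The updated belief state tibble.
#' @export
update_belief <- function(bs, disorder_id, fact) {
  i <- match(disorder_id, bs$disorder_id)
  if (is.na(i)) {
    abort(sprintf("Unknown disorder id '%s'", disorder_id),
      class = "vriksha_lookup_error"
    )
  }
  body <- bs$symptom_ids[[i]]
  if (!fact$symptom_id %in% body) {
    abort(
      sprintf(
        "Fact about '%s' does not concern a symptom of disorder '%s'",
        fact$symptom_id, disorder_id
      ),
      class = "vriksha_contract_error"
    )
  }
  if (fact$value == "yes") {
    bs$yes_facts[[i]] <- union(bs$yes_facts[[i]], fact$symptom_id)
    bs$no_facts[[i]] <- setdiff(bs$no_facts[[i]], fact$symptom_id)
  } else {
    bs$no_facts[[i]] <- union(bs$no_facts[[i]], fact$symptom_id)
    bs$yes_facts[[i]] <- setdiff(bs$yes_facts[[i]], fact$symptom_id)
  }
  bs$confirmed_fraction[[i]] <- length(bs$yes_facts[[i]]) / bs$n_symptoms[[i]]
  bs$status[[i]] <- belief_status(
    length(bs$yes_facts[[i]]), length(bs$no_facts[[i]]), bs$n_symptoms[[i]]
  )
  bs
}

# Vectorized belief computation from a session's accumulated fact set
# (named character vector symptom_id -> "yes"/"no").
belief_from_facts <- function(kb, facts) {
  bs <- new_belief_state(kb)
  yes_ids <- names(facts)[facts == "yes"]
  no_ids <- names(facts)[facts == "no"]
  bs$yes_facts <- purrr::map(bs$symptom_ids, intersect, yes_ids)
  bs$no_facts <- purrr::map(bs$symptom_ids, intersect, no_ids)
  n_yes <- lengths(bs$yes_facts)
  n_no <- lengths(bs$no_facts)
  bs$confirmed_fraction <- n_yes / bs$n_symptoms
  bs$status <- belief_status(n_yes, n_no, bs$n_symptoms)
  bs
}
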