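# Small knowledge bases built in code, plus answer-vector helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

fixture_symptoms <- function(ids) {
  tibble::tibble(
    id = ids,
    question_text = paste0("Is symptom ", ids, " present?"),
    label = paste0("symptom ", ids)
  )
}

fixture_disorders <- function(ids, bodies, categories = NULL, subcategories = NULL) {
  n <- length(ids)
  tibble::tibble(
    id = ids,
    name = paste("Disorder", toupper(ids)),
    category = categories %||% rep("internal", n),
    subcategory = subcategories %||% rep(c("vata", "pitta", "kapha"), length.out = n),
    description = "",
    curated = FALSE,
    symptom_ids = bodies,
    treatment_ids = rep(list(character()), n)
  )
}

# Three disorders over eight symptoms, pairwise-disjoint bodies.
kb_disjoint <- function() {
  new_kb(
    fixture_disorders(
      c("d1", "d2", "d3"),
      list(c("s1", "s2", "s3"), c("s4", "s5"), c("s6", "s7", "s8")),
      categories = c("internal", "internal", "external"),
      subcategories = c("vata", "pitta", "insects")
    ),
    fixture_symptoms(paste0("s", 1:8))
  )
}

# Three disorders over six symptoms with overlapping bodies (s2, s3 shared).
kb_overlap <- function() {
  new_kb(
    fixture_disorders(
      c("d1", "d2", "d3"),
      list(c("s1", "s2", "s3"), c("s2", "s3", "s4"), c("s3", "s5", "s6"))
    ),
    fixture_symptoms(paste0("s", 1:6))
  )
}

# d_in's body is a strict subset of d_out's.
kb_nested <- function() {
  new_kb(
    fixture_disorders(
      c("d_in", "d_out"),
      list(c("s1", "s2"), c("s1", "s2", "s3"))
    ),
    fixture_symptoms(paste0("s", 1:3))
  )
}

# Three disorders partitioning ten symptoms; used for exhaustive sweeps.
kb_ten_symptoms <- function() {
  new_kb(
    fixture_disorders(
      c("d1", "d2", "d3"),
      list(c("s1", "s2", "s3"), c("s4", "s5", "s6"), c("s7", "s8", "s9", "s10"))
    ),
    fixture_symptoms(paste0("s", 1:10))
  )
}

# Indicator answer vector: yes exactly on one disorder's symptoms.
indicator_answers <- function(kb, disorder_id) {
  body <- disorder_body(kb, disorder_id)
  setNames(ifelse(kb$symptoms$id %in% body, "yes", "no"), kb$symptoms$id)
}

uniform_answers <- function(kb, value) {
  setNames(rep(value, nrow(kb$symptoms)), kb$symptoms$id)
}

# All 2^n complete answer vectors over the KB's symptoms.
all_answer_vectors <- function(kb) {
  ids <- kb$symptoms$id
  grid <- expand.grid(rep(list(c("yes", "no")), length(ids)),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    setNames(unlist(grid[i, ], use.names = FALSE), ids)
  })
}

random_answers <- function(kb, p_yes = 0.5) {
  setNames(
    ifelse(runif(nrow(kb$symptoms)) < p_yes, "yes", "no"),
    kb$symptoms$id
  )
}

write_kb_tempfile <- function(kb) {
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  jsonlite::write_json(kb_as_document(kb), path, auto_unbox = TRUE)
  path
}

# Document (list) form of a KB tibble bundle, bypassing write_kb so invalid
# KBs can be serialized for load_kb error-path tests.
kb_as_document <- function(kb) {
  list(
    schema_version = kb$schema_version,
    symptoms = purrr::pmap(kb$symptoms, function(id, question_text, label) {
      list(id = id, question_text = question_text, label = label)
    }),
    disorders = purrr::pmap(kb$disorders, function(id, name, category, subcategory,
                                                   description, curated, symptom_ids,
                                                   treatment_ids) {
      list(
        id = id, name = name, category = category, subcategory = subcategory,
        description = description, curated = curated,
        symptom_ids = as.list(symptom_ids), treatment_ids = as.list(treatment_ids)
      )
    }),
    treatments = purrr::pmap(kb$treatments, function(id, description, ingredients,
                                                     source_note) {
      list(
        id = id, description = description, ingredients = as.list(ingredients),
        source_note = source_note
      )
    })
  )
}
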