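# Knowledge-base model: loading, validation, taxonomy, rule compilation.
#
# A knowledge base bundles the three tables the diagnostic shell reasons
# over: disorder descriptions, symptom questions, and treatments. Disorders
# split two ways (internal vs external); internal disorders carry one of the
# three dosha subcategories (vata, pitta, kapha), external ones a cause tag
# (insects, cold, wind, sun) or "general".

KB_CATEGORIES <- c("internal", "external")
KB_INTERNAL_SUBCATEGORIES <- c("vata", "pitta", "kapha")
KB_EXTERNAL_SUBCATEGORIES <- c("insects", "cold", "wind", "sun", "general")

#' Construct a knowledge base from its three component tables
#'
#' Builds a `vriksha_kb` object from tibbles of disorders, symptoms and
#' treatments. Most users will call [load_kb()] on a JSON document instead;
#' this constructor is the programmatic route used by tests and generators.
#' No validation is performed here: run [validate_kb()] to check invariants.
#'
#' @param disorders Tibble with columns `id`, `name`, `category`,
#'   `subcategory`, `description`, `curated` (logical), and list-columns
#'   `symptom_ids` and `treatment_ids`.
#' @param symptoms Tibble with columns `id`, `question_text`, `label`.
#' @param treatments Tibble with columns `id`, `description`, `source_note`
#'   and list-column `ingredients`.
#' @param schema_version Document schema version string.
#' @return A `vriksha_kb` object (a named list of the three tibbles plus
#'   `schema_version`).
#' @export
new_kb <- function(disorders, symptoms, treatments = empty_treatments(),
                   schema_version = "1.0") {
  kb <- list(
    schema_version = schema_version,
    disorders = as_tibble(disorders),
    symptoms = as_tibble(symptoms),
    treatments = as_tibble(treatments)
  )
  class(kb) <- c("vriksha_kb", "list")
  kb
}

empty_treatments <- function() {
  tibble(
    id = character(), description = character(),
    ingredients = list(), source_note = character()
  )
}

chr_field <- function(x, field, default = NA_character_) {
  v <- x[[field]]
  if (is.null(v)) default else as.character(v)[[1]]
}

#' Load and validate a knowledge base document
#'
#' Reads a knowledge-base file (JSON canonically; `.yaml`/`.yml` accepted as
#' a convenience), builds the disorder/symptom/treatment tables and runs
#' [validate_kb()]. A file that parses but violates any invariant is
#' rejected with an aggregated report of every violation, not just the
#' first.
#'
#' @param path Path to the KB document.
#' @return A validated `vriksha_kb` object.
#' @seealso [example_kb()] for the packaged reference knowledge base.
#' @export
#' @examples
#' kb <- example_kb()
#' kb$disorders
load_kb <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("Knowledge base file not found: '%s'", path),
      class = "vriksha_io_error"
    )
  }
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path), error = function(e) {
      abort(sprintf("Failed to parse knowledge base '%s': %s", path, conditionMessage(e)),
        class = "vriksha_parse_error", parent = e
      )
    })
  } else {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE), error = function(e) {
      abort(sprintf("Failed to parse knowledge base '%s': %s", path, conditionMessage(e)),
        class = "vriksha_parse_error", parent = e
      )
    })
  }
  kb <- kb_from_document(doc)
  violations <- validate_kb(kb)
  if (nrow(violations) > 0) {
    report <- sprintf("[%s] %s: %s", violations$code, violations$id, violations$message)
    abort(
      c(
        sprintf(
          "Knowledge base '%s' failed validation with %d violation(s):",
          path, nrow(violations)
        ),
        setNames(report, rep("x", length(report)))
      ),
      class = "vriksha_validation_error", violations = violations
    )
  }
  kb
}

# Build the tibble representation from a parsed (list-of-lists) document.
kb_from_document <- function(doc) {
  as_rows <- function(items, f) purrr::map(items %||% list(), f) |> purrr::list_rbind()
  symptoms <- as_rows(doc$symptoms, function(s) {
    tibble(
      id = chr_field(s, "id"),
      question_text = chr_field(s, "question_text", ""),
      label = chr_field(s, "label", "")
    )
  })
  disorders <- as_rows(doc$disorders, function(d) {
    tibble(
      id = chr_field(d, "id"),
      name = chr_field(d, "name", chr_field(d, "id")),
      category = chr_field(d, "category"),
      subcategory = chr_field(d, "subcategory"),
      description = chr_field(d, "description", ""),
      curated = isTRUE(d$curated),
      symptom_ids = list(as.character(unlist(d$symptom_ids))),
      treatment_ids = list(as.character(unlist(d$treatment_ids)))
    )
  })
  treatments <- as_rows(doc$treatments, function(t) {
    tibble(
      id = chr_field(t, "id"),
      description = chr_field(t, "description", ""),
      ingredients = list(as.character(unlist(t$ingredients))),
      source_note = chr_field(t, "source_note", "")
    )
  })
  if (nrow(treatments) == 0) treatments <- empty_treatments()
  new_kb(
    disorders = disorders, symptoms = symptoms, treatments = treatments,
    schema_version = chr_field(doc, "schema_version", "1.0")
  )
}

#' Write a knowledge base back to a JSON document
#'
#' Serialization round-trips: `load_kb(write_kb(kb, path))` is structurally
#' identical to `kb`.
#'
#' @param kb A `vriksha_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  doc <- list(
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
        id = id, description = description,
        ingredients = as.list(ingredients), source_note = source_note
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

add_violation <- function(acc, code, id, message) {
  c(acc, list(tibble(code = code, id = id, message = message)))
}

#' Validate a knowledge base against its invariants
#'
#' Checks every structural invariant of the KB model and returns all
#' violations found as data, never as an error: unique identifiers,
#' well-formed question text, non-empty duplicate-free rule bodies,
#' referential integrity of symptom and treatment ids, legal
#' category/subcategory combinations, and pairwise-distinguishable rules
#' (no two disorders may share an identical symptom set).
#'
#' @param kb A structurally parsed `vriksha_kb` (need not be valid).
#' @return A tibble with columns `code` (machine-readable violation code),
#'   `id` (offending identifier) and `message`; zero rows iff the KB is
#'   valid.
#' @export
#' @examples
#' validate_kb(example_kb()) # zero rows
validate_kb <- function(kb) {
  v <- list()
  if (nrow(kb$disorders) == 0) {
    v <- add_violation(v, "EMPTY_KB", "<kb>", "knowledge base defines no disorders")
  }
  for (tbl_name in c("symptoms", "disorders", "treatments")) {
    ids <- kb[[tbl_name]]$id
    bad <- is.na(ids) | !nzchar(ids)
    for (i in which(bad)) {
      v <- add_violation(v, "MISSING_ID", sprintf("%s[%d]", tbl_name, i),
        sprintf("entry %d of %s has no id", i, tbl_name))
    }
    for (dup in unique(ids[duplicated(ids) & !bad])) {
      v <- add_violation(v, "DUPLICATE_ID", dup,
        sprintf("id '%s' appears more than once in %s", dup, tbl_name))
    }
  }
  for (i in seq_len(nrow(kb$symptoms))) {
    s <- kb$symptoms[i, ]
    q <- s$question_text
    if (is.na(q) || !nzchar(trimws(q)) || !grepl("\\?$", trimws(q))) {
      v <- add_violation(v, "BAD_QUESTION_TEXT", s$id,
        "question_text must be non-empty and end in '?'")
    }
  }
  symptom_ids <- kb$symptoms$id
  treatment_ids <- kb$treatments$id
  for (i in seq_len(nrow(kb$disorders))) {
    d <- kb$disorders[i, ]
    body <- d$symptom_ids[[1]]
    if (length(body) == 0) {
      v <- add_violation(v, "EMPTY_RULE_BODY", d$id,
        "disorder has an empty symptom list; its rule could never be tested")
    }
    for (dup in unique(body[duplicated(body)])) {
      v <- add_violation(v, "DUPLICATE_SYMPTOM_IN_RULE", d$id,
        sprintf("symptom '%s' listed more than once", dup))
    }
    for (missing in setdiff(body, symptom_ids)) {
      v <- add_violation(v, "DANGLING_SYMPTOM_REF", d$id,
        sprintf("references unknown symptom '%s'", missing))
    }
    for (missing in setdiff(d$treatment_ids[[1]], treatment_ids)) {
      v <- add_violation(v, "DANGLING_TREATMENT_REF", d$id,
        sprintf("references unknown treatment '%s'", missing))
    }
    if (is.na(d$category) || !d$category %in% KB_CATEGORIES) {
      v <- add_violation(v, "BAD_CATEGORY", d$id,
        sprintf("category must be one of: %s", paste(KB_CATEGORIES, collapse = ", ")))
    } else {
      allowed <- if (d$category == "internal") KB_INTERNAL_SUBCATEGORIES else KB_EXTERNAL_SUBCATEGORIES
      if (is.na(d$subcategory) || !d$subcategory %in% allowed) {
        v <- add_violation(v, "BAD_SUBCATEGORY", d$id,
          sprintf("subcategory for a %s disorder must be one of: %s",
            d$category, paste(allowed, collapse = ", ")))
      }
    }
  }
  # Rules must be distinguishable: identical symptom sets cannot be told apart
  # by any sequence of yes/no answers.
  if (nrow(kb$disorders) > 1) {
    keys <- purrr::map_chr(kb$disorders$symptom_ids, function(b) {
      paste(sort(unique(b)), collapse = "|")
    })
    for (k in unique(keys[duplicated(keys)])) {
      ids <- kb$disorders$id[keys == k]
      v <- add_violation(v, "INDISTINGUISHABLE_RULES", paste(ids, collapse = "+"),
        sprintf("disorders %s share an identical symptom set",
          paste(sprintf("'%s'", ids), collapse = ", ")))
    }
  }
  if (length(v) == 0) {
    tibble(code = character(), id = character(), message = character())
  } else {
    purrr::list_rbind(v)
  }
}

#' Two-level disorder taxonomy in hypothesis order
#'
#' Flattens the classification tree (category, then subcategory, then
#' disorder) into a tibble whose row order is the engine's hypothesis
#' order: internal disorders first (vata, pitta, kapha), then external
#' causes in order of first appearance in the KB; ties within a branch
#' follow KB file order.
#'
#' @param kb A valid `vriksha_kb`.
#' @return Tibble with columns `category`, `subcategory`, `disorder_id`,
#'   `name`; every disorder appears exactly once.
#' @export
#' @examples
#' kb_taxonomy(example_kb())
kb_taxonomy <- function(kb) {
  d <- kb$disorders
  tax <- tibble(
    category = d$category, subcategory = d$subcategory,
    disorder_id = d$id, name = d$name
  )
  cat_rank <- match(tax$category, KB_CATEGORIES)
  sub_rank <- ifelse(tax$category == "internal",
    match(tax$subcategory, KB_INTERNAL_SUBCATEGORIES),
    match(tax$subcategory, unique(tax$subcategory[tax$category == "external"]))
  )
  tax[order(cat_rank, sub_rank, seq_len(nrow(tax))), ]
}

#' Compile the KB into an ordered production-rule set
#'
#' One conjunctive rule per disorder: IF every listed symptom is present
#' THEN the disorder. Rule order equals disorder order in the KB document.
#'
#' @param kb A valid `vriksha_kb`.
#' @return Tibble with columns `order`, `disorder_id`, `body` (list-column
#'   of symptom ids, the rule's conjunctive literals) and `n_literals`.
#' @export
compile_rules <- function(kb) {
  tibble(
    order = seq_len(nrow(kb$disorders)),
    disorder_id = kb$disorders$id,
    body = kb$disorders$symptom_ids,
    n_literals = lengths(kb$disorders$symptom_ids)
  )
}

kb_disorder <- function(kb, disorder_id) {
  i <- match(disorder_id, kb$disorders$id)
  if (is.na(i)) {
    abort(sprintf("Unknown disorder id '%s'", disorder_id),
      class = "vriksha_lookup_error"
    )
  }
  kb$disorders[i, ]
}

#' Symptom ids making up a disorder's rule body
#'
#' @param kb A valid `vriksha_kb`.
#' @param disorder_id Disorder identifier.
#' @return Character vector of symptom ids, in rule order.
#' @export
disorder_body <- function(kb, disorder_id) {
  kb_disorder(kb, disorder_id)$symptom_ids[[1]]
}

symptom_question <- function(kb, symptom_id) {
  i <- match(symptom_id, kb$symptoms$id)
  if (is.na(i)) {
    abort(sprintf("Unknown symptom id '%s'", symptom_id),
      class = "vriksha_lookup_error"
    )
  }
  kb$symptoms$question_text[[i]]
}

symptom_label <- function(kb, symptom_id) {
  i <- match(symptom_id, kb$symptoms$id)
  if (is.na(i)) symptom_id else kb$symptoms$label[[i]]
}

kb_treatments_for <- function(kb, disorder_id) {
  tids <- kb_disorder(kb, disorder_id)$treatment_ids[[1]]
  kb$treatments[match(tids, kb$treatments$id), ]
}

#' Path to the packaged reference knowledge base
#'
#' @return File path of the shipped JSON knowledge base (ten disorders:
#'   the three dosha-caused internal disorders plus seven external ones).
#' @export
vriksha_kb_file <- function() {
  system.file("extdata", "vrikshayurveda_kb.json",
    package = "vrikshadx", mustWork = TRUE
  )
}

#' Load the packaged reference knowledge base
#'
#' The reference KB curates the classical material: internal disorders
#' caused by the three doshas (vata, pitta, kapha) and external disorders
#' caused by insects, cold, wind and sun, plus three general syndromes
#' (etiolation, bud-growth arrest, sap exudation with drying branches).
#' Records whose symptom lists are curator-assigned rather than taken from
#' the classical description are flagged `curated = TRUE`.
#'
#' @return A validated `vriksha_kb` with 10 disorders.
#' @export
#' @examples
#' example_kb()
example_kb <- function() {
  load_kb(vriksha_kb_file())
}

#' @export
print.vriksha_kb <- function(x, ...) {
  tax <- kb_taxonomy(x)
  cat(sprintf(
    "<vriksha_kb> schema %s: %d disorders, %d symptoms, %d treatments\n",
    x$schema_version, nrow(x$disorders), nrow(x$symptoms), nrow(x$treatments)
  ))
  for (cc in unique(tax$category)) {
    cat(sprintf("  %s:\n", cc))
    sub <- tax[tax$category == cc, ]
    for (sc in unique(sub$subcategory)) {
      cat(sprintf(
        "    %s: %s\n", sc,
        paste(sub$disorder_id[sub$subcategory == sc], collapse = ", ")
      ))
    }
  }
  invisible(x)
}
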