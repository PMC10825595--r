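---
title: "The vrikshadx diagnostic engine: knowledge base, inference, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vrikshadx diagnostic engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrikshadx)
```

## The problem and the model

Vrikshayurveda — the classical Indian science of plant life — classifies
plant disease two ways: *internal* disorders arising from an imbalance of
the three doshas (vata, pitta, kapha) and *external* disorders caused by
insects, cold, wind, or sun. A diseased plant shows a small set of
characteristic signs: leaves yellow (etiolation), buds fail to form or
stop growing, branches dry, sap leaks. `vrikshadx` packages this body of
knowledge as a rule-based diagnostic shell: a declarative knowledge base
(KB) of disorders, yes/no symptom questions and treatments, and a
backward-chaining engine that interviews an observer and concludes which
disorder the plant has.

Each disorder $d$ carries an ordered symptom list $S_d$. Its production
rule is strictly conjunctive:

$$\big(\forall s \in S_d:\ \text{answer}(s) = \text{yes}\big) \implies d,$$

so a single "no" on any symptom of $S_d$ rejects the hypothesis. Alongside
the hard conclusion the engine tracks a graded belief, the
confirmed-symptom fraction

$$f_d = \frac{|\{s \in S_d : \text{answer}(s)=\text{yes}\}|}{|S_d|} \in [0,1],$$

reported per hypothesis. The fraction never licenses a partial-match
conclusion — it exists so that a failed consultation can still say which
hypotheses came closest.

## The knowledge base

The KB is a single JSON document (`inst/extdata/vrikshayurveda_kb.json`;
draft JSON Schema in `kb_schema.json` beside it) holding the three tables
the shell reasons over — disorder descriptions, symptom questions, and
treatments — with explicit id cross-references. `validate_kb()` enforces
the invariants the schema cannot express: referential integrity, non-empty
duplicate-free rule bodies, legal category/subcategory pairs, and rule
*distinguishability* (no two disorders may share an identical symptom set,
otherwise no sequence of answers could ever tell them apart). All
violations are returned as data in one pass, so a curator sees the full
repair list at once.

The reference KB contains exactly ten disorders. Three are internal, one
per dosha; the classical texts name the vata indications (dryness,
roughness, wilting, stunted growth) and the pitta indications
(inflammation and heat, yellowing leaves, burning sensation, irritability,
with exposure to excessive wind recorded among them as transmitted), but no
kapha list — the kapha record therefore carries curator-assigned
waterlogging/heaviness indicators and is flagged `curated: true`. Four
external disorders cover the named causes (insects, cold, wind, sun), and
three further external records, also flagged curated, encode the general
description of the diseased plant as three syndromes: etiolation, bud
growth arrest, and sap exudation with drying branches. The Kunapajala
treatment record preserves the classical fermented-manure ingredient list.
The curated records were fixed once when the KB was assembled and are not
tuned; their symptom sets were chosen to be pairwise non-nested (see
`detect_nested_rules()`) so every disorder is recoverable from its own
indicator presentation.

```{r kb}
kb <- example_kb()
kb
kb_taxonomy(kb)
```

## Backward chaining, memoization, and the dialogue

`diagnose()` walks hypotheses in taxonomy pre-order — internal (vata,
pitta, kapha) first, then the external branches in KB order; within a
branch, KB file order decides. File order is therefore authoritative and
semantically meaningful. For each goal the engine asks that disorder's
symptoms in listed order, with two economies:

* **Memoization.** Every answer becomes a fact in working memory; a
  symptom shared by several hypotheses is asked exactly once per session.
* **Early rejection.** The first "no" rejects the hypothesis and its
  remaining symptoms are skipped. The classical behaviour only states the
  all-or-nothing rule; skipping is this package's choice, made to minimize
  interview length, and `exhaustive = TRUE` restores ask-everything
  behaviour for callers who want complete belief fractions.

By default every hypothesis is evaluated (`stop_at_first = FALSE`) so the
final belief statement can name *all* matching disorders; the first
confirmed disorder in hypothesis order is reported as primary. Co-occurring
confirmations are all listed — the classical account is silent on
co-occurrence, and discarding information seemed the worse default.

```{r diagnose}
vata_presentation <- setNames(
  ifelse(kb$symptoms$id %in% disorder_body(kb, "vata"), "yes", "no"),
  kb$symptoms$id
)
d <- diagnose(kb, vata_presentation)
d
glance(d)
```

The dialogue layer (`run_session()`) renders the KB's question text,
parses free-text replies case-insensitively (`y`/`yes`/`n`/`no`),
re-prompts on anything else up to `max_reprompts` times (default 3, after
which the session aborts cleanly with its partial transcript), and accepts
`why` at any prompt to print the current line of reasoning. "Unknown" is
deliberately not a storable answer: the engine's facts are binary, and
uncertainty is handled at the dialogue level by re-prompting.

Two explanation facilities mirror classic consultation systems:
`explain_why()` justifies the pending question by the goal disorder and
its still-unverified symptoms; `explain_how()` linearizes the trace into
one line per hypothesis with the facts that decided it. Traces serialize
as JSON lines (`write_trace()`) and the CLI's `replay` subcommand
re-renders the how-explanation from a saved file.

## Numerical and degenerate-input choices

* Answers and facts are the strings `"yes"`/`"no"`; anything else from a
  provider is a contract error, never coerced.
* Confirmed fractions are exact ratios of small integers; status is
  derived as: any no-fact ⇒ rejected, else all-yes ⇒ confirmed, else open.
  Ties in near-miss ranking are broken by hypothesis order, so output text
  is deterministic.
* A KB with zero disorders, empty rule bodies, or dangling references is
  rejected at load with the complete violation list; the engine itself
  only ever sees validated KBs.
* Trace ordinals are strictly increasing integers assigned at emission,
  making byte-identical serialization a meaningful determinism check.

## The synthetic evaluation harness

No expert-labelled case data accompanies the classical material, so the
harness generates its own cases. A case for true disorder $d$ starts from
the indicator vector of $S_d$ ("yes" exactly on $d$'s symptoms) and flips
each of the KB's symptoms independently with probability `noise_rate` —
a symmetric-noise stand-in for imperfect observation by the person
answering the questions. This emulates random misreporting only: it does
not model correlated observation errors, systematically ambiguous
symptoms, co-occurring disorders, or an observer who misunderstands a
question the same way every time. Perfect noise-free accuracy on these
cases therefore shows that the rules are mutually distinguishable and the
chainer is sound, not that field diagnosis of real plants would be
error-free.

Reproducibility is by construction: a master seed expands into per-case
seeds by fixed arithmetic (recorded in the metrics for replay), and
identical inputs yield bit-identical metrics files. `evaluate_cases()`
reports accuracy (primary conclusion equals the true disorder; an
unmatched vector counts as incorrect with predicted `"none"`), mean
questions per interview, and a true-by-predicted confusion table. If a
KB's rule bodies are nested the generator warns, because the outer
disorder's indicator also fires the inner rule and the ambiguity then
shows up as off-diagonal confusion rather than silent error.

```{r evaluate}
m <- evaluate_cases(kb, generate_cases(kb, noise_rate = 0.2,
  n_per_disorder = 10, master_seed = 1))
glance(m)
```

The test suite sizes its simulations to be thorough but quick: exhaustive
oracle comparison against dialogue-free rule matching over all $2^{10}$
answer vectors on a ten-symptom KB, one thousand randomized sessions for
the no-repeated-question and belief-monotonicity invariants, and a noise
sweep over rates 0, 0.1, 0.3 and 0.5 with 500 cases per level. These
sizes were chosen as comfortably sufficient for the binary properties
being checked.

## Known limitations

* The identities of the original ten diseases are not recoverable from
  the available classical description; three KB records are explicit
  curator constructions and are flagged as such in the document.
* Belief is all-or-nothing plus a fraction — no certainty factors or
  probabilistic updating, by design.
* The engine is strictly goal-driven (no forward chaining), answers are
  binary, interaction is English-only, and the interface is a library
  plus CLI rather than a web service.
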