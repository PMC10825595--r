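test_that("a pure vata presentation is classified as vata", {
  kb <- example_kb()
  d <- diagnose(kb, indicator_answers(kb, "vata"))
  expect_equal(d$primary, "vata")
  expect_equal(d$confirmed, "vata")
  expect_true("kunapajala" %in% d$treatments$id)
  # belief invariants: confirmed iff full fraction, rejected iff a no-fact
  b <- d$belief
  expect_equal(b$status == "confirmed", b$confirmed_fraction == 1)
  expect_equal(b$status == "rejected", lengths(b$no_facts) > 0)
})

test_that("an all-no session confirms nothing", {
  kb <- example_kb()
  d <- diagnose(kb, uniform_answers(kb, "no"))
  expect_length(d$confirmed, 0)
  expect_true(is.na(d$primary))
  expect_equal(nrow(d$treatments), 0)
  expect_true(all(d$belief$status == "rejected"))
})

test_that("hypothesis evaluation asks in order, stops at the first no, and memoizes", {
  kb <- example_kb() # vata has 4 symptoms
  wm <- new_working_memory()
  status <- evaluate_hypothesis(kb, "vata", wm, uniform_answers(kb, "yes"))
  expect_equal(status, "confirmed")
  expect_equal(length(wm$question_log), 4)
  expect_equal(wm$question_log, disorder_body(kb, "vata"))

  # "no" on the second symptom rejects after exactly 2 questions
  ans <- uniform_answers(kb, "yes")
  ans[[disorder_body(kb, "vata")[2]]] <- "no"
  wm2 <- new_working_memory()
  expect_equal(evaluate_hypothesis(kb, "vata", wm2, ans), "rejected")
  expect_equal(length(wm2$question_log), 2)

  # exhaustive mode keeps asking the remaining symptoms anyway
  wm3 <- new_working_memory()
  expect_equal(evaluate_hypothesis(kb, "vata", wm3, ans, exhaustive = TRUE), "rejected")
  expect_equal(length(wm3$question_log), 4)

  # a second hypothesis sharing answered symptoms asks only the new ones
  okb <- kb_overlap() # d1: s1 s2 s3; d2: s2 s3 s4
  wm4 <- new_working_memory()
  evaluate_hypothesis(okb, "d1", wm4, uniform_answers(okb, "yes"))
  expect_equal(length(wm4$question_log), 3)
  evaluate_hypothesis(okb, "d2", wm4, uniform_answers(okb, "yes"))
  expect_equal(wm4$question_log, c("s1", "s2", "s3", "s4"))

  expect_error(
    evaluate_hypothesis(kb, "not_a_disorder", new_working_memory(), ans),
    class = "vriksha_lookup_error"
  )
})

test_that("backward chainer agrees with brute-force matching on every complete vector", {
  for (kb in list(kb_disjoint(), kb_overlap(), kb_nested())) {
    for (vec in all_answer_vectors(kb)) {
      d <- diagnose(kb, vec, stop_at_first = FALSE)
      expect_equal(sort(d$confirmed), sort(brute_force_diagnose(kb, vec)))
    }
  }
})

test_that("brute-force oracle handles the degenerate vectors and contracts", {
  kb <- kb_disjoint()
  expect_equal(brute_force_diagnose(kb, uniform_answers(kb, "yes")), kb$disorders$id)
  expect_length(brute_force_diagnose(kb, uniform_answers(kb, "no")), 0)
  expect_equal(brute_force_diagnose(kb, indicator_answers(kb, "d2")), "d2")
  expect_error(
    brute_force_diagnose(kb, c(s1 = "yes")),
    class = "vriksha_contract_error"
  )
  expect_error(
    brute_force_diagnose(kb, setNames(rep("maybe", 8), kb$symptoms$id)),
    class = "vriksha_contract_error"
  )
})

test_that("update_belief recomputes fractions and obeys its contracts", {
  kb <- kb_disjoint()
  bs <- new_belief_state(kb)
  expect_true(all(bs$status == "open"))
  expect_true(all(bs$confirmed_fraction == 0))

  # k yes-facts of N give fraction k/N; brute-force recount over the fact set
  body <- disorder_body(kb, "d1") # 3 symptoms
  facts <- list(new_fact("s1", "yes"), new_fact("s2", "yes"))
  for (f in facts) bs <- update_belief(bs, "d1", f)
  i <- match("d1", bs$disorder_id)
  recount <- sum(vapply(facts, function(f) f$value == "yes", logical(1)))
  expect_equal(bs$confirmed_fraction[[i]], recount / length(body))
  expect_equal(bs$status[[i]], "open")

  # any no-fact rejects regardless of fraction
  bs2 <- update_belief(bs, "d1", new_fact("s3", "no"))
  expect_equal(bs2$status[[match("d1", bs2$disorder_id)]], "rejected")

  # all yes confirms
  bs3 <- update_belief(bs, "d1", new_fact("s3", "yes"))
  expect_equal(bs3$status[[match("d1", bs3$disorder_id)]], "confirmed")
  expect_equal(bs3$confirmed_fraction[[match("d1", bs3$disorder_id)]], 1)

  # a fact for an unrelated symptom is a contract violation
  expect_error(update_belief(bs, "d1", new_fact("s4", "yes")),
    class = "vriksha_contract_error"
  )
  expect_error(new_fact("s1", "maybe"), class = "vriksha_contract_error")
})

test_that("belief fractions are monotone in yes-facts without no-facts", {
  kb <- kb_ten_symptoms()
  withr::with_seed(42, {
    for (rep in 1:200) {
      did <- sample(kb$disorders$id, 1)
      body <- sample(disorder_body(kb, did)) # random arrival order
      bs <- new_belief_state(kb)
      prev <- 0
      for (sid in body) {
        bs <- update_belief(bs, did, new_fact(sid, "yes"))
        fr <- bs$confirmed_fraction[[match(did, bs$disorder_id)]]
        expect_gte(fr, prev)
        prev <- fr
      }
      expect_equal(prev, 1)
    }
  })
})

test_that("engine beliefs equal a fold of update_belief over the recorded facts", {
  kb <- kb_overlap()
  withr::with_seed(7, {
    for (rep in 1:50) {
      vec <- random_answers(kb)
      d <- diagnose(kb, vec, exhaustive = TRUE)
      bs <- new_belief_state(kb)
      for (i in seq_len(nrow(d$facts))) {
        f <- new_fact(d$facts$symptom_id[[i]], d$facts$value[[i]], "scripted")
        for (did in bs$disorder_id) {
          if (f$symptom_id %in% disorder_body(kb, did)) {
            bs <- update_belief(bs, did, f)
          }
        }
      }
      expect_equal(bs$status, d$belief$status)
      expect_equal(bs$confirmed_fraction, d$belief$confirmed_fraction)
    }
  })
})

test_that("why-explanations cite the current goal and its untested symptoms", {
  kb <- example_kb()
  seen <- list()
  probing <- function(symptom_id, state) {
    if (symptom_id %in% c("dry_leaves", "inflamed_tissue")) {
      seen[[symptom_id]] <<- explain_why(state)
    }
    if (symptom_id %in% disorder_body(kb, "vata")[1:2]) "yes" else "no"
  }
  diagnose(kb, probing)
  # first question of the session cites the first hypothesis in taxonomy order
  expect_match(seen$dry_leaves, "'vata'")
  expect_match(seen$dry_leaves, "dryness in leaves")
  expect_match(seen$dry_leaves, "wilting") # still to verify
  # after the goal switches, the new goal is cited, not the rejected one
  expect_match(seen$inflamed_tissue, "'pitta'")
  expect_no_match(seen$inflamed_tissue, "'vata'")
  # outside a pending question there is nothing to justify
  expect_error(explain_why(new_kb(
    fixture_disorders("d", list("s1")), fixture_symptoms("s1")
  )), class = "vriksha_state_error")
})

test_that("how-explanations list deciding facts and replay to the same conclusion", {
  kb <- example_kb()
  d <- diagnose(kb, indicator_answers(kb, "vata"))
  txt <- explain_how(d)
  expect_match(txt, "Hypothesis 'vata': CONFIRMED")
  for (sid in disorder_body(kb, "vata")) {
    expect_match(txt, paste0(sid, "=yes"))
  }

  d_none <- diagnose(kb, uniform_answers(kb, "no"))
  txt_none <- explain_how(d_none)
  # one deciding no per rejected hypothesis
  expect_equal(
    length(gregexpr("REJECTED — decided by", txt_none)[[1]]),
    nrow(kb$disorders)
  )

  # trace replay: facts recorded in the trace, completed with "no",
  # reproduce the confirmed set through the independent oracle
  withr::with_seed(11, {
    for (rep in 1:25) {
      vec <- random_answers(kb, p_yes = 0.8)
      d <- diagnose(kb, vec)
      recorded <- d$trace[d$trace$kind == "fact_recorded", ]
      replayed <- uniform_answers(kb, "no")
      replayed[recorded$symptom_id] <- recorded$value
      expect_equal(
        sort(brute_force_diagnose(kb, replayed)),
        sort(d$confirmed)
      )
    }
  })
})

test_that("identical sessions serialize to byte-identical traces", {
  kb <- example_kb()
  vec <- withr::with_seed(3, random_answers(kb, p_yes = 0.7))
  d1 <- diagnose(kb, vec)
  d2 <- diagnose(kb, vec)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_trace(d1, f1)
  write_trace(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
  # and the trace round-trips through the JSONL reader
  expect_equal(read_trace(f1), d1$trace)
})

test_that("no question is ever repeated and early stopping never asks more", {
  kb <- example_kb()
  n_symptoms <- nrow(kb$symptoms)
  withr::with_seed(23, {
    for (rep in 1:100) {
      vec <- random_answers(kb)
      d <- diagnose(kb, vec)
      expect_equal(anyDuplicated(d$question_log), 0)
      expect_equal(length(d$question_log), nrow(d$facts))
      expect_lte(length(d$question_log), n_symptoms)
      d_ex <- diagnose(kb, vec, exhaustive = TRUE)
      expect_lte(length(d$question_log), length(d_ex$question_log))
      # trace ordinals strictly increase
      expect_true(all(diff(d$trace$ordinal) > 0))
      expect_true(all(d$trace$kind %in% c(
        "goal_selected", "question_asked", "fact_recorded",
        "belief_updated", "hypothesis_concluded"
      )))
    }
  })
})

test_that("stop_at_first halts at the first confirmed hypothesis", {
  kb <- kb_overlap()
  vec <- uniform_answers(kb, "yes")
  d <- diagnose(kb, vec, stop_at_first = TRUE)
  expect_equal(d$confirmed, "d1")
  expect_equal(d$evaluated, "d1")
  d_all <- diagnose(kb, vec, stop_at_first = FALSE)
  expect_equal(d_all$confirmed, c("d1", "d2", "d3"))
})

test_that("a failing provider raises a session error carrying the partial trace", {
  kb <- example_kb()
  flaky <- local({
    n <- 0
    function(symptom_id, state) {
      n <<- n + 1
      if (n > 3) stop("sensor offline")
      "yes"
    }
  })
  err <- expect_error(diagnose(kb, flaky), class = "vriksha_session_error")
  expect_s3_class(err$trace_tbl, "tbl_df")
  expect_equal(sum(err$trace_tbl$kind == "fact_recorded"), 3)

  # a provider returning a non-answer is also a session error
  broken <- function(symptom_id, state) "perhaps"
  expect_error(diagnose(kb, broken), class = "vriksha_session_error")
})
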