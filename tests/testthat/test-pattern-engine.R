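test_that("sentence segmentation handles empty, simple and degenerate text", {
  expect_equal(nrow(segment_sentences("")), 0)
  expect_equal(nrow(segment_sentences(NA_character_)), 0)

  s <- segment_sentences("Pt denies misuse. Plan: refill.")
  expect_equal(nrow(s), 2)
  txt <- "Pt denies misuse. Plan: refill."
  expect_equal(substring(txt, s$start + 1, s$end),
               c("Pt denies misuse.", "Plan: refill."))

  s2 <- segment_sentences("no terminal punctuation at all")
  expect_equal(nrow(s2), 1)
  expect_equal(s2$start, 0L)
  expect_equal(s2$end, nchar("no terminal punctuation at all"))
})

test_that("sentence segmentation respects clinical abbreviations and newlines", {
  txt <- "Oxycodone 5 mg. daily was continued. Seen by Dr. Smith today."
  s <- segment_sentences(txt)
  expect_equal(nrow(s), 2)
  expect_equal(substring(txt, s$start + 1, s$end)[1],
               "Oxycodone 5 mg. daily was continued.")

  txt2 <- "Line one\nLine two"
  s2 <- segment_sentences(txt2)
  expect_equal(substring(txt2, s2$start + 1, s2$end), c("Line one", "Line two"))
})

test_that("sentence spans are ordered, non-overlapping and partition text", {
  corpus <- simulate_corpus(sim_config(n_patients = 15, seed = 11))
  for (txt in corpus$notes$text[1:20]) {
    s <- segment_sentences(txt)
    expect_true(all(s$start >= 0 & s$start < s$end & s$end <= nchar(txt)))
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    # non-whitespace content is fully covered
    covered <- paste(substring(txt, s$start + 1, s$end), collapse = "")
    expect_equal(gsub("\\s", "", covered), gsub("\\s", "", txt))
  }
})

test_that("opioid-context filter honors the lexicon and order constraint", {
  lex <- c(abc_patterns()$lexicons$opioid_terms,
           abc_patterns()$lexicons$drug_names)
  sent <- "patient has been hoarding pain meds"
  ts <- stringr::str_locate(sent, "hoarding")
  expect_true(has_opioid_context(sent, ts[1] - 1, ts[2], lex,
                                 order = "trigger_before_term"))
  sent2 <- "patient hoards coins"
  ts2 <- stringr::str_locate(sent2, "hoards")
  expect_false(has_opioid_context(sent2, ts2[1] - 1, ts2[2], lex))

  sent3 <- "oxycodone was hoarded"
  ts3 <- stringr::str_locate(sent3, "hoarded")
  expect_false(has_opioid_context(sent3, ts3[1] - 1, ts3[2], lex,
                                  order = "trigger_before_term"))
  expect_true(has_opioid_context(sent3, ts3[1] - 1, ts3[2], lex,
                                 order = "none"))
})

test_that("negation fires only for terms preceding the trigger", {
  neg <- abc_patterns()$lexicons$negation_terms
  s1 <- "patient denies hoarding opioids"
  t1 <- stringr::str_locate(s1, "hoarding")
  expect_true(is_negated(s1, t1[1] - 1, t1[2], neg))

  s2 <- "patient is hoarding opioids and denies alcohol use"
  t2 <- stringr::str_locate(s2, "hoarding")
  expect_false(is_negated(s2, t2[1] - 1, t2[2], neg))

  expect_false(is_negated(s1, t1[1] - 1, t1[2], character()))
  # whole-word matching: "not" must not fire inside "cannot"
  s3 <- "he cannot function without his meds"
  t3 <- stringr::str_locate(s3, "function")
  expect_false(is_negated(s3, t3[1] - 1, t3[2], c("no", "not")))
})

test_that("prefix exclusion scans the note text before the trigger", {
  txt <- "Discharge Instructions: take oxycodone as needed."
  off <- stringr::str_locate(txt, "oxycodone")[1] - 1
  expect_true(is_excluded_by_prefix(txt, off, "discharge instructions"))
  expect_false(is_excluded_by_prefix(txt, 0, "discharge instructions"))
  expect_false(is_excluded_by_prefix(txt, off, character()))
})

test_that("the item-2 walkthrough matches and its filters fire", {
  m <- default_matcher()
  hit <- match_note(m, make_note("Patient admits to hoarding pain meds since last visit."))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$item_id, 2L)
  expect_match(hit$filters_passed, "opioid_context=pass")
  expect_match(hit$filters_passed, "negation=pass")

  expect_equal(nrow(match_note(m, make_note("Patient denies hoarding opioids."))), 0)
  expect_equal(nrow(match_note(m, make_note("Discharge instructions: resume left over hydrocodone."))), 0)
})

test_that("filtered hits are auditable with the failing stage recorded", {
  m <- default_matcher()
  all_hits <- match_note(m, make_note("Patient denies hoarding opioids."),
                         keep_filtered = TRUE)
  expect_gte(nrow(all_hits), 1)
  expect_match(all_hits$filters_passed[all_hits$item_id == 2], "negation=fail")
  expect_false(any(all_hits$survived))
})

test_that("audit fidelity: matched_text equals the note slice at the span", {
  corpus <- simulate_corpus(sim_config(n_patients = 25, seed = 5))
  m <- default_matcher()
  matches <- match_notes(m, corpus$notes)
  expect_gt(nrow(matches), 0)
  note_text <- corpus$notes$text[match(matches$note_id, corpus$notes$note_id)]
  expect_equal(matches$matched_text,
               substring(note_text, matches$start + 1, matches$end))
  # sentence_text contains the matched trigger
  expect_true(all(mapply(grepl, stringr::fixed(matches$matched_text),
                         matches$sentence_text, MoreArgs = list(fixed = TRUE))))
})

test_that("matching is case-insensitive and deterministic", {
  m <- default_matcher()
  corpus <- simulate_corpus(sim_config(n_patients = 10, seed = 8))
  notes <- corpus$notes
  base <- match_notes(m, notes)
  upper <- notes
  upper$text <- toupper(notes$text)
  up <- match_notes(m, upper)
  expect_equal(up[c("note_id", "item_id", "start", "end")],
               base[c("note_id", "item_id", "start", "end")])
  expect_identical(match_notes(m, notes), base)
})

test_that("each added filter stage can only remove matches", {
  cfg <- abc_patterns()
  strip <- function(cfg, ctx = TRUE, neg = TRUE, excl = TRUE) {
    out <- unclass(cfg)
    out$items <- lapply(out$items, function(it) {
      if (!ctx) {
        it$require_opioid_context <- FALSE
        it$opioid_order_constraint <- "none"
      }
      if (!neg) it$negation_enabled <- FALSE
      if (!excl) it$exclusion_prefixes <- character()
      it
    })
    validate_pattern_config(out)
  }
  corpus <- simulate_corpus(sim_config(n_patients = 30, seed = 13,
                                       negated_mention_rate = 0.5,
                                       non_opioid_decoy_rate = 0.4,
                                       discharge_decoy_rate = 0.5))
  n_full <- nrow(match_notes(compile_patterns(cfg), corpus$notes))
  n_noexcl <- nrow(match_notes(compile_patterns(strip(cfg, excl = FALSE)),
                               corpus$notes))
  n_noneg <- nrow(match_notes(compile_patterns(strip(cfg, neg = FALSE,
                                                     excl = FALSE)),
                              corpus$notes))
  n_core <- nrow(match_notes(compile_patterns(strip(cfg, ctx = FALSE,
                                                    neg = FALSE, excl = FALSE)),
                             corpus$notes))
  expect_lte(n_full, n_noexcl)
  expect_lte(n_noexcl, n_noneg)
  expect_lte(n_noneg, n_core)
  expect_lt(n_full, n_core)  # the decoys guarantee a strict drop somewhere
})

test_that("empty and whitespace-only notes produce no matches", {
  m <- default_matcher()
  expect_equal(nrow(match_note(m, make_note(""))), 0)
  expect_equal(nrow(match_note(m, make_note("   \n  "))), 0)
})
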