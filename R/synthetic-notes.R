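# Synthetic multi-note patient corpora with planted ABC-item mentions,
# negated mentions and decoys, plus exactly-known ground truth. Templates
# are deliberately disjoint from real patient text; each template sentence
# is engineered (and regression-tested) to interact with exactly one item
# of the default pattern configuration.

#' Template bank for the synthetic corpus generator
#'
#' One row per template sentence, aligned with the default pattern config:
#' `positive` templates survive the full filter chain for their item and no
#' other; `negated` templates fire the core expression but are removed by
#' the negation filter; `decoy` templates use non-opioid objects so the
#' opioid-context filter (or the core expression itself) rejects them;
#' `paraphrase` templates (hard mode) are genuine mentions phrased outside
#' the expression set — known false negatives for benchmarking.
#'
#' @return A tibble with `item_id`, `kind`, `text`.
#' @export
abc_templates <- function() {
  tpl <- function(item_id, kind, text) tibble::tibble(item_id = item_id, kind = kind, text = text)
  dplyr::bind_rows(
    tpl(1L, "positive", "Patient admits to using illicit drugs on weekends."),
    tpl(1L, "positive", "There is a longstanding pattern of problem drinking at home."),
    tpl(1L, "negated", "Patient denies any illicit drug use."),
    tpl(1L, "decoy", "Patient attended a community support group this week."),
    tpl(2L, "positive", "Patient admits to hoarding pain meds since the last visit."),
    tpl(2L, "positive", "She has been stockpiling oxycodone tablets at home."),
    tpl(2L, "negated", "Patient denies hoarding opioids."),
    tpl(2L, "decoy", "Patient has been hoarding canned goods in the pantry."),
    tpl(3L, "positive", "He has been taking more oxycodone than prescribed this month."),
    tpl(3L, "negated", "She is not taking more pain medication than directed."),
    tpl(3L, "decoy", "He walked more miles than expected at rehab."),
    tpl(4L, "positive", "Patient ran out of hydrocodone early again this month."),
    tpl(4L, "negated", "Patient denies running out of pain meds early."),
    tpl(4L, "decoy", "Patient ran out of shampoo early this week."),
    tpl(5L, "positive", "Patient reports increased use of narcotics since the last visit."),
    tpl(5L, "negated", "No increased use of opioids was reported today."),
    tpl(5L, "decoy", "Patient increased use of the stationary bike this month."),
    tpl(6L, "positive", "Patient takes her morphine prn rather than on the scheduled dosing plan."),
    tpl(6L, "negated", "She does not take tramadol prn instead of the scheduled doses."),
    tpl(6L, "decoy", "Uses albuterol inhaler prn rather than the scheduled nebulizer."),
    tpl(7L, "positive", "Patient obtained narcotic prescriptions from multiple providers this year."),
    tpl(7L, "negated", "Patient denied getting pain meds from multiple doctors."),
    tpl(7L, "decoy", "Patient saw multiple providers for her diabetes care."),
    tpl(8L, "positive", "Patient admitted he bought percocet on the street last month."),
    tpl(8L, "negated", "Patient denies buying narcotics on the street."),
    tpl(8L, "decoy", "Patient bought groceries on the street market nearby."),
    tpl(9L, "positive", "Patient appears sedated with slurred speech this morning."),
    tpl(9L, "negated", "No slurred speech was noted on exam."),
    tpl(9L, "decoy", "Patient appears alert and oriented on exam."),
    tpl(10L, "positive", "Patient is worried about becoming addicted to her medication."),
    tpl(10L, "negated", "Patient is not worried about addiction at this time."),
    tpl(10L, "decoy", "Patient is worried about transportation to appointments."),
    tpl(11L, "positive", "Patient is anxious about running out of oxycodone before the next appointment."),
    tpl(11L, "negated", "Patient is not concerned about her opioid supply."),
    tpl(11L, "decoy", "Patient is worried about the availability of parking downtown."),
    tpl(12L, "positive", "Patient reports her prescription was stolen from her car."),
    tpl(12L, "negated", "Patient denies any lost or stolen medications."),
    tpl(12L, "decoy", "Patient lost his house keys at the park."),
    tpl(13L, "positive", "Patient states she needs her pain meds to get through the day."),
    tpl(13L, "negated", "Patient never says she must have narcotic medication."),
    tpl(13L, "decoy", "Patient needs a new walker for ambulation."),
    tpl(14L, "positive", "Discussion of analgesic medication was the predominant issue of this visit."),
    tpl(14L, "negated", "Pain medication was not the predominant topic of the visit."),
    tpl(14L, "decoy", "Fatigue was the predominant complaint of this visit."),
    tpl(15L, "positive", "Patient remains noncompliant with the recommended physical therapy plan."),
    tpl(15L, "negated", "Patient has never been noncompliant with recommended therapy."),
    tpl(15L, "decoy", "Patient completed the recommended physical therapy plan."),
    tpl(16L, "positive", "Patient requested an early refill of her percocet."),
    tpl(16L, "positive", "She called asking for an early refill of oxycodone."),
    tpl(16L, "negated", "Patient has not requested early refills of her pain meds."),
    tpl(16L, "decoy", "Patient requested an early refill of her statin."),
    tpl(17L, "positive", "Patient exhibits opioid withdrawal symptoms including sweating and tremor."),
    tpl(17L, "negated", "No withdrawal signs were observed today."),
    tpl(17L, "decoy", "Patient withdrew from the aquatics class."),
    tpl(18L, "positive", "He states he cannot function without his oxycodone."),
    tpl(18L, "negated", "She no longer says she cannot manage without narcotic medication."),
    tpl(18L, "decoy", "She cannot function without her reading glasses."),
    tpl(19L, "positive", "His wife is concerned about his use of pain medication."),
    tpl(19L, "negated", "There is no indication that her husband is worried about her pain medication."),
    tpl(19L, "decoy", "Her husband is concerned about her blood pressure."),
    tpl(20L, "positive", "Patient violated the opioid treatment agreement this quarter."),
    tpl(20L, "negated", "Patient has not violated her medication agreement."),
    tpl(20L, "decoy", "Patient signed the medication agreement today."),
    tpl(2L, "paraphrase", "Patient has been squirreling away her tablets for later."),
    tpl(4L, "paraphrase", "He goes through his monthly tablets in under three weeks."),
    tpl(10L, "paraphrase", "Patient voiced unease about getting hooked on the pills.")
  )
}

#' Discharge-instruction decoy notes
#'
#' Decoy note texts that fire an exclusion-enabled core expression with
#' opioid context but sit after a "Discharge instructions" header, so the
#' prefix filter must remove them. The generator plants them as dedicated
#' notes so the header cannot mask genuine mentions elsewhere in a note.
#'
#' @return Character vector of note texts.
#' @export
discharge_templates <- function() {
  c(paste("Discharge instructions: take remaining left over oxycodone as",
          "directed. Call the clinic with any questions."),
    paste("Discharge instructions: patient may use remaining left over pain",
          "meds as needed for breakthrough pain. Follow up with primary care."))
}

#' Neutral clinical boilerplate sentences
#'
#' Filler sentences giving synthetic notes realistic bulk; regression-tested
#' to match no core expression in the packaged pattern set.
#'
#' @return Character vector of sentences.
#' @export
filler_bank <- function() {
  c("Vital signs were stable today.",
    "Patient presents for routine follow up.",
    "Blood pressure was 128 over 76.",
    "Reviewed current medication list with the patient.",
    "Gait steady with no assistive device in use.",
    "Labs were reviewed and unremarkable.",
    "Imaging of the lumbar spine shows mild degenerative changes.",
    "Patient will continue the home exercise program.",
    "Sleep remains fair with occasional awakenings.",
    "Appetite is good and weight is stable.",
    "Plan to continue current management.",
    "Patient was counseled on diet and exercise.",
    "Physical exam otherwise within normal limits.",
    "Return to clinic in three months.")
}

#' Synthetic OUD ICD code set
#'
#' Opioid use disorder diagnosis codes used by the simulator and examples.
#' The published study's full code list is not public; this synthetic
#' default covers the common ICD-9 304.0x/305.5x and ICD-10 F11.x families.
#'
#' @return Character vector of ICD codes.
#' @export
default_oud_codes <- function() {
  c("304.00", "304.01", "304.02", "305.50", "305.51",
    "F11.10", "F11.20", "F11.21", "F11.90")
}

#' Simulation configuration
#'
#' Parameters of the synthetic corpus generator. Defaults are desk-scale
#' study conditions: 200 patients, heavy-tailed (negative-binomial) note
#' counts, item mention probabilities concentrated on the
#' general-addiction and analgesic-discussion items, a logistic link from
#' true total score to case probability, and score-independent ICD-code
#' emission given case status.
#'
#' @param n_patients Number of patients (>= 1).
#' @param note_mean,note_size Mean and dispersion (negative binomial `mu`,
#'   `size`) of per-patient note counts; at least one note unless the
#'   patient is selected as note-less.
#' @param p_no_notes Probability a patient has no notes at all (mirrors the
#'   small note-less fraction seen in EHR cohorts).
#' @param p_mention Length-20 vector of per-item true-mention
#'   probabilities.
#' @param negated_mention_rate Per-item probability of planting a negated
#'   mention (does not affect ground truth).
#' @param non_opioid_decoy_rate Per-item probability of planting a
#'   non-opioid decoy sentence.
#' @param discharge_decoy_rate Per-patient probability of adding a
#'   dedicated discharge-instructions decoy note.
#' @param label_intercept,label_slope Logistic model
#'   `P(case) = plogis(intercept + slope * total_score)`.
#' @param icd_p_case,icd_p_control Probability of a 2-distinct-day OUD ICD
#'   code given case / control status.
#' @param p_single_day_icd Probability (among patients without the 2-day
#'   code) of a single-day OUD code, exercising the distinct-day rule.
#' @param hard_mode Also plant paraphrase mentions outside the expression
#'   set (known false negatives); excluded from exact-recovery checks.
#' @param paraphrase_rate Per-item plant probability in hard mode.
#' @param seed Mandatory integer RNG seed.
#' @return A validated list of class `abc_sim_config`.
#' @export
sim_config <- function(n_patients = 200,
                       note_mean = 4, note_size = 1.5,
                       p_no_notes = 0.02,
                       p_mention = default_mention_probs(),
                       negated_mention_rate = 0.15,
                       non_opioid_decoy_rate = 0.10,
                       discharge_decoy_rate = 0.10,
                       label_intercept = -1.0, label_slope = 0.8,
                       icd_p_case = 0.12, icd_p_control = 0.01,
                       p_single_day_icd = 0.05,
                       hard_mode = FALSE, paraphrase_rate = 0.05,
                       seed) {
  if (missing(seed)) abort_input("sim_config requires an explicit seed")
  cfg <- list(n_patients = as.integer(n_patients), note_mean = note_mean,
              note_size = note_size, p_no_notes = p_no_notes,
              p_mention = p_mention,
              negated_mention_rate = negated_mention_rate,
              non_opioid_decoy_rate = non_opioid_decoy_rate,
              discharge_decoy_rate = discharge_decoy_rate,
              label_intercept = label_intercept, label_slope = label_slope,
              icd_p_case = icd_p_case, icd_p_control = icd_p_control,
              p_single_day_icd = p_single_day_icd,
              hard_mode = isTRUE(hard_mode), paraphrase_rate = paraphrase_rate,
              seed = as.integer(seed))
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) {
    abort_input("n_patients must be a positive integer")
  }
  if (length(cfg$p_mention) != 20) abort_input("p_mention must have length 20")
  probs <- c(cfg$p_mention, cfg$p_no_notes, cfg$negated_mention_rate,
             cfg$non_opioid_decoy_rate, cfg$discharge_decoy_rate,
             cfg$icd_p_case, cfg$icd_p_control, cfg$p_single_day_icd,
             cfg$paraphrase_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_input("all probabilities must lie in [0, 1]")
  }
  if (cfg$note_mean <= 0 || cfg$note_size <= 0) {
    abort_input("note_mean and note_size must be positive")
  }
  class(cfg) <- "abc_sim_config"
  cfg
}

#' Default per-item mention probabilities
#'
#' Most probability mass sits on the general-addiction item (1) and the
#' analgesic-discussion item (14) — the behaviors most often documented —
#' with modest rates elsewhere.
#'
#' @return Numeric vector of length 20.
#' @export
default_mention_probs <- function() {
  p <- rep(0.05, 20)
  p[1] <- 0.30; p[14] <- 0.25
  p[c(3, 5, 16)] <- 0.12
  p[c(2, 4, 12)] <- 0.08
  p
}

#' Generate a synthetic note corpus with ground truth
#'
#' Deterministic given `config$seed`. Every planted positive sentence comes
#' from the template bank aligned with the default pattern config, so a
#' patient's true item flag is, by construction, exactly "at least one
#' surviving planted sentence exists". Negated variants, non-opioid decoys
#' and discharge-instruction decoy notes add realistic false-positive
#' pressure without touching the truth.
#'
#' @param config An `abc_sim_config` from [sim_config()].
#' @return A list with tibbles `notes`, `diagnoses`, `labels`, `truth`
#'   (per-patient item flags, `total_score`, `case`), and `patients`
#'   (`patient_id`, `birth_date`).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "abc_sim_config"))
  tb <- abc_templates()
  pos_t <- split(tb$text[tb$kind == "positive"], tb$item_id[tb$kind == "positive"])
  neg_t <- split(tb$text[tb$kind == "negated"], tb$item_id[tb$kind == "negated"])
  dec_t <- split(tb$text[tb$kind == "decoy"], tb$item_id[tb$kind == "decoy"])
  par_t <- split(tb$text[tb$kind == "paraphrase"], tb$item_id[tb$kind == "paraphrase"])
  fillers <- filler_bank()
  note_types <- c("progress note", "history and physical",
                  "patient communication", "telephone encounter")

  with_local_seed(config$seed, {
    pids <- sprintf("P%04d", seq_len(config$n_patients))
    note_rows <- list(); dx_rows <- list(); truth_rows <- list()
    note_counter <- 0L
    for (i in seq_len(config$n_patients)) {
      pid <- pids[i]
      no_notes <- stats::runif(1) < config$p_no_notes
      n_notes <- if (no_notes) 0L else
        stats::rnbinom(1, size = config$note_size, mu = config$note_mean - 1) + 1L

      flags <- stats::runif(20) < config$p_mention & !no_notes
      planted <- list()
      if (n_notes > 0) {
        for (it in which(flags)) {
          planted[[length(planted) + 1]] <-
            list(note = sample.int(n_notes, 1), text = sample(pos_t[[as.character(it)]], 1))
        }
        for (it in which(stats::runif(20) < config$negated_mention_rate)) {
          planted[[length(planted) + 1]] <-
            list(note = sample.int(n_notes, 1), text = sample(neg_t[[as.character(it)]], 1))
        }
        for (it in which(stats::runif(20) < config$non_opioid_decoy_rate)) {
          planted[[length(planted) + 1]] <-
            list(note = sample.int(n_notes, 1), text = sample(dec_t[[as.character(it)]], 1))
        }
        if (config$hard_mode) {
          for (it in intersect(which(stats::runif(20) < config$paraphrase_rate),
                               as.integer(names(par_t)))) {
            flags[it] <- TRUE  # a genuine mention the expressions will miss
            planted[[length(planted) + 1]] <-
              list(note = sample.int(n_notes, 1), text = sample(par_t[[as.character(it)]], 1))
          }
        }
      }

      base_date <- as.Date("2018-01-01") + sample.int(1100, 1)
      if (n_notes > 0) {
        note_dates <- sort(base_date + sample.int(720, n_notes, replace = TRUE))
        sentences_by_note <- lapply(seq_len(n_notes), function(k) {
          sample(fillers, sample(2:5, 1), replace = FALSE)
        })
        for (pl in planted) {
          s <- sentences_by_note[[pl$note]]
          pos <- sample.int(length(s) + 1, 1)
          sentences_by_note[[pl$note]] <- append(s, pl$text, after = pos - 1)
        }
        for (k in seq_len(n_notes)) {
          note_counter <- note_counter + 1L
          note_rows[[note_counter]] <- tibble::tibble(
            patient_id = pid,
            note_id = sprintf("N%06d", note_counter),
            note_datetime = as.POSIXct(paste0(note_dates[k], " 09:00:00"), tz = "UTC"),
            note_type = sample(note_types, 1),
            text = paste(sentences_by_note[[k]], collapse = " "))
        }
        if (stats::runif(1) < config$discharge_decoy_rate) {
          note_counter <- note_counter + 1L
          note_rows[[note_counter]] <- tibble::tibble(
            patient_id = pid,
            note_id = sprintf("N%06d", note_counter),
            note_datetime = as.POSIXct(paste0(base_date + 30, " 09:00:00"), tz = "UTC"),
            note_type = "discharge summary",
            text = sample(discharge_templates(), 1))
        }
      }

      total <- sum(flags)
      case <- stats::runif(1) < stats::plogis(config$label_intercept +
                                                config$label_slope * total)
      category <- if (!case) "no" else sample(c("some", "high"), 1, prob = c(2, 1))

      # chronic-pain codes on two distinct days for everyone (cohort substrate)
      pain_code <- sample(default_pain_codes(), 1)
      dx <- tibble::tibble(patient_id = pid,
                           code = pain_code,
                           date = base_date + c(0, sample.int(200, 1)))
      icd_pos <- stats::runif(1) < (if (case) config$icd_p_case else config$icd_p_control)
      if (icd_pos) {
        dx <- dplyr::bind_rows(dx, tibble::tibble(
          patient_id = pid, code = sample(default_oud_codes(), 1),
          date = base_date + c(10, 10 + sample.int(150, 1))))
      } else if (stats::runif(1) < config$p_single_day_icd) {
        dx <- dplyr::bind_rows(dx, tibble::tibble(
          patient_id = pid, code = sample(default_oud_codes(), 1),
          date = base_date + 10))
      }
      dx_rows[[i]] <- dx

      tr <- tibble::as_tibble(as.list(stats::setNames(as.integer(flags), item_cols())))
      tr$patient_id <- pid
      tr$total_score <- as.integer(total)
      tr$case <- case
      tr$category <- category
      truth_rows[[i]] <- tr
    }

    notes <- if (note_counter == 0) {
      tibble::tibble(patient_id = character(), note_id = character(),
                     note_datetime = as.POSIXct(character(), tz = "UTC"),
                     note_type = character(), text = character())
    } else dplyr::bind_rows(note_rows)
    truth <- dplyr::bind_rows(truth_rows) |>
      dplyr::select("patient_id", dplyr::all_of(item_cols()), "total_score",
                    "case", "category")
    birth_dates <- tibble::tibble(
      patient_id = pids,
      birth_date = as.Date("2000-01-01") - sample(20:80, config$n_patients,
                                                  replace = TRUE) * 365)
    list(
      notes = notes,
      diagnoses = normalize_diagnoses(dplyr::bind_rows(dx_rows)),
      labels = as_labels(truth[, c("patient_id", "category")]),
      truth = truth,
      patients = birth_dates
    )
  })
}

#' End-to-end recovery check
#'
#' Runs the full match-and-score pipeline over a generated corpus and
#' compares the recovered item flags with the planted ground truth. On
#' template-bank-only corpora (hard mode off) recovery is exact by
#' construction — the core generator/engine consistency property.
#'
#' @param corpus Output of [simulate_corpus()], or an `abc_sim_config` to
#'   generate one.
#' @param matcher Optional precompiled `abc_matcher` (defaults to the
#'   packaged configuration).
#' @return A list with `per_item` (tibble: `item_id`, `n_true`,
#'   `n_recovered`, `agreement` over patients), `overall_agreement_pct`
#'   (percentage of patient-item cells agreeing), `totals_all_equal`, and
#'   the `scores` tibble.
#' @export
end_to_end_check <- function(corpus, matcher = NULL) {
  if (inherits(corpus, "abc_sim_config")) corpus <- simulate_corpus(corpus)
  if (is.null(matcher)) matcher <- compile_patterns()
  matches <- match_notes(matcher, corpus$notes)
  scores <- score_patients(matches, corpus$notes,
                           patients = corpus$patients$patient_id)
  truth <- corpus$truth[match(scores$patient_id, corpus$truth$patient_id), ]
  sc_mat <- as.matrix(scores[item_cols()])
  tr_mat <- as.matrix(truth[item_cols()])
  agree <- sc_mat == tr_mat
  per_item <- tibble::tibble(
    item_id = 1:20,
    n_true = as.integer(colSums(tr_mat)),
    n_recovered = as.integer(colSums(sc_mat)),
    agreement = colMeans(agree)
  )
  list(per_item = per_item,
       overall_agreement_pct = 100 * mean(agree),
       totals_all_equal = all(scores$total_score == truth$total_score),
       scores = scores)
}
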