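# Patient-level aggregation: one point per ABC item with >= 1 surviving
# match in any in-window note, regardless of multiplicity.

item_cols <- function() sprintf("item_%02d", 1:20)

#' Score patients from matches
#'
#' Aggregates surviving matches into per-patient ABC item vectors: item *i*
#' is flagged when at least one match for item *i* occurs in any of the
#' patient's notes inside the time window; the total score is the count of
#' flagged items (0-20). Match multiplicity is ignored. Patients present in
#' the corpus (or listed via `patients`) with no notes are retained with
#' `no_notes_flag` so they can be excluded from — or included in —
#' evaluation explicitly.
#'
#' @param matches Match tibble from [match_notes()].
#' @param notes The note tibble the matches were computed from.
#' @param cutoff_date Optional `Date` (or ISO string): only notes dated on
#'   or before it are scored, mirroring a consent-date restriction.
#' @param patients Optional character vector extending the patient universe
#'   beyond patients having notes (e.g. a cohort with note-less members).
#' @return A tibble with `patient_id`, `item_01`..`item_20` (0/1 integers),
#'   `total_score`, `n_notes_scanned`, `no_notes_flag`.
#' @export
score_patients <- function(matches, notes, cutoff_date = NULL, patients = NULL) {
  orphan <- setdiff(matches$note_id, notes$note_id)
  if (length(orphan) > 0) {
    abort_input(paste0("matches reference unknown note_id(s): ",
                       paste(utils::head(orphan, 10), collapse = ", ")))
  }
  if (!is.null(cutoff_date)) {
    cutoff_date <- as.Date(cutoff_date)
    in_window <- notes[as.Date(notes$note_datetime) <= cutoff_date, , drop = FALSE]
  } else {
    in_window <- notes
  }
  universe <- sort(unique(c(notes$patient_id, as.character(patients %||% character()))))
  n_notes <- table(factor(in_window$patient_id, levels = universe))

  flags <- matrix(0L, nrow = length(universe), ncol = 20,
                  dimnames = list(universe, item_cols()))
  if (nrow(matches) > 0) {
    mm <- matches[matches$note_id %in% in_window$note_id, , drop = FALSE]
    if (nrow(mm) > 0) {
      bad_item <- mm$item_id < 1 | mm$item_id > 20
      if (any(bad_item)) abort_input("match item_id outside 1..20")
      flags[cbind(match(mm$patient_id, universe), mm$item_id)] <- 1L
    }
  }
  out <- tibble::as_tibble(flags)
  out <- dplyr::bind_cols(tibble::tibble(patient_id = universe), out)
  out$total_score <- as.integer(rowSums(flags))
  out$n_notes_scanned <- as.integer(n_notes[universe])
  out$no_notes_flag <- out$n_notes_scanned == 0L
  out
}

#' Classify patients at a score threshold
#'
#' The binary ABC indicator: positive when `total_score >= threshold`.
#'
#' @param scores Score tibble from [score_patients()].
#' @param threshold Non-negative integer score threshold.
#' @return `scores` with added logical column `abc_positive` and a
#'   `threshold` attribute.
#' @export
classify_patients <- function(scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  out <- scores
  out$abc_positive <- scores$total_score >= threshold
  attr(out, "threshold") <- as.integer(threshold)
  out
}

#' Select the operating threshold by F1 sweep
#'
#' Sweeps every threshold tau in 0..20, computing the confusion of
#' `total_score >= tau` against the binary labels, and returns the smallest
#' tau attaining the maximal F1 (the "best balance between sensitivity and
#' positive predictive value", tie-broken toward sensitivity). The full
#' sweep table is returned for transparency; thresholds with no positive
#' calls have undefined precision and cannot win the sweep.
#'
#' @param scores Score tibble from [score_patients()].
#' @param labels Label tibble ([read_labels()] / [as_labels()]) or a data
#'   frame with `patient_id` and logical `binary_label`.
#' @param include_no_notes Include note-less patients as score 0
#'   (default `FALSE`: they are dropped from evaluation).
#' @return A list with `threshold` (integer), `f1` (its F1), and `sweep`
#'   (tibble: `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `ppv`,
#'   `f1`).
#' @export
select_threshold <- function(scores, labels, include_no_notes = FALSE) {
  ev <- align_scores_labels(scores, labels, include_no_notes)
  if (length(unique(ev$label)) < 2) {
    abort_input("select_threshold needs at least one positive and one negative label")
  }
  sweep <- lapply(0:20, function(tau) {
    pred <- ev$total_score >= tau
    cc <- confusion_from_logical(pred, ev$label)
    ms <- metric_point(cc)
    tibble::tibble(threshold = tau, tp = cc[["tp"]], fp = cc[["fp"]],
                   tn = cc[["tn"]], fn = cc[["fn"]],
                   sensitivity = ms[["sensitivity"]], ppv = ms[["ppv"]],
                   f1 = ms[["f1"]])
  })
  sweep <- dplyr::bind_rows(sweep)
  ok <- which(!is.na(sweep$f1))
  if (length(ok) == 0) abort_input("F1 undefined at every threshold")
  best <- ok[which.max(sweep$f1[ok])]  # which.max takes the first (smallest tau)
  list(threshold = sweep$threshold[best], f1 = sweep$f1[best], sweep = sweep)
}

# Join scores to labels on patient_id, applying the no-notes policy.
align_scores_labels <- function(scores, labels, include_no_notes = FALSE) {
  lab <- if ("binary_label" %in% names(labels)) {
    tibble::tibble(patient_id = as.character(labels$patient_id),
                   label = as.logical(labels$binary_label))
  } else {
    abort_schema("labels need a 'binary_label' column (see as_labels())")
  }
  sc <- scores
  if (!include_no_notes) sc <- sc[!sc$no_notes_flag, , drop = FALSE]
  ev <- dplyr::inner_join(sc, lab, by = "patient_id")
  if (nrow(ev) == 0) abort_input("no patients shared between scores and labels")
  ev
}
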