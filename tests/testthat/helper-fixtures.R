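# Shared fixture builders: tiny in-code corpora, no files on disk.

make_note <- function(text, patient_id = "p1", note_id = "n1",
                      note_datetime = "2020-06-01 09:00:00",
                      note_type = "progress note") {
  tibble::tibble(patient_id = patient_id, note_id = note_id,
                 note_datetime = as.POSIXct(note_datetime, tz = "UTC"),
                 note_type = note_type, text = text)
}

make_notes <- function(texts, patient_ids = "p1") {
  dplyr::bind_rows(lapply(seq_along(texts), function(i) {
    make_note(texts[i],
              patient_id = rep_len(patient_ids, length(texts))[i],
              note_id = paste0("n", i))
  }))
}

make_dx <- function(patient_id, code, date) {
  tibble::tibble(patient_id = patient_id, code = code, date = as.Date(date))
}

default_matcher <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- compile_patterns()
    m
  }
})

# Per-patient vectors from the published test-set contingency: strata sizes
# with their ICD-positive counts, expanded to patient-level logicals.
adjudication_vectors <- function() {
  path <- system.file("extdata", "primary_test_adjudication.csv",
                      package = "abcscore")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  ids <- sprintf("t%03d", seq_len(sum(tab$n_patients)))
  label <- rep(tab$category != "no", tab$n_patients)
  icd <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    c(rep(TRUE, tab$n_oud_icd_2day[i]),
      rep(FALSE, tab$n_patients[i] - tab$n_oud_icd_2day[i]))
  }))
  list(predicted = stats::setNames(icd, ids),
       labels = stats::setNames(label, ids))
}
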