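#' Read a table of clinical notes
#'
#' Reads one row per clinical note from CSV or JSON-lines, validates the
#' schema, and returns a note tibble — the matching substrate for the
#' pattern engine. Timestamps are parsed as ISO 8601 (date-only precision is
#' accepted) and kept timezone-naive by convention.
#'
#' @param path Path to the note file.
#' @param format `"csv"` or `"jsonl"`. Guessed from the file extension when
#'   omitted.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`patient_id`, `note_id`, `note_datetime`, `note_type`,
#'   `text`) to the names used in the file, e.g.
#'   `c(patient_id = "mrn", text = "note_text")`.
#' @param quiet Suppress the row-count message.
#'
#' @return A tibble with columns `patient_id`, `note_id` (unique),
#'   `note_datetime` (POSIXct), `note_type`, `text`. Row order is preserved.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,note_id,note_datetime,note_type,text",
#'              "p1,n1,2020-01-01,progress note,Stable."), f)
#' read_notes(f)
#' @export
read_notes <- function(path, format = c("auto", "csv", "jsonl"),
                       col_map = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_input(paste0("note file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(stringr::str_trim(lines))]
    if (length(lines) == 0) tibble::tibble() else
      dplyr::bind_rows(lapply(lines, function(l) {
        rec <- jsonlite::fromJSON(l)
        tibble::as_tibble(lapply(rec, function(v) as.character(v %||% NA_character_)))
      }))
  }
  notes <- remap_columns(raw, col_map,
                         required = c("patient_id", "note_id", "note_datetime",
                                      "note_type", "text"),
                         what = "note")
  if (nrow(notes) == 0) {
    out <- tibble::tibble(patient_id = character(), note_id = character(),
                          note_datetime = as.POSIXct(character(), tz = "UTC"),
                          note_type = character(), text = character())
    if (!quiet) rlang::inform("read 0 notes")
    return(out)
  }
  bad_id <- which(is.na(notes$patient_id) | !nzchar(notes$patient_id) |
                    is.na(notes$note_id) | !nzchar(notes$note_id))
  if (length(bad_id) > 0) {
    abort_schema(paste0("note rows with missing patient_id/note_id: row(s) ",
                        paste(bad_id, collapse = ", ")))
  }
  dt <- parse_note_datetime(notes$note_datetime)
  bad_dt <- which(is.na(dt))
  if (length(bad_dt) > 0) {
    abort_input(paste0("unparseable note_datetime at row(s): ",
                       paste(bad_dt, collapse = ", ")))
  }
  if (anyDuplicated(notes$note_id)) {
    abort_schema(paste0("duplicate note_id: ",
                        paste(unique(notes$note_id[duplicated(notes$note_id)]),
                              collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = notes$patient_id,
    note_id = notes$note_id,
    note_datetime = dt,
    note_type = dplyr::coalesce(notes$note_type, ""),
    text = dplyr::coalesce(notes$text, "")
  )
  if (!quiet) rlang::inform(paste0("read ", nrow(out), " notes"))
  out
}

remap_columns <- function(df, col_map, required, what) {
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(!nzchar(names(col_map)))) {
      abort_input("col_map must be a named character vector")
    }
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        abort_schema(paste0(what, " file is missing mapped column '", src, "'"))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_schema(paste0(what, " file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df[required]
}

#' Write notes as JSON lines
#'
#' One JSON object per line with the canonical note fields; timestamps are
#' serialized as ISO 8601 so that [read_notes()] round-trips them exactly.
#'
#' @param notes A note tibble as returned by [read_notes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(
      patient_id = notes$patient_id[i],
      note_id = notes$note_id[i],
      note_datetime = format(notes$note_datetime[i], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      note_type = notes$note_type[i],
      text = notes$text[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a diagnosis (ICD code) table
#'
#' CSV with `patient_id`, `code`, `date` (ISO 8601). Codes are uppercased
#' and whitespace-stripped on read.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named vector mapping canonical names
#'   (`patient_id`, `code`, `date`) to file column names.
#' @return A tibble with `patient_id`, `code` (normalized), `date` (Date).
#' @export
read_diagnoses <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort_input(paste0("diagnosis file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  df <- remap_columns(raw, col_map, required = c("patient_id", "code", "date"),
                      what = "diagnosis")
  normalize_diagnoses(df)
}

#' Normalize an in-memory diagnosis table
#'
#' Applies the same normalization as [read_diagnoses()]: codes uppercased
#' and stripped, dates coerced to `Date`, row-level errors for empty codes
#' or invalid dates.
#'
#' @param df Data frame with `patient_id`, `code`, `date`.
#' @return A normalized diagnosis tibble.
#' @export
normalize_diagnoses <- function(df) {
  if (nrow(df) == 0) {
    return(tibble::tibble(patient_id = character(), code = character(),
                          date = as.Date(character())))
  }
  code <- stringr::str_to_upper(stringr::str_trim(as.character(df$code)))
  bad_code <- which(is.na(code) | !nzchar(code))
  if (length(bad_code) > 0) {
    abort_input(paste0("empty diagnosis code at row(s): ",
                       paste(bad_code, collapse = ", ")))
  }
  date <- if (inherits(df$date, "Date")) df$date else parse_iso_date(df$date)
  bad_date <- which(is.na(date))
  if (length(bad_date) > 0) {
    abort_input(paste0("invalid diagnosis date at row(s): ",
                       paste(bad_date, collapse = ", ")))
  }
  tibble::tibble(patient_id = as.character(df$patient_id), code = code, date = date)
}

#' Read manual-review (adjudication) labels
#'
#' CSV with `patient_id` and `category` in `no` / `some` / `high` evidence
#' of opioid use disorder. The binary label used throughout evaluation is
#' `some or high = positive`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `patient_id`, `category` (factor no/some/high) and
#'   derived `binary_label` (logical).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_input(paste0("label file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  df <- remap_columns(raw, NULL, required = c("patient_id", "category"), what = "label")
  as_labels(df)
}

#' Validate a label table and derive the binary label
#'
#' @param df Data frame with `patient_id` and `category` (no/some/high), or
#'   `patient_id` and logical `binary_label`.
#' @return A tibble with `patient_id`, `category`, `binary_label`.
#' @export
as_labels <- function(df) {
  if ("category" %in% names(df)) {
    cat <- stringr::str_to_lower(stringr::str_trim(as.character(df$category)))
    bad <- which(!cat %in% c("no", "some", "high"))
    if (length(bad) > 0) {
      abort_input(paste0("label category must be no/some/high; bad row(s): ",
                         paste(bad, collapse = ", ")))
    }
    tibble::tibble(patient_id = as.character(df$patient_id),
                   category = factor(cat, levels = c("no", "some", "high")),
                   binary_label = cat != "no")
  } else if ("binary_label" %in% names(df)) {
    tibble::tibble(patient_id = as.character(df$patient_id),
                   category = factor(ifelse(df$binary_label, "some", "no"),
                                     levels = c("no", "some", "high")),
                   binary_label = as.logical(df$binary_label))
  } else {
    abort_schema("label table needs a 'category' or 'binary_label' column")
  }
}

#' Default chronic-pain ICD code set
#'
#' The four chronic-pain codes published with the cohort definition
#' (ICD-9 338.2, 338.21 and ICD-10 G89.2, G89.21). The full institutional
#' list is not public, so this default is intentionally minimal and
#' user-extensible: pass your own code set to [build_cohort()].
#'
#' @return Character vector of normalized ICD codes.
#' @export
default_pain_codes <- function() c("338.2", "338.21", "G89.2", "G89.21")

#' Build the chronic-pain study cohort
#'
#' A patient enters the cohort when (i) codes from `codes` appear on at
#' least `min_days` *distinct calendar dates* (a single repeated-day code is
#' treated as possibly spurious and excluded), and (ii) the patient is at
#' least `min_age` years old at the earliest qualifying code date. Patients
#' with qualifying codes but no birth date are excluded with a warning
#' rather than assumed adult.
#'
#' @param diagnoses Diagnosis tibble ([read_diagnoses()] /
#'   [normalize_diagnoses()]).
#' @param birth_dates Data frame with `patient_id`, `birth_date` (Date).
#' @param codes Character vector of qualifying ICD codes; matching is
#'   exact-string after normalization (uppercase, trimmed).
#' @param min_days Minimum number of distinct calendar dates bearing a
#'   qualifying code (default 2).
#' @param min_age Minimum age in completed years at first qualifying code
#'   (default 13).
#'
#' @return A tibble with `patient_id`, `first_dx_date`, `age_at_first_dx`,
#'   one row per included patient, sorted by `patient_id`.
#' @export
build_cohort <- function(diagnoses, birth_dates,
                         codes = default_pain_codes(),
                         min_days = 2, min_age = 13) {
  stopifnot(min_days >= 1, min_age >= 0)
  if (length(codes) == 0) abort_input("cohort code set must be non-empty")
  codes <- stringr::str_to_upper(stringr::str_trim(codes))
  if (nrow(diagnoses) == 0) {
    return(tibble::tibble(patient_id = character(),
                          first_dx_date = as.Date(character()),
                          age_at_first_dx = integer()))
  }
  qual <- diagnoses[diagnoses$code %in% codes, , drop = FALSE]
  if (nrow(qual) == 0) {
    return(tibble::tibble(patient_id = character(),
                          first_dx_date = as.Date(character()),
                          age_at_first_dx = integer()))
  }
  per <- qual |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$date),
                     first_dx_date = min(.data$date), .groups = "drop") |>
    dplyr::filter(.data$n_days >= min_days)
  bd <- tibble::tibble(patient_id = as.character(birth_dates$patient_id),
                       birth_date = as.Date(birth_dates$birth_date))
  per <- dplyr::left_join(per, bd, by = "patient_id")
  no_bd <- per$patient_id[is.na(per$birth_date)]
  if (length(no_bd) > 0) {
    rlang::warn(paste0("excluding ", length(no_bd),
                       " patient(s) with qualifying codes but no birth date: ",
                       paste(utils::head(no_bd, 10), collapse = ", ")))
    per <- per[!is.na(per$birth_date), , drop = FALSE]
  }
  per$age_at_first_dx <- age_at(per$birth_date, per$first_dx_date)
  per <- per[per$age_at_first_dx >= min_age, , drop = FALSE]
  per |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::select("patient_id", "first_dx_date", "age_at_first_dx")
}
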