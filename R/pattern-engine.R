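# The four-stage match pipeline: core expression -> opioid-context filter ->
# negation exclusion -> false-positive prefix exclusion. All character
# offsets in the public interface are 0-based half-open into the note text.

.abbrev_stoplist <- c("dr", "mr", "mrs", "ms", "jr", "sr", "st", "vs",
                      "mg", "mcg", "ml", "tab", "approx", "e.g", "i.e")

#' Segment note text into sentence spans
#'
#' Rule-based splitter: sentences end at runs of `.`, `!` or `?` followed by
#' whitespace (unless the preceding token is a common clinical abbreviation
#' such as `mg.` or `Dr.`) and at newline runs. Spans are trimmed of
#' surrounding whitespace and returned as 0-based half-open character
#' offsets that partition the non-whitespace text in order.
#'
#' @param text A single character string (may be empty).
#' @return A tibble with integer columns `start`, `end` (0-based half-open).
#' @export
segment_sentences <- function(text) {
  stopifnot(length(text) == 1)
  empty <- tibble::tibble(start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)

  breaks <- integer() # 1-based index of last char of each terminator run
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      before <- substr(text, 1, m[i] - 1)
      tok <- stringr::str_to_lower(
        stringr::str_extract(before, "[A-Za-z][A-Za-z.]*$") %||% "")
      punct <- substr(text, m[i], m[i] + len[i] - 1)
      if (punct == "." && !is.na(tok) && tok %in% .abbrev_stoplist) next
      breaks <- c(breaks, m[i] + len[i] - 1)
    }
  }
  m2 <- gregexpr("\\n+", text)[[1]]
  if (m2[1] != -1) {
    breaks <- c(breaks, m2 + attr(m2, "match.length") - 1)
  }
  breaks <- sort(unique(c(breaks, n)))

  out <- list()
  seg_start <- 1
  for (b in breaks) {
    seg <- substr(text, seg_start, b)
    loc <- stringr::str_locate(seg, "^\\s*")
    lead <- loc[1, 2]
    if (is.na(lead)) lead <- 0
    trail <- nchar(seg) - nchar(stringr::str_trim(seg, side = "right"))
    s1 <- seg_start + lead          # 1-based first non-ws char
    e1 <- b - trail                 # 1-based last non-ws char
    if (s1 <= e1) out[[length(out) + 1]] <- c(s1 - 1L, e1)  # 0-based half-open
    seg_start <- b + 1
  }
  if (length(out) == 0) return(empty)
  mat <- do.call(rbind, out)
  tibble::tibble(start = as.integer(mat[, 1]), end = as.integer(mat[, 2]))
}

# Left-anchored stem regex for context lexicon entries; whole-word/phrase
# regex for negation entries.
stem_pattern <- function(entries) {
  paste0("\\b(", paste(regex_escape(entries), collapse = "|"), ")")
}
word_pattern <- function(entries) {
  paste0("\\b(", paste(regex_escape(entries), collapse = "|"), ")\\b")
}

#' Opioid-context filter
#'
#' Tests whether a sentence carries opioid context for a core-expression
#' hit: some lexicon entry (term stem or drug name) occurs in the sentence;
#' under `order = "trigger_before_term"` the entry must begin at or after
#' the end of the trigger span (the "followed by" constraint).
#'
#' @param sentence Sentence text.
#' @param trigger_start,trigger_end 0-based half-open trigger span within
#'   `sentence`.
#' @param lexicon Character vector of opioid terms/drug-name stems.
#' @param order `"none"` or `"trigger_before_term"`.
#' @return Logical scalar.
#' @export
has_opioid_context <- function(sentence, trigger_start, trigger_end,
                               lexicon, order = c("none", "trigger_before_term")) {
  order <- match.arg(order)
  stopifnot(trigger_start >= 0, trigger_end <= nchar(sentence),
            trigger_start < trigger_end)
  pat <- stringr::regex(stem_pattern(lexicon), ignore_case = TRUE)
  loc <- stringr::str_locate_all(sentence, pat)[[1]]
  if (nrow(loc) == 0) return(FALSE)
  if (order == "none") return(TRUE)
  any(loc[, "start"] - 1L >= trigger_end)
}

#' Negation filter
#'
#' A hit is negated when a negation-lexicon entry occurs in the sentence
#' strictly before the start of the trigger span. Entries match as whole
#' words or phrases, so `"no"` does not fire inside `"noted"` and `"not"`
#' does not fire inside `"cannot"`.
#'
#' @inheritParams has_opioid_context
#' @param lexicon Character vector of negation terms.
#' @return Logical scalar.
#' @export
is_negated <- function(sentence, trigger_start, trigger_end, lexicon) {
  stopifnot(trigger_start >= 0, trigger_end <= nchar(sentence))
  if (length(lexicon) == 0) return(FALSE)
  pat <- stringr::regex(word_pattern(lexicon), ignore_case = TRUE)
  loc <- stringr::str_locate_all(sentence, pat)[[1]]
  if (nrow(loc) == 0) return(FALSE)
  any(loc[, "start"] - 1L < trigger_start)
}

#' False-positive prefix exclusion
#'
#' Drops a hit when any exclusion phrase (e.g. `"discharge instructions"`)
#' occurs anywhere in the note text before the trigger offset. The scan is
#' note-wide, not sentence-wide, because such phrases are section headers.
#'
#' @param note_text Full note text.
#' @param trigger_offset 0-based offset of the trigger start in the note.
#' @param prefixes Character vector of literal phrases (case-insensitive).
#' @return Logical scalar.
#' @export
is_excluded_by_prefix <- function(note_text, trigger_offset, prefixes) {
  stopifnot(trigger_offset >= 0, trigger_offset <= nchar(note_text))
  if (length(prefixes) == 0) return(FALSE)
  pat <- stringr::regex(paste(regex_escape(prefixes), collapse = "|"),
                        ignore_case = TRUE)
  loc <- stringr::str_locate_all(note_text, pat)[[1]]
  if (nrow(loc) == 0) return(FALSE)
  any(loc[, "start"] - 1L < trigger_offset)
}

#' Compile a pattern configuration into a matcher
#'
#' Precompiles all core expressions and lexicon patterns for repeated use
#' by [match_note()] / [match_notes()]. Matching is deterministic and
#' case-insensitive.
#'
#' @param config An `abc_pattern_config` (see [abc_patterns()],
#'   [load_pattern_config()]); a plain list is validated first.
#' @return An object of class `abc_matcher`.
#' @export
compile_patterns <- function(config = abc_patterns()) {
  if (!inherits(config, "abc_pattern_config")) {
    config <- validate_pattern_config(config)
  }
  ctx_lexicon <- c(config$lexicons$opioid_terms, config$lexicons$drug_names)
  matcher <- list(
    config = config,
    ctx_lexicon = ctx_lexicon,
    ctx_pattern = stringr::regex(stem_pattern(ctx_lexicon), ignore_case = TRUE),
    neg_lexicon = config$lexicons$negation_terms,
    neg_pattern = stringr::regex(word_pattern(config$lexicons$negation_terms),
                                 ignore_case = TRUE),
    items = lapply(config$items, function(it) {
      it$compiled <- lapply(it$core_expressions, function(e) {
        stringr::regex(e, ignore_case = TRUE)
      })
      it
    }),
    digest = attr(config, "digest")
  )
  class(matcher) <- "abc_matcher"
  matcher
}

#' Empty match table skeleton
#'
#' A zero-row match tibble with the canonical columns; useful for building
#' fixtures and for code paths with no hits.
#'
#' @return A zero-row match tibble.
#' @export
empty_match_tbl <- function() {
  tibble::tibble(patient_id = character(), note_id = character(),
                 item_id = integer(), start = integer(), end = integer(),
                 matched_text = character(), sentence_text = character(),
                 filters_passed = character())
}

#' Match one note against all ABC items
#'
#' Runs every core expression over each sentence of the note, then applies
#' the filter chain in order (opioid context, negation, prefix exclusion).
#' Each surviving hit is an auditable match: its span, matched and sentence
#' text, and a filter trail showing which stages applied. `matched_text`
#' always equals the note-text slice at the span.
#'
#' @param matcher An `abc_matcher` from [compile_patterns()].
#' @param note A one-row note tibble (or list) with `patient_id`, `note_id`,
#'   `text`.
#' @param keep_filtered Also return hits removed by a filter (trail shows
#'   the failing stage); default `FALSE` returns survivors only.
#' @return A match tibble with columns `patient_id`, `note_id`, `item_id`,
#'   `start`, `end` (0-based half-open), `matched_text`, `sentence_text`,
#'   `filters_passed`; sorted by position in the note then item.
#' @export
match_note <- function(matcher, note, keep_filtered = FALSE) {
  stopifnot(inherits(matcher, "abc_matcher"))
  text <- note$text
  if (is.na(text) || !nzchar(text)) return(empty_match_tbl())
  sents <- segment_sentences(text)
  if (nrow(sents) == 0) return(empty_match_tbl())
  sent_txt <- substring(text, sents$start + 1L, sents$end)

  rows <- list()
  for (it in matcher$items) {
    for (pat in it$compiled) {
      locs <- stringr::str_locate_all(sent_txt, pat)
      for (si in seq_along(locs)) {
        loc <- locs[[si]]
        if (nrow(loc) == 0) next
        for (hi in seq_len(nrow(loc))) {
          # offsets relative to sentence, 0-based half-open
          ts <- loc[hi, "start"] - 1L
          te <- loc[hi, "end"]
          trail <- c(core = "pass", opioid_context = "skip",
                     negation = "skip", exclusion = "skip")
          ok <- TRUE
          if (it$require_opioid_context) {
            pass <- has_opioid_context(sent_txt[si], ts, te,
                                       matcher$ctx_lexicon,
                                       it$opioid_order_constraint)
            trail["opioid_context"] <- if (pass) "pass" else "fail"
            ok <- pass
          }
          if (ok && it$negation_enabled) {
            neg <- is_negated(sent_txt[si], ts, te, matcher$neg_lexicon)
            trail["negation"] <- if (neg) "fail" else "pass"
            ok <- !neg
          } else if (!ok) trail["negation"] <- "not_run"
          note_start <- sents$start[si] + ts   # 0-based in note
          note_end <- sents$start[si] + te
          if (ok && length(it$exclusion_prefixes) > 0) {
            excl <- is_excluded_by_prefix(text, note_start, it$exclusion_prefixes)
            trail["exclusion"] <- if (excl) "fail" else "pass"
            ok <- !excl
          } else if (!ok && length(it$exclusion_prefixes) > 0) {
            trail["exclusion"] <- "not_run"
          }
          if (ok || keep_filtered) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              patient_id = note$patient_id, note_id = note$note_id,
              item_id = it$item_id,
              start = as.integer(note_start), end = as.integer(note_end),
              matched_text = substring(text, note_start + 1L, note_end),
              sentence_text = sent_txt[si],
              filters_passed = paste(names(trail), trail, sep = "=",
                                     collapse = ";"),
              survived = ok
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_match_tbl())
  out <- dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$note_id, .data$item_id, .data$start, .data$end,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$start, .data$item_id)
  if (!keep_filtered) out$survived <- NULL else names(out)[names(out) == "survived"] <- "survived"
  out
}

#' Match a note corpus
#'
#' Applies [match_note()] to every row of a note tibble and binds the
#' results.
#'
#' @inheritParams match_note
#' @param notes Note tibble ([read_notes()] or [simulate_corpus()]).
#' @param quiet Suppress the per-corpus match-count message.
#' @return A match tibble (see [match_note()]).
#' @export
match_notes <- function(matcher, notes, keep_filtered = FALSE, quiet = TRUE) {
  if (nrow(notes) == 0) return(empty_match_tbl())
  res <- lapply(seq_len(nrow(notes)), function(i) {
    match_note(matcher, notes[i, ], keep_filtered = keep_filtered)
  })
  out <- dplyr::bind_rows(res)
  if (!quiet) {
    rlang::inform(paste0("matched ", nrow(out), " hits across ",
                         nrow(notes), " notes"))
  }
  out
}
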