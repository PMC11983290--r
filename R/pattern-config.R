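#' Load a pattern configuration
#'
#' Reads and validates a YAML (or JSON) pattern configuration: the three
#' lexicons (`opioid_terms`, `drug_names`, `negation_terms`) and one entry
#' per ABC item with its core expressions and filter chain. The opioid
#' context lexicon used at match time is the union of `opioid_terms` and
#' `drug_names`.
#'
#' @param path Path to the configuration file. YAML unless the extension is
#'   `.json`.
#' @return A validated config list of class `abc_pattern_config`, with a
#'   provenance `digest` attribute recorded in downstream outputs.
#' @seealso [abc_patterns()] for the packaged default.
#' @export
load_pattern_config <- function(path) {
  if (!file.exists(path)) abort_input(paste0("pattern config not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_pattern_config(cfg)
}

#' Default ABC pattern configuration
#'
#' The packaged default: 20 items with 27 core expressions, a stem-based
#' opioid lexicon (with its documented intentional misspellings), a
#' drug-name list and a 7-term negation lexicon. The published instrument's
#' exact lexicons and expressions are not public, so this set is a
#' reconstruction intended for testing, simulation and as a starting point
#' for site-specific tuning.
#'
#' @return A validated `abc_pattern_config` list.
#' @export
abc_patterns <- function() {
  load_pattern_config(system.file("extdata", "abc_patterns.yaml",
                                  package = "abcscore", mustWork = TRUE))
}

#' Validate a pattern configuration list
#'
#' Checks the schema, compiles every expression, enforces the invariant
#' that an opioid order constraint requires the opioid-context filter, and
#' deduplicates (with a warning) repeated core expressions or case-folded
#' lexicon entries.
#'
#' @param cfg A list with `lexicons` and `items` as described in
#'   [load_pattern_config()].
#' @return The normalized config, classed `abc_pattern_config`.
#' @export
validate_pattern_config <- function(cfg) {
  if (!is.list(cfg) || is.null(cfg$lexicons) || is.null(cfg$items)) {
    abort_schema("pattern config must have top-level 'lexicons' and 'items'")
  }
  lex <- cfg$lexicons
  for (nm in c("opioid_terms", "negation_terms")) {
    if (is.null(lex[[nm]]) || length(lex[[nm]]) == 0) {
      abort_schema(paste0("lexicon '", nm, "' must be present and non-empty"))
    }
  }
  lex$drug_names <- as.character(lex$drug_names %||% character())
  for (nm in c("opioid_terms", "drug_names", "negation_terms")) {
    entries <- stringr::str_trim(as.character(lex[[nm]]))
    if (any(!nzchar(entries))) {
      abort_schema(paste0("lexicon '", nm, "' contains an empty entry"))
    }
    folded <- stringr::str_to_lower(entries)
    if (anyDuplicated(folded)) {
      rlang::warn(paste0("lexicon '", nm, "': dropping duplicate entries"))
      entries <- entries[!duplicated(folded)]
    }
    lex[[nm]] <- entries
  }

  items <- lapply(cfg$items, normalize_item_spec)
  ids <- vapply(items, function(it) it$item_id, integer(1))
  if (anyDuplicated(ids)) {
    abort_schema(paste0("duplicate item_id: ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  items <- items[order(ids)]

  out <- list(lexicons = lex, items = items)
  attr(out, "digest") <- content_digest(out)
  class(out) <- "abc_pattern_config"
  out
}

normalize_item_spec <- function(it) {
  if (is.null(it$item_id)) abort_schema("item spec missing item_id")
  id <- as.integer(it$item_id)
  if (is.na(id) || id < 1 || id > 20) {
    abort_schema(paste0("item_id must be in 1..20, got: ", it$item_id))
  }
  core <- as.character(unlist(it$core_expressions %||% character()))
  if (length(core) == 0) {
    abort_schema(paste0("item ", id, ": core_expressions must be non-empty"))
  }
  for (k in seq_along(core)) {
    ok <- tryCatch({
      stringr::str_detect("", stringr::regex(core[k], ignore_case = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      abort_schema(paste0("item ", id, ": core expression ", k,
                          " does not compile: ", core[k]))
    }
  }
  if (anyDuplicated(core)) {
    rlang::warn(paste0("item ", id, ": dropping duplicate core expressions"))
    core <- unique(core)
  }
  order_c <- as.character(it$opioid_order_constraint %||% "none")
  if (!order_c %in% c("none", "trigger_before_term")) {
    abort_schema(paste0("item ", id, ": bad opioid_order_constraint '", order_c, "'"))
  }
  req_ctx <- isTRUE(it$require_opioid_context)
  if (order_c != "none" && !req_ctx) {
    abort_schema(paste0("item ", id,
                        ": opioid_order_constraint requires require_opioid_context"))
  }
  list(
    item_id = id,
    label = as.character(it$label %||% paste("ABC item", id)),
    core_expressions = core,
    require_opioid_context = req_ctx,
    opioid_order_constraint = order_c,
    negation_enabled = isTRUE(it$negation_enabled %||% TRUE),
    exclusion_prefixes = as.character(unlist(it$exclusion_prefixes %||% character()))
  )
}

#' @export
print.abc_pattern_config <- function(x, ...) {
  n_expr <- sum(vapply(x$items, function(it) length(it$core_expressions), integer(1)))
  cat("ABC pattern configuration\n")
  cat("  items:              ", length(x$items), " (", n_expr, " core expressions)\n", sep = "")
  cat("  opioid lexicon:     ", length(x$lexicons$opioid_terms), " terms + ",
      length(x$lexicons$drug_names), " drug names\n", sep = "")
  cat("  negation lexicon:   ", length(x$lexicons$negation_terms), " terms\n", sep = "")
  cat("  digest:             ", attr(x, "digest"), "\n", sep = "")
  invisible(x)
}
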