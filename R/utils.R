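# Internal helpers shared across modules.

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "abcscore_schema_error", ...)
}

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "abcscore_input_error", ...)
}

#' @noRd
`%||%` <- rlang::`%||%`

# Parse note timestamps: ISO 8601 datetime or bare date (date-only precision
# is admitted; validation-site cutoff logic needs only dates). Returned as
# timezone-naive-by-convention POSIXct in UTC.
parse_note_datetime <- function(x) {
  x <- stringr::str_trim(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = fmt)
  }
  out
}

parse_iso_date <- function(x) {
  as.Date(stringr::str_trim(as.character(x)), format = "%Y-%m-%d")
}

# Completed years between two dates (birthday-aware).
age_at <- function(birth_date, at_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ay <- as.integer(format(at_date, "%Y"))
  bmd <- format(birth_date, "%m-%d")
  amd <- format(at_date, "%m-%d")
  ay - by - as.integer(amd < bmd)
}

# Escape a literal phrase for use inside a regular expression.
regex_escape <- function(x) {
  stringr::str_replace_all(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
}

# Stable content digest for provenance manifests.
content_digest <- function(x) rlang::hash(x)

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
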