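# Evaluation battery: confusion metrics with bootstrap CIs, rank AUC,
# recall-precision curves, pairwise phi coefficients, ICD baselines and
# score-stratified prevalence tables. Undefined metrics (zero denominators)
# propagate as NA, never as 0.

#' Confusion counts of a binary predictor against binary labels
#'
#' Both inputs are named logical vectors (names = patient ids); the two
#' patient sets must match exactly, otherwise the symmetric difference is
#' reported. Unnamed vectors of equal length are paired positionally.
#'
#' @param predicted Named logical vector of predictions.
#' @param labels Named logical vector of reference labels.
#' @return Named integer vector `c(tp, fp, tn, fn)` of class
#'   `abc_confusion`.
#' @export
confusion_counts <- function(predicted, labels) {
  if (length(predicted) == 0 || length(labels) == 0) {
    abort_input("confusion_counts needs at least one patient")
  }
  if (!is.null(names(predicted)) && !is.null(names(labels))) {
    only_p <- setdiff(names(predicted), names(labels))
    only_l <- setdiff(names(labels), names(predicted))
    if (length(only_p) > 0 || length(only_l) > 0) {
      abort_input(paste0(
        "patient sets differ; only in predictions: [",
        paste(utils::head(only_p, 10), collapse = ", "),
        "], only in labels: [",
        paste(utils::head(only_l, 10), collapse = ", "), "]"))
    }
    labels <- labels[names(predicted)]
  } else if (length(predicted) != length(labels)) {
    abort_input("unnamed prediction/label vectors must have equal length")
  }
  confusion_from_logical(as.logical(predicted), as.logical(labels))
}

confusion_from_logical <- function(pred, lab) {
  cc <- c(tp = sum(pred & lab), fp = sum(pred & !lab),
          tn = sum(!pred & !lab), fn = sum(!pred & lab))
  cc <- vapply(cc, as.integer, integer(1))
  class(cc) <- c("abc_confusion", class(cc))
  cc
}

# Point metrics from counts; zero denominators yield NA.
metric_point <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens)) {
    if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  } else NA_real_
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

#' Classification metrics with optional bootstrap confidence intervals
#'
#' Sensitivity (recall), specificity, positive and negative predictive
#' value, and F1 (the harmonic mean of PPV and sensitivity) from confusion
#' counts. A metric whose denominator is zero is reported as `NA`. The
#' optional CI is a nonparametric patient-level percentile bootstrap over
#' the 2x2 table's underlying patient multiset.
#'
#' @param cc Confusion counts from [confusion_counts()] (or a named vector
#'   with `tp`, `fp`, `tn`, `fn`).
#' @param ci `"none"` or `"bootstrap"`.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return A tibble with one row per metric: `metric`, `estimate`, and when
#'   bootstrapped `ci_low`, `ci_high`, plus `ci_method`, `B`, `seed`
#'   attributes.
#' @export
classification_metrics <- function(cc, ci = c("none", "bootstrap"),
                                   B = 2000, seed = 1) {
  ci <- match.arg(ci)
  n <- sum(cc[c("tp", "fp", "tn", "fn")])
  if (n == 0) abort_input("all-zero confusion counts")
  est <- metric_point(cc)
  out <- tibble::tibble(metric = names(est), estimate = unname(est))
  if (ci == "bootstrap") {
    stopifnot(B >= 100)
    pred <- rep(c(TRUE, TRUE, FALSE, FALSE), cc[c("tp", "fp", "tn", "fn")])
    lab <- rep(c(TRUE, FALSE, FALSE, TRUE), cc[c("tp", "fp", "tn", "fn")])
    bounds <- lapply(names(est), function(m) {
      b <- bootstrap_ci(function(idx) {
        metric_point(confusion_from_logical(pred[idx], lab[idx]))[[m]]
      }, n = n, B = B, seed = seed)
      tibble::tibble(ci_low = b[["low"]], ci_high = b[["high"]])
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(bounds))
    attr(out, "ci_method") <- "patient-level percentile bootstrap"
    attr(out, "B") <- B
    attr(out, "seed") <- seed
  }
  out
}

#' Rank AUC of a binary predictor
#'
#' For a binary score the tie-corrected rank AUC collapses exactly to
#' `(sensitivity + specificity) / 2`.
#'
#' @param cc Confusion counts of the binary predictor.
#' @return AUC as a proportion.
#' @export
binary_predictor_auc <- function(cc) {
  if (cc[["tp"]] + cc[["fn"]] == 0) abort_input("no cases")
  if (cc[["tn"]] + cc[["fp"]] == 0) abort_input("no controls")
  ms <- metric_point(cc)
  unname((ms["sensitivity"] + ms["specificity"]) / 2)
}

#' Rank (Mann-Whitney) AUC of an ordinal score
#'
#' The probability that a random case outscores a random control, counting
#' ties as one half — the tie-corrected rank statistic. The returned curve
#' enumerates every achievable threshold (each unique score, plus one above
#' the maximum) rather than interpolating, which is exact for integer
#' scores.
#'
#' @param scores Numeric (typically integer 0-20) score per patient.
#' @param labels Logical case indicator per patient.
#' @param ci `"none"` or `"bootstrap"` (patient-level percentile bootstrap).
#' @param B,seed Bootstrap resamples and seed.
#' @return A list of class `abc_curve`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `kind = "roc"`, and optionally `ci_low`,
#'   `ci_high`.
#' @export
roc_auc <- function(scores, labels, ci = c("none", "bootstrap"),
                    B = 2000, seed = 1) {
  ci <- match.arg(ci)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) abort_input("need both cases and controls")
  auc <- rank_auc(scores, labels)
  thresholds <- sort(unique(c(scores, max(scores) + 1)))
  pts <- lapply(thresholds, function(tau) {
    cc <- confusion_from_logical(scores >= tau, labels)
    ms <- metric_point(cc)
    tibble::tibble(threshold = tau, fpr = 1 - ms[["specificity"]],
                   tpr = ms[["sensitivity"]])
  })
  out <- list(points = dplyr::bind_rows(pts) |> dplyr::arrange(.data$fpr, .data$tpr),
              auc = auc, kind = "roc")
  if (ci == "bootstrap") {
    b <- bootstrap_ci(function(idx) {
      l <- labels[idx]
      if (length(unique(l)) < 2) return(NA_real_)
      rank_auc(scores[idx], l)
    }, n = length(scores), B = B, seed = seed)
    out$ci_low <- b[["low"]]
    out$ci_high <- b[["high"]]
  }
  class(out) <- "abc_curve"
  out
}

rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores) # midranks handle ties (+1/2 per tied pair)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Recall-precision curve
#'
#' One operating point per achievable threshold; recall is non-increasing
#' as the threshold rises. Points with undefined precision (no positive
#' calls) are omitted rather than imputed.
#'
#' @inheritParams roc_auc
#' @return An `abc_curve` list: `points` (tibble `threshold`, `recall`,
#'   `precision`), `auc` (average precision by step integration over
#'   recall), `kind = "precision_recall"`.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0) abort_input("need at least one case")
  thresholds <- sort(unique(c(scores, max(scores) + 1)))
  pts <- lapply(thresholds, function(tau) {
    cc <- confusion_from_logical(scores >= tau, labels)
    ms <- metric_point(cc)
    tibble::tibble(threshold = tau, recall = ms[["sensitivity"]],
                   precision = ms[["ppv"]])
  })
  pts <- dplyr::bind_rows(pts)
  pts <- pts[!is.na(pts$precision), , drop = FALSE]
  # average precision: sum precision * step-down in recall, high->low threshold
  pts <- dplyr::arrange(pts, dplyr::desc(.data$threshold))
  ap <- sum(diff(c(0, pts$recall)) * pts$precision)
  out <- list(points = pts, auc = ap, kind = "precision_recall")
  class(out) <- "abc_curve"
  out
}

#' @export
print.abc_curve <- function(x, ...) {
  cat(if (x$kind == "roc") "ROC curve" else "Recall-precision curve",
      sprintf(" (%d points), AUC = %.3f\n", nrow(x$points), x$auc), sep = "")
  if (!is.null(x$ci_low)) {
    cat(sprintf("  95%% CI: %.3f-%.3f\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Pairwise phi coefficients between ABC items
#'
#' The phi coefficient of two binary items is their Pearson correlation,
#' computed here from the 2x2 cell counts:
#' `(n11 n00 - n10 n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))`.
#' Items with zero variance produce flagged-undefined (`NA`) cells rather
#' than an imputed value.
#'
#' @param item_flags A 0/1 matrix (patients x items) or a score tibble from
#'   [score_patients()] (its `item_01..item_20` columns are used).
#' @return A symmetric numeric matrix of class `abc_phi` with `NA` for
#'   undefined cells and an `undefined_items` attribute naming
#'   zero-variance items.
#' @export
phi_matrix <- function(item_flags) {
  if (is.data.frame(item_flags)) {
    cols <- intersect(item_cols(), names(item_flags))
    if (length(cols) == 0) abort_schema("no item_01..item_20 columns found")
    item_flags <- as.matrix(item_flags[cols])
  }
  x <- matrix(as.numeric(item_flags), nrow = nrow(item_flags),
              dimnames = dimnames(item_flags))
  if (nrow(x) < 2) abort_input("phi_matrix needs at least 2 patients")
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  varies <- apply(x, 2, function(v) length(unique(v)) > 1)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (!varies[i] || !varies[j]) next
      n11 <- sum(x[, i] == 1 & x[, j] == 1)
      n10 <- sum(x[, i] == 1 & x[, j] == 0)
      n01 <- sum(x[, i] == 0 & x[, j] == 1)
      n00 <- sum(x[, i] == 0 & x[, j] == 0)
      denom <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
      out[i, j] <- out[j, i] <- (n11 * n00 - n10 * n01) / denom
    }
  }
  attr(out, "undefined_items") <- colnames(x)[!varies]
  class(out) <- c("abc_phi", class(out))
  out
}

#' ICD-code baseline indicator
#'
#' The diagnostic-code comparator: a patient is positive when codes from
#' `codes` occur on at least `min_days` distinct calendar dates (the same
#' distinct-day logic as the cohort builder).
#'
#' @param diagnoses Diagnosis tibble.
#' @param codes Character vector of (e.g. OUD) ICD codes.
#' @param min_days Minimum distinct dates (default 2).
#' @param patients Optional patient universe; patients without records are
#'   negative.
#' @return A tibble with `patient_id`, `icd_positive` (logical).
#' @export
icd_baseline <- function(diagnoses, codes, min_days = 2, patients = NULL) {
  if (length(codes) == 0) abort_input("code set must be non-empty")
  codes <- stringr::str_to_upper(stringr::str_trim(codes))
  universe <- sort(unique(c(as.character(diagnoses$patient_id),
                            as.character(patients %||% character()))))
  qual <- diagnoses[diagnoses$code %in% codes, , drop = FALSE]
  pos <- if (nrow(qual) == 0) character() else {
    per <- qual |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(n_days = dplyr::n_distinct(.data$date), .groups = "drop")
    per$patient_id[per$n_days >= min_days]
  }
  tibble::tibble(patient_id = universe, icd_positive = universe %in% pos)
}

#' Prevalence of an ICD indicator stratified by total ABC score
#'
#' One row per observed total score with the stratum size and the count and
#' percentage (1 decimal place) of ICD-positive patients — the
#' score-gradient report.
#'
#' @param scores Score tibble from [score_patients()].
#' @param diagnoses Diagnosis tibble.
#' @param codes ICD codes defining the indicator.
#' @param min_days Minimum distinct dates (default 2).
#' @return A tibble with `score`, `n`, `n_icd_positive`, `pct_icd_positive`.
#' @export
stratify_by_score <- function(scores, diagnoses, codes, min_days = 2) {
  if (nrow(scores) == 0) {
    return(tibble::tibble(score = integer(), n = integer(),
                          n_icd_positive = integer(),
                          pct_icd_positive = numeric()))
  }
  icd <- icd_baseline(diagnoses, codes, min_days, patients = scores$patient_id)
  df <- dplyr::left_join(scores, icd, by = "patient_id")
  df |>
    dplyr::group_by(score = .data$total_score) |>
    dplyr::summarise(n = dplyr::n(),
                     n_icd_positive = sum(.data$icd_positive),
                     .groups = "drop") |>
    dplyr::mutate(pct_icd_positive = round(100 * .data$n_icd_positive / .data$n, 1)) |>
    dplyr::arrange(.data$score)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric patient-level bootstrap: `B` resamples of indices
#' `1..n` with replacement, the statistic evaluated on each, and the
#' 2.5/97.5 percentiles returned. Deterministic given `seed` (the caller's
#' RNG state is preserved). Resamples on which the statistic is undefined
#' (`NA`) are redrawn; the redraw count is recorded.
#'
#' @param statistic Function of an integer index vector returning a scalar.
#' @param n Number of patients to resample from.
#' @param B Number of resamples (minimum 100, default 2000).
#' @param seed Integer RNG seed (mandatory).
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic, n, B = 2000, seed, level = 0.95) {
  stopifnot(B >= 100, n >= 1)
  if (missing(seed)) abort_input("bootstrap_ci requires an explicit seed")
  stats_out <- numeric(B)
  n_redrawn <- 0L
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      val <- NA_real_
      tries <- 0L
      while (is.na(val) && tries < 100L) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- statistic(idx)
        tries <- tries + 1L
      }
      n_redrawn <- n_redrawn + (tries - 1L)
      stats_out[b] <- val
    }
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(stats_out, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  out <- c(low = qs[1], high = qs[2])
  attr(out, "n_redrawn") <- n_redrawn
  out
}
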