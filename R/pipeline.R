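# End-to-end orchestration: match -> score -> classify -> (evaluate), with
# a provenance manifest. The same functions back the exec/abc-autoscore
# command-line wrapper.

#' Run the full scoring (and optional evaluation) pipeline
#'
#' Matches every note against the pattern set, aggregates patient-level ABC
#' scores, classifies at the threshold, and — when adjudication labels are
#' supplied — computes the evaluation battery (confusion metrics with
#' bootstrap CIs, rank AUC, recall-precision curve, phi matrix, and, with
#' diagnoses, the ICD baseline and score-stratified prevalence). Per-stage
#' counts go to the message stream; outputs are reproducible byte-for-byte
#' given identical inputs and seed.
#'
#' @param notes Note tibble.
#' @param patterns An `abc_pattern_config` (default: packaged set).
#' @param labels Optional label tibble (`patient_id`, `binary_label`).
#' @param diagnoses Optional diagnosis tibble for the ICD comparator.
#' @param oud_codes ICD codes for the comparator (default
#'   [default_oud_codes()]).
#' @param threshold Score threshold for the binary ABC indicator
#'   (default 2).
#' @param cutoff_date Optional consent-style date cutoff for scoring.
#' @param patients Optional patient universe beyond note-bearing patients.
#' @param bootstrap_B Bootstrap resamples for CIs (default 2000).
#' @param seed Seed for bootstrap resampling (default 7).
#' @param out_dir Optional directory; when given, writes `matches.csv`,
#'   `scores.csv`, `classifications.csv`, `metrics.json`, curve/phi CSVs
#'   and `manifest.json`.
#' @param quiet Suppress per-stage messages.
#' @return A list with `matches`, `scores`, `classified`, `manifest`, and
#'   when labels are given `evaluation` (metrics tibble, curves, phi,
#'   optional ICD comparison).
#' @export
run_pipeline <- function(notes, patterns = abc_patterns(), labels = NULL,
                         diagnoses = NULL, oud_codes = default_oud_codes(),
                         threshold = 2, cutoff_date = NULL, patients = NULL,
                         bootstrap_B = 2000, seed = 7, out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) rlang::inform(paste0(...))
  matcher <- compile_patterns(patterns)
  say("stage match: ", nrow(notes), " notes against ",
      length(matcher$items), " items")
  matches <- match_notes(matcher, notes)
  say("stage match: ", nrow(matches), " surviving matches")

  scores <- score_patients(matches, notes, cutoff_date = cutoff_date,
                           patients = patients)
  say("stage score: ", nrow(scores), " patients scored (",
      sum(scores$no_notes_flag), " without notes)")
  classified <- classify_patients(scores, threshold)

  evaluation <- NULL
  if (!is.null(labels)) {
    ev <- align_scores_labels(classified, labels)
    pred <- stats::setNames(ev$abc_positive, ev$patient_id)
    lab <- stats::setNames(ev$label, ev$patient_id)
    cc <- confusion_counts(pred, lab)
    metrics <- classification_metrics(cc, ci = "bootstrap", B = bootstrap_B,
                                      seed = seed)
    roc <- roc_auc(ev$total_score, ev$label, ci = "bootstrap",
                   B = bootstrap_B, seed = seed)
    pr <- precision_recall_curve(ev$total_score, ev$label)
    phi <- phi_matrix(ev)
    evaluation <- list(confusion = cc, metrics = metrics, roc = roc,
                       pr = pr, phi = phi, threshold = threshold,
                       n_evaluated = nrow(ev))
    say("stage evaluate: n=", nrow(ev), ", F1=",
        round(metrics$estimate[metrics$metric == "f1"], 3),
        ", AUC=", round(roc$auc, 3))
    if (!is.null(diagnoses)) {
      icd <- icd_baseline(diagnoses, oud_codes, patients = ev$patient_id)
      icd <- icd[match(ev$patient_id, icd$patient_id), ]
      icd_cc <- confusion_counts(stats::setNames(icd$icd_positive, ev$patient_id), lab)
      evaluation$icd <- list(
        confusion = icd_cc,
        metrics = classification_metrics(icd_cc, ci = "bootstrap",
                                         B = bootstrap_B, seed = seed),
        auc = binary_predictor_auc(icd_cc),
        stratified = stratify_by_score(scores, diagnoses, oud_codes))
      say("stage evaluate: ICD baseline AUC=",
          round(evaluation$icd$auc, 3))
    }
  } else {
    say("stage evaluate: skipped (no labels supplied)")
  }

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    tool_version = as.character(utils::packageVersion("abcscore")),
    pattern_digest = attr(matcher$config, "digest"),
    input_digests = list(notes = content_digest(notes),
                         labels = if (!is.null(labels)) content_digest(labels),
                         diagnoses = if (!is.null(diagnoses)) content_digest(diagnoses)),
    threshold = threshold,
    cutoff_date = if (!is.null(cutoff_date)) as.character(cutoff_date),
    bootstrap_B = if (!is.null(labels)) bootstrap_B,
    seed = if (!is.null(labels)) seed
  )

  result <- list(matches = matches, scores = scores, classified = classified,
                 evaluation = evaluation, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$matches, file.path(out_dir, "matches.csv"))
  readr::write_csv(result$scores, file.path(out_dir, "scores.csv"))
  cls <- result$classified
  readr::write_csv(cls[c("patient_id", "total_score", "abc_positive")],
                   file.path(out_dir, "classifications.csv"))
  if (!is.null(result$evaluation)) {
    ev <- result$evaluation
    metrics_json <- list(
      threshold = ev$threshold,
      n_evaluated = ev$n_evaluated,
      confusion = as.list(unclass(ev$confusion)),
      metrics = ev$metrics,
      roc_auc = ev$roc$auc,
      roc_auc_ci = c(ev$roc$ci_low, ev$roc$ci_high),
      pr_auc = ev$pr$auc,
      ci_method = attr(ev$metrics, "ci_method"),
      B = attr(ev$metrics, "B"),
      seed = attr(ev$metrics, "seed")
    )
    if (!is.null(ev$icd)) {
      metrics_json$icd <- list(confusion = as.list(unclass(ev$icd$confusion)),
                               metrics = ev$icd$metrics, auc = ev$icd$auc)
      readr::write_csv(ev$icd$stratified,
                       file.path(out_dir, "score_stratified_icd.csv"))
    }
    jsonlite::write_json(metrics_json, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
    readr::write_csv(ev$roc$points, file.path(out_dir, "roc_points.csv"))
    readr::write_csv(ev$pr$points, file.path(out_dir, "pr_points.csv"))
    phi_df <- tibble::as_tibble(as.data.frame(unclass(ev$phi)), rownames = "item")
    readr::write_csv(phi_df, file.path(out_dir, "phi_matrix.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Plot an evaluation curve
#'
#' Simple ggplot2 rendering of an `abc_curve` (ROC or recall-precision).
#'
#' @param curve An `abc_curve` from [roc_auc()] or
#'   [precision_recall_curve()].
#' @return A ggplot object.
#' @export
plot_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_input("plot_curve requires the ggplot2 package")
  }
  if (curve$kind == "roc") {
    ggplot2::ggplot(curve$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::labs(x = "False-positive rate", y = "Sensitivity (recall)",
                    title = sprintf("ROC, AUC = %.2f", curve$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curve$points, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Sensitivity (recall)", y = "PPV (precision)",
                    title = sprintf("Recall-precision, AP = %.2f", curve$auc)) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
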