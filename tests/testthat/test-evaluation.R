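test_that("confusion counts partition the patient set", {
  pred <- stats::setNames(rep(c(TRUE, FALSE), each = 5), sprintf("p%d", 1:10))
  cc <- confusion_counts(pred, pred)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               c(tp = 5L, fp = 0L, tn = 5L, fn = 0L))
  expect_equal(sum(cc), 10)
})

test_that("mismatched patient sets report the symmetric difference", {
  pred <- stats::setNames(c(TRUE, FALSE), c("a", "b"))
  lab <- stats::setNames(c(TRUE, FALSE), c("a", "c"))
  expect_error(confusion_counts(pred, lab), regexp = "b.*c")
  expect_error(confusion_counts(logical(), logical()),
               class = "abcscore_input_error")
})

test_that("the adjudication-strata contingency reproduces its 2x2 table", {
  av <- adjudication_vectors()
  cc <- confusion_counts(av$predicted, av$labels)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               c(tp = 2L, fp = 0L, tn = 49L, fn = 48L))
})

test_that("metrics follow their defining ratios, with NA for 0 denominators", {
  cc <- confusion_counts(stats::setNames(c(TRUE, TRUE, FALSE, FALSE),
                                         letters[1:4]),
                         stats::setNames(c(TRUE, FALSE, FALSE, TRUE),
                                         letters[1:4]))
  ms <- classification_metrics(cc)
  est <- stats::setNames(ms$estimate, ms$metric)
  expect_equal(est[["sensitivity"]], 0.5)
  expect_equal(est[["specificity"]], 0.5)
  expect_equal(est[["ppv"]], 0.5)
  expect_equal(est[["f1"]], 0.5)

  # perfect classifier
  perfect <- confusion_counts(stats::setNames(c(TRUE, FALSE), c("a", "b")),
                              stats::setNames(c(TRUE, FALSE), c("a", "b")))
  expect_true(all(classification_metrics(perfect)$estimate == 1))

  # no true positives but positives exist: F1 is 0, not NA
  cc0 <- c(tp = 0L, fp = 2L, tn = 3L, fn = 4L)
  est0 <- stats::setNames(classification_metrics(cc0)$estimate,
                          classification_metrics(cc0)$metric)
  expect_equal(est0[["f1"]], 0)

  # undefined metrics propagate as NA, never silently 0
  cc_nd <- c(tp = 0L, fp = 0L, tn = 3L, fn = 4L)
  est_nd <- stats::setNames(classification_metrics(cc_nd)$estimate,
                            classification_metrics(cc_nd)$metric)
  expect_true(is.na(est_nd[["ppv"]]))
  expect_true(is.na(est_nd[["f1"]]))

  expect_error(classification_metrics(c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)),
               class = "abcscore_input_error")
})

test_that("the F1 harmonic-mean identity holds exactly", {
  set.seed(9)
  for (r in 1:50) {
    cc <- c(tp = rpois(1, 5) + 1L, fp = rpois(1, 3), tn = rpois(1, 5) + 1L,
            fn = rpois(1, 3))
    ms <- classification_metrics(cc)
    est <- stats::setNames(ms$estimate, ms$metric)
    expect_equal(est[["f1"]] * (est[["ppv"]] + est[["sensitivity"]]),
                 2 * est[["ppv"]] * est[["sensitivity"]])
    expect_equal(est[["sensitivity"]] + cc[["fn"]] / (cc[["tp"]] + cc[["fn"]]), 1)
  }
})

test_that("a binary predictor's rank AUC is (sensitivity + specificity) / 2", {
  cc <- c(tp = 2L, fp = 0L, fn = 48L, tn = 49L)
  expect_equal(binary_predictor_auc(cc), (0.04 + 1) / 2)
  # random-equivalent: sens = 1 - spec
  cc_r <- c(tp = 30L, fn = 70L, fp = 30L, tn = 70L)
  expect_equal(binary_predictor_auc(cc_r), 0.5)
  perfect <- c(tp = 10L, fn = 0L, fp = 0L, tn = 10L)
  expect_equal(binary_predictor_auc(perfect), 1.0)
  expect_error(binary_predictor_auc(c(tp = 0L, fn = 0L, fp = 1L, tn = 1L)),
               regexp = "no cases")
})

test_that("rank AUC handles separation and pure ties", {
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), regexp = "cases and controls")
})

test_that("rank AUC equals the all-pairs counting oracle on random fixtures", {
  pair_auc <- function(scores, labels) {
    cs <- scores[labels]; ct <- scores[!labels]
    tot <- 0
    for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
  }
  set.seed(2024)
  for (r in 1:100) {
    n <- 40
    scores <- sample(0:12, n, replace = TRUE)
    labels <- runif(n) < 0.45
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, pair_auc(scores, labels))
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- sample(0:10, 80, replace = TRUE)
  labels <- runif(80) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("rank AUC is invariant under strictly monotone transforms", {
  set.seed(14)
  scores <- sample(0:20, 60, replace = TRUE)
  labels <- runif(60) < 0.5
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(scores^3 + 2, labels)$auc, base)
  expect_equal(roc_auc(exp(scores / 5), labels)$auc, base)
})

test_that("roc_auc on a 0/1 score equals the binary formula to machine precision", {
  set.seed(15)
  pred <- runif(100) < 0.3
  labels <- runif(100) < 0.5
  cc <- confusion_counts(pred, labels)
  expect_equal(roc_auc(as.integer(pred), labels)$auc, binary_predictor_auc(cc))
})

test_that("recall-precision points equal a brute-force confusion sweep", {
  set.seed(7)
  for (r in 1:100) {
    n <- 30
    scores <- sample(0:8, n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (sum(labels) == 0) next
    curve <- precision_recall_curve(scores, labels)
    for (i in seq_len(nrow(curve$points))) {
      tau <- curve$points$threshold[i]
      pred <- scores >= tau
      tp <- sum(pred & labels); fp <- sum(pred & !labels)
      fn <- sum(!pred & labels)
      expect_equal(curve$points$recall[i], tp / (tp + fn))
      expect_equal(curve$points$precision[i], tp / (tp + fp))
    }
    # recall non-increasing as threshold rises
    ord <- order(curve$points$threshold)
    expect_true(all(diff(curve$points$recall[ord]) <= 0))
  }
})

test_that("precision-undefined points are omitted, perfect separation reaches (1,1)", {
  scores <- c(5, 5, 0, 0)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  curve <- precision_recall_curve(scores, labels)
  expect_true(any(curve$points$recall == 1 & curve$points$precision == 1))
  expect_false(any(is.na(curve$points$precision)))
  expect_error(precision_recall_curve(c(1, 2), c(FALSE, FALSE)),
               regexp = "at least one case")
})

test_that("phi coefficients: identity, orthogonality, symmetry and bounds", {
  x <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
             c = c(1, 0, 1, 0), d = c(0, 0, 1, 1))
  phi <- phi_matrix(x)
  expect_equal(phi["a", "b"], 1.0)
  expect_equal(phi["a", "c"], 0.0)   # balanced orthogonal items
  expect_equal(phi["a", "d"], -1.0)
  expect_equal(unclass(phi), t(unclass(phi)))
  expect_true(all(abs(phi) <= 1, na.rm = TRUE))
})

test_that("phi equals the Pearson correlation oracle on random fixtures", {
  set.seed(123)
  for (r in 1:100) {
    x <- matrix(rbinom(50 * 6, 1, runif(6, 0.2, 0.8)), nrow = 50, byrow = TRUE)
    colnames(x) <- paste0("i", 1:6)
    phi <- unclass(phi_matrix(x))
    attr(phi, "undefined_items") <- NULL
    ref <- stats::cor(x)
    expect_equal(phi, ref, tolerance = 1e-12)
  }
})

test_that("zero-variance items yield flagged-undefined phi cells", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0))
  phi <- phi_matrix(x)
  expect_true(is.na(phi["a", "b"]))
  expect_true(is.na(phi["a", "a"]))
  expect_equal(phi["b", "b"], 1.0)
  expect_equal(attr(phi, "undefined_items"), "a")
})

test_that("phi accepts score tibbles and uses the item columns", {
  corpus <- simulate_corpus(sim_config(n_patients = 50, seed = 17))
  phi <- phi_matrix(corpus$truth)
  expect_equal(dim(unclass(phi)), c(20, 20))
})

test_that("ICD baseline requires distinct days, like the cohort rule", {
  dx <- dplyr::bind_rows(
    make_dx("one_day", "F11.20", c("2020-01-01", "2020-01-01")),
    make_dx("two_days", "F11.20", c("2020-01-01", "2020-02-01")),
    make_dx("other_code", "E11.9", c("2020-01-01", "2020-02-01")))
  base <- icd_baseline(dx, default_oud_codes(), patients = "no_records")
  got <- stats::setNames(base$icd_positive, base$patient_id)
  expect_false(got[["one_day"]])
  expect_true(got[["two_days"]])
  expect_false(got[["other_code"]])
  expect_false(got[["no_records"]])
})

test_that("score stratification matches a hand tally", {
  scores <- tibble::tibble(
    patient_id = sprintf("p%d", 1:6),
    total_score = c(0L, 0L, 2L, 2L, 2L, 5L),
    no_notes_flag = FALSE)
  dx <- dplyr::bind_rows(
    make_dx("p3", "F11.20", c("2020-01-01", "2020-02-01")),
    make_dx("p6", "304.00", c("2020-01-01", "2020-02-01")))
  tab <- stratify_by_score(scores, dx, default_oud_codes())
  expect_equal(tab$score, c(0L, 2L, 5L))
  expect_equal(tab$n, c(2L, 3L, 1L))
  expect_equal(tab$n_icd_positive, c(0L, 1L, 1L))
  expect_equal(tab$pct_icd_positive, c(0, 33.3, 100))

  empty <- stratify_by_score(scores[0, ], dx, default_oud_codes())
  expect_equal(nrow(empty), 0)
})

test_that("bootstrap CIs: zero width for constants, seed determinism", {
  b <- bootstrap_ci(function(idx) 0.42, n = 50, B = 200, seed = 4)
  expect_equal(unname(b[["high"]] - b[["low"]]), 0)
  stat <- function(idx) mean(idx <= 25)
  b1 <- bootstrap_ci(stat, n = 50, B = 200, seed = 4)
  b2 <- bootstrap_ci(stat, n = 50, B = 200, seed = 4)
  expect_identical(b1, b2)
  b3 <- bootstrap_ci(stat, n = 50, B = 200, seed = 5)
  expect_false(identical(unclass(b1), unclass(b3)))
  expect_error(bootstrap_ci(stat, n = 50, B = 200), regexp = "seed")
})

test_that("bootstrap resamples with undefined statistics are redrawn and counted", {
  stat <- function(idx) if (1 %in% idx) mean(idx) else NA_real_
  b <- bootstrap_ci(stat, n = 5, B = 100, seed = 2)
  expect_gte(attr(b, "n_redrawn"), 1)
  expect_false(any(is.na(b)))
})
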