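#' Stratified patient-wise k-fold splits
#'
#' Splits *patients* (never individual samples) into k folds: within each
#' class, patients are shuffled and dealt round-robin, so per-fold class
#' counts deviate by at most one patient from exact proportionality, and
#' every sample of a patient — a second slide, an RNA aliquot — lands on the
#' same side of every split. This is the leakage guard for multi-sample
#' cohorts.
#'
#' @param patient_ids Patient id per patient (unique).
#' @param labels Class label per patient.
#' @param k Number of folds (>= 2, at most the smallest class size).
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return List of k splits, each `list(fold, train_patients, test_patients)`.
#' @export
stratified_patientwise_kfold <- function(patient_ids, labels, k, seed = 1L) {
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  if (k < 2) stop("k must be >= 2 (k = 1 leaves no training data)")
  counts <- table(labels)
  if (k > min(counts)) {
    stop("k exceeds the size of the smallest class (", min(counts), ")")
  }
  set.seed(seed)
  fold <- stratified_fold_ids(labels, k)
  lapply(seq_len(k), function(f) {
    list(
      fold = f,
      train_patients = patient_ids[fold != f],
      test_patients = patient_ids[fold == f]
    )
  })
}

# Average precision (area under the precision-recall curve by the
# step-wise estimator): mean of precision at each positive, in decreasing
# score order.
average_precision <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  t <- truth[ord]
  if (sum(t) == 0) return(NA_real_)
  prec <- cumsum(t) / seq_along(t)
  sum(prec * t) / sum(t)
}

#' Classification metrics from per-class scores
#'
#' Computes accuracy, per-class precision/recall/F1 with weighted
#' (support-weighted) and macro averages, per-class one-vs-rest ROC AUC and
#' average precision (AUPRC) with macro averages, and the confusion matrix.
#' Predictions are the per-sample argmax of `scores` (ties to the first
#' class in order). A class absent from `y_true` has undefined AUC/AUPRC;
#' it is reported as `NA` and excluded from the macro averages with a
#' warning.
#'
#' @param y_true Character vector of true classes.
#' @param scores Matrix samples x classes (fused scores or probabilities);
#'   column order defines the class order.
#' @param classes Optional explicit class order (default: `colnames(scores)`).
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(y_true, scores, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(classes)) stop("class order required (colnames or `classes`)")
  stopifnot(length(y_true) == nrow(scores), ncol(scores) == length(classes))
  y_true <- as.character(y_true)
  pred <- classes[max.col(scores, ties.method = "first")]
  yf <- factor(y_true, levels = classes)
  pf <- factor(pred, levels = classes)
  cm <- table(truth = yf, predicted = pf)
  acc <- sum(diag(cm)) / sum(cm)

  support <- as.numeric(table(yf))
  prec <- rec <- f1 <- auc <- auprc <- stats::setNames(
    rep(NA_real_, length(classes)), classes
  )
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (support[i] > 0) tp / sum(cm[i, ]) else NA_real_
    f1[i] <- if (isTRUE(prec[i] + rec[i] > 0)) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else if (support[i] > 0) 0 else NA_real_
    if (support[i] > 0 && support[i] < length(y_true)) {
      truth_bin <- as.integer(y_true == classes[i])
      auc[i] <- as.numeric(pROC::auc(pROC::roc(
        truth_bin, scores[, i], quiet = TRUE, direction = "<",
        levels = c(0, 1)
      )))
      auprc[i] <- average_precision(truth_bin, scores[, i])
    }
  }
  if (anyNA(auc)) {
    warning("class(es) with undefined AUC excluded from macro averages: ",
            paste(classes[is.na(auc)], collapse = ", "), call. = FALSE)
  }
  present <- support > 0
  structure(
    list(
      accuracy = acc,
      f1_weighted = sum(f1[present] * support[present]) / sum(support),
      f1_macro = mean(f1[present]),
      precision = prec, recall = rec, f1 = f1,
      auc = auc, auc_macro = mean(auc, na.rm = TRUE),
      auprc = auprc, auprc_macro = mean(auprc, na.rm = TRUE),
      confusion = cm,
      n = length(y_true)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  acc=%.4f  F1w=%.4f  AUC=%.3f  AUPRC=%.3f\n",
    x$n, x$accuracy, x$f1_weighted, x$auc_macro, x$auprc_macro
  ))
  invisible(x)
}

#' Misclassification-rate reduction in percentage points
#'
#' The headline accounting for how many diagnoses the fusion rescues from a
#' single-modality model: `100 * (wrong_single - wrong_fusion) / total`,
#' rounded to one decimal. For instance 220 vs 60 misclassified out of 1856
#' gives 8.6 percentage points.
#'
#' @param misclassified_single,misclassified_fusion Misclassified sample
#'   counts for the single-modality and fusion models on the same samples.
#' @param total Total number of samples.
#' @return Reduction in percentage points, one decimal.
#' @export
error_rate_reduction <- function(misclassified_single, misclassified_fusion,
                                 total) {
  if (total <= 0) stop("total must be positive")
  if (misclassified_single < 0 || misclassified_fusion < 0 ||
      misclassified_single > total || misclassified_fusion > total) {
    stop("inconsistent counts: misclassified must be within [0, total]")
  }
  round(100 * (misclassified_single - misclassified_fusion) / total, 1)
}

#' Cross-validated per-modality probabilities
#'
#' Runs the full leakage-safe loop: for each stratified patient-wise fold
#' and each modality, an RBF SVM is fitted on the training patients present
#' in that modality (optionally after a feature-selection function applied
#' to the training split only) and produces class probabilities for both
#' splits. Samples missing a modality get exact all-zero rows.
#'
#' @param cohort A [generate_cohort()] result (or any object with the same
#'   shape).
#' @param k Folds (default 10).
#' @param seed Seed controlling fold assignment and inner grid-search folds.
#' @param svm A [svm_config()].
#' @param selector Optional `function(modality_matrix) -> feature names`
#'   applied per fold per modality on training data only; `NULL` keeps all
#'   features.
#' @return List of k folds, each with `train`/`test`
#'   [probability_table()]s, matching label vectors, and the fitted models.
#' @export
cv_modality_probabilities <- function(cohort, k = 10, seed = 1L,
                                      svm = svm_config(seed = seed),
                                      selector = NULL) {
  splits <- stratified_patientwise_kfold(
    cohort$patients$patient_id, cohort$patients$label, k, seed = seed
  )
  classes <- cohort$classes
  modalities <- cohort$modalities
  lab_of <- stats::setNames(cohort$patients$label, cohort$patients$patient_id)

  lapply(splits, function(sp) {
    make_pt <- function(ids) {
      arr <- array(0, dim = c(length(ids), length(modalities), length(classes)))
      for (j in seq_along(modalities)) {
        mm <- cohort$matrices[[modalities[j]]]
        tr_rows <- which(mm$patient_ids %in% sp$train_patients)
        mm_tr <- subset_modality(mm, tr_rows)
        if (!is.null(selector)) {
          feats <- selector(mm_tr)
          if (length(feats) == 0) feats <- mm_tr$feature_names  # keep all if screen empties
          mm_tr <- select_features(mm_tr, feats)
        }
        model <- fit_svm_modality(mm_tr, svm, classes = classes)
        rows <- match(ids, mm$patient_ids)
        have <- which(!is.na(rows))
        if (length(have)) {
          vals <- mm$values[rows[have], model$feature_names, drop = FALSE]
          arr[have, j, ] <- predict_modality_proba(model, vals)
        }
      }
      probability_table(arr, ids, classes, modalities)
    }
    list(
      fold = sp$fold,
      train = make_pt(sp$train_patients),
      test = make_pt(sp$test_patients),
      train_labels = unname(lab_of[sp$train_patients]),
      test_labels = unname(lab_of[sp$test_patients])
    )
  })
}

# Aggregate per-fold metric reports into mean (sd) rows.
aggregate_fold_metrics <- function(reports) {
  pull <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  data.frame(
    accuracy = mean(pull("accuracy")), accuracy_sd = stats::sd(pull("accuracy")),
    f1_weighted = mean(pull("f1_weighted")), f1_weighted_sd = stats::sd(pull("f1_weighted")),
    auc_macro = mean(pull("auc_macro"), na.rm = TRUE),
    auprc_macro = mean(pull("auprc_macro"), na.rm = TRUE)
  )
}

#' Sweep fusion performance over modality subsets
#'
#' For every requested subset of modalities, trains fusion weights on each
#' fold's training probabilities and evaluates on the test split, either on
#' the samples the subset's modalities have in common (`regime = "common"`)
#' or on every sample with at least one member modality, missing rows
#' zero-filled (`regime = "all"`). Singleton subsets reduce exactly to the
#' single modality's argmax. Subsets with no eligible sample in some fold
#' are skipped with a warning.
#'
#' @param fold_probs Output of [cv_modality_probabilities()].
#' @param subsets List of character vectors of modality names; default all
#'   nonempty subsets.
#' @param regime `"common"` or `"all"` (see above).
#' @param fusion A [fusion_config()].
#' @return Data frame: one row per subset with across-fold mean/sd metrics.
#' @export
subset_sweep <- function(fold_probs, subsets = NULL,
                         regime = c("common", "all"),
                         fusion = fusion_config()) {
  regime <- match.arg(regime)
  modalities <- fold_probs[[1]]$train$modalities
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(modalities), function(m) {
      utils::combn(modalities, m, simplify = FALSE)
    }), recursive = FALSE)
  }
  rows <- lapply(subsets, function(sub) {
    reports <- list()
    for (fp in fold_probs) {
      res <- eval_fusion_fold(fp, sub, regime, fusion)
      if (is.null(res)) next
      reports[[length(reports) + 1L]] <- res
    }
    if (length(reports) == 0) {
      warning("subset {", paste(sub, collapse = ","),
              "} has no eligible samples; skipped", call. = FALSE)
      return(NULL)
    }
    cbind(
      data.frame(subset = paste(sub, collapse = "+"), n_modalities = length(sub)),
      aggregate_fold_metrics(reports)
    )
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

# Train fusion weights on one fold's training split (restricted to a
# modality subset) and score the test split. Returns NULL when no sample
# is eligible.
eval_fusion_fold <- function(fp, sub, regime, fusion) {
  eligible <- function(pt) {
    m <- pt$mask[, match(sub, pt$modalities), drop = FALSE]
    if (regime == "common") which(rowSums(m) == length(sub)) else which(rowSums(m) > 0)
  }
  tr_pt <- subset_probability_table(fp$train, modalities = sub)
  te_pt <- subset_probability_table(fp$test, modalities = sub)
  tr_keep <- eligible(fp$train)
  te_keep <- eligible(fp$test)
  if (length(tr_keep) < 10 || length(te_keep) == 0) return(NULL)
  tr_lab <- fp$train_labels[tr_keep]
  if (length(unique(tr_lab)) < 2) return(NULL)
  w <- optimize_weights(
    subset_probability_table(tr_pt, samples = tr_keep), tr_lab, fusion
  )
  scores <- fuse(subset_probability_table(te_pt, samples = te_keep), w)
  suppressWarnings(
    compute_metrics(fp$test_labels[te_keep], scores, classes = fp$test$classes)
  )
}

#' End-to-end cross-validated fusion benchmark
#'
#' Convenience driver: per-modality CV probabilities, single-modality
#' metrics, and full-fusion metrics, all on the same folds. Single-modality
#' metrics are computed on the samples where that modality is available;
#' fusion metrics on all samples with at least one modality
#' (`regime = "all"`) or on the common samples (`regime = "common"`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param k Folds.
#' @param seed Global seed.
#' @param svm,fusion Stage configurations.
#' @param selector Optional per-fold feature selector (see
#'   [cv_modality_probabilities()]).
#' @param regime Evaluation regime for the fusion model.
#' @return List: `single` (data frame per modality), `fusion` (one row),
#'   `fold_probs` (for further sweeps).
#' @export
run_fusion_cv <- function(cohort, k = 10, seed = 1L,
                          svm = svm_config(seed = seed),
                          fusion = fusion_config(seed = seed),
                          selector = NULL,
                          regime = c("all", "common")) {
  regime <- match.arg(regime)
  fold_probs <- cv_modality_probabilities(cohort, k = k, seed = seed,
                                          svm = svm, selector = selector)
  classes <- cohort$classes

  single <- do.call(rbind, lapply(cohort$modalities, function(m) {
    reports <- list()
    for (fp in fold_probs) {
      j <- match(m, fp$test$modalities)
      keep <- which(fp$test$mask[, j])
      if (length(keep) == 0) next
      scores <- matrix(fp$test$probs[keep, j, ], length(keep), length(classes),
                       dimnames = list(NULL, classes))
      reports[[length(reports) + 1L]] <- suppressWarnings(
        compute_metrics(fp$test_labels[keep], scores, classes = classes)
      )
    }
    cbind(data.frame(modality = m), aggregate_fold_metrics(reports))
  }))

  fusion_row <- subset_sweep(
    fold_probs, subsets = list(cohort$modalities),
    regime = regime, fusion = fusion
  )
  list(single = single, fusion = fusion_row, fold_probs = fold_probs)
}
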