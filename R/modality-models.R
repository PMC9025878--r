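#' SVM training configuration
#'
#' The per-modality reference classifier is a Gaussian-RBF support vector
#' machine whose cost `C` and kernel width `gamma` are chosen by stratified
#' inner cross-validation over a log-spaced grid; features are min-max
#' scaled to \[-1, 1\] on the training data only.
#'
#' @param C_grid,gamma_grid Positive candidate values. Default
#'   `2^c(-7, -5, -2, 1, 4, 7)` for both.
#' @param inner_cv_folds Stratified folds for the grid search (default 5).
#' @param seed Seed fixing the inner fold assignment.
#' @return An `svm_config` object.
#' @export
svm_config <- function(C_grid = 2^c(-7, -5, -2, 1, 4, 7),
                       gamma_grid = 2^c(-7, -5, -2, 1, 4, 7),
                       inner_cv_folds = 5,
                       seed = 1L) {
  if (length(C_grid) == 0 || any(C_grid <= 0)) stop("C_grid must be positive")
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0)) stop("gamma_grid must be positive")
  structure(
    list(
      C_grid = C_grid, gamma_grid = gamma_grid,
      inner_cv_folds = as.integer(inner_cv_folds),
      seed = as.integer(seed)
    ),
    class = "svm_config"
  )
}

# Fit [-1, 1] min-max scaling parameters on training data.
fit_minmax <- function(values) {
  mins <- apply(values, 2, min)
  maxs <- apply(values, 2, max)
  list(mins = mins, maxs = maxs, constant = maxs == mins)
}

# Apply stored scaling. Test values outside the training range map outside
# [-1, 1]; they are deliberately left unclipped.
apply_minmax <- function(values, sc) {
  rng <- sc$maxs - sc$mins
  rng[sc$constant] <- 1
  scaled <- sweep(sweep(values, 2, sc$mins), 2, rng, `/`) * 2 - 1
  scaled[, sc$constant] <- 0
  scaled
}

#' Fit a per-modality probabilistic SVM
#'
#' Scaling is fit on the training data only; `(C, gamma)` is chosen by mean
#' inner-CV accuracy. Because the deployed output is the pairwise-coupling
#' probability vector — whose Platt calibration can collapse at very small
#' `C` even when hard-label accuracy is high — accuracy ties and near-ties
#' (within 1 percentage point, at most 8 candidates) are resolved by a
#' second inner-CV pass scored by probability log-loss. The winning pair is
#' refit on the full training split with probability estimates enabled.
#'
#' @param mm A [modality_matrix()] of training samples.
#' @param config An [svm_config()].
#' @param classes Optional class order to record; default the order of
#'   appearance in `mm$labels`.
#' @return A `modality_model`: scaling parameters, chosen `C`/`gamma`, the
#'   fitted SVM, the grid-search table, and the class order.
#' @export
fit_svm_modality <- function(mm, config = svm_config(), classes = NULL) {
  stopifnot(inherits(mm, "modality_matrix"), inherits(config, "svm_config"))
  classes <- classes %||% unique(mm$labels)
  if (length(unique(mm$labels)) < 2) {
    stop("need at least 2 classes present in training data")
  }
  counts <- table(mm$labels)
  if (any(counts < config$inner_cv_folds)) {
    stop("every class needs at least inner_cv_folds samples")
  }
  sc <- fit_minmax(mm$values)
  if (any(sc$constant)) {
    warning(sum(sc$constant), " constant feature(s) scaled to 0", call. = FALSE)
  }
  x <- apply_minmax(mm$values, sc)
  y <- factor(mm$labels, levels = classes)

  set.seed(config$seed)
  fold <- stratified_fold_ids(mm$labels, config$inner_cv_folds)
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(config$inner_cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g],
                        scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    grid$accuracy[g] <- correct / length(y)
  }
  # shortlist near-ties and break them by probability log-loss
  shortlist <- order(-grid$accuracy, seq_len(nrow(grid)))
  shortlist <- shortlist[grid$accuracy[shortlist] >= max(grid$accuracy) - 0.01]
  shortlist <- utils::head(shortlist, 8L)
  if (length(shortlist) > 1L) {
    logloss <- vapply(shortlist, function(g) {
      tot <- 0
      for (f in seq_len(config$inner_cv_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                          kernel = "radial",
                          cost = grid$C[g], gamma = grid$gamma[g],
                          scale = FALSE, probability = TRUE)
        pr <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                                  probability = TRUE), "probabilities")
        p_true <- pr[cbind(seq_len(sum(!tr)), match(y[!tr], colnames(pr)))]
        tot <- tot - sum(log(pmax(p_true, 1e-12)))
      }
      tot / length(y)
    }, numeric(1))
    best <- shortlist[which.min(logloss)]
  } else {
    best <- shortlist
  }
  fit <- e1071::svm(x, y,
                    kernel = "radial",
                    cost = grid$C[best], gamma = grid$gamma[best],
                    scale = FALSE, probability = TRUE)
  structure(
    list(
      scaling = sc,
      C = grid$C[best], gamma = grid$gamma[best],
      fit = fit,
      grid = grid,
      classes = classes,
      feature_names = mm$feature_names
    ),
    class = "modality_model"
  )
}

#' @export
print.modality_model <- function(x, ...) {
  cat(sprintf(
    "<modality_model> RBF SVM, C=%g gamma=%g, %d features, classes: %s\n",
    x$C, x$gamma, length(x$feature_names), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Class probabilities from a fitted modality model
#'
#' Applies the stored training scaling, then returns the SVM's
#' pairwise-coupling probability estimates, with columns reordered to the
#' model's recorded class order. Each row sums to 1.
#'
#' @param model A [fit_svm_modality()] result.
#' @param values Numeric matrix with the training feature columns.
#' @return Matrix samples x classes of probabilities (possibly 0 rows).
#' @export
predict_modality_proba <- function(model, values) {
  stopifnot(inherits(model, "modality_model"))
  values <- as.matrix(values)
  if (ncol(values) != length(model$feature_names)) {
    stop("feature dimension mismatch: expected ", length(model$feature_names))
  }
  if (nrow(values) == 0) {
    return(matrix(numeric(0), 0, length(model$classes),
                  dimnames = list(NULL, model$classes)))
  }
  x <- apply_minmax(values, model$scaling)
  pred <- stats::predict(model$fit, x, probability = TRUE)
  pr <- attr(pred, "probabilities")
  pr <- pr[, model$classes, drop = FALSE]
  rownames(pr) <- rownames(values)
  pr
}
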