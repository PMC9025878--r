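#' Assemble a per-sample, per-modality, per-class probability table
#'
#' The fusion stage consumes a 3-dimensional tensor of class probabilities:
#' `samples x modalities x classes`. A modality missing for a sample is
#' encoded as an exactly all-zero row, which contributes nothing to the
#' weighted sum — the mechanism by which the fusion handles incomplete
#' screening. Available rows must sum to 1 (within 1e-6).
#'
#' @param probs 3-d array `samples x modalities x classes`, or a list of
#'   per-modality `samples x classes` matrices (all with the same rows).
#' @param sample_ids Sample identifiers.
#' @param classes Ordered class labels.
#' @param modalities Ordered modality names.
#' @return A `probability_table` with an availability `mask`
#'   (`samples x modalities`) derived from the all-zero rows.
#' @export
probability_table <- function(probs, sample_ids, classes, modalities) {
  if (is.list(probs)) {
    stopifnot(length(probs) == length(modalities))
    arr <- array(0, dim = c(length(sample_ids), length(modalities), length(classes)))
    for (j in seq_along(modalities)) arr[, j, ] <- probs[[j]]
    probs <- arr
  }
  d <- dim(probs)
  stopifnot(length(d) == 3, d[1] == length(sample_ids),
            d[2] == length(modalities), d[3] == length(classes))
  rs <- apply(probs, c(1, 2), sum)
  mask <- rs > 0
  bad <- mask & abs(rs - 1) > 1e-6
  if (any(bad)) {
    stop("available (sample, modality) rows must sum to 1 within 1e-6")
  }
  dimnames(probs) <- list(sample_ids, modalities, classes)
  structure(
    list(
      probs = probs,
      sample_ids = as.character(sample_ids),
      classes = classes, modalities = modalities,
      mask = mask
    ),
    class = "probability_table"
  )
}

#' @export
print.probability_table <- function(x, ...) {
  cat(sprintf(
    "<probability_table> %d samples, %d modalities (%s), %d classes; %.1f%% rows available\n",
    length(x$sample_ids), length(x$modalities),
    paste(x$modalities, collapse = ", "), length(x$classes),
    100 * mean(x$mask)
  ))
  invisible(x)
}

# Restrict a probability table to a subset of modalities and/or samples.
subset_probability_table <- function(pt, modalities = pt$modalities,
                                     samples = seq_along(pt$sample_ids)) {
  j <- match(modalities, pt$modalities)
  if (anyNA(j)) stop("unknown modality")
  probability_table(
    pt$probs[samples, j, , drop = FALSE],
    sample_ids = pt$sample_ids[samples],
    classes = pt$classes, modalities = pt$modalities[j]
  )
}

#' Project a raw weight matrix onto row-stochastic form
#'
#' Applies a row-wise softmax to the raw `classes x modalities` parameter
#' matrix, so every row sums to 1 and entries stay in (0, 1). The softmax
#' preserves the within-row order of the raw weights.
#'
#' @param raw Numeric matrix, rows = classes, columns = modalities; all
#'   entries finite.
#' @return Row-stochastic matrix of the same shape.
#' @export
project_weights <- function(raw) {
  softmax_rows(raw)
}

#' Fusion weights
#'
#' @param raw Raw (unconstrained) `classes x modalities` parameter matrix.
#' @param classes,modalities Dimension labels.
#' @return A `fusion_weights` object carrying both the raw matrix and its
#'   row-stochastic projection.
#' @export
fusion_weights <- function(raw, classes, modalities) {
  raw <- matrix(as.numeric(raw), length(classes), length(modalities),
                dimnames = list(classes, modalities))
  structure(
    list(
      raw = raw,
      projected = project_weights(raw),
      classes = classes, modalities = modalities
    ),
    class = "fusion_weights"
  )
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("<fusion_weights> projected (row-stochastic):\n")
  print(round(x$projected, 4))
  invisible(x)
}

#' Write fusion weights as TSV
#'
#' @param weights A [fusion_weights()].
#' @param path Output path; rows = classes, columns = modalities.
#' @export
write_weights_tsv <- function(weights, path) {
  df <- data.frame(class = weights$classes, weights$projected,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Weighted-sum fusion of per-modality class probabilities
#'
#' The fused score for class `i` of a sample is
#' `sum_j w[i, j] * P_j(c_i)` — each class row of the projected weight
#' matrix weights that class's probability across modalities. Missing
#' modalities (all-zero rows) contribute exactly 0. Fused scores are *not*
#' renormalized; the predicted class is their argmax.
#'
#' @param pt A [probability_table()].
#' @param weights A [fusion_weights()] with matching class and modality
#'   order.
#' @return Matrix `samples x classes` of fused scores.
#' @export
fuse <- function(pt, weights) {
  stopifnot(inherits(pt, "probability_table"), inherits(weights, "fusion_weights"))
  if (!identical(pt$classes, weights$classes) ||
      !identical(pt$modalities, weights$modalities)) {
    stop("class/modality order mismatch between probabilities and weights")
  }
  w <- weights$projected
  n <- length(pt$sample_ids)
  out <- matrix(0, n, length(pt$classes),
                dimnames = list(pt$sample_ids, pt$classes))
  for (i in seq_along(pt$classes)) {
    out[, i] <- matrix(pt$probs[, , i], n, length(pt$modalities)) %*% w[i, ]
  }
  out
}

#' Predict classes from fused scores
#'
#' Argmax of [fuse()] per sample; ties broken by class order with a
#' warning. A sample with every modality missing carries no information and
#' raises an error.
#'
#' @param pt A [probability_table()].
#' @param weights A [fusion_weights()].
#' @return Character vector of predicted classes.
#' @export
predict_fused <- function(pt, weights) {
  none <- rowSums(pt$mask) == 0
  if (any(none)) {
    stop("no information: sample(s) with all modalities missing: ",
         paste(pt$sample_ids[none], collapse = ", "))
  }
  scores <- fuse(pt, weights)
  vapply(seq_len(nrow(scores)), function(s) {
    argmax_first(scores[s, ], labels = pt$classes)
  }, character(1))
}

#' Fusion training configuration
#'
#' @param epochs Training epochs (default 5).
#' @param lr Adam learning rate (default 0.1). The fusion layer has only
#'   `classes x modalities` parameters and trains for few epochs, so the
#'   step size must be large enough to overcome the random initialization
#'   within that budget; with Adam's unit-scaled steps, 0.1 moves the raw
#'   weights several units over a typical run.
#' @param batch_size Minibatch size (default 32).
#' @param val_fraction Fraction of the training samples held out to monitor
#'   fusion performance across epochs (default 0.10), in (0, 0.5].
#' @param best_epoch Return the weights from the epoch with the best
#'   validation accuracy (default `TRUE`); otherwise the final epoch.
#' @param softmax_mode `"forward"` (default): the row softmax is part of
#'   the differentiable forward pass and the raw parameters are optimized.
#'   `"projection"`: the raw weights are used directly in the forward pass
#'   and a softmax is applied to them after each optimizer step.
#' @param seed Seed for initialization, the validation split and batch
#'   shuffling.
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(epochs = 5, lr = 0.1, batch_size = 32,
                          val_fraction = 0.10, best_epoch = TRUE,
                          softmax_mode = c("forward", "projection"),
                          seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (val_fraction <= 0 || val_fraction > 0.5) {
    stop("val_fraction must be in (0, 0.5]")
  }
  structure(
    list(
      epochs = as.integer(epochs), lr = lr,
      batch_size = as.integer(batch_size),
      val_fraction = val_fraction,
      best_epoch = isTRUE(best_epoch),
      softmax_mode = match.arg(softmax_mode),
      seed = as.integer(seed)
    ),
    class = "fusion_config"
  )
}

# Cross-entropy of fused scores against integer labels y (1-based class
# index). Fused scores are clamped at 1e-12 before the log; no
# renormalization.
fusion_cross_entropy <- function(scores, y, eps = 1e-12) {
  p <- pmax(scores[cbind(seq_along(y), y)], eps)
  -mean(log(p))
}

# Analytic gradient of the mean cross-entropy w.r.t. the raw weight matrix.
# probs: n x M x C array; y: integer class per sample; raw: C x M.
# With softmax_in_forward, the softmax Jacobian is chained per row;
# otherwise the gradient is w.r.t. the weights used directly.
fusion_gradient <- function(probs, y, raw, softmax_in_forward = TRUE,
                            eps = 1e-12) {
  C <- nrow(raw)
  M <- ncol(raw)
  n <- length(y)
  w <- if (softmax_in_forward) softmax_rows(raw) else raw
  # fused scores
  f <- matrix(0, n, C)
  for (i in seq_len(C)) {
    f[, i] <- matrix(probs[, , i], n, M) %*% w[i, ]
  }
  # dL/df: only the true-class column is touched; clamped entries get 0
  g_f <- matrix(0, n, C)
  idx <- cbind(seq_len(n), y)
  fy <- f[idx]
  live <- fy > eps
  g_f[idx[live, , drop = FALSE]] <- -1 / (n * fy[live])
  # dL/dw[i, j] = sum_s g_f[s, i] * probs[s, j, i]
  g_w <- matrix(0, C, M)
  for (i in seq_len(C)) {
    g_w[i, ] <- crossprod(matrix(probs[, , i], n, M), g_f[, i])
  }
  if (!softmax_in_forward) return(g_w)
  # chain through the row softmax: g_raw = w * (g_w - <g_w, w>)
  g_raw <- matrix(0, C, M)
  for (i in seq_len(C)) {
    g_raw[i, ] <- w[i, ] * (g_w[i, ] - sum(g_w[i, ] * w[i, ]))
  }
  g_raw
}

#' Learn the fusion weight matrix by minibatch Adam
#'
#' Raw weights are initialized from a standard normal (their row softmax
#' therefore sums to one from the start) and optimized by minibatch Adam
#' under cross-entropy of the fused scores against the training labels.
#' A stratified `val_fraction` split of the supplied samples monitors
#' fusion accuracy after each epoch; by default the weights from the best
#' validation epoch are returned. After every optimizer step the stored
#' projected matrix is recomputed, so it is row-stochastic at all times.
#'
#' A modality that is missing for every training sample is unconstrained
#' by the data; a warning is emitted and its raw column is left at
#' initialization (the row softmax then gives it a finite but arbitrary
#' share — interpret such columns with care).
#'
#' @param pt A [probability_table()] of training samples.
#' @param labels Class label per training sample.
#' @param config A [fusion_config()].
#' @return A [fusion_weights()] with a `history` attribute (per-epoch
#'   training loss and validation accuracy).
#' @export
optimize_weights <- function(pt, labels, config = fusion_config()) {
  stopifnot(inherits(pt, "probability_table"), inherits(config, "fusion_config"))
  if (length(labels) != length(pt$sample_ids)) {
    stop("one label per sample required")
  }
  if (length(unique(labels)) < 2) stop("need at least 2 classes in labels")
  y <- match(as.character(labels), pt$classes)
  if (anyNA(y)) stop("labels outside the table's class set")
  C <- length(pt$classes)
  M <- length(pt$modalities)
  if (any(colSums(pt$mask) == 0)) {
    warning("modality missing for ALL training samples: ",
            paste(pt$modalities[colSums(pt$mask) == 0], collapse = ", "),
            "; its weights are unconstrained by the data", call. = FALSE)
  }

  set.seed(config$seed)
  raw <- matrix(stats::rnorm(C * M), C, M)
  softfwd <- config$softmax_mode == "forward"
  if (!softfwd) raw <- softmax_rows(raw)

  # stratified validation split
  n <- length(y)
  val <- logical(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, round(config$val_fraction * length(idx)))
    val[sample(idx, n_val)] <- TRUE
  }
  tr_idx <- which(!val)
  val_idx <- which(val)

  # Adam state
  m_t <- v_t <- matrix(0, C, M)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L

  val_acc <- function(raw) {
    w <- fusion_weights(if (softfwd) raw else log(pmax(raw, 1e-300)),
                        pt$classes, pt$modalities)
    # projection mode: raw already stochastic; log() makes softmax recover it
    scores <- fuse(subset_probability_table(pt, samples = val_idx), w)
    pred <- max.col(scores, ties.method = "first")
    mean(pred == y[val_idx])
  }

  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = NA_real_, val_accuracy = NA_real_)
  best <- list(acc = -Inf, loss = Inf, raw = raw)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      pb <- pt$probs[batch, , , drop = FALSE]
      yb <- y[batch]
      g <- fusion_gradient(pb, yb, raw, softmax_in_forward = softfwd)
      w_used <- if (softfwd) softmax_rows(raw) else raw
      fb <- matrix(0, length(yb), C)
      for (i in seq_len(C)) {
        fb[, i] <- matrix(pb[, , i], length(yb), M) %*% w_used[i, ]
      }
      losses <- c(losses, fusion_cross_entropy(fb, yb))
      step <- step + 1L
      m_t <- b1 * m_t + (1 - b1) * g
      v_t <- b2 * v_t + (1 - b2) * g^2
      raw <- raw - config$lr * (m_t / (1 - b1^step)) /
        (sqrt(v_t / (1 - b2^step)) + adam_eps)
      if (!softfwd) raw <- softmax_rows(raw)
    }
    acc <- val_acc(raw)
    loss <- mean(losses)
    history$train_loss[ep] <- loss
    history$val_accuracy[ep] <- acc
    # validation accuracy is coarse on a 10% split; ties go to the epoch
    # with the lower training loss (i.e. the better-trained weights)
    if (acc > best$acc || (acc == best$acc && loss < best$loss)) {
      best <- list(acc = acc, loss = loss, raw = raw)
    }
  }

  final_raw <- if (config$best_epoch) best$raw else raw
  out <- fusion_weights(
    if (softfwd) final_raw else log(pmax(final_raw, 1e-300)),
    pt$classes, pt$modalities
  )
  attr(out, "history") <- history
  out
}
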