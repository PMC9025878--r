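#' @keywords internal
"_PACKAGE"

# Row-wise softmax; rows must be finite.
softmax_rows <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite entries in weight matrix")
  z <- m - apply(m, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Argmax over a numeric vector with first-index tie-break.
# Warns when the maximum is attained more than once (tie broken by order).
argmax_first <- function(x, labels = NULL, warn_tie = TRUE) {
  i <- which(x == max(x))
  if (length(i) > 1L && warn_tie) {
    warning("tie in scores; broken by class order", call. = FALSE)
  }
  i <- i[1L]
  if (is.null(labels)) i else labels[i]
}

# Stratified fold ids for a label vector: within each class, samples are
# shuffled and dealt round-robin, so per-fold class counts differ by <= 1.
stratified_fold_ids <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
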