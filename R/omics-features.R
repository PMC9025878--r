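#' Remove features containing missing values
#'
#' Molecular matrices from public repositories routinely carry missing
#' entries (unmeasured CpG sites, unassigned gene values); the cleaning rule
#' here drops every feature column with at least one missing value and keeps
#' all samples.
#'
#' @param mm A [modality_matrix()], possibly with `NA` entries.
#' @return A [modality_matrix()] without missing values.
#' @export
drop_missing_features <- function(mm) {
  stopifnot(inherits(mm, "modality_matrix"))
  keep <- colSums(is.na(mm$values)) == 0
  if (!any(keep)) stop("empty matrix: every feature contains missing values")
  select_features(mm, mm$feature_names[keep])
}

#' Configuration for pairwise t-test feature screening
#'
#' @param alpha Significance level for the (possibly Bonferroni-adjusted)
#'   p-value, default 0.001.
#' @param bonferroni Apply Bonferroni control over the whole family
#'   (features x 3 pairwise comparisons), default `TRUE`.
#' @param required_comparisons How many of the three pairwise class
#'   comparisons must be significant: 3 for copy-number-style screening,
#'   2 for methylation-style screening.
#' @param mean_diff_threshold Minimum absolute between-class mean
#'   difference, evaluated on the significant comparisons (0.1 for
#'   copy-number values, 0.4 for methylation beta values).
#' @return A `ttest_config` object.
#' @export
ttest_config <- function(alpha = 0.001, bonferroni = TRUE,
                         required_comparisons = 3,
                         mean_diff_threshold = 0.1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!required_comparisons %in% 1:3) stop("required_comparisons must be 1, 2 or 3")
  if (mean_diff_threshold < 0) stop("mean_diff_threshold must be >= 0")
  structure(
    list(
      alpha = alpha, bonferroni = isTRUE(bonferroni),
      required_comparisons = as.integer(required_comparisons),
      mean_diff_threshold = mean_diff_threshold
    ),
    class = "ttest_config"
  )
}

#' Screen features by pairwise two-tailed t-tests
#'
#' For a three-class matrix, every feature is tested in the three pairwise
#' class comparisons with Welch's two-sample t-test. A feature is selected
#' iff (a) its p-value — Bonferroni-adjusted over the family of
#' `n_features * 3` tests when `bonferroni = TRUE` — is at most `alpha` in at
#' least `required_comparisons` of the three comparisons, and (b) the
#' absolute difference of class means is at least `mean_diff_threshold` in
#' every one of those significant comparisons. Welch's unequal-variance
#' test is used because class sizes in real cohorts are rarely balanced.
#'
#' @param mm A [modality_matrix()] with exactly 3 classes.
#' @param config A [ttest_config()].
#' @return Character vector of selected feature names (input order).
#' @export
ttest_screen <- function(mm, config = ttest_config()) {
  stopifnot(inherits(mm, "modality_matrix"), inherits(config, "ttest_config"))
  classes <- unique(mm$labels)
  if (length(classes) != 3) stop("ttest_screen expects exactly 3 classes")
  counts <- table(mm$labels)
  if (any(counts < 2)) {
    stop("degenerate class: every class needs at least 2 samples")
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  p <- ncol(mm$values)
  pmat <- matrix(NA_real_, p, 3)
  dmat <- matrix(NA_real_, p, 3)
  for (k in 1:3) {
    a <- mm$labels == pairs[[k]][1]
    b <- mm$labels == pairs[[k]][2]
    for (j in seq_len(p)) {
      xa <- mm$values[a, j]
      xb <- mm$values[b, j]
      dmat[j, k] <- abs(mean(xa) - mean(xb))
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        # Welch's statistic undefined for two constant groups: identical
        # constants are clearly non-significant, differing ones clearly are
        pmat[j, k] <- if (dmat[j, k] == 0) 1 else 0
      } else {
        pmat[j, k] <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
    }
  }
  if (config$bonferroni) pmat <- pmin(pmat * (p * 3), 1)
  sig <- pmat <= config$alpha
  big <- dmat >= config$mean_diff_threshold
  # a comparison counts only when it is significant AND clears the
  # mean-difference threshold
  selected <- rowSums(sig & big) >= config$required_comparisons
  mm$feature_names[selected]
}

#' Configuration for fold-change differential-expression filtering
#'
#' @param lfc_threshold Minimum absolute log2 fold change between any two
#'   class means (default 2).
#' @param p_threshold Significance level for the omnibus class-difference
#'   test (default 0.05).
#' @param cov_threshold Maximum coefficient of variation across all samples
#'   (default 2), excluding features whose overall spread swamps their
#'   class signal.
#' @return A `deg_config` object.
#' @export
deg_config <- function(lfc_threshold = 2, p_threshold = 0.05,
                       cov_threshold = 2) {
  if (lfc_threshold <= 0 || p_threshold <= 0 || cov_threshold <= 0) {
    stop("all thresholds must be > 0")
  }
  structure(
    list(
      lfc_threshold = lfc_threshold,
      p_threshold = p_threshold,
      cov_threshold = cov_threshold
    ),
    class = "deg_config"
  )
}

#' Filter features by log2 fold change, p-value and coefficient of variation
#'
#' The classical differential-expressed-gene screen for expression data:
#' a feature is kept iff (a) the maximum absolute log2 fold change between
#' any pair of class means reaches `lfc_threshold`, (b) a one-way ANOVA
#' across the classes gives p at most `p_threshold`, and (c) its
#' coefficient of variation (SD/mean over all samples) is at most
#' `cov_threshold`. Values must be positive (expression scale); add a
#' pseudocount upstream if your matrix contains zeros.
#'
#' @param mm A [modality_matrix()] of positive expression values.
#' @param config A [deg_config()].
#' @return Character vector of selected feature names.
#' @export
deg_filter <- function(mm, config = deg_config()) {
  stopifnot(inherits(mm, "modality_matrix"), inherits(config, "deg_config"))
  if (any(mm$values <= 0)) {
    stop("nonpositive values: log2 fold change needs positive expression; ",
         "add a pseudocount (e.g. +1) before filtering")
  }
  classes <- unique(mm$labels)
  p <- ncol(mm$values)
  lab <- factor(mm$labels)
  keep <- logical(p)
  for (j in seq_len(p)) {
    x <- mm$values[, j]
    means <- tapply(x, lab, mean)
    lfc <- max(abs(outer(log2(means), log2(means), `-`)))
    if (lfc < config$lfc_threshold) next
    cov <- stats::sd(x) / mean(x)
    if (cov > config$cov_threshold) next
    pv <- stats::oneway.test(x ~ lab, var.equal = FALSE)$p.value
    if (is.na(pv) || pv > config$p_threshold) next
    keep[j] <- TRUE
  }
  mm$feature_names[keep]
}

# Mutual information (nats) between two discrete vectors, from the joint
# contingency table.
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (px[row(pj)[nz]] * py[col(pj)[nz]])))
}

# Equal-width 3-bin discretization of a continuous feature; a constant
# feature collapses to one bin (zero mutual information with anything).
discretize_feature <- function(x, bins = 3) {
  if (length(unique(x)) <= bins) return(as.integer(factor(x)))
  br <- seq(min(x), max(x), length.out = bins + 1)
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Rank features by minimum-redundancy maximum-relevance
#'
#' Greedy mRMR ranking with the MID (mutual-information difference)
#' criterion: the first feature maximizes mutual information with the class
#' label; each subsequent pick maximizes relevance minus the mean mutual
#' information with the already-selected features. Continuous features are
#' discretized into 3 equal-width bins before computing mutual information.
#' Ties are broken by input feature order.
#'
#' @param mm A [modality_matrix()].
#' @param k How many features to rank (at most the number of features).
#' @return A list with `feature_names` (ranked) and `scores` (the MID score
#'   at the step each feature was picked; the first entry is pure
#'   relevance).
#' @export
mrmr_rank <- function(mm, k) {
  stopifnot(inherits(mm, "modality_matrix"))
  p <- ncol(mm$values)
  if (k > p) stop("k exceeds number of features")
  if (k == 0) return(list(feature_names = character(0), scores = numeric(0)))
  disc <- apply(mm$values, 2, discretize_feature)
  y <- mm$labels
  relevance <- apply(disc, 2, discrete_mi, y = y)
  selected <- integer(0)
  scores <- numeric(0)
  candidates <- seq_len(p)
  # pairwise feature MI cache, filled lazily
  fmi <- matrix(NA_real_, p, p)
  for (step in seq_len(k)) {
    if (length(selected) == 0) {
      crit <- relevance[candidates]
    } else {
      red <- vapply(candidates, function(j) {
        for (s in selected) {
          if (is.na(fmi[j, s])) {
            fmi[j, s] <<- fmi[s, j] <<- discrete_mi(disc[, j], disc[, s])
          }
        }
        mean(fmi[j, selected])
      }, numeric(1))
      crit <- relevance[candidates] - red
    }
    best <- candidates[which.max(crit)]  # which.max: first index on ties
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
    candidates <- setdiff(candidates, best)
  }
  list(feature_names = mm$feature_names[selected], scores = scores)
}
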