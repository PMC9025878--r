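test_that("features with any missing value are dropped, samples untouched", {
  set.seed(1)
  mm <- toy_matrix(10, n_features = 10)
  mm$values[3, 2] <- NA
  mm$values[17, 7] <- NA
  out <- drop_missing_features(mm)
  expect_equal(ncol(out$values), 8)
  expect_equal(nrow(out$values), nrow(mm$values))
  expect_false(anyNA(out$values))

  clean <- toy_matrix(5, n_features = 4)
  expect_equal(drop_missing_features(clean)$values, clean$values)

  allna <- toy_matrix(5, n_features = 2)
  allna$values[1, ] <- NA
  expect_error(drop_missing_features(allna), "empty matrix")
})

test_that("t-test screen selects planted shifts and rejects flat features", {
  set.seed(2)
  # feature 1: 5-SD shift in LUAD; feature 2: identical across classes
  mm <- toy_matrix(100, shifts = list(`1` = list(LUAD = 5)), n_features = 4)
  mm$values[, 2] <- rep(1.0, nrow(mm$values))
  cfg <- ttest_config(alpha = 0.001, bonferroni = TRUE,
                      required_comparisons = 2, mean_diff_threshold = 0.1)
  sel <- ttest_screen(mm, cfg)
  expect_true("f1" %in% sel)
  expect_false("f2" %in% sel)

  # oracle cross-check on the planted feature: direct Welch statistic for
  # LUAD vs control must clear Bonferroni at alpha with a 5-SD shift
  a <- mm$values[mm$labels == "LUAD", 1]
  b <- mm$values[mm$labels == "control", 1]
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 100 + var(b) / 100)
  expect_gt(abs(tstat), qt(1 - 0.001 / (2 * 4 * 3), df = 100))
})

test_that("near-vacuous thresholds select every varying feature", {
  set.seed(3)
  mm <- toy_matrix(30, n_features = 8)
  cfg <- ttest_config(alpha = 0.999, bonferroni = FALSE,
                      required_comparisons = 1, mean_diff_threshold = 0)
  expect_setequal(ttest_screen(mm, cfg), mm$feature_names)
})

test_that("dropping Bonferroni control only ever widens the selection", {
  for (seed in 1:5) {
    set.seed(seed)
    mm <- toy_matrix(40, shifts = list(`1` = list(LUAD = 0.8),
                                       `2` = list(LUSC = 0.4)),
                     n_features = 6)
    for (rc in 1:3) {
      sel_bonf <- ttest_screen(mm, ttest_config(
        alpha = 0.01, bonferroni = TRUE,
        required_comparisons = rc, mean_diff_threshold = 0.1
      ))
      sel_raw <- ttest_screen(mm, ttest_config(
        alpha = 0.01, bonferroni = FALSE,
        required_comparisons = rc, mean_diff_threshold = 0.1
      ))
      expect_true(all(sel_bonf %in% sel_raw))
    }
  }
})

test_that("selection operations leave the input matrix unmodified", {
  set.seed(4)
  mm <- toy_matrix(20, shifts = list(`1` = list(LUAD = 2)), n_features = 5)
  snapshot <- mm$values
  invisible(ttest_screen(mm, ttest_config(required_comparisons = 2)))
  invisible(mrmr_rank(mm, 3))
  mm_pos <- mm
  mm_pos$values <- abs(mm_pos$values) + 1
  snap_pos <- mm_pos$values
  invisible(deg_filter(mm_pos))
  expect_identical(mm$values, snapshot)
  expect_identical(mm_pos$values, snap_pos)
})

test_that("t-test screen errors on degenerate classes and wrong class counts", {
  mm <- toy_matrix(1, n_features = 3)
  expect_error(ttest_screen(mm), "degenerate class")
  two <- modality_matrix(matrix(rnorm(20), 10, 2),
                         patient_ids = paste0("P", 1:10),
                         labels = rep(c("a", "b"), 5))
  expect_error(ttest_screen(two), "3 classes")
})

test_that("fold-change filter applies LFC, p-value and COV rules", {
  set.seed(5)
  n <- 60
  labels <- rep(c("LUAD", "control", "LUSC"), each = n / 3)
  # f1: 8-fold mean difference (LFC 3), tight spread -> selected
  # f2: constant -> LFC 0 -> excluded
  # f3: huge overall spread -> COV above threshold -> excluded
  f1 <- ifelse(labels == "LUAD", 8, 1) + rnorm(n, sd = 0.05)
  f2 <- rep(2, n)
  f3 <- abs(rnorm(n, mean = 0.05, sd = 2)) + 0.01
  mm <- modality_matrix(cbind(f1 = f1, f2 = f2, f3 = f3),
                        patient_ids = sprintf("P%02d", 1:n), labels = labels)
  # hand-computed oracle for f1: LFC = log2(mean_LUAD/mean_other) ~ 3, COV < 2
  means <- tapply(f1, labels, mean)
  expect_gt(max(abs(outer(log2(means), log2(means), `-`))), 2)
  expect_lt(sd(f1) / mean(f1), 2)

  sel <- deg_filter(mm, deg_config(lfc_threshold = 2, p_threshold = 0.05,
                                   cov_threshold = 2))
  expect_equal(sel, "f1")
  expect_length(deg_filter(mm, deg_config(lfc_threshold = 1e6)), 0)
  mm$values[1, 1] <- -1
  expect_error(deg_filter(mm), "pseudocount")
})

test_that("mRMR ranks an informative feature first (exhaustive MI oracle)", {
  set.seed(6)
  n <- 150
  labels <- rep(c("LUAD", "control", "LUSC"), each = n / 3)
  informative <- ifelse(labels == "LUAD", 2, 0) + rnorm(n, sd = 0.5)
  noise1 <- rnorm(n)
  noise2 <- rnorm(n)
  mm <- modality_matrix(cbind(a = noise1, b = informative, c = noise2),
                        patient_ids = sprintf("P%03d", 1:n), labels = labels)
  rk <- mrmr_rank(mm, 3)
  expect_equal(rk$feature_names[1], "b")
  # exhaustive oracle on the same toy
  expect_equal(rk$feature_names, c("a", "b", "c")[oracle_mrmr(mm$values, labels, 3)])
  # k = 1 returns the argmax-relevance feature only
  expect_equal(mrmr_rank(mm, 1)$feature_names, "b")
  expect_length(mrmr_rank(mm, 0)$feature_names, 0)
  expect_error(mrmr_rank(mm, 4), "exceeds")
})

test_that("mRMR penalizes a duplicated feature below an independent weaker one", {
  set.seed(7)
  n <- 300
  labels <- rep(c("LUAD", "control", "LUSC"), each = n / 3)
  strong <- ifelse(labels == "LUAD", 3, 0) + rnorm(n, sd = 0.4)
  weak <- ifelse(labels == "LUSC", 1, 0) + rnorm(n, sd = 0.8)
  mm <- modality_matrix(cbind(strong = strong, copy = strong, weak = weak),
                        patient_ids = sprintf("P%03d", 1:n), labels = labels)
  rk <- mrmr_rank(mm, 3)
  expect_equal(rk$feature_names[1], "strong")
  expect_equal(rk$feature_names[2], "weak")  # redundancy pushes the copy last
  expect_equal(rk$feature_names,
               c("strong", "copy", "weak")[oracle_mrmr(mm$values, labels, 3)])
})

test_that("mRMR ranking is invariant to feature column order", {
  set.seed(8)
  mm <- toy_matrix(60, shifts = list(`1` = list(LUAD = 2), `3` = list(LUSC = 1)),
                   n_features = 5)
  perm <- c(4, 1, 5, 3, 2)
  mm_perm <- modality_matrix(mm$values[, perm],
                             patient_ids = mm$patient_ids, labels = mm$labels,
                             feature_names = mm$feature_names[perm])
  expect_setequal(mrmr_rank(mm, 5)$feature_names,
                  mrmr_rank(mm_perm, 5)$feature_names)
  expect_equal(mrmr_rank(mm, 3)$feature_names,
               mrmr_rank(mm_perm, 3)$feature_names)
})

test_that("planted informative features are recovered at realistic settings", {
  co <- generate_cohort(cohort_spec(200, modalities = "metDNA",
                                    n_features = 40, effect_size = 1,
                                    informative_fraction = 0.25, seed = 17))
  mm <- co$matrices$metDNA
  sel <- ttest_screen(mm, ttest_config(alpha = 0.001, bonferroni = TRUE,
                                       required_comparisons = 2,
                                       mean_diff_threshold = 0.4))
  tr <- co$truth$metDNA
  recall <- mean(tr$informative %in% sel)
  fpr <- mean(tr$noise %in% sel)
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
})
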