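classes3 <- c("LUAD", "control", "LUSC")

test_that("weight projection is a row softmax onto the simplex", {
  # all-zero row: symmetry gives the uniform vector
  expect_equal(unname(project_weights(matrix(0, 1, 5))[1, ]), rep(0.2, 5))
  # hand-computed softmax of (ln 2, 0, 0, 0, 0)
  expect_equal(unname(project_weights(matrix(c(log(2), 0, 0, 0, 0), 1, 5))[1, ]),
               c(2 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6))
  set.seed(40)
  for (i in 1:25) {
    raw <- matrix(rnorm(15, sd = 3), 3, 5)
    w <- project_weights(raw)
    expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(w > 0 & w < 1))
    # order-preserving within each row
    for (r in 1:3) expect_equal(order(w[r, ]), order(raw[r, ]))
  }
  expect_error(project_weights(matrix(c(1, Inf, 0, 1), 2, 2)), "non-finite")
})

test_that("probability tables validate row sums and derive the missingness mask", {
  set.seed(41)
  p1 <- random_simplex(4, 3)
  p2 <- random_simplex(4, 3)
  p2[2, ] <- 0  # missing modality 2 for sample 2
  pt <- make_pt(list(p1, p2), classes3, c("m1", "m2"))
  expect_equal(unname(pt$mask[, 2]), c(TRUE, FALSE, TRUE, TRUE))
  expect_true(all(pt$mask[, 1]))

  bad <- p2
  bad[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(make_pt(list(p1, bad), classes3, c("m1", "m2")), "sum to 1")
})

test_that("fusion is the per-class weighted sum of Eq. 3", {
  set.seed(42)
  # identical vectors across modalities + uniform weights -> the vector itself
  p <- random_simplex(1, 3)
  pt <- make_pt(list(p, p, p), classes3, c("m1", "m2", "m3"))
  w <- fusion_weights(matrix(0, 3, 3), classes3, c("m1", "m2", "m3"))
  expect_equal(unname(fuse(pt, w)[1, ]), unname(p[1, ]), tolerance = 1e-12)

  # single available modality with uniform rows: argmax preserved
  pz <- matrix(0, 1, 3)
  pt1 <- make_pt(list(p, pz), classes3, c("m1", "m2"))
  wu <- fusion_weights(matrix(0, 3, 2), classes3, c("m1", "m2"))
  expect_equal(unname(which.max(fuse(pt1, wu)[1, ])),
               unname(which.max(p[1, ])))

  # hand-worked 2-modality example with weight rows (0.75, 0.25)
  raw <- matrix(rep(c(log(3), 0), each = 3), 3, 2)  # softmax -> (0.75, 0.25)
  wh <- fusion_weights(raw, classes3, c("m1", "m2"))
  expect_equal(unname(wh$projected[1, ]), c(0.75, 0.25))
  pa <- matrix(c(1, 0, 0), 1, 3)
  pb <- matrix(c(0, 1, 0), 1, 3)
  pt2 <- make_pt(list(pa, pb), classes3, c("m1", "m2"))
  got <- fuse(pt2, wh)[1, ]
  # brute-force loop oracle
  want <- sapply(1:3, function(i) {
    0.75 * pa[1, i] + 0.25 * pb[1, i]
  })
  expect_equal(unname(got), want)
  expect_equal(unname(got), c(0.75, 0.25, 0))

  # order mismatch is refused
  w_bad <- fusion_weights(raw, classes3, c("m2", "m1"))
  expect_error(fuse(pt2, w_bad), "mismatch")
})

test_that("a zeroed modality contributes bit-identically to dropping its term", {
  set.seed(43)
  n <- 20
  p1 <- random_simplex(n, 3)
  p2 <- random_simplex(n, 3)
  p3 <- random_simplex(n, 3)
  p2[5:9, ] <- 0
  pt <- make_pt(list(p1, p2, p3), classes3, c("m1", "m2", "m3"))
  raw <- matrix(rnorm(9), 3, 3)
  w <- fusion_weights(raw, classes3, c("m1", "m2", "m3"))
  full <- fuse(pt, w)
  # Eq. 3 summed two ways: with the missing modality's zero term included,
  # and with that term dropped entirely. Same accumulation order, so the
  # two must agree bit for bit.
  mats <- list(p1, p2, p3)
  manual_sum <- function(drop_missing) {
    out <- matrix(0, n, 3)
    for (s in 1:n) {
      for (i in 1:3) {
        acc <- 0
        for (j in 1:3) {
          if (drop_missing && all(mats[[j]][s, ] == 0)) next
          acc <- acc + w$projected[i, j] * mats[[j]][s, i]
        }
        out[s, i] <- acc
      }
    }
    out
  }
  expect_identical(manual_sum(TRUE), manual_sum(FALSE))
  expect_equal(unname(full), manual_sum(TRUE), tolerance = 1e-15)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(44)
  n <- 3
  p1 <- random_simplex(n, 3)
  p2 <- random_simplex(n, 3)
  pt <- make_pt(list(p1, p2), classes3, c("m1", "m2"))
  y <- c(1L, 2L, 3L)
  for (softfwd in c(TRUE, FALSE)) {
    raw <- if (softfwd) matrix(rnorm(6), 3, 2) else latefuse:::softmax_rows(matrix(rnorm(6), 3, 2))
    g <- latefuse:::fusion_gradient(pt$probs, y, raw, softmax_in_forward = softfwd)
    loss_at <- function(r) {
      w <- if (softfwd) latefuse:::softmax_rows(r) else r
      f <- sapply(1:3, function(i) matrix(pt$probs[, , i], n, 2) %*% w[i, ])
      latefuse:::fusion_cross_entropy(f, y)
    }
    h <- 1e-6
    fd <- matrix(0, 3, 2)
    for (i in 1:3) for (j in 1:2) {
      rp <- raw; rp[i, j] <- rp[i, j] + h
      rm <- raw; rm[i, j] <- rm[i, j] - h
      fd[i, j] <- (loss_at(rp) - loss_at(rm)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("optimized weights are row-stochastic, deterministic, and trivial for M=1", {
  set.seed(45)
  n <- 60
  p1 <- random_simplex(n, 3)
  labels <- classes3[max.col(p1)]
  pt1 <- make_pt(list(p1), classes3, "only")
  cfg <- fusion_config(epochs = 3, seed = 6)
  w1 <- optimize_weights(pt1, labels, cfg)
  # softmax of a single column is identically 1
  expect_equal(unname(w1$projected[, 1]), rep(1, 3))

  p2 <- random_simplex(n, 3)
  pt <- make_pt(list(p1, p2), classes3, c("m1", "m2"))
  wa <- optimize_weights(pt, labels, cfg)
  wb <- optimize_weights(pt, labels, cfg)
  expect_identical(wa$raw, wb$raw)
  expect_equal(unname(rowSums(wa$projected)), rep(1, 3), tolerance = 1e-9)
  hist <- attr(wa, "history")
  expect_equal(nrow(hist), 3)
  expect_true(all(is.finite(hist$train_loss)))

  # projection mode keeps the stored matrix row-stochastic too
  wp <- optimize_weights(pt, labels,
                         fusion_config(epochs = 3, seed = 6,
                                       softmax_mode = "projection"))
  expect_equal(unname(rowSums(wp$projected)), rep(1, 3), tolerance = 1e-9)
})

test_that("an oracle modality out-weighs a random one in every class row", {
  set.seed(46)
  n <- 500
  labels <- sample(classes3, n, replace = TRUE)
  oracle <- matrix(0, n, 3)
  oracle[cbind(seq_len(n), match(labels, classes3))] <- 1
  noise <- random_simplex(n, 3)
  pt <- make_pt(list(noise, oracle), classes3, c("random", "oracle"))
  w <- optimize_weights(pt, labels, fusion_config(epochs = 5, seed = 8))
  expect_true(all(w$projected[, "oracle"] > w$projected[, "random"]))
})

test_that("fused prediction handles argmax, ties and all-missing samples", {
  w <- fusion_weights(matrix(0, 3, 1), classes3, "m1")
  p <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  pt <- make_pt(list(p), classes3, "m1")
  expect_equal(predict_fused(pt, w), "LUAD")

  tied <- make_pt(list(matrix(c(0.4, 0.4, 0.2), 1, 3)), classes3, "m1")
  expect_warning(pred <- predict_fused(tied, w), "tie")
  expect_equal(unname(pred), "LUAD")

  two <- fusion_weights(matrix(0, 3, 2), classes3, c("m1", "m2"))
  pz <- matrix(0, 1, 3)
  allmiss <- make_pt(list(pz, pz), classes3, c("m1", "m2"))
  expect_error(predict_fused(allmiss, two), "no information")
})

test_that("a modality absent from all training samples triggers a warning", {
  set.seed(47)
  n <- 40
  p1 <- random_simplex(n, 3)
  labels <- classes3[max.col(p1)]
  pz <- matrix(0, n, 3)
  pt <- make_pt(list(p1, pz), classes3, c("m1", "gone"))
  expect_warning(optimize_weights(pt, labels, fusion_config(epochs = 2, seed = 3)),
                 "ALL training samples")
})

test_that("learned weights export as a headed TSV", {
  w <- fusion_weights(matrix(rnorm(6), 3, 2), classes3, c("m1", "m2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights_tsv(w, path)
  back <- read.delim(path)
  expect_equal(back$class, classes3)
  expect_equal(as.matrix(back[, c("m1", "m2")]), w$projected,
               ignore_attr = TRUE, tolerance = 1e-6)
})
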