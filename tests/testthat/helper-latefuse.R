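# Shared fixture builders and independent oracles for the test suite.

# n random points on the C-simplex (Dirichlet(1,...,1) via normalized
# exponentials).
random_simplex <- function(n, C) {
  m <- matrix(stats::rexp(n * C), n, C)
  m / rowSums(m)
}

# Build a probability table from a list of per-modality samples x classes
# matrices; NULL rows are encoded missing by passing 0 rows upstream.
make_pt <- function(mats, classes, modalities,
                    sample_ids = paste0("s", seq_len(nrow(mats[[1]])))) {
  probability_table(mats, sample_ids = sample_ids,
                    classes = classes, modalities = modalities)
}

# Independent plug-in mutual information oracle (nats): H(X)+H(Y)-H(X,Y)
# from empirical frequencies. Deliberately a different formula route than
# the implementation's joint-table sum.
oracle_mi <- function(x, y) {
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  H(x) + H(y) - H(paste(x, y, sep = "\r"))
}

# Equal-width 3-bin discretization mirroring the package contract, for use
# by the mRMR brute-force oracle.
oracle_bin3 <- function(x) {
  if (length(unique(x)) <= 3) return(as.integer(factor(x)))
  as.integer(cut(x, breaks = seq(min(x), max(x), length.out = 4),
                 include.lowest = TRUE))
}

# Brute-force greedy mRMR (MID criterion) used as oracle on tiny toys.
oracle_mrmr <- function(values, labels, k) {
  disc <- apply(values, 2, oracle_bin3)
  rel <- apply(disc, 2, oracle_mi, y = labels)
  sel <- integer(0)
  cand <- seq_len(ncol(values))
  for (step in seq_len(k)) {
    crit <- sapply(cand, function(j) {
      if (length(sel) == 0) return(rel[j])
      rel[j] - mean(sapply(sel, function(s) oracle_mi(disc[, j], disc[, s])))
    })
    pick <- cand[which.max(crit)]
    sel <- c(sel, pick)
    cand <- setdiff(cand, pick)
  }
  sel
}

# Small 3-class modality matrix with planted class-mean shifts.
toy_matrix <- function(n_per_class = 50, shifts = list(), n_features = 5,
                       classes = c("LUAD", "control", "LUSC"), sd = 1) {
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  vals <- matrix(stats::rnorm(n * n_features, sd = sd), n, n_features)
  for (j in names(shifts)) {
    jj <- as.integer(j)
    for (cl in names(shifts[[j]])) {
      vals[labels == cl, jj] <- vals[labels == cl, jj] + shifts[[j]][[cl]]
    }
  }
  modality_matrix(vals, patient_ids = sprintf("P%03d", seq_len(n)),
                  labels = labels)
}

# A uniform-colour RGB tile.
flat_tile <- function(rgb, px = 8) {
  array(rep(as.integer(rgb), each = px * px), dim = c(px, px, 3))
}
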