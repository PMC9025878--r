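#' Specify a synthetic multi-modal cohort
#'
#' Describes a patient-linked cohort with one feature matrix per modality.
#' Features are independent Gaussians (within-class SD 1); a configurable
#' fraction of features per modality is informative, each shifting the mean
#' of exactly one class by `effect_size` standard deviations. Per-modality
#' missingness is missing-completely-at-random at the patient level, which
#' emulates the uneven per-modality sample availability of real multi-omic
#' cohorts without modelling any particular missingness mechanism.
#'
#' @param n_patients_per_class Patients per class (scalar or one per class).
#' @param classes Ordered class labels. Default `c("LUAD","control","LUSC")`,
#'   the two non-small-cell lung cancer subtypes plus healthy tissue.
#' @param modalities Ordered modality names.
#' @param n_features Features per modality (scalar or one per modality).
#' @param effect_size Between-class mean shift in within-class SD units
#'   (scalar or one per modality). Zero means pure noise.
#' @param missing_rate Per-patient probability that the modality is absent
#'   (scalar or one per modality), in \[0, 1\].
#' @param informative_fraction Fraction of each modality's features that
#'   carry signal (default 0.1); the rest are noise, giving selection
#'   procedures a planted ground truth.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients_per_class,
                        classes = c("LUAD", "control", "LUSC"),
                        modalities = c("WSI", "RNA", "miRNA", "CNV", "metDNA"),
                        n_features = 10,
                        effect_size = 1,
                        missing_rate = 0,
                        informative_fraction = 0.1,
                        seed = 1L) {
  if (length(classes) < 2) stop("invalid spec: need at least 2 classes")
  if (length(modalities) < 1) stop("invalid spec: need at least 1 modality")
  n_patients_per_class <- rep_len(as.integer(n_patients_per_class), length(classes))
  if (any(n_patients_per_class < 1)) stop("invalid spec: zero patients")
  n_features <- rep_len(as.integer(n_features), length(modalities))
  if (any(n_features < 1)) stop("invalid spec: zero features")
  effect_size <- rep_len(as.numeric(effect_size), length(modalities))
  if (any(effect_size < 0)) stop("invalid spec: effect_size must be >= 0")
  missing_rate <- rep_len(as.numeric(missing_rate), length(modalities))
  if (any(missing_rate < 0 | missing_rate > 1)) {
    stop("invalid spec: missing_rate must be in [0, 1]")
  }
  if (informative_fraction < 0 || informative_fraction > 1) {
    stop("invalid spec: informative_fraction must be in [0, 1]")
  }
  structure(
    list(
      n_patients_per_class = n_patients_per_class,
      classes = classes,
      modalities = modalities,
      n_features = stats::setNames(n_features, modalities),
      effect_size = stats::setNames(effect_size, modalities),
      missing_rate = stats::setNames(missing_rate, modalities),
      informative_fraction = informative_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic patient-linked cohort
#'
#' Draws class-conditional Gaussian feature matrices for every modality in
#' the spec, masks patients out of modalities at the configured
#' missing-completely-at-random rate, and records which features were
#' planted as informative (and for which class) so that selection
#' procedures can be scored against ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` object: `patients` (data frame of `patient_id`,
#'   `label`), `classes`, `modalities`, `matrices` (one [modality_matrix()]
#'   per modality, rows only for patients with that modality), and `truth`
#'   (per modality, the informative feature names and their target class).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labels <- rep(spec$classes, times = spec$n_patients_per_class)
  n <- length(labels)
  patient_ids <- sprintf("P%04d", seq_len(n))
  patients <- data.frame(
    patient_id = patient_ids, label = labels,
    stringsAsFactors = FALSE
  )

  matrices <- list()
  truth <- list()
  for (m in spec$modalities) {
    p <- spec$n_features[[m]]
    n_inf <- round(spec$informative_fraction * p)
    if (spec$informative_fraction > 0 && n_inf == 0) n_inf <- 1L
    feat_names <- paste0(m, "_f", seq_len(p))
    vals <- matrix(stats::rnorm(n * p), n, p, dimnames = list(patient_ids, feat_names))
    # informative features shift the mean of exactly one class, assigned
    # round-robin so every class gets signal when n_inf >= n_classes
    target <- character(0)
    if (n_inf > 0) {
      target <- rep_len(spec$classes, n_inf)
      for (j in seq_len(n_inf)) {
        hit <- labels == target[j]
        vals[hit, j] <- vals[hit, j] + spec$effect_size[[m]]
      }
    }
    missing <- stats::runif(n) < spec$missing_rate[[m]]
    keep <- which(!missing)
    matrices[[m]] <- modality_matrix(
      vals[keep, , drop = FALSE],
      patient_ids = patient_ids[keep],
      labels = labels[keep],
      feature_names = feat_names
    )
    truth[[m]] <- list(
      informative = feat_names[seq_len(n_inf)],
      target_class = target,
      noise = if (n_inf < p) feat_names[(n_inf + 1):p] else character(0)
    )
  }

  structure(
    list(
      patients = patients,
      classes = spec$classes,
      modalities = spec$modalities,
      matrices = matrices,
      truth = truth,
      spec = spec
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d patients (%s); modalities: %s\n",
    nrow(x$patients),
    paste(names(table(x$patients$label)), table(x$patients$label),
          sep = "=", collapse = ", "),
    paste(sprintf("%s[%d x %d]", x$modalities,
                  vapply(x$matrices, function(m) nrow(m$values), 0L),
                  vapply(x$matrices, function(m) ncol(m$values), 0L)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Write a cohort's modality matrices as TSV files
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed); one
#'   `<modality>.tsv` per modality.
#' @return The directory, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in cohort$modalities) {
    write_modality_tsv(cohort$matrices[[m]], file.path(dir, paste0(m, ".tsv")))
  }
  invisible(dir)
}

#' Specify a synthetic tiled slide
#'
#' Describes a square composite image assembled from a grid of tiles:
#' a configured fraction are near-white background tiles (all three channel
#' means above the background threshold of 220) and the rest are tissue
#' tiles coloured around a per-class RGB mean. This gives the tile
#' extraction and background filter a fixture with known composition; it
#' does not attempt histology texture realism.
#'
#' @param grid Tiles per side (total tiles = `grid^2`).
#' @param tile_px Tile edge length in pixels (default 512).
#' @param background_fraction Proportion of background tiles; the count is
#'   `round(background_fraction * grid^2)`, placed uniformly at random.
#' @param class_color_means Named list of RGB mean triples (0-255), one per
#'   class; each must have at least one channel no greater than 210 so a
#'   tissue tile can never be mistaken for background.
#' @param noise_sd Per-pixel Gaussian noise SD (default 8).
#' @param seed Integer seed.
#' @return A `slide_spec` object.
#' @export
slide_spec <- function(grid,
                       tile_px = 512L,
                       background_fraction = 0.3,
                       class_color_means = list(
                         LUAD = c(150, 90, 140),
                         control = c(200, 160, 190),
                         LUSC = c(110, 130, 180)
                       ),
                       noise_sd = 8,
                       seed = 1L) {
  if (grid < 1) stop("invalid spec: grid must be >= 1")
  if (tile_px < 1) stop("invalid spec: tile_px must be >= 1")
  if (background_fraction < 0 || background_fraction > 1) {
    stop("invalid spec: background_fraction must be in [0, 1]")
  }
  ok <- vapply(class_color_means, function(x) {
    length(x) == 3 && min(x) <= 210 && all(x >= 0 & x <= 255)
  }, logical(1))
  if (!all(ok)) {
    stop("invalid spec: each class colour needs 3 channels in [0,255], min channel <= 210")
  }
  structure(
    list(
      grid = as.integer(grid), tile_px = as.integer(tile_px),
      background_fraction = background_fraction,
      class_color_means = class_color_means,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "slide_spec"
  )
}

#' Generate a synthetic slide image
#'
#' @param spec A [slide_spec()].
#' @param class_label Which class's tissue colour to use; must name an entry
#'   of `spec$class_color_means`.
#' @return An integer array `(grid*tile_px) x (grid*tile_px) x 3` with
#'   channel values in 0-255, row-major tile layout.
#' @export
generate_slide <- function(spec, class_label) {
  stopifnot(inherits(spec, "slide_spec"))
  if (!class_label %in% names(spec$class_color_means)) {
    stop("unknown class label: ", class_label)
  }
  set.seed(spec$seed)
  g <- spec$grid
  t <- spec$tile_px
  n_tiles <- g * g
  n_bg <- round(spec$background_fraction * n_tiles)
  bg_idx <- sample.int(n_tiles, n_bg)
  col_tissue <- spec$class_color_means[[class_label]]
  col_bg <- c(245, 245, 245)
  img <- array(0L, dim = c(g * t, g * t, 3))
  for (k in seq_len(n_tiles)) {
    # row-major tile order
    r <- (k - 1L) %/% g
    c0 <- (k - 1L) %% g
    base <- if (k %in% bg_idx) col_bg else col_tissue
    for (ch in 1:3) {
      px <- base[ch] + stats::rnorm(t * t, 0, spec$noise_sd)
      px <- pmin(pmax(round(px), 0), 255)
      img[r * t + seq_len(t), c0 * t + seq_len(t), ch] <- as.integer(px)
    }
  }
  img
}

#' Write a slide image to PNG
#'
#' @param img Integer RGB array (values 0-255), as from [generate_slide()].
#' @param path Output path.
#' @export
write_slide_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write slides")
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
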