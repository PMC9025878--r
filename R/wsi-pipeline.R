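#' Extract non-overlapping tiles from a slide image
#'
#' Cuts the image into a row-major grid of `tile_px`-square tiles (partial
#' edge tiles are dropped) and discards background tiles: a tile is
#' discarded iff the mean of *all three* colour channels exceeds
#' `background_threshold` (default 220), the standard near-white test for
#' haematoxylin-eosin slides. A tile with channel means (230, 200, 230) is
#' therefore retained.
#'
#' @param slide_image Integer RGB array (H x W x 3, values 0-255).
#' @param tile_px Tile edge length (default 512).
#' @param background_threshold Per-channel mean above which a channel looks
#'   like background (default 220).
#' @param slide_id,patient_id,label Optional metadata carried along.
#' @return A `slide_tile_set`: `tiles` (list of tile arrays), `positions`
#'   (row/col grid indices of the retained tiles), `n_grid_tiles`,
#'   `n_discarded`, plus the metadata. Zero retained tiles is allowed: the
#'   caller decides how to treat an empty slide.
#' @export
extract_tiles <- function(slide_image, tile_px = 512L,
                          background_threshold = 220,
                          slide_id = "slide", patient_id = NA_character_,
                          label = NULL) {
  d <- dim(slide_image)
  if (length(d) != 3 || d[3] != 3) stop("slide_image must be H x W x 3")
  if (d[1] < tile_px || d[2] < tile_px) {
    stop("slide smaller than one tile")
  }
  nr <- d[1] %/% tile_px
  nc <- d[2] %/% tile_px
  tiles <- list()
  positions <- NULL
  n_disc <- 0L
  for (r in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      tile <- slide_image[(r - 1) * tile_px + seq_len(tile_px),
                          (c0 - 1) * tile_px + seq_len(tile_px), , drop = FALSE]
      ch_means <- apply(tile, 3, mean)
      if (all(ch_means > background_threshold)) {
        n_disc <- n_disc + 1L
      } else {
        tiles[[length(tiles) + 1L]] <- tile
        positions <- rbind(positions, c(r, c0))
      }
    }
  }
  structure(
    list(
      slide_id = slide_id, patient_id = patient_id, label = label,
      tiles = tiles,
      positions = positions,
      tile_px = as.integer(tile_px),
      n_grid_tiles = nr * nc,
      n_discarded = n_disc
    ),
    class = "slide_tile_set"
  )
}

#' @export
print.slide_tile_set <- function(x, ...) {
  cat(sprintf(
    "<slide_tile_set> %s: %d/%d tiles retained (%d background)\n",
    x$slide_id, length(x$tiles), x$n_grid_tiles, x$n_discarded
  ))
  invisible(x)
}

#' Per-tile class predictions for one slide
#'
#' @param slide_id Slide identifier.
#' @param predictions Character vector of per-tile predicted classes.
#' @param classes Ordered class labels the predictions are drawn from.
#' @return A `tile_prediction_set`.
#' @export
tile_prediction_set <- function(slide_id, predictions, classes) {
  predictions <- as.character(predictions)
  if (length(predictions) < 1) stop("empty prediction set")
  if (!all(predictions %in% classes)) {
    stop("predictions must be drawn from the class set")
  }
  structure(
    list(slide_id = slide_id, predictions = predictions, classes = classes),
    class = "tile_prediction_set"
  )
}

#' Slide-level class probabilities from tile predictions
#'
#' The slide's probability for each class is the fraction of its tiles
#' predicted as that class, so the vector always lies on the probability
#' simplex.
#'
#' @param preds A [tile_prediction_set()].
#' @return Named numeric vector of per-class probabilities (class order).
#' @export
slide_probabilities <- function(preds) {
  stopifnot(inherits(preds, "tile_prediction_set"))
  counts <- table(factor(preds$predictions, levels = preds$classes))
  stats::setNames(as.numeric(counts) / length(preds$predictions), preds$classes)
}

#' Majority-vote slide prediction
#'
#' The slide label is the most frequently predicted tile class; ties are
#' broken by class order (with a warning). Always equals the argmax of
#' [slide_probabilities()].
#'
#' @param preds A [tile_prediction_set()].
#' @return A single class label.
#' @export
slide_predict_majority <- function(preds) {
  p <- slide_probabilities(preds)
  argmax_first(p, labels = preds$classes)
}

#' Fit the default tile classifier (multinomial logistic on channel means)
#'
#' The tile-classifier contract is behavioural: any object with a
#' [predict_tiles()] method that maps a list of tiles to class labels can
#' drive the slide-level aggregation. The default supplied here is a
#' multinomial logistic regression on the three per-tile channel means —
#' deliberately lightweight, so the tile-to-slide mathematics can be
#' exercised end-to-end at desk scale. A convolutional backend can be
#' plugged in behind the same contract.
#'
#' @param tiles List of RGB tile arrays.
#' @param labels Class label per tile.
#' @return A `mean_color_tile_classifier`.
#' @export
fit_tile_classifier <- function(tiles, labels) {
  if (length(tiles) != length(labels)) stop("one label per tile required")
  feats <- t(vapply(tiles, function(tl) apply(tl, 3, mean), numeric(3)))
  colnames(feats) <- c("r", "g", "b")
  df <- data.frame(label = factor(labels), feats)
  fit <- nnet::multinom(label ~ r + g + b, data = df, trace = FALSE)
  structure(
    list(fit = fit, classes = levels(df$label)),
    class = "mean_color_tile_classifier"
  )
}

#' Predict tile classes
#'
#' @param clf A fitted tile classifier.
#' @param tiles List of RGB tile arrays.
#' @return Character vector of predicted classes, one per tile.
#' @export
predict_tiles <- function(clf, tiles) UseMethod("predict_tiles")

#' @export
predict_tiles.mean_color_tile_classifier <- function(clf, tiles) {
  feats <- t(vapply(tiles, function(tl) apply(tl, 3, mean), numeric(3)))
  colnames(feats) <- c("r", "g", "b")
  as.character(stats::predict(clf$fit, newdata = data.frame(feats)))
}

#' Classify a slide with a tile classifier
#'
#' Convenience wrapper: predicts every retained tile, then aggregates with
#' [slide_probabilities()] and [slide_predict_majority()].
#'
#' @param tile_set A [extract_tiles()] result with at least one tile.
#' @param clf A fitted tile classifier.
#' @param classes Ordered class labels.
#' @return List with `probabilities` and `prediction`.
#' @export
classify_slide <- function(tile_set, clf, classes) {
  if (length(tile_set$tiles) == 0) {
    stop("empty slide: no tissue tiles retained")
  }
  preds <- tile_prediction_set(
    tile_set$slide_id, predict_tiles(clf, tile_set$tiles), classes
  )
  list(
    probabilities = slide_probabilities(preds),
    prediction = slide_predict_majority(preds)
  )
}
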