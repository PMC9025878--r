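#' Construct a modality matrix
#'
#' A modality matrix holds one data modality's samples-by-features values
#' together with sample identifiers, the owning patient of each sample, and
#' the class label of each sample. It is the common currency of the feature
#' selection and model-fitting functions.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param patient_ids Character vector, one patient id per row. Several
#'   samples may share a patient (e.g. two slides from one case).
#' @param labels Character vector of class labels, one per row.
#' @param sample_ids Optional sample identifiers; default the patient ids.
#' @param feature_names Optional feature names; default the column names of
#'   `values`.
#' @return An object of class `modality_matrix`.
#' @export
modality_matrix <- function(values, patient_ids, labels,
                            sample_ids = patient_ids,
                            feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (length(patient_ids) != nrow(values)) {
    stop("patient_ids length must equal number of rows")
  }
  if (length(labels) != nrow(values)) {
    stop("labels length must equal number of rows (one label per sample)")
  }
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  colnames(values) <- feature_names
  rownames(values) <- sample_ids
  structure(
    list(
      values = values,
      sample_ids = as.character(sample_ids),
      patient_ids = as.character(patient_ids),
      labels = as.character(labels),
      feature_names = as.character(feature_names)
    ),
    class = "modality_matrix"
  )
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf(
    "<modality_matrix> %d samples x %d features; classes: %s\n",
    nrow(x$values), ncol(x$values),
    paste(names(table(x$labels)), table(x$labels), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

# Subset a modality matrix by row index, keeping metadata aligned.
subset_modality <- function(mm, idx) {
  modality_matrix(
    mm$values[idx, , drop = FALSE],
    patient_ids = mm$patient_ids[idx],
    labels = mm$labels[idx],
    sample_ids = mm$sample_ids[idx],
    feature_names = mm$feature_names
  )
}

# Keep only the named feature columns.
select_features <- function(mm, features) {
  keep <- match(features, mm$feature_names)
  if (anyNA(keep)) stop("unknown feature name(s)")
  modality_matrix(
    mm$values[, keep, drop = FALSE],
    patient_ids = mm$patient_ids,
    labels = mm$labels,
    sample_ids = mm$sample_ids,
    feature_names = mm$feature_names[keep]
  )
}

#' Write / read a modality matrix as TSV
#'
#' The on-disk layout is one row per sample: `patient_id`, `label`, then one
#' column per feature.
#'
#' @param mm A [modality_matrix()].
#' @param path File path.
#' @return `read_modality_tsv` returns a [modality_matrix()].
#' @export
write_modality_tsv <- function(mm, path) {
  df <- data.frame(
    patient_id = mm$patient_ids,
    label = mm$labels,
    mm$values,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modality_tsv
#' @export
read_modality_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  modality_matrix(
    as.matrix(df[, -(1:2), drop = FALSE]),
    patient_ids = df$patient_id,
    labels = df$label
  )
}
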