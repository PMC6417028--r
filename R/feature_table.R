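#' Lesion-by-feature tables
#'
#' A `feature_table` is a data.frame with identifier columns `subject_id`,
#' `lesion_id`, a binary `label` column, and one column per feature. Feature
#' columns are sequence-qualified, e.g. `t2wi::original::glcm::Contrast`.
#'
#' @param features numeric matrix or data.frame of features (columns named).
#' @param labels integer/numeric vector of 0/1 class labels.
#' @param subject_id,lesion_id identifier vectors; defaults enumerate rows.
#' @return A data.frame of class `feature_table`.
#' @export
feature_table <- function(features, labels,
                          subject_id = NULL, lesion_id = NULL) {
  features <- as.data.frame(features, check.names = FALSE)
  n <- nrow(features)
  if (length(labels) != n) stop("labels length must match feature rows")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (anyDuplicated(names(features)))
    stop("duplicate feature names: ",
         paste(unique(names(features)[duplicated(names(features))]), collapse = ", "))
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(n))
  if (is.null(lesion_id)) lesion_id <- sprintf("L%04d", seq_len(n))
  if (anyDuplicated(lesion_id)) stop("lesion_id values must be unique")
  reserved <- c("subject_id", "lesion_id", "label")
  if (any(names(features) %in% reserved))
    stop("feature names may not collide with identifier columns")
  out <- cbind(
    data.frame(subject_id = as.character(subject_id),
               lesion_id = as.character(lesion_id),
               label = as.integer(labels),
               stringsAsFactors = FALSE),
    features
  )
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the numeric feature matrix of a feature table
#' @param table a [feature_table()].
#' @return numeric matrix, rows named by `lesion_id`.
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cols <- setdiff(names(table), c("subject_id", "lesion_id", "label"))
  m <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  rownames(m) <- table$lesion_id
  storage.mode(m) <- "double"
  m
}

#' Read and write feature tables (CSV)
#'
#' CSV round trips preserve values to at least 15 significant digits and
#' column order. The label column is mandatory on read.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return [read_feature_table()] returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (anyDuplicated(names(table))) stop("duplicate column names")
  dt <- data.table::as.data.table(as.data.frame(table))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, check.names = FALSE)
  nm <- names(dt)
  if (anyDuplicated(nm)) stop("duplicate column names in ", path)
  if (!all(c("subject_id", "lesion_id", "label") %in% nm))
    stop("label or identifier column missing in ", path)
  df <- as.data.frame(dt, check.names = FALSE)
  feats <- df[, setdiff(nm, c("subject_id", "lesion_id", "label")), drop = FALSE]
  feature_table(feats, df$label, subject_id = df$subject_id,
                lesion_id = df$lesion_id)
}
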