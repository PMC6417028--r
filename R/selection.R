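#' Variance threshold filter
#'
#' Keeps features whose across-lesion sample variance is at least
#' `threshold` (boundary kept). The threshold operates on raw feature
#' variance, the semantics of the usual variance-threshold preprocessing
#' step; z-scored features would all pass and [0,1]-rescaled features would
#' all fail (a bounded variable has variance at most 0.25), so neither
#' rescaling is applied.
#'
#' @param table a [feature_table()] or plain numeric matrix.
#' @param threshold minimum sample variance.
#' @return Character vector of kept feature names.
#' @export
variance_filter <- function(table, threshold = 0.8) {
  x <- if (inherits(table, "feature_table")) feature_matrix(table) else as.matrix(table)
  if (nrow(x) < 2L) stop("variance undefined for a single-row table")
  v <- apply(x, 2, stats::var)
  colnames(x)[v >= threshold]
}

#' Univariate (select-k-best style) filter
#'
#' Per-feature two-sided Mann-Whitney U test of class 0 versus class 1;
#' features with p > alpha are removed. No multiple-testing correction is
#' applied, matching the usual radiomics preconditioning step (a deliberately
#' liberal pre-filter ahead of the LASSO).
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param labels 0/1 labels (taken from the table when omitted).
#' @param alpha removal threshold; keep p <= alpha.
#' @param features optional subset of feature names to test.
#' @return List with `kept` (names) and `p_values` (named, all tested).
#' @export
univariate_filter <- function(table, labels = NULL, alpha = 0.05,
                              features = NULL) {
  x <- if (inherits(table, "feature_table")) feature_matrix(table) else as.matrix(table)
  if (is.null(labels) && inherits(table, "feature_table")) labels <- table$label
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for the univariate filter")
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[labels == 0, j]
    b <- x[labels == 1, j]
    if (stats::var(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  names(p) <- colnames(x)
  list(kept = colnames(x)[p <= alpha], p_values = p)
}

#' LASSO feature selection
#'
#' L1-penalized least-squares regression of the 0/1 label on internally
#' standardized features over a log-spaced penalty grid; the optimal penalty
#' minimizes subject-grouped cross-validated mean squared error, and the
#' selected features are those with nonzero coefficients at the optimum. The
#' penalty is reported as `alpha` (the name used for the LASSO tuning
#' parameter in the scikit-learn lineage; it equals glmnet's `lambda` for the
#' gaussian objective `RSS/(2n) + alpha * ||w||_1`).
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param labels 0/1 labels (taken from the table when omitted).
#' @param features optional subset of feature names to fit on.
#' @param subjects grouping key for cross-validation folds; lesions of one
#'   subject never straddle folds (taken from the table when omitted).
#' @param cv_folds number of folds.
#' @param alpha_grid optional penalty grid (decreasing); default lets glmnet
#'   choose its log-spaced path.
#' @param seed seed for fold assignment.
#' @return List with `alpha`, `coefficients` (named, nonzero only),
#'   `selected`, and the full `path` (penalties, nonzero counts, cv error).
#' @export
lasso_select <- function(table, labels = NULL, features = NULL,
                         subjects = NULL, cv_folds = 5, alpha_grid = NULL,
                         seed = 1L) {
  x <- if (inherits(table, "feature_table")) feature_matrix(table) else as.matrix(table)
  if (is.null(labels) && inherits(table, "feature_table")) labels <- table$label
  if (is.null(subjects) && inherits(table, "feature_table")) subjects <- table$subject_id
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(x)))
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- as.numeric(labels)
  n <- nrow(x)
  if (n < cv_folds) stop("fewer rows than cross-validation folds")
  if (ncol(x) == 0L)
    return(list(alpha = NA_real_, coefficients = numeric(0),
                selected = character(0), path = NULL))
  # standardize here so reported coefficients refer to unit-variance features
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  set.seed(as.integer(seed))
  subj <- unique(subjects)
  fold_of_subject <- sample(rep_len(seq_len(cv_folds), length(subj)))
  foldid <- fold_of_subject[match(subjects, subj)]
  if (ncol(xs) == 1L) xs <- cbind(xs, `..aux..` = 0)  # glmnet needs >= 2 cols
  cv <- glmnet::cv.glmnet(xs, y, family = "gaussian", alpha = 1,
                          lambda = alpha_grid, foldid = foldid,
                          standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  co <- co[names(co) != "..aux.."]
  nz <- co[co != 0]
  list(alpha = cv$lambda.min,
       coefficients = nz,
       selected = names(nz),
       path = list(alpha = cv$lambda, cv_error = cv$cvm,
                   nonzero = cv$nzero))
}

#' The three-stage selection cascade for one sequence
#'
#' Variance threshold, then the univariate Mann-Whitney filter, then LASSO;
#' stages only ever remove features, so the surviving sets form a subset
#' chain (asserted). An empty survivor set at any stage yields a valid
#' result with an empty selection and a warning; downstream model fitting for
#' that sequence is then skipped.
#'
#' @param table a [feature_table()] restricted to one sequence's columns (or
#'   any feature table).
#' @param labels,subjects optional overrides (taken from the table).
#' @param variance_threshold,p_alpha,cv_folds,alpha_grid,seed stage
#'   parameters.
#' @param sequence tag recorded in the result.
#' @return An object of class `selection_result`: per-stage survivor names,
#'   p-values, LASSO alpha and coefficients, and stage counts.
#' @export
select_pipeline <- function(table, labels = NULL, subjects = NULL,
                            variance_threshold = 0.8, p_alpha = 0.05,
                            cv_folds = 5, alpha_grid = NULL, seed = 1L,
                            sequence = "all") {
  x <- if (inherits(table, "feature_table")) feature_matrix(table) else as.matrix(table)
  if (is.null(labels) && inherits(table, "feature_table")) labels <- table$label
  if (is.null(subjects) && inherits(table, "feature_table")) subjects <- table$subject_id
  n_all <- ncol(x)
  kept_var <- variance_filter(x, variance_threshold)
  p_values <- stats::setNames(numeric(0), character(0))
  kept_uni <- character(0)
  las <- list(alpha = NA_real_, coefficients = numeric(0),
              selected = character(0), path = NULL)
  if (length(kept_var) == 0L) {
    warning("variance filter removed every feature")
  } else {
    uni <- univariate_filter(x[, kept_var, drop = FALSE], labels, alpha = p_alpha)
    p_values <- uni$p_values
    kept_uni <- uni$kept
    if (length(kept_uni) == 0L) {
      warning("univariate filter removed every feature")
    } else {
      las <- lasso_select(x[, kept_uni, drop = FALSE], labels,
                          subjects = subjects, cv_folds = cv_folds,
                          alpha_grid = alpha_grid, seed = seed)
    }
  }
  stopifnot(all(las$selected %in% kept_uni), all(kept_uni %in% kept_var))
  structure(list(
    sequence = sequence,
    names_after_variance = kept_var,
    names_after_univariate = kept_uni,
    p_values = p_values,
    lasso_alpha = las$alpha,
    lasso_coefficients = las$coefficients,
    selected = las$selected,
    lasso_path = las$path,
    counts = c(input = n_all, variance = length(kept_var),
               univariate = length(kept_uni), lasso = length(las$selected))
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s: %d -> %d -> %d -> %d (alpha = %s)>\n",
              x$sequence, x$counts["input"], x$counts["variance"],
              x$counts["univariate"], x$counts["lasso"],
              format(x$lasso_alpha, digits = 4)))
  invisible(x)
}

#' Serialize selection results to JSON
#'
#' @param results a `selection_result` or named list of them.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_selection <- function(results, path) {
  if (inherits(results, "selection_result")) results <- list(results)
  payload <- lapply(results, function(r) {
    list(sequence = r$sequence,
         counts = as.list(r$counts),
         lasso_alpha = r$lasso_alpha,
         selected = r$selected,
         coefficients = as.list(r$lasso_coefficients),
         names_after_variance = r$names_after_variance,
         names_after_univariate = r$names_after_univariate,
         p_values = as.list(r$p_values))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
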