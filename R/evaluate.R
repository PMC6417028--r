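#' Subject-grouped, class-stratified train/test split
#'
#' Randomly assigns roughly `test_fraction` of each class's subjects to the
#' test side; all lesions of a subject stay on one side, so multi-lesion
#' patients can never leak between training and testing. (A lesion-level
#' split - the literal "randomly selecting 80% of the samples" procedure -
#' is available with `group_by_subject = FALSE`.)
#'
#' @param manifest a `cohort_manifest`, [feature_table()], or any data.frame
#'   with `subject_id`, `lesion_id`, `label`.
#' @param test_fraction fraction of subjects (per class) held out.
#' @param seed integer seed.
#' @param group_by_subject keep subjects intact (default) or split lesions.
#' @return An object of class `split_plan` with `train` and `test` lesion
#'   ids, the seed, and the grouping key.
#' @export
split_cohort <- function(manifest, test_fraction = 0.2, seed = 1L,
                         group_by_subject = TRUE) {
  df <- as.data.frame(manifest)
  stopifnot(all(c("subject_id", "lesion_id", "label") %in% names(df)))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  if (group_by_subject) {
    subj <- unique(df[, c("subject_id", "label")])
    if (anyDuplicated(subj$subject_id))
      subj <- subj[!duplicated(subj$subject_id), ]  # mixed-class subject: first label
    test_subjects <- character(0)
    for (cl in c(0, 1)) {
      s <- subj$subject_id[subj$label == cl]
      if (length(s) < 2L)
        stop("impossible stratification: need >= 2 subjects per class")
      k <- max(1L, round(test_fraction * length(s)))
      test_subjects <- c(test_subjects, sample(s, k))
    }
    test_ids <- df$lesion_id[df$subject_id %in% test_subjects]
  } else {
    test_ids <- character(0)
    for (cl in c(0, 1)) {
      l <- df$lesion_id[df$label == cl]
      if (length(l) < 2L) stop("impossible stratification: need >= 2 lesions per class")
      test_ids <- c(test_ids, sample(l, max(1L, round(test_fraction * length(l)))))
    }
  }
  train_ids <- setdiff(df$lesion_id, test_ids)
  structure(list(train = train_ids, test = test_ids, seed = as.integer(seed),
                 grouping = if (group_by_subject) "subject" else "lesion"),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d train / %d test lesions, grouped by %s>\n",
              length(x$train), length(x$test), x$grouping))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney statistic: the probability that a random
#' class-1 score exceeds a random class-0 score, ties counted one half. The
#' curve has a vertex at every distinct threshold.
#'
#' @param scores numeric scores (higher = more class-1).
#' @param labels 0/1 labels; both classes required.
#' @return List of class `roc_curve`: `auc`, and vectors `threshold`,
#'   `sensitivity`, `specificity` over all distinct thresholds (decision rule
#'   `score >= threshold`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1) / m, numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & labels == 0) / n, numeric(1))
  structure(list(auc = auc, threshold = th, sensitivity = sens,
                 specificity = spec), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.4f over %d thresholds>\n", x$auc,
              length(x$threshold)))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Maximizes sensitivity + specificity - 1; ties are broken toward higher
#' sensitivity. The threshold is reported in score units.
#'
#' @param roc a [roc_auc()] curve.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  youden <- roc$sensitivity + roc$specificity - 1
  best <- which(youden == max(youden))
  best <- best[which.max(roc$sensitivity[best])]
  list(threshold = roc$threshold[best], sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best], youden = youden[best])
}

# DeLong placements: V10[i] = P(score_i > controls) with ties = 1/2
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), theta = mean(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same test lesions
#' (two-sided). When the variance of the AUC difference degenerates (e.g.
#' identical scores), p = 1 is returned with the `degenerate` flag.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @return List with `p_value`, `auc_a`, `auc_b`, `variance`, `degenerate`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(v) || v <= 0)
    return(list(p_value = 1, auc_a = pa$theta, auc_b = pb$theta,
                variance = v, degenerate = TRUE))
  z <- (pa$theta - pb$theta) / sqrt(v)
  list(p_value = 2 * stats::pnorm(-abs(z)), auc_a = pa$theta,
       auc_b = pb$theta, variance = v, degenerate = FALSE)
}

# column subset of one sequence
sequence_columns <- function(table, sequence) {
  grep(paste0("^", sequence, "::"), names(table), value = TRUE)
}

#' Evaluate the full classifier grid on a feature table
#'
#' Runs the complete modelling protocol: subject-grouped stratified split,
#' per-sequence three-stage feature selection on training rows only, training
#' of the four classifiers per sequence and on the combined (concatenated
#' selected features of all sequences) model, and ROC analysis on the held-out
#' test lesions. No test information reaches selection or fitting; classifier
#' standardization uses training statistics only. Sequences whose selection
#' ends empty yield unavailable cells (recorded, never silently dropped).
#'
#' @param table a [feature_table()] whose feature columns are
#'   sequence-qualified (`<sequence>::...`).
#' @param sequences sequence prefixes to model.
#' @param classifiers classifier kinds.
#' @param test_fraction,seed split parameters.
#' @param variance_threshold,p_alpha,cv_folds selection parameters.
#' @param group_by_subject see [split_cohort()].
#' @param split optional precomputed [split_cohort()] plan; when supplied the
#'   split parameters are ignored.
#' @return An object of class `evaluation_report`: `cells` (one row per
#'   sequence x classifier), `selection` (per-sequence `selection_result`),
#'   `pairwise` (DeLong p-values), `split`, and `provenance`.
#' @export
evaluate_all <- function(table,
                         sequences = c("inphase", "outphase", "t2wi", "dwi"),
                         classifiers = CLASSIFIER_KINDS,
                         test_fraction = 0.2, seed = 1L,
                         variance_threshold = 0.8, p_alpha = 0.05,
                         cv_folds = 5, group_by_subject = TRUE,
                         split = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(split)) {
    split <- split_cohort(table, test_fraction = test_fraction, seed = seed,
                          group_by_subject = group_by_subject)
  } else {
    stopifnot(inherits(split, "split_plan"),
              setequal(c(split$train, split$test), table$lesion_id))
  }
  tr <- table[table$lesion_id %in% split$train, ]
  te <- table[table$lesion_id %in% split$test, ]
  class(tr) <- class(te) <- class(table)
  xtr_all <- feature_matrix(tr)
  xte_all <- feature_matrix(te)
  ytr <- tr$label; yte <- te$label
  if (length(unique(yte)) < 2L) stop("test side lost a class; use more subjects")

  selection <- list()
  selected_by_seq <- list()
  for (sq in sequences) {
    cols <- sequence_columns(table, sq)
    if (length(cols) == 0L) stop("no columns found for sequence ", sq)
    selection[[sq]] <- suppressWarnings(select_pipeline(
      xtr_all[, cols, drop = FALSE], labels = ytr, subjects = tr$subject_id,
      variance_threshold = variance_threshold, p_alpha = p_alpha,
      cv_folds = cv_folds, seed = seed, sequence = sq))
    selected_by_seq[[sq]] <- selection[[sq]]$selected
  }
  selected_by_seq[["combined"]] <- unlist(selected_by_seq[sequences],
                                          use.names = FALSE)

  cells <- list()
  scores_by_cell <- list()
  for (sq in c(sequences, "combined")) {
    feats <- selected_by_seq[[sq]]
    for (kind in classifiers) {
      cell_id <- paste(sq, kind, sep = ".")
      if (length(feats) == 0L) {
        cells[[cell_id]] <- data.frame(
          sequence = sq, classifier = kind, available = FALSE,
          auc = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
          threshold = NA_real_, n_features = 0L,
          n_train = nrow(tr), n_test = nrow(te), stringsAsFactors = FALSE)
        next
      }
      model <- train_classifier(kind, xtr_all[, feats, drop = FALSE], ytr,
                                seed = seed)
      sc <- predict_scores(model, xte_all)
      roc <- roc_auc(sc, yte)
      op <- operating_point(roc)
      scores_by_cell[[cell_id]] <- sc
      cells[[cell_id]] <- data.frame(
        sequence = sq, classifier = kind, available = TRUE,
        auc = roc$auc, sensitivity = op$sensitivity,
        specificity = op$specificity, threshold = op$threshold,
        n_features = length(feats),
        n_train = nrow(tr), n_test = nrow(te), stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL

  # pairwise AUC comparisons: sequences within each classifier, classifiers
  # within the combined model
  pairs <- list()
  add_pair <- function(a, b) {
    if (!is.null(scores_by_cell[[a]]) && !is.null(scores_by_cell[[b]])) {
      cmp <- compare_auc(scores_by_cell[[a]], scores_by_cell[[b]], yte)
      pairs[[length(pairs) + 1L]] <<- data.frame(
        model_a = a, model_b = b, auc_a = cmp$auc_a, auc_b = cmp$auc_b,
        p_value = cmp$p_value, degenerate = cmp$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  for (kind in classifiers) {
    sqs <- c(sequences, "combined")
    for (i in seq_along(sqs)) for (j in seq_len(i - 1L))
      add_pair(paste(sqs[j], kind, sep = "."), paste(sqs[i], kind, sep = "."))
  }
  pairwise <- if (length(pairs)) do.call(rbind, pairs) else NULL

  structure(list(
    cells = cells, selection = selection, pairwise = pairwise, split = split,
    provenance = list(
      sequences = sequences, classifiers = classifiers,
      test_fraction = test_fraction, seed = seed,
      variance_threshold = variance_threshold, p_alpha = p_alpha,
      cv_folds = cv_folds, group_by_subject = group_by_subject,
      n_lesions = nrow(table), timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("ROC analysis on the testing set\n")
  for (kind in unique(x$cells$classifier)) {
    cat(sprintf("\n%s\n", kind))
    sub <- x$cells[x$cells$classifier == kind,
                   c("sequence", "auc", "sensitivity", "specificity")]
    sub[, 2:4] <- round(sub[, 2:4], 3)
    names(sub) <- c("Images", "AUC", "Sensitivity", "Specificity")
    print(sub, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_all()] report.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    cells = report$cells,
    pairwise = report$pairwise,
    split = list(train = report$split$train, test = report$split$test,
                 seed = report$split$seed, grouping = report$split$grouping),
    selection = lapply(report$selection, function(r)
      list(sequence = r$sequence, counts = as.list(r$counts),
           lasso_alpha = r$lasso_alpha, selected = r$selected)),
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
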