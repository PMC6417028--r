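CLASSIFIER_KINDS <- c("decision_tree", "random_forest", "knn",
                      "logistic_regression")

# ---- CART (Gini) ------------------------------------------------------------
# Small purpose-built implementation: binary splits on numeric features,
# Gini impurity, bounded depth. Leaves store the class-1 proportion so every
# model yields a continuous score.

gini_best_split <- function(x, y, min_leaf) {
  n <- length(y)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  k <- seq_len(n - 1L)
  valid <- xs[k] < xs[k + 1L] & k >= min_leaf & (n - k) >= min_leaf
  if (!any(valid)) return(NULL)
  nl <- k; nr <- n - k
  l1 <- cum1[k]; r1 <- n1 - l1
  gini <- nl / n * (1 - (l1 / nl)^2 - (1 - l1 / nl)^2) +
    nr / n * (1 - (r1 / nr)^2 - (1 - r1 / nr)^2)
  gini[!valid] <- Inf
  b <- which.min(gini)
  list(threshold = (xs[b] + xs[b + 1L]) / 2, gini = gini[b])
}

cart_grow <- function(x, y, depth, max_depth, min_split, min_leaf, mtry) {
  n <- length(y)
  p1 <- mean(y)
  if (depth >= max_depth || n < min_split || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, score = p1, n = n))
  p <- ncol(x)
  cand <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  parent_gini <- 1 - p1^2 - (1 - p1)^2
  best <- NULL
  for (j in cand) {
    s <- gini_best_split(x[, j], y, min_leaf)
    if (!is.null(s) && (is.null(best) || s$gini < best$gini)) {
      best <- s; best$feature <- j
    }
  }
  if (is.null(best) || best$gini >= parent_gini - 1e-12)
    return(list(leaf = TRUE, score = p1, n = n))
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n = n,
       left = cart_grow(x[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_split, min_leaf, mtry),
       right = cart_grow(x[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_split, min_leaf, mtry))
}

cart_predict <- function(node, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$score
      return()
    }
    left <- x[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(node, seq_len(nrow(x)))
  out
}

# ---- user-facing training ---------------------------------------------------

#' Train one of the four classifiers
#'
#' Fixed, documented hyperparameters (the emulated study states none):
#' decision tree - CART with Gini impurity, maximum depth 5, minimum split
#' size 4; random forest - 100 bagged CART trees of depth up to 10 with
#' `mtry = floor(sqrt(p))` features considered per node, scored by the mean
#' leaf class-1 proportion; k-nearest-neighbours - k = 5 on standardized
#' features, scored by the neighbour class-1 fraction; logistic regression -
#' ridge (L2) penalized with penalty `1/n` (the unit-regularization
#' convention). Features are standardized with training-set statistics only;
#' the same statistics are reused at prediction time.
#'
#' @param kind one of `"decision_tree"`, `"random_forest"`, `"knn"`,
#'   `"logistic_regression"`.
#' @param x numeric matrix of training features (columns named).
#' @param y 0/1 labels.
#' @param seed integer seed (bootstrap and node subsampling).
#' @return An object of class `lesion_classifier`.
#' @export
train_classifier <- function(kind, x, y, seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (ncol(x) == 0L) stop("no features selected: cannot train")
  if (length(unique(y)) < 2L) stop("both classes required in training data")
  storage.mode(x) <- "double"
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  set.seed(as.integer(seed))
  model <- switch(kind,
    decision_tree = cart_grow(xs, y, 0L, max_depth = 5L, min_split = 4L,
                              min_leaf = 1L, mtry = ncol(xs)),
    random_forest = {
      n <- nrow(xs)
      mtry <- max(1L, floor(sqrt(ncol(xs))))
      lapply(seq_len(100L), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cart_grow(xs[idx, , drop = FALSE], y[idx], 0L, max_depth = 10L,
                  min_split = 2L, min_leaf = 1L, mtry = mtry)
      })
    },
    knn = list(train = xs, y = y, k = 5L),
    logistic_regression = {
      xg <- if (ncol(xs) == 1L) cbind(xs, `..aux..` = 0) else xs
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(xs), standardize = FALSE)
    }
  )
  structure(list(kind = kind, model = model, center = mu, scale = sdv,
                 features = colnames(x), seed = seed),
            class = "lesion_classifier")
}

#' @export
print.lesion_classifier <- function(x, ...) {
  cat(sprintf("<lesion_classifier %s on %d features>\n", x$kind,
              length(x$features)))
  invisible(x)
}

#' Continuous class-1 scores of a fitted classifier
#'
#' @param model a [train_classifier()] fit.
#' @param x feature matrix; columns must cover the training features.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "lesion_classifier"))
  x <- as.matrix(x)
  if (!all(model$features %in% colnames(x)))
    stop("feature columns do not match the training features")
  x <- x[, model$features, drop = FALSE]
  storage.mode(x) <- "double"
  xs <- scale(x, center = model$center, scale = model$scale)
  out <- switch(model$kind,
    decision_tree = cart_predict(model$model, xs),
    random_forest = {
      per_tree <- vapply(model$model, cart_predict, numeric(nrow(xs)), x = xs)
      rowMeans(matrix(per_tree, nrow = nrow(xs)))
    },
    knn = {
      nn <- FNN::get.knnx(model$model$train, xs, k = model$model$k)
      rowMeans(matrix(model$model$y[nn$nn.index], nrow(xs)))
    },
    logistic_regression = {
      xg <- if (length(model$features) == 1L) cbind(xs, `..aux..` = 0) else xs
      as.numeric(stats::predict(model$model, xg, type = "response"))
    }
  )
  pmin(pmax(out, 0), 1)
}
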