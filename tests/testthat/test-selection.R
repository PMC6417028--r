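test_that("variance filter: zero-variance removed, boundary kept, chi-square tail", {
  set.seed(61)
  x <- cbind(const = rep(2, 60), wide = rnorm(60, sd = 3), narrow = rnorm(60, sd = 0.1))
  kept <- variance_filter(x, 0.8)
  expect_false("const" %in% kept)
  expect_true("wide" %in% kept)
  expect_false("narrow" %in% kept)

  # exact-boundary convention: variance == threshold is kept
  b <- c(scale(rnorm(40)))            # unit sample variance
  b <- b * sqrt(0.8)
  xb <- cbind(boundary = b)
  expect_identical(variance_filter(xb, 0.8), "boundary")
  expect_error(variance_filter(x[1, , drop = FALSE]), "single-row")

  # standard-normal features: kept fraction ~ P(S^2 >= 0.8), S^2 ~ chi2_{n-1}/(n-1)
  n <- 50
  xs <- matrix(rnorm(n * 4000), n)
  colnames(xs) <- paste0("f", 1:4000)
  frac <- length(variance_filter(xs, 0.8)) / 4000
  p_theory <- stats::pchisq(0.8 * (n - 1), df = n - 1, lower.tail = FALSE)
  expect_equal(frac, p_theory, tolerance = 0.03)
})

test_that("univariate filter keeps separated features and is calibrated under the null", {
  set.seed(62)
  n <- 40
  labels <- rep(c(0L, 1L), each = 20)
  sep <- c(rnorm(20, 0, 0.2), rnorm(20, 10, 0.2))       # perfectly separated
  same <- rep(1:8, 5)                                    # identical distribution
  x <- cbind(sep = sep, same = same, noise = rnorm(n))
  res <- univariate_filter(x, labels, alpha = 0.05)
  expect_true("sep" %in% res$kept)
  expect_false("same" %in% res$kept)
  expect_lt(res$p_values[["sep"]], 1e-6)
  expect_error(univariate_filter(x, rep(1L, n)), "both classes")

  # type-I calibration over label permutations
  set.seed(63)
  xr <- matrix(rnorm(200 * 60), 200)
  colnames(xr) <- paste0("f", 1:60)
  rates <- vapply(1:100, function(i) {
    length(univariate_filter(xr, sample(rep(c(0L, 1L), each = 100)),
                             alpha = 0.05)$kept) / 60
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("LASSO: full shrinkage at huge alpha, OLS at zero penalty", {
  set.seed(64)
  x <- matrix(rnorm(100 * 5), 100)
  colnames(x) <- paste0("f", 1:5)
  y <- rbinom(100, 1, stats::plogis(1.5 * x[, 1]))
  big <- lasso_select(x, y, alpha_grid = c(10, 9.99), cv_folds = 5, seed = 1)
  expect_length(big$selected, 0L)

  near0 <- lasso_select(x, y, alpha_grid = c(1, 1e-8), cv_folds = 5, seed = 1)
  xs <- scale(x)
  ols <- stats::coef(stats::lm(y ~ xs))[-1]
  expect_equal(unname(near0$coefficients[paste0("f", 1:5)]), unname(ols),
               tolerance = 1e-5)
})

test_that("LASSO recovers planted informative features across seeds", {
  hits <- 0L; false_sel <- integer(0)
  for (s in 1:5) {
    ft <- simulate_feature_table(n_lesions = 200, n_features = 100,
                                 n_informative = 3, effect_size = 2,
                                 sequences = "t2wi", seed = 70 + s)
    res <- lasso_select(ft, seed = s)
    hits <- hits + sum(grepl("::informative::", res$selected))
    false_sel <- c(false_sel, sum(grepl("::noise::", res$selected)))
  }
  expect_gte(hits, 14L)                  # >= 90% of 15
  expect_lte(stats::median(false_sel), 5)
})

test_that("the cascade preserves the subset chain and handles empty survivors", {
  ft <- simulate_feature_table(n_lesions = 120, n_features = 60,
                               n_informative = 3, effect_size = 2,
                               sequences = "dwi", seed = 81)
  sel <- select_pipeline(ft, sequence = "dwi", seed = 81)
  expect_true(all(sel$selected %in% sel$names_after_univariate))
  expect_true(all(sel$names_after_univariate %in% sel$names_after_variance))
  ct <- sel$counts
  expect_true(all(diff(ct) <= 0))
  expect_identical(ct[["input"]], 60L)
  expect_s3_class(sel, "selection_result")

  # all features constant: empty at stage 1, valid empty result with warning
  xc <- matrix(1, 30, 5); colnames(xc) <- paste0("c", 1:5)
  expect_warning(empty <- select_pipeline(xc, labels = rep(c(0L, 1L), 15)),
                 "removed every feature")
  expect_length(empty$selected, 0L)
  expect_true(is.na(empty$lasso_alpha))
})

test_that("selection is deterministic and invariant to feature column order", {
  ft <- simulate_feature_table(n_lesions = 150, n_features = 40,
                               n_informative = 2, effect_size = 2,
                               sequences = "t2wi", seed = 91)
  x <- feature_matrix(ft)
  s1 <- select_pipeline(x, labels = ft$label, subjects = ft$subject_id, seed = 4)
  s2 <- select_pipeline(x, labels = ft$label, subjects = ft$subject_id, seed = 4)
  expect_identical(s1$selected, s2$selected)
  expect_equal(s1$lasso_alpha, s2$lasso_alpha)
  perm <- sample(ncol(x))
  s3 <- select_pipeline(x[, perm], labels = ft$label, subjects = ft$subject_id,
                        seed = 4)
  expect_setequal(s3$selected, s1$selected)
})

test_that("selection results serialize to JSON", {
  ft <- simulate_feature_table(n_lesions = 80, n_features = 20,
                               n_informative = 1, effect_size = 2.5,
                               sequences = "t2wi", seed = 95)
  sel <- select_pipeline(ft, sequence = "t2wi", seed = 95)
  p <- tempfile(fileext = ".json")
  write_selection(sel, p)
  back <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_equal(back[[1]]$sequence, "t2wi")
  expect_equal(unlist(back[[1]]$counts), sel$counts)
  expect_setequal(unlist(back[[1]]$selected), sel$selected)
})
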