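# scaled-down spec used throughout: small grids keep image tests fast
small_spec <- function(lesion_radius_range_mm = c(4, 7), ...) {
  phantom_spec(n_subjects = 10, lesions_per_subject_range = c(1, 1),
               grid_shape = c(20, 20, 8),
               lesion_radius_range_mm = lesion_radius_range_mm, ...)
}

test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(n_subjects = 1), "n_subjects")
  expect_error(phantom_spec(class_balance = 0), "strictly between")
  expect_error(phantom_spec(class_balance = 1), "strictly between")
  expect_error(phantom_spec(spacing_mm = c(1, 1, 0)), "positive")
  expect_error(small_spec(lesion_radius_range_mm = c(4, 40)), "degenerate spec")
  expect_error(phantom_spec(class_effects = list(
    mean_shift = c(inphase = 0, outphase = 0, t2wi = 0, dwi = 0),
    heterogeneity = 0.5)), "heterogeneity")
})

test_that("lesion generation is deterministic and structurally sound", {
  spec <- small_spec(seed = 5)
  l1 <- generate_lesion(spec, 1, seed = 77)
  l2 <- generate_lesion(spec, 1, seed = 77)
  expect_identical(l1$mask$values, l2$mask$values)
  for (sq in names(l1$volumes))
    expect_identical(l1$volumes[[sq]]$values, l2$volumes[[sq]]$values)
  expect_gte(sum(l1$mask$values), 27L)
  expect_length(l1$volumes, 4L)
  for (sq in names(l1$volumes))
    expect_true(check_alignment(l1$volumes[[sq]], l1$mask))
  # mask is 26-connected
  d <- suppressWarnings(discretize(l1$volumes$t2wi, l1$mask, 2))
  d$levels[!is.na(d$levels)] <- 1L
  tm <- glszm_matrix(d)
  expect_equal(sum(tm$counts > 0), 1L)
})

test_that("null class effects make the two classes distributionally identical", {
  spec <- small_spec(class_effects = null_effects(), seed = 3)
  l0 <- generate_lesion(spec, 0, seed = 123)
  l1 <- generate_lesion(spec, 1, seed = 123)
  for (sq in names(l0$volumes))
    expect_identical(l0$volumes[[sq]]$values, l1$volumes[[sq]]$values)
})

test_that("heterogeneity multiplier raises within-mask variance (Monte Carlo)", {
  base <- list(mean_shift = c(inphase = 0, outphase = 0, t2wi = 0, dwi = 0))
  v_at <- function(h, seeds) {
    spec <- small_spec(class_effects = c(base, heterogeneity = h), seed = 1)
    vapply(seeds, function(s) {
      l <- generate_lesion(spec, 1, seed = s)
      stats::var(l$volumes$t2wi$values[l$mask$values])
    }, numeric(1))
  }
  seeds <- 1:50
  v1 <- v_at(1, seeds)
  v3 <- v_at(3, seeds)
  expect_gt(mean(v3), mean(v1))
  expect_gt(mean(v3 > v1), 0.9)     # strictly larger in almost every replicate
})

test_that("cohort generation writes correct bookkeeping and is reproducible", {
  spec <- small_spec(class_balance = 0.5, seed = 7)
  td1 <- tempfile(); td2 <- tempfile()
  m1 <- generate_cohort(spec, td1)
  m2 <- generate_cohort(spec, td2)
  expect_equal(nrow(m1), 10L)
  expect_length(list.files(td1, pattern = "_((inphase|outphase|t2wi|dwi))\\.nii\\.gz$"), 40L)
  expect_length(list.files(td1, pattern = "_mask\\.nii\\.gz$"), 10L)
  expect_false(anyDuplicated(m1$lesion_id) > 0)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$lesion_id, m2$lesion_id)
  # identical file checksums across reruns
  read_all <- function(p) {
    con <- gzfile(p, "rb")
    on.exit(close(con))
    readBin(con, "raw", 4e5)
  }
  for (f in c(m1$t2wi[1], m1$mask[3])) {
    g <- file.path(td2, basename(f))
    expect_identical(read_all(f), read_all(g))
  }
  rt <- read_manifest(file.path(td1, "manifest.csv"))
  expect_identical(rt$lesion_id, m1$lesion_id)
  unlink(c(td1, td2), recursive = TRUE)
})

test_that("class-1 prevalence stays within the binomial 99.9% interval", {
  spec <- phantom_spec(n_subjects = 400, class_balance = 0.5, seed = 13)
  set.seed(spec$seed)
  labels <- stats::rbinom(spec$n_subjects, 1, spec$class_balance)
  expect_gte(sum(labels), 170)
  expect_lte(sum(labels), 230)
})

test_that("null-effect image cohorts give test AUC consistent with 0.5", {
  # scaled down for runtime: one sequence, original features only, simple
  # univariate + logistic model downstream, 20 seeds
  aucs <- vapply(1:20, function(s) {
    spec <- phantom_spec(n_subjects = 16, lesions_per_subject_range = c(1, 1),
                         grid_shape = c(14, 14, 6),
                         lesion_radius_range_mm = c(3, 5),
                         class_effects = null_effects(), seed = 100 + s)
    set.seed(spec$seed)
    labels <- stats::rbinom(16, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    feats <- t(vapply(seq_along(labels), function(i) {
      l <- generate_lesion(spec, labels[i], seed = 1000 * s + i)
      extract_original(l$volumes$t2wi, l$mask,
                       extract_config(n_bins = 8, smooth_iterations = 5))
    }, numeric(93)))
    tr <- 1:12; te <- 13:16
    if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2)
      return(NA_real_)
    keep <- apply(feats[tr, ], 2, stats::var) > 0
    model <- suppressWarnings(
      train_classifier("logistic_regression", feats[tr, keep], labels[tr],
                       seed = s))
    roc_auc(predict_scores(model, feats[te, keep]), labels[te])$auc
  }, numeric(1))
  aucs <- aucs[!is.na(aucs)]
  expect_gte(length(aucs), 10)
  ci <- mean(aucs) + c(-1, 1) * 1.96 * stats::sd(aucs) / sqrt(length(aucs))
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("larger configured mean shift never decreases downstream AUC", {
  # 3 effect levels x 4 seeds, one sequence, first-order mean as the readout
  auc_at <- function(shift, s) {
    spec <- phantom_spec(n_subjects = 20, lesions_per_subject_range = c(1, 1),
                         grid_shape = c(14, 14, 6),
                         lesion_radius_range_mm = c(3, 5),
                         class_effects = list(
                           mean_shift = c(inphase = 0, outphase = 0,
                                          t2wi = shift, dwi = 0),
                           heterogeneity = 1),
                         seed = 200 + s)
    set.seed(spec$seed)
    labels <- rep(c(0L, 1L), 10)
    means <- vapply(seq_along(labels), function(i) {
      l <- generate_lesion(spec, labels[i], seed = 5000 * s + i)
      mean(l$volumes$t2wi$values[l$mask$values])
    }, numeric(1))
    roc_auc(means, labels)$auc
  }
  seeds <- 1:4
  m0 <- mean(vapply(seeds, function(s) auc_at(0, s), numeric(1)))
  m1 <- mean(vapply(seeds, function(s) auc_at(1.5, s), numeric(1)))
  m2 <- mean(vapply(seeds, function(s) auc_at(3, s), numeric(1)))
  expect_lte(m0, m1 + 0.05)
  expect_lte(m1, m2 + 0.05)
  expect_gt(m2, 0.9)
})

test_that("feature-level simulator plants the requested structure", {
  ft <- simulate_feature_table(n_lesions = 300, n_features = 50,
                               n_informative = 2, effect_size = 1.5,
                               sequences = c("t2wi", "dwi"), seed = 5)
  x <- feature_matrix(ft)
  expect_equal(dim(x), c(300L, 100L))
  inf <- grep("::informative::", colnames(x))
  expect_length(inf, 4L)
  d <- colMeans(x[ft$label == 1, inf]) - colMeans(x[ft$label == 0, inf])
  expect_equal(unname(d), rep(1.5, 4), tolerance = 0.35)
  noise <- grep("::noise::", colnames(x))[1:5]
  dn <- colMeans(x[ft$label == 1, noise]) - colMeans(x[ft$label == 0, noise])
  expect_lt(max(abs(dn)), 0.5)
})
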