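test_that("split arithmetic, stratification and subject grouping", {
  df <- data.frame(subject_id = sprintf("S%02d", 1:10),
                   lesion_id = sprintf("L%02d", 1:10),
                   label = rep(c(0L, 1L), 5))
  sp <- split_cohort(df, 0.2, seed = 3)
  expect_length(sp$test, 2L)
  expect_length(sp$train, 8L)
  expect_setequal(c(sp$train, sp$test), df$lesion_id)
  expect_identical(sort(df$label[df$lesion_id %in% sp$test]), c(0L, 1L))

  # a 3-lesion subject never splits across sides
  df3 <- data.frame(subject_id = c(rep("S01", 3), sprintf("S%02d", 2:9)),
                    lesion_id = sprintf("L%02d", 1:11),
                    label = c(rep(1L, 3), rep(c(0L, 1L), 4)))
  for (s in 1:20) {
    sp3 <- split_cohort(df3, 0.25, seed = s)
    side <- c("L01", "L02", "L03") %in% sp3$test
    expect_true(all(side) || !any(side))
  }
  expect_error(split_cohort(df[df$label == 0, ], 0.2, 1), "stratification")

  # moving a subject across sides changes the plan
  sp_a <- split_cohort(df3, 0.25, seed = 1)
  sp_b <- split_cohort(df3, 0.25, seed = 2)
  expect_false(identical(sort(sp_a$test), sort(sp_b$test)) &&
                 identical(sp_a$seed, sp_b$seed))
})

test_that("test fraction concentrates near 20% over seeds on a realistic cohort", {
  set.seed(100)
  n_subj <- 180
  counts <- sample(1:3, n_subj, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  df <- data.frame(subject_id = rep(sprintf("S%03d", 1:n_subj), counts),
                   label = rep(rbinom(n_subj, 1, 0.5), counts))
  df$lesion_id <- sprintf("L%03d", seq_len(nrow(df)))
  fr <- vapply(1:50, function(s)
    length(split_cohort(df, 0.2, seed = s)$test) / nrow(df), numeric(1))
  expect_equal(mean(fr), 0.2, tolerance = 0.02)
  expect_true(all(abs(fr - 0.2) < 0.08))
})

test_that("all four classifiers fit separable data and are deterministic", {
  sep <- separable_xy()
  for (k in c("decision_tree", "random_forest", "knn", "logistic_regression")) {
    m <- train_classifier(k, sep$x, sep$y, seed = 2)
    sc <- predict_scores(m, sep$x)
    expect_true(all(sc >= 0 & sc <= 1), info = k)
    expect_equal(mean((sc > 0.5) == sep$y), 1, info = k)
    # duplicated rows get identical scores
    dup <- rbind(sep$x[1, , drop = FALSE], sep$x[1, , drop = FALSE])
    expect_equal(diff(predict_scores(m, dup)), 0, info = k)
    m2 <- train_classifier(k, sep$x, sep$y, seed = 2)
    expect_equal(predict_scores(m2, sep$x), sc, info = k)
  }
  expect_error(train_classifier("knn", sep$x[, 0], sep$y), "no features")
  expect_error(train_classifier("knn", sep$x, rep(1L, nrow(sep$x))),
               "both classes")
  m <- train_classifier("knn", sep$x, sep$y)
  expect_error(predict_scores(m, matrix(1, 2, 2,
                                        dimnames = list(NULL, c("u", "v")))),
               "match")
})

test_that("logistic regression recovers a monotone score in one strong feature", {
  set.seed(102)
  x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "f"))
  y <- rbinom(200, 1, stats::plogis(3 * x[, 1]))
  m <- train_classifier("logistic_regression", x, y, seed = 1)
  grid <- matrix(seq(-2, 2, length.out = 9), ncol = 1,
                 dimnames = list(NULL, "f"))
  sc <- predict_scores(m, grid)
  expect_true(all(diff(sc) > 0))
})

test_that("ROC/AUC matches enumeration and handles boundary cases", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(103)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    sc <- round(runif(n), 2)              # ties likely
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb), info = i)
  }
})

test_that("operating point maximizes Youden with sensitivity tie-break", {
  roc <- roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), c(1, 1, 1, 0, 0, 0))
  op <- operating_point(roc)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_true(op$threshold > 0.3 && op$threshold <= 0.7)
  # symmetric random scores: sens + spec stays near 1
  set.seed(104)
  mean_youden <- mean(vapply(1:40, function(i) {
    r <- roc_auc(runif(60), rep(c(0, 1), 30))
    operating_point(r)$youden
  }, numeric(1)))
  expect_lt(mean_youden, 0.45)
})

test_that("DeLong comparison: identity, power, and bootstrap agreement", {
  set.seed(105)
  l <- rep(c(0L, 1L), each = 100)
  s <- runif(200)
  expect_equal(compare_auc(s, s, l)$p_value, 1)
  expect_true(compare_auc(s, s, l)$degenerate)

  # power: strong vs independent null scores
  hits <- vapply(1:40, function(i) {
    strong <- l + rnorm(200, sd = 0.5)
    null <- rnorm(200)
    compare_auc(strong, null, l)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # DeLong variance of a single AUC difference vs bootstrap
  strong <- l + rnorm(200, sd = 0.8)
  weak <- l + rnorm(200, sd = 2.5)
  v_delong <- compare_auc(strong, weak, l)$variance
  boots <- vapply(1:400, function(b) {
    idx <- sample(200, replace = TRUE)
    if (length(unique(l[idx])) < 2) return(NA_real_)
    roc_auc(strong[idx], l[idx])$auc - roc_auc(weak[idx], l[idx])$auc
  }, numeric(1))
  v_boot <- stats::var(boots, na.rm = TRUE)
  expect_lt(abs(v_delong - v_boot), 0.2 * max(v_delong, v_boot))
})

test_that("evaluate_all fills the 20-cell grid without test leakage", {
  ft <- simulate_feature_table(n_lesions = 160, n_features = 60,
                               n_informative = 3, effect_size = 2, seed = 106)
  rep1 <- suppressWarnings(evaluate_all(ft, seed = 106))
  expect_equal(nrow(rep1$cells), 20L)
  expect_setequal(unique(rep1$cells$sequence),
                  c("inphase", "outphase", "t2wi", "dwi", "combined"))
  expect_true(all(rep1$cells$auc[rep1$cells$available] >= 0 &
                    rep1$cells$auc[rep1$cells$available] <= 1))
  # combined = concatenation of per-sequence selections
  n_comb <- rep1$cells$n_features[rep1$cells$sequence == "combined"][1]
  expect_equal(n_comb, sum(vapply(rep1$selection, function(s)
    length(s$selected), integer(1))))

  # no leakage: shuffling test labels leaves training artifacts identical
  sp <- rep1$split
  ft2 <- ft
  te_rows <- ft2$lesion_id %in% sp$test
  set.seed(1); ft2$label[te_rows] <- sample(ft2$label[te_rows])
  # guard: keep both classes on test side for the run to complete
  if (length(unique(ft2$label[te_rows])) < 2)
    ft2$label[which(te_rows)[1:2]] <- c(0L, 1L)
  rep2 <- suppressWarnings(evaluate_all(ft2, seed = 106, split = sp))
  for (sq in names(rep1$selection)) {
    expect_identical(rep1$selection[[sq]]$selected,
                     rep2$selection[[sq]]$selected, info = sq)
    expect_equal(rep1$selection[[sq]]$lasso_alpha,
                 rep2$selection[[sq]]$lasso_alpha, info = sq)
  }

  # pairwise DeLong table covers combined-vs-sequence contrasts
  expect_true(any(grepl("combined", rep1$pairwise$model_b)))
  expect_true(all(rep1$pairwise$p_value >= 0 & rep1$pairwise$p_value <= 1))

  # report serializes
  p <- tempfile(fileext = ".json")
  write_report(rep1, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(nrow(back$cells), 20L)
  expect_equal(back$provenance$seed, 106)
})
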