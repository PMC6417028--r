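test_that("co-occurrence counts match the classic 4x4 worked example", {
  v <- mk_vol(haralick_grid())
  d <- discretize(v, full_mask(c(4, 4, 1)), n_bins = 4)
  tm <- glcm_matrix(d, c(1, 0, 0))
  expected <- matrix(c(4, 2, 1, 0,
                       2, 4, 0, 0,
                       1, 0, 6, 1,
                       0, 0, 1, 2), 4, 4, byrow = TRUE)
  expect_equal(tm$counts, expected)
  expect_equal(sum(tm$counts), 24)
  expect_equal(sum(tm$normalized), 1)
  expect_true(isSymmetric(tm$counts))
  # Contrast at this direction from the 24-pair matrix:
  # (4*1 + 2*4 + 2*1)/24 = 14/24
  p <- tm$normalized
  i <- matrix(1:4, 4, 4); j <- t(i)
  expect_equal(sum((i - j)^2 * p), 14 / 24)
})

test_that("texture matrices equal brute-force enumeration on random ROIs", {
  dirs <- texture_directions()
  for (seed in 1:25) {
    d <- random_roi(seed)
    k <- (seed %% 13) + 1
    expect_equal(glcm_matrix(d, dirs[k, ])$counts, oracle_glcm(d, dirs[k, ]),
                 info = sprintf("glcm seed %d", seed))
    rl <- glrlm_matrix(d, dirs[k, ])$counts
    orl <- oracle_glrlm(d, dirs[k, ])
    expect_equal(rl, orl, info = sprintf("glrlm seed %d", seed))
    expect_equal(glszm_matrix(d)$counts, oracle_glszm(d),
                 info = sprintf("glszm seed %d", seed))
  }
})

test_that("degenerate and boundary matrix cases behave as specified", {
  # constant ROI: all co-occurrence mass at (1,1)
  cv <- mk_vol(array(1, c(3, 3, 2)))
  cd <- suppressWarnings(discretize(cv, full_mask(c(3, 3, 2))))
  tm <- glcm_matrix(cd, c(1, 0, 0))
  expect_equal(tm$normalized, matrix(1, 1, 1))
  # single-voxel mask: empty pair set, flagged degenerate
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  sd1 <- suppressWarnings(discretize(mk_vol(array(rnorm(27), c(3, 3, 3))),
                                     mk_mask(m)))
  expect_true(glcm_matrix(sd1, c(0, 0, 1))$degenerate)
  expect_error(glcm_matrix(cd, c(0, 0, 0)), "non-zero")
  expect_error(glcm_matrix(cd, c(2, 0, 0)), "in \\{-1, 0, 1\\}")
})

test_that("run-length examples: 1-D row, constant row, checkerboard", {
  rv <- mk_vol(array(c(1, 2, 3, 4, 5, 6), c(6, 1, 1)))
  rd <- discretize(mk_vol(array(c(1, 1, 2, 2, 2, 3), c(6, 1, 1))),
                   full_mask(c(6, 1, 1)), n_bins = 3)
  rm <- glrlm_matrix(rd, c(1, 0, 0))
  expect_equal(rm$counts, matrix(c(0, 1, 0,
                                   0, 0, 1,
                                   1, 0, 0), 3, 3, byrow = TRUE))
  f <- lesionrad:::glrlm_features_single(rm, 6)
  expect_equal(f[["RunPercentage"]], 0.5)

  # constant row of length L: one run; LRE = L^2, SRE = 1/L^2
  L <- 7
  cd <- suppressWarnings(discretize(mk_vol(array(2, c(L, 1, 1))),
                                    full_mask(c(L, 1, 1))))
  cf <- lesionrad:::glrlm_features_single(glrlm_matrix(cd, c(1, 0, 0)), L)
  expect_equal(cf[["LongRunEmphasis"]], L^2)
  expect_equal(cf[["ShortRunEmphasis"]], 1 / L^2)

  # checkerboard slice: all runs length 1 along axis directions
  ch <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  chd <- discretize(mk_vol(array(ch, c(6, 6, 1))), full_mask(c(6, 6, 1)),
                    n_bins = 2)
  chf <- lesionrad:::glrlm_features_single(glrlm_matrix(chd, c(1, 0, 0)), 36)
  expect_equal(chf[["RunPercentage"]], 1)
})

test_that("size-zone examples: constant patch, diagonal touch, checkerboard", {
  # constant 2x2x1 ROI inside a 2x2x4 grid: one zone of size 4
  m <- array(FALSE, c(2, 2, 4)); m[, , 2] <- TRUE
  zd <- suppressWarnings(discretize(mk_vol(array(1, c(2, 2, 4))), mk_mask(m)))
  zf <- glszm_features(zd)
  expect_equal(zf[["ZonePercentage"]], 0.25)

  # two diagonal same-level voxels form one zone under 26-connectivity
  v <- array(c(1, 2, 2, 1), c(2, 2, 1))
  dd <- discretize(mk_vol(v), full_mask(c(2, 2, 1)), n_bins = 2)
  tm <- glszm_matrix(dd)
  expect_equal(sum(tm$counts), 2)          # two zones of size 2
  expect_equal(unname(tm$counts[, 2]), c(1, 1))

  # cross-slice checkerboard zone count agrees with the flood-fill oracle
  ch <- array((outer(1:4, 1:4, `+`) %% 2), c(4, 4, 3))
  ch[, , 2] <- 1 - ch[, , 2]
  chd <- discretize(mk_vol(ch), full_mask(c(4, 4, 3)), n_bins = 2)
  expect_equal(glszm_matrix(chd)$counts, oracle_glszm(chd))
})

test_that("grey-level reversal leaves contrast, entropy and homogeneity unchanged", {
  for (seed in c(21, 22, 23)) {
    d <- random_roi(seed)
    drev <- d
    drev$levels <- d$n_levels + 1L - d$levels
    f1 <- glcm_features(d)
    f2 <- glcm_features(drev)
    for (nm in c("Contrast", "Entropy", "Homogeneity1", "Homogeneity2",
                 "Energy", "Dissimilarity", "DifferenceEntropy"))
      expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12, info = nm)
  }
})

test_that("constant-ROI feature conventions hold across all three families", {
  cd <- suppressWarnings(discretize(mk_vol(array(5, c(3, 3, 2))),
                                    full_mask(c(3, 3, 2))))
  g <- glcm_features(cd)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["Correlation"]], 1)
  expect_equal(g[["MaximumProbability"]], 1)
  expect_equal(g[["Entropy"]], 0)
  r <- glrlm_features(cd)
  expect_true(all(is.finite(r)))
  z <- glszm_features(cd)
  expect_equal(z[["ZonePercentage"]], 1 / 18)
  expect_identical(names(g), lesionrad:::GLCM_NAMES)
  expect_identical(names(r), lesionrad:::GLRLM_NAMES)
  expect_identical(names(z), lesionrad:::GLSZM_NAMES)
})

test_that("normalized matrices sum to 1 and features stay finite on fuzzed ROIs", {
  dirs <- texture_directions()
  for (seed in 31:40) {
    d <- random_roi(seed, dims = c(5, 4, 3), n_bins = sample(2:6, 1))
    k <- (seed %% 13) + 1
    for (tm in list(glcm_matrix(d, dirs[k, ]), glrlm_matrix(d, dirs[k, ]),
                    glszm_matrix(d))) {
      if (!tm$degenerate) expect_equal(sum(tm$normalized), 1)
      expect_true(all(tm$counts >= 0))
    }
    expect_true(all(is.finite(glcm_features(d))))
    expect_true(all(is.finite(glrlm_features(d))))
    expect_true(all(is.finite(glszm_features(d))))
  }
})
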