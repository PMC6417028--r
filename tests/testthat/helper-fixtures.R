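# Small builders used across tests.

mk_vol <- function(values, spacing = c(1, 1, 1), sequence = "unknown") {
  volume_image(values, spacing = spacing, sequence = sequence)
}

mk_mask <- function(values, spacing = c(1, 1, 1)) {
  lesion_mask(values, spacing = spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  mk_mask(array(TRUE, dims), spacing)
}

# the classic 4x4 single-slice co-occurrence example; written rows become
# runs along dim 1 so that offset (1,0,0) pairs horizontal neighbours
haralick_grid <- function() {
  g <- matrix(c(0, 0, 1, 1,
                0, 0, 1, 1,
                0, 2, 2, 2,
                2, 2, 3, 3), nrow = 4, byrow = TRUE)
  array(t(g), c(4, 4, 1))
}

# random small discretized ROI with a random mask
random_roi <- function(seed, dims = c(6, 6, 3), n_bins = 4,
                       mask_prob = 0.85) {
  set.seed(seed)
  v <- mk_vol(array(stats::runif(prod(dims)), dims))
  m <- array(stats::runif(prod(dims)) < mask_prob, dims)
  if (sum(m) < 2) m[c(1, 2)] <- TRUE
  suppressWarnings(discretize(v, mk_mask(m), n_bins = n_bins))
}

# digital ball mask of radius r (isotropic unit spacing)
ball_mask <- function(r, margin = 3L) {
  n <- 2L * r + 2L * margin + 1L
  ax <- seq_len(n) - (r + margin + 1L)
  g <- expand.grid(x = ax, y = ax, z = ax)
  mk_mask(array(g$x^2 + g$y^2 + g$z^2 <= r^2, c(n, n, n)))
}

# linearly separable 2-feature training set
separable_xy <- function(n_per_class = 20, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per_class, gap / 2), ncol = 2),
             matrix(stats::rnorm(2 * n_per_class, -gap / 2), ncol = 2))
  colnames(x) <- c("a", "b")
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}
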