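PHANTOM_SEQUENCES <- c("inphase", "outphase", "t2wi", "dwi")

#' Specification of a synthetic two-class lesion-phantom cohort
#'
#' The generator emulates a liver-lesion MR cohort: two lesion classes of
#' roughly equal prevalence where class 0 ("haemangioma-like") is texturally
#' homogeneous and T2-bright, and class 1 ("carcinoma-like") receives
#' per-sequence mean shifts and a multiplicative heterogeneity texture.
#' Defaults mirror the emulated study's stated cohort geometry: 369 subjects
#' with 1-3 lesions each (about 1.2 on average), near-balanced classes, and
#' 1 x 1 x 5 mm voxels matching the 5-mm slice thickness. Lesion sizes are
#' not stated by that study, so the radius range is a free generator
#' parameter (5-15 mm, typical of reported liver-lesion series).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param lesions_per_subject_range integer (min, max) lesion count; counts
#'   are drawn with geometric decay 0.2 within the range, giving a mean of
#'   about 1.2 at the default range.
#' @param class_balance expected fraction of class-1 subjects, strictly in
#'   (0, 1).
#' @param grid_shape voxels per axis of each lesion volume.
#' @param spacing_mm physical voxel spacing.
#' @param lesion_radius_range_mm (min, max) ellipsoid semi-axis length; the
#'   maximum must fit inside half the grid extent on every axis.
#' @param class_effects list with `mean_shift` (named per-sequence shifts for
#'   class 1, in units of `noise_sd`) and `heterogeneity` (multiplier >= 1;
#'   1 is neutral). Use [null_effects()] for a no-signal cohort.
#' @param noise_sd background Gaussian noise SD (intensity units).
#' @param background_mean background intensity level.
#' @param bias_amplitude amplitude of the smooth multiplicative-free bias
#'   field added to every volume (makes normalization consequential).
#' @param lesion_contrast named per-sequence additive lesion contrast common
#'   to both classes (class 0 keeps exactly this).
#' @param lobulation_max maximum amplitude of the low-order angular
#'   perturbation of the ellipsoid radius ("lobulated" shapes).
#' @param seed integer seed controlling the whole cohort.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 369,
                         lesions_per_subject_range = c(1L, 3L),
                         class_balance = 0.5,
                         grid_shape = c(48L, 48L, 16L),
                         spacing_mm = c(1, 1, 5),
                         lesion_radius_range_mm = c(5, 15),
                         class_effects = list(
                           mean_shift = c(inphase = 0.5, outphase = 1.0,
                                          t2wi = -1.5, dwi = 0.8),
                           heterogeneity = 2.0
                         ),
                         noise_sd = 10,
                         background_mean = 100,
                         bias_amplitude = 15,
                         lesion_contrast = c(inphase = 8, outphase = 6,
                                             t2wi = 25, dwi = 15),
                         lobulation_max = 0.2,
                         seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               lesions_per_subject_range = as.integer(lesions_per_subject_range),
               class_balance = class_balance,
               grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
               class_effects = class_effects,
               noise_sd = noise_sd,
               background_mean = background_mean,
               bias_amplitude = bias_amplitude,
               lesion_contrast = lesion_contrast,
               lobulation_max = lobulation_max,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
null_effects <- function() {
  list(mean_shift = c(inphase = 0, outphase = 0, t2wi = 0, dwi = 0),
       heterogeneity = 1.0)
}

validate_phantom_spec <- function(spec) {
  if (spec$n_subjects < 2L) stop("n_subjects must be >= 2")
  if (!(spec$class_balance > 0 && spec$class_balance < 1))
    stop("class_balance must be strictly between 0 and 1")
  r <- spec$lesions_per_subject_range
  if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
    stop("invalid lesions_per_subject_range")
  if (any(spec$spacing_mm <= 0)) stop("spacing must be positive")
  if (any(spec$grid_shape < 2L)) stop("grid too small")
  rr <- spec$lesion_radius_range_mm
  if (rr[1] <= 0 || rr[2] < rr[1]) stop("lesion radii must be positive")
  half_extent <- spec$grid_shape * spec$spacing_mm / 2
  if (any(rr[2] >= half_extent))
    stop("degenerate spec: lesion radius ", rr[2],
         " mm does not fit inside half the grid extent (",
         paste(half_extent, collapse = "x"), " mm)")
  ms <- spec$class_effects$mean_shift
  if (!all(PHANTOM_SEQUENCES %in% names(ms)))
    stop("class_effects$mean_shift must name all four sequences")
  if (spec$class_effects$heterogeneity < 1)
    stop("heterogeneity multiplier must be >= 1 (1 is neutral)")
  invisible(spec)
}

# smooth unit-variance Gaussian random field (separable Gaussian kernel,
# sigma in voxels, periodic boundaries)
smooth_grf <- function(grid_shape, sigma = 2) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  half <- max(3L, ceiling(3 * sigma))
  taps <- stats::dnorm(seq(-half, half), sd = sigma)
  taps <- taps / sum(taps)
  for (ax in 1:3) {
    if (grid_shape[ax] >= length(taps)) w <- conv_axis_periodic(w, taps, ax)
  }
  s <- stats::sd(as.vector(w))
  if (s > 0) w <- w / s
  w
}

# ellipsoid with low-order angular radius perturbation; returns logical array
lobulated_ellipsoid_mask <- function(grid_shape, spacing, center_mm, semi_mm,
                                     lob_amp) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing[a])
  X <- array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  u <- (X - center_mm[1]) / semi_mm[1]
  v <- (Y - center_mm[2]) / semi_mm[2]
  w <- (Z - center_mm[3]) / semi_mm[3]
  r <- sqrt(u^2 + v^2 + w^2)
  # low-order directional modulation of the boundary radius
  theta <- atan2(v, u)
  phi <- atan2(w, sqrt(u^2 + v^2))
  mvals <- sample(1:3, 2, replace = TRUE)
  ph <- stats::runif(3, 0, 2 * pi)
  pert <- 1 + lob_amp * (cos(mvals[1] * theta + ph[1]) *
                           cos(ph[2] + phi) +
                           0.5 * cos(mvals[2] * theta + ph[3]))
  r <= pmax(pert, 0.5)
}

#' Generate one synthetic lesion (4 sequence volumes + mask)
#'
#' Background is Gaussian noise over a smooth low-frequency bias field; the
#' lesion is a connected lobulated ellipsoid of at least 27 voxels. Class-1
#' lesions additionally receive the configured per-sequence mean shift (in
#' noise-SD units) and a heterogeneity texture: a Gaussian random field
#' smoothed at a 2-voxel scale, scaled by `(heterogeneity - 1) * noise_sd`,
#' added inside the mask. With `heterogeneity = 1` and zero mean shifts the
#' two classes are distributionally identical.
#'
#' @param spec a [phantom_spec()].
#' @param class_label 0 or 1.
#' @param seed integer seed for this lesion.
#' @return List with `volumes` (named list of 4 [volume_image()]s) and
#'   `mask` (a [lesion_mask()]).
#' @export
generate_lesion <- function(spec, class_label, seed) {
  validate_phantom_spec(spec)
  stopifnot(class_label %in% c(0, 1))
  set.seed(as.integer(seed))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  extent <- gs * sp
  for (attempt in 1:10) {
    semi <- stats::runif(3, spec$lesion_radius_range_mm[1],
                         spec$lesion_radius_range_mm[2])
    margin <- semi * 1.3
    lo <- pmin(margin, extent / 2)
    center <- stats::runif(3, lo, pmax(extent - lo, lo))
    lob <- stats::runif(1, 0, spec$lobulation_max)
    m <- lobulated_ellipsoid_mask(gs, sp, center, semi, lob)
    if (sum(m) >= 27L) break
  }
  if (sum(m) < 27L)
    stop("could not place a lesion of >= 27 voxels; spec too tight")
  mask <- lesion_mask(m, spacing = sp)
  hetero <- spec$class_effects$heterogeneity
  vols <- lapply(PHANTOM_SEQUENCES, function(sq) {
    bias_dir <- stats::rnorm(3)
    bias_dir <- bias_dir / sqrt(sum(bias_dir^2))
    ax <- lapply(1:3, function(a) (seq_len(gs[a]) - 0.5) * sp[a] / extent[a])
    phase <- stats::runif(1, 0, 2 * pi)
    X1 <- array(rep(ax[[1]] * bias_dir[1], times = gs[2] * gs[3]), gs)
    Y1 <- array(rep(rep(ax[[2]] * bias_dir[2], each = gs[1]), times = gs[3]), gs)
    Z1 <- array(rep(ax[[3]] * bias_dir[3], each = gs[1] * gs[2]), gs)
    bias <- spec$bias_amplitude * cos(2 * pi * (X1 + Y1 + Z1) + phase)
    v <- spec$background_mean + bias +
      array(stats::rnorm(prod(gs), sd = spec$noise_sd), gs)
    v[m] <- v[m] + spec$lesion_contrast[[sq]]
    if (class_label == 1) {
      v[m] <- v[m] + spec$class_effects$mean_shift[[sq]] * spec$noise_sd
      if (hetero > 1) {
        g <- smooth_grf(gs, sigma = 2)
        v[m] <- v[m] + (hetero - 1) * spec$noise_sd * g[m]
      }
    }
    volume_image(v, spacing = sp, sequence = sq)
  })
  names(vols) <- PHANTOM_SEQUENCES
  list(volumes = vols, mask = mask)
}

#' Generate a synthetic cohort on disk
#'
#' Draws a per-subject class label (Bernoulli `class_balance`) and lesion
#' count, generates each lesion's four sequence volumes and mask, writes them
#' as NIfTI (.nii.gz), and writes `manifest.csv` mapping subject, lesion and
#' class to file paths. All lesions of a subject share its class so that
#' subject-grouped splits are class-clean.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return The manifest data.frame, invisibly carrying class
#'   `cohort_manifest`.
#' @export
generate_cohort <- function(spec, out_dir) {
  validate_phantom_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(spec$seed)
  r <- spec$lesions_per_subject_range
  k <- r[1]:r[2]
  wts <- 0.2^(k - r[1])
  labels <- stats::rbinom(spec$n_subjects, 1, spec$class_balance)
  counts <- sample(k, spec$n_subjects, replace = TRUE, prob = wts / sum(wts))
  rows <- list()
  lesion_idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (l in seq_len(counts[s])) {
      lesion_idx <- lesion_idx + 1L
      lseed <- (spec$seed %% 100000L) * 7919L + lesion_idx * 104729L
      lseed <- lseed %% 2147483647L
      les <- generate_lesion(spec, labels[s], seed = lseed)
      lesion_id <- sprintf("L%05d", lesion_idx)
      paths <- vapply(PHANTOM_SEQUENCES, function(sq) {
        p <- file.path(out_dir, sprintf("%s_%s.nii.gz", lesion_id, sq))
        write_volume(les$volumes[[sq]], p)
        p
      }, character(1))
      mpath <- file.path(out_dir, sprintf("%s_mask.nii.gz", lesion_id))
      write_mask(les$mask, mpath)
      rows[[lesion_idx]] <- data.frame(
        subject_id = sprintf("S%04d", s), lesion_id = lesion_id,
        label = labels[s],
        inphase = paths[["inphase"]], outphase = paths[["outphase"]],
        t2wi = paths[["t2wi"]], dwi = paths[["dwi"]], mask = mpath,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("cohort_manifest", "data.frame")
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest CSV
#' @param path path to `manifest.csv`.
#' @return A `cohort_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "lesion_id", "label", PHANTOM_SEQUENCES, "mask")
  if (!all(needed %in% names(m)))
    stop("manifest is missing columns: ",
         paste(setdiff(needed, names(m)), collapse = ", "))
  if (anyDuplicated(m$lesion_id)) stop("lesion_ids must be unique")
  if (!all(m$label %in% c(0, 1))) stop("labels must be binary 0/1")
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Simulate a feature-level two-class cohort
#'
#' A tabular counterpart of the image phantom for testing the selection
#' cascade and classifiers directly: per sequence, `n_features` standard
#' normal features of which the first `n_informative` get a mean shift of
#' `effect_size` (in SD units) in class 1. One subject per lesion.
#'
#' @param n_lesions rows.
#' @param n_features features per sequence.
#' @param n_informative informative features per sequence.
#' @param effect_size standardized class-1 mean shift of informative features.
#' @param class_balance P(label = 1).
#' @param sequences sequence prefixes to simulate.
#' @param seed integer seed.
#' @return A [feature_table()]; informative column names carry the
#'   `::informative::` marker.
#' @export
simulate_feature_table <- function(n_lesions = 200, n_features = 100,
                                   n_informative = 3, effect_size = 2,
                                   class_balance = 0.5,
                                   sequences = PHANTOM_SEQUENCES,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  labels <- stats::rbinom(n_lesions, 1, class_balance)
  # guard: both classes present
  if (sum(labels) == 0) labels[1] <- 1L
  if (sum(labels) == n_lesions) labels[1] <- 0L
  blocks <- lapply(sequences, function(sq) {
    x <- matrix(stats::rnorm(n_lesions * n_features), n_lesions, n_features)
    if (n_informative > 0)
      x[, seq_len(n_informative)] <- x[, seq_len(n_informative), drop = FALSE] +
        outer(labels, rep(effect_size, n_informative))
    colnames(x) <- c(
      if (n_informative > 0)
        sprintf("%s::informative::f%03d", sq, seq_len(n_informative)),
      sprintf("%s::noise::f%03d", sq, seq_len(n_features - n_informative))
    )[seq_len(n_features)]
    x
  })
  feature_table(do.call(cbind, blocks), labels)
}
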