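#' Feature registry
#'
#' The machine-readable list of every feature the extractor can emit: 93
#' original features (19 first-order, 15 shape, 27 GLCM, 16 GLRLM, 16 GLSZM)
#' plus 936 higher-order features (the 78 intensity-dependent features -
#' first-order, GLCM, GLRLM, GLSZM; shape excluded - recomputed on each of
#' the 12 filtered image variants), 1029 in total. Names follow
#' `<filter>::<class>::<FeatureName>` with `filter = "original"` for the
#' unfiltered image.
#'
#' @return A data.frame with columns `name`, `filter`, `class`, `feature`.
#' @export
feature_registry <- function() {
  classes <- list(firstorder = FIRSTORDER_NAMES, shape = SHAPE_NAMES,
                  glcm = GLCM_NAMES, glrlm = GLRLM_NAMES, glszm = GLSZM_NAMES)
  rows <- list()
  for (cl in names(classes)) {
    rows[[cl]] <- data.frame(filter = "original", class = cl,
                             feature = classes[[cl]],
                             stringsAsFactors = FALSE)
  }
  for (f in FILTER_NAMES) {
    for (cl in c("firstorder", "glcm", "glrlm", "glszm")) {
      rows[[paste(f, cl)]] <- data.frame(filter = f, class = cl,
                                         feature = classes[[cl]],
                                         stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg$name <- paste(reg$filter, reg$class, reg$feature, sep = "::")
  reg[, c("name", "filter", "class", "feature")]
}

#' Write the feature registry as JSON
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_feature_registry <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extraction configuration
#'
#' @param n_bins grey levels for discretization (>= 2).
#' @param normalize_scale `s` of the intensity normalization.
#' @param normalize apply z-score normalization before extraction.
#' @param filters subset of the 12 filter names to run for higher-order
#'   features.
#' @param smooth_iterations Taubin iterations for the shape surface mesh.
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(n_bins = 32, normalize_scale = 1, normalize = TRUE,
                           filters = FILTER_NAMES, smooth_iterations = 20) {
  if (!all(filters %in% FILTER_NAMES))
    stop("unknown filter name(s): ",
         paste(setdiff(filters, FILTER_NAMES), collapse = ", "))
  structure(list(n_bins = n_bins, normalize_scale = normalize_scale,
                 normalize = normalize, filters = filters,
                 smooth_iterations = smooth_iterations),
            class = "extract_config")
}

# 78 intensity-dependent features of one (possibly filtered) volume
intensity_features <- function(vol, mask, cfg) {
  d <- suppressWarnings(discretize(vol, mask, cfg$n_bins))
  c(
    stats::setNames(first_order_features(vol, mask, cfg$n_bins),
                    paste0("firstorder::", FIRSTORDER_NAMES)),
    stats::setNames(glcm_features(d), paste0("glcm::", GLCM_NAMES)),
    stats::setNames(glrlm_features(d), paste0("glrlm::", GLRLM_NAMES)),
    stats::setNames(glszm_features(d), paste0("glszm::", GLSZM_NAMES))
  )
}

maybe_normalize <- function(vol, cfg) {
  if (isTRUE(cfg$normalize)) normalize_intensity(vol, cfg$normalize_scale)
  else vol
}

#' Extract the 93 original features
#'
#' First-order, shape and texture features of the unfiltered (but
#' z-score-normalized) volume over the lesion mask.
#'
#' @param vol a [volume_image()].
#' @param mask an aligned [lesion_mask()].
#' @param cfg an [extract_config()].
#' @return Named numeric vector of 93 features (`original::...`).
#' @export
extract_original <- function(vol, mask, cfg = extract_config()) {
  check_alignment(vol, mask)
  nv <- maybe_normalize(vol, cfg)
  fo_tex <- intensity_features(nv, mask, cfg)
  out <- c(
    fo_tex[paste0("firstorder::", FIRSTORDER_NAMES)],
    stats::setNames(shape_features(mask,
                                   smooth_iterations = cfg$smooth_iterations),
                    paste0("shape::", SHAPE_NAMES)),
    fo_tex[c(paste0("glcm::", GLCM_NAMES), paste0("glrlm::", GLRLM_NAMES),
             paste0("glszm::", GLSZM_NAMES))]
  )
  names(out) <- paste0("original::", names(out))
  out
}

#' Extract the 936 higher-order features
#'
#' The 78 intensity-dependent features (shape excluded, since filtering does
#' not change the mask) recomputed on each of the 12 filtered variants of the
#' normalized volume; each filtered volume is re-discretized with the same
#' bin count.
#'
#' @inheritParams extract_original
#' @return Named numeric vector (936 when all 12 filters are enabled).
#' @export
extract_higher_order <- function(vol, mask, cfg = extract_config()) {
  check_alignment(vol, mask)
  nv <- maybe_normalize(vol, cfg)
  bank <- filter_bank(nv)[cfg$filters]
  out <- unlist(lapply(names(bank), function(f) {
    v <- intensity_features(bank[[f]], mask, cfg)
    stats::setNames(as.numeric(v), paste0(f, "::", names(v)))
  }))
  out
}

#' Extract all 1029 features of one volume/mask pair
#'
#' @inheritParams extract_original
#' @return Named numeric vector: 93 original + 936 higher-order features in
#'   registry order.
#' @export
extract_all <- function(vol, mask, cfg = extract_config()) {
  check_alignment(vol, mask)
  nv <- maybe_normalize(vol, cfg)
  fo_tex <- intensity_features(nv, mask, cfg)
  original <- c(
    fo_tex[paste0("firstorder::", FIRSTORDER_NAMES)],
    stats::setNames(shape_features(mask,
                                   smooth_iterations = cfg$smooth_iterations),
                    paste0("shape::", SHAPE_NAMES)),
    fo_tex[c(paste0("glcm::", GLCM_NAMES), paste0("glrlm::", GLRLM_NAMES),
             paste0("glszm::", GLSZM_NAMES))]
  )
  names(original) <- paste0("original::", names(original))
  bank <- filter_bank(nv)[cfg$filters]
  higher <- unlist(lapply(names(bank), function(f) {
    v <- intensity_features(bank[[f]], mask, cfg)
    stats::setNames(as.numeric(v), paste0(f, "::", names(v)))
  }))
  out <- c(original, higher)
  if (anyDuplicated(names(out))) stop("internal error: duplicate feature names")
  out
}

#' Extract features for a whole cohort manifest
#'
#' Reads each lesion's four sequence volumes and mask, extracts all features
#' per sequence, and assembles the lesions-by-features table with
#' sequence-qualified column names (`t2wi::original::glcm::Contrast` style).
#'
#' @param manifest a cohort manifest data.frame (see [generate_cohort()]):
#'   columns `subject_id`, `lesion_id`, `label`, `inphase`, `outphase`,
#'   `t2wi`, `dwi`, `mask`.
#' @param cfg an [extract_config()].
#' @param sequences sequence columns to extract.
#' @param verbose print per-lesion progress.
#' @return A [feature_table()].
#' @export
extract_cohort <- function(manifest, cfg = extract_config(),
                           sequences = c("inphase", "outphase", "t2wi", "dwi"),
                           verbose = FALSE) {
  needed <- c("subject_id", "lesion_id", "label", sequences, "mask")
  if (!all(needed %in% names(manifest)))
    stop("manifest is missing columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(r) {
    mask <- read_mask(manifest$mask[r])
    per_seq <- lapply(sequences, function(sq) {
      vol <- read_volume(manifest[[sq]][r], sequence = sq)
      v <- extract_all(vol, mask, cfg)
      stats::setNames(as.numeric(v), paste0(sq, "::", names(v)))
    })
    if (verbose) message("extracted lesion ", manifest$lesion_id[r])
    unlist(per_seq)
  })
  feats <- do.call(rbind, rows)
  feature_table(feats, manifest$label,
                subject_id = manifest$subject_id,
                lesion_id = manifest$lesion_id)
}
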