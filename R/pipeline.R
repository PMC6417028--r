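PIPELINE_KEYS <- list(
  seed = "integer",
  phantom = c("n_subjects", "lesions_per_subject_range", "class_balance",
              "grid_shape", "spacing_mm", "lesion_radius_range_mm",
              "class_effects", "noise_sd", "background_mean",
              "bias_amplitude", "lesion_contrast", "lobulation_max", "seed"),
  extract = c("n_bins", "normalize_scale", "normalize", "filters",
              "smooth_iterations"),
  selection = c("variance_threshold", "p_alpha", "cv_folds"),
  split = c("test_fraction", "group_by_subject"),
  sequences = "character"
)

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_all()]. Unknown keys
#' (top-level or nested) are rejected so that typos cannot silently revert a
#' parameter to its default. The configuration embeds the protocol constants
#' of the emulated study: variance threshold 0.8, univariate p 0.05, 80/20
#' train/test split.
#'
#' @param config named list, or path to a YAML file with the same structure.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  unknown <- setdiff(names(config), names(PIPELINE_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (section in c("phantom", "extract", "selection", "split")) {
    bad <- setdiff(names(config[[section]]), PIPELINE_KEYS[[section]])
    if (length(bad))
      stop("unknown config key(s) in ", section, ": ",
           paste(bad, collapse = ", "))
  }
  seed <- as.integer(config$seed %||% 1L)
  phantom_args <- config$phantom %||% list()
  if (is.null(phantom_args$seed)) phantom_args$seed <- seed
  if (!is.null(phantom_args$class_effects)) {
    ce <- phantom_args$class_effects
    if (!is.null(ce$mean_shift)) ce$mean_shift <- unlist(ce$mean_shift)
    phantom_args$class_effects <- ce
  }
  if (!is.null(phantom_args$lesion_contrast))
    phantom_args$lesion_contrast <- unlist(phantom_args$lesion_contrast)
  cfg <- list(
    seed = seed,
    phantom = do.call(phantom_spec, phantom_args),
    extract = do.call(extract_config, config$extract %||% list()),
    selection = utils::modifyList(
      list(variance_threshold = 0.8, p_alpha = 0.05, cv_folds = 5),
      config$selection %||% list()),
    split = utils::modifyList(
      list(test_fraction = 0.2, group_by_subject = TRUE),
      config$split %||% list()),
    sequences = config$sequences %||% c("inphase", "outphase", "t2wi", "dwi")
  )
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' simulate -> extract -> select -> evaluate, writing every artifact under
#' `out_dir`: the NIfTI cohort and `manifest.csv` (under `cohort/`),
#' `features.csv`, `selection.json`, `report.json`, and the fully resolved
#' configuration (`config.json`). Stages are cached on re-runs: an existing
#' artifact produced under the same configuration hash is reused, and a rerun
#' with the same config is bit-identical apart from timestamps.
#'
#' @param config a [pipeline_config()], raw list, or YAML path.
#' @param out_dir output directory.
#' @param verbose log stage progress and feature counts.
#' @return The [evaluate_all()] report, invisibly.
#' @export
run_all <- function(config, out_dir, verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  cfg_json <- jsonlite::serializeJSON(unclass(cfg))
  cfg_hash <- substr(digest_string(cfg_json), 1, 12)
  hash_path <- file.path(out_dir, "config.hash")
  stale <- !file.exists(hash_path) || readLines(hash_path)[1] != cfg_hash

  cohort_dir <- file.path(out_dir, "cohort")
  manifest_path <- file.path(cohort_dir, "manifest.csv")
  t0 <- Sys.time()
  if (stale || !file.exists(manifest_path)) {
    say("stage simulate: generating cohort (seed %d)", cfg$seed)
    manifest <- generate_cohort(cfg$phantom, cohort_dir)
  } else {
    say("stage simulate: reusing cached cohort")
    manifest <- read_manifest(manifest_path)
  }
  say("stage simulate: %d lesions / %d subjects [%.1fs]",
      nrow(manifest), length(unique(manifest$subject_id)),
      as.numeric(Sys.time() - t0, units = "secs"))

  features_path <- file.path(out_dir, "features.csv")
  t0 <- Sys.time()
  if (stale || !file.exists(features_path)) {
    say("stage extract: %d sequences x %d lesions",
        length(cfg$sequences), nrow(manifest))
    table <- extract_cohort(manifest, cfg$extract, sequences = cfg$sequences)
    write_feature_table(table, features_path)
  } else {
    say("stage extract: reusing cached features")
    table <- read_feature_table(features_path)
  }
  say("stage extract: %d feature columns [%.1fs]",
      ncol(feature_matrix(table)), as.numeric(Sys.time() - t0, units = "secs"))

  t0 <- Sys.time()
  report <- evaluate_all(
    table, sequences = cfg$sequences,
    test_fraction = cfg$split$test_fraction,
    group_by_subject = cfg$split$group_by_subject,
    seed = cfg$seed,
    variance_threshold = cfg$selection$variance_threshold,
    p_alpha = cfg$selection$p_alpha, cv_folds = cfg$selection$cv_folds)
  for (sq in names(report$selection)) {
    ct <- report$selection[[sq]]$counts
    say("stage select [%s]: %d -> %d -> %d -> %d", sq,
        ct["input"], ct["variance"], ct["univariate"], ct["lasso"])
  }
  write_selection(report$selection, file.path(out_dir, "selection.json"))
  write_report(report, file.path(out_dir, "report.json"))
  jsonlite::write_json(jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  writeLines(cfg_hash, hash_path)
  say("stage evaluate: %d model cells [%.1fs]", nrow(report$cells),
      as.numeric(Sys.time() - t0, units = "secs"))
  invisible(report)
}

# small stable string hash (djb2); only used as a cache key
digest_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    for (x in chunk) h <- (h * 33 + x) %% 2^31
  }
  sprintf("%08x%04x", as.integer(h), length(v) %% 65536L)
}
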