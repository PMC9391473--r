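#' Pipeline run configuration
#'
#' Bundles every knob of a simulate/match/stats run. Child configurations
#' validate on construction; the master seed lives in the study design and
#' is recorded in every output manifest. A YAML file of scalar overrides
#' (`n_subjects`, `n_scans`, `seed`, `grid_shape`, `mode`, `threshold`,
#' `window_length`, `window_stride`, `b1_step_deg`) may be layered on top.
#'
#' @param design A [study_design()].
#' @param phantom A [phantom_spec()].
#' @param dist A [tissue_distribution()].
#' @param train A [make_pulse_train()] train (EPG mode).
#' @param mode `"direct"` or `"epg"`.
#' @param threshold Mask binarization threshold.
#' @param window_length,window_stride Dictionary sliding window.
#' @param b1_step_deg Spacing of the dictionary B1+ axis in degrees
#'   (1 = full axis; larger values coarsen it).
#' @param yaml Optional YAML file of scalar overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(design = study_design(), phantom = phantom_spec(),
                       dist = tissue_distribution(),
                       train = make_pulse_train(), mode = c("direct", "epg"),
                       threshold = 0.9, window_length = 8L, window_stride = 8L,
                       b1_step_deg = 1L, yaml = NULL) {
  mode <- match.arg(mode)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    if (!is.null(ov$n_subjects) || !is.null(ov$n_scans) || !is.null(ov$seed))
      design <- study_design(ov$n_subjects %||% design$n_subjects,
                             ov$n_scans %||% design$n_scans,
                             ov$seed %||% design$seed)
    if (!is.null(ov$grid_shape)) phantom <- phantom_spec(grid_shape = ov$grid_shape)
    if (!is.null(ov$mode)) mode <- match.arg(ov$mode, c("direct", "epg"))
    threshold <- ov$threshold %||% threshold
    window_length <- ov$window_length %||% window_length
    window_stride <- ov$window_stride %||% window_stride
    b1_step_deg <- ov$b1_step_deg %||% b1_step_deg
  }
  stopifnot(inherits(design, "study_design"), inherits(phantom, "phantom_spec"),
            inherits(dist, "tissue_distribution"), inherits(train, "pulse_train"),
            threshold > 0.5, threshold <= 1, b1_step_deg >= 1)
  structure(list(design = design, phantom = phantom, dist = dist, train = train,
                 mode = mode, threshold = threshold,
                 window_length = as.integer(window_length),
                 window_stride = as.integer(window_stride),
                 b1_step_deg = as.integer(b1_step_deg)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_volume <- function(arr, path, voxel_size) {
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

config_manifest <- function(config) {
  list(package = "mrfrepeat",
       version = as.character(utils::packageVersion("mrfrepeat")),
       seed = config$design$seed,
       n_subjects = config$design$n_subjects, n_scans = config$design$n_scans,
       mode = config$mode, threshold = config$threshold,
       grid_shape = config$phantom$grid_shape,
       na_shape = config$phantom$na_shape,
       na_inplane_factor = config$phantom$na_inplane_factor,
       pv_smoothing_mm = config$phantom$pv_smoothing_mm,
       window_length = config$window_length,
       window_stride = config$window_stride,
       b1_step_deg = config$b1_step_deg,
       train = list(n_pulses = config$train$n_pulses, tr = config$train$tr,
                    te = config$train$te,
                    flip_checksum = round(sum(config$train$flip_deg), 6)))
}

#' Simulate a study to disk
#'
#' Generates the study and writes, per scan, the quantitative maps (direct
#' mode) or the fingerprint stack (EPG mode), the sodium image, plus the
#' shared probability maps, eye ROI and a JSON manifest embedding the
#' seed and configuration. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return The in-memory `mrf_study`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  study <- generate_study(config$design, config$phantom, config$dist,
                          mode = config$mode, train = config$train)
  vs <- config$phantom$voxel_size_mm
  geo_dir <- file.path(out_dir, "geometry")
  dir.create(geo_dir, showWarnings = FALSE)
  for (t in names(study$geometry$prob))
    write_volume(study$geometry$prob[[t]], file.path(geo_dir, paste0("prob_", t, ".nii.gz")), vs)
  write_volume(study$geometry$eye_roi_na, file.path(geo_dir, "eye_roi_na.nii.gz"),
               c(vs[1:2] * config$phantom$na_inplane_factor, vs[3]))
  for (s in seq_along(study$subjects)) {
    for (k in seq_along(study$subjects[[s]]$scans)) {
      scan <- study$subjects[[s]]$scans[[k]]
      d <- file.path(out_dir, sprintf("subject-%02d", s), sprintf("scan-%02d", k))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      if (config$mode == "direct") {
        for (nm in names(scan$measured))
          write_volume(scan$measured[[nm]], file.path(d, paste0(nm, ".nii.gz")), vs)
      } else {
        saveRDS(list(fingerprints = scan$fingerprints, vox = scan$vox),
                file.path(d, "fingerprints.rds"))
      }
      write_volume(scan$na_image, file.path(d, "na.nii.gz"),
                   c(vs[1:2] * config$phantom$na_inplane_factor, vs[3]))
      jsonlite::write_json(list(subject = s, scan = k, seed = scan$seed,
                                mode = scan$mode),
                           file.path(d, "scan.json"), auto_unbox = TRUE)
    }
  }
  jsonlite::write_json(config_manifest(config), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

#' Match an EPG-mode study against a dictionary
#'
#' Builds the dictionary the config describes (full T1/T2 axes, B1+ axis
#' thinned to every `b1_step_deg` degrees) unless one is supplied, matches
#' every scan, and optionally writes the matched maps as NIfTI.
#'
#' @param study An EPG-mode `mrf_study` (from [run_simulate()] or
#'   [generate_study()]).
#' @param config The [run_config()] used to simulate it.
#' @param dict Optional prebuilt `mrf_dictionary`.
#' @param out_dir Optional directory for matched maps.
#' @return The study with matched maps attached.
#' @export
run_match <- function(study, config, dict = NULL, out_dir = NULL) {
  stopifnot(inherits(study, "mrf_study"), inherits(config, "run_config"))
  if (study$mode != "epg")
    stop("nothing to match: direct-mode studies already carry measured maps")
  if (is.null(dict)) {
    grid <- dictionary_grid(b1_deg = seq(10L, 130L, by = config$b1_step_deg))
    dict <- build_dictionary(grid, config$train,
                             config$window_length, config$window_stride)
  }
  study <- match_study(study, dict)
  if (!is.null(out_dir)) {
    vs <- config$phantom$voxel_size_mm
    for (s in seq_along(study$subjects))
      for (k in seq_along(study$subjects[[s]]$scans)) {
        d <- file.path(out_dir, sprintf("subject-%02d", s), sprintf("scan-%02d", k))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        for (nm in names(study$subjects[[s]]$scans[[k]]$measured))
          write_volume(study$subjects[[s]]$scans[[k]]$measured[[nm]],
                       file.path(d, paste0("matched_", nm, ".nii.gz")), vs)
      }
  }
  study
}

#' Compute repeatability statistics for a study
#'
#' Summarizes every scan (masks, normalizations, per-tissue mean/SD) and
#' builds the repeatability table with CV, ICC, bands and the 2 x CV
#' detectable-change column. Accepts either a study with measured maps or
#' an already-long-format summary data.frame (the CSV ingestion path).
#'
#' @param study An `mrf_study` with measured maps, or a data.frame in the
#'   [summarize_study()] schema.
#' @param config A [run_config()] (for the threshold; optional for
#'   data.frame input).
#' @param out_dir Optional directory: writes `scan_summaries.csv`,
#'   `repeatability_table.csv` and `repeatability_table.json`.
#' @return The `repeatability_table`.
#' @export
run_stats <- function(study, config = NULL, out_dir = NULL) {
  threshold <- if (!is.null(config)) config$threshold else 0.9
  summaries <- if (is.data.frame(study)) study else summarize_study(study, threshold)
  table <- build_table(summaries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summaries, file.path(out_dir, "scan_summaries.csv"), row.names = FALSE)
    write_repeatability_table(table, file.path(out_dir, "repeatability_table.csv"))
    jsonlite::write_json(table, file.path(out_dir, "repeatability_table.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  }
  table
}

#' Verify the published ICC column from its printed components
#'
#' Thin wrapper over [check_table_components()] that can ingest an
#' external components CSV and write a JSON verification report.
#'
#' @param components_csv Optional CSV path in the [reference_components()]
#'   schema; the packaged reference table by default.
#' @param out_path Optional JSON report path.
#' @param tolerance Pass tolerance on |recomputed - printed|.
#' @return The verification data.frame.
#' @export
run_check_table <- function(components_csv = NULL, out_path = NULL,
                            tolerance = 0.01) {
  components <- if (is.null(components_csv)) reference_components()
                else read.csv(components_csv, stringsAsFactors = FALSE)
  report <- check_table_components(components, tolerance)
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  report
}

#' Run the full pipeline
#'
#' Simulate (and for EPG mode, match), then compute the repeatability
#' table; everything lands under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param dict Optional prebuilt dictionary (EPG mode).
#' @return List with `study` and `table`, invisibly.
#' @export
run_full <- function(config, out_dir, dict = NULL) {
  study <- run_simulate(config, out_dir)
  if (config$mode == "epg")
    study <- run_match(study, config, dict = dict, out_dir = out_dir)
  table <- run_stats(study, config, out_dir = out_dir)
  invisible(list(study = study, table = table))
}
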