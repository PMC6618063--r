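#' Write a velocity series as NIfTI files
#'
#' One 4D NIfTI per quantity: `<prefix>_mag.nii.gz`, `_vx`, `_vy`, `_vz`
#' (cardiac frame as the 4th dimension, voxel size in the header pixdims,
#' frame duration as the temporal pixdim), plus a JSON sidecar
#' `<prefix>_meta.json` carrying venc and frame duration exactly.
#'
#' @param series A [velocity_series()].
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_velocity_series <- function(series, prefix) {
  stopifnot(inherits(series, "velocity_series"))
  pd <- c(series$voxel_size, series$frame_duration / 1000)
  files <- character(0)
  wr <- function(arr, tag) {
    f <- paste0(prefix, "_", tag, ".nii.gz")
    img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, pd, 0, 0, 0)))
    RNifti::writeNifti(img, f)
    f
  }
  files <- c(files, wr(series$magnitude, "mag"))
  for (ci in 1:3)
    files <- c(files, wr(series$v[, , , , ci], c("vx", "vy", "vz")[ci]))
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(list(voxel_size = series$voxel_size,
                            frame_duration = series$frame_duration,
                            venc = series$venc),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}

#' Read a velocity series written by [write_velocity_series()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [velocity_series()].
#' @export
read_velocity_series <- function(prefix) {
  rd <- function(tag) {
    f <- paste0(prefix, "_", tag, ".nii.gz")
    if (!file.exists(f))
      stop_ctx("missing NIfTI file: ", f, class = "spiral4d_io")
    as.array(RNifti::readNifti(f))
  }
  meta_f <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_f))
    stop_ctx("missing sidecar: ", meta_f, class = "spiral4d_io")
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  mag <- rd("mag")
  d <- dim(mag)
  v <- array(0, dim = c(d, 3))
  for (ci in 1:3) v[, , , , ci] <- rd(c("vx", "vy", "vz")[ci])
  velocity_series(mag, v, voxel_size = meta$voxel_size,
                  frame_duration = meta$frame_duration, venc = meta$venc)
}

#' Write / read a logical mask as NIfTI
#'
#' @param mask Logical 3D array.
#' @param path Output `.nii.gz` path.
#' @param voxel_size Voxel size, mm (length 3).
#' @return `write_mask_nifti` the path; `read_mask_nifti` a logical array.
#' @export
write_mask_nifti <- function(mask, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         reference = list(pixdim = c(-1, voxel_size, rep(0, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path))
    stop_ctx("missing NIfTI file: ", path, class = "spiral4d_io")
  as.array(RNifti::readNifti(path)) != 0
}

#' Save / load intermediate pipeline objects
#'
#' Trajectories, k-space sample sets and binned k-space are R-native
#' containers; they round-trip through RDS files.
#'
#' @param object Object to save.
#' @param path File path (`.rds`).
#' @return `save_object` the path; `load_object` the object.
#' @export
save_object <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) {
  if (!file.exists(path))
    stop_ctx("missing file: ", path, class = "spiral4d_io")
  tryCatch(readRDS(path),
           error = function(e) stop_ctx("unreadable file ", path, ": ",
                                        conditionMessage(e),
                                        class = "spiral4d_io"))
}

#' Example per-patient flow-component volumes
#'
#' Plane-flow and pathline-analysis results of three clinical intracardiac
#' 4D flow examinations (ml and ml/s and m/s): net aortic and pulmonary
#' volumes, peak flow rates and velocities, pathline inflow/outflow, and
#' the four flow components. Used in examples and to exercise the
#' component-additivity identities.
#'
#' @return Data frame with one row per patient.
#' @export
patient_flow_table <- function() {
  data.frame(
    patient = 1:3,
    aa_flow = c(56, 66, 99), pt_flow = c(55, 61, 86),
    aa_peak_flow_rate = c(286, 354, 519),
    aa_peak_velocity = c(1.80, 1.34, 1.13),
    pt_peak_flow_rate = c(296, 295, 529),
    pt_peak_velocity = c(0.80, 0.74, 1.26),
    inflow = c(56, 46, 114), outflow = c(57, 58, 111),
    direct = c(17, 36, 66), retained_inflow = c(39, 10, 48),
    delayed_ejection = c(40, 22, 46), residual = c(87, 29, 75))
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end chain.
#' Accepts a YAML file path or a named list; unknown fields error.
#'
#' @param config Path to a YAML file or a named list with (optional)
#'   sections `phantom` (arguments of [phantom_spec()]), `sequence`
#'   ([sequence_params()]), `limits` ([gradient_limits()]), `gating`
#'   ([gating_config()]), `gridding` ([gridding_config()]), `navigator`
#'   ([navigator_config()]), `correction` (sd_percentile, magnitude_floor),
#'   `seed`, `out_dir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_ctx("config file not found: ", config, class = "spiral4d_io")
    config <- yaml::read_yaml(config)
  }
  known <- c("phantom", "sequence", "limits", "gating", "gridding",
             "navigator", "correction", "seed", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop_ctx("unknown config field(s): ", paste(bad, collapse = ", "),
             class = "spiral4d_config")
  build <- function(fn, args) do.call(fn, as.list(args %||% list()))
  structure(list(
    phantom = build(phantom_spec, config$phantom),
    sequence = build(sequence_params, config$sequence),
    limits = build(gradient_limits, config$limits),
    gating = build(gating_config, config$gating),
    gridding = build(gridding_config, config$gridding),
    navigator = build(navigator_config, config$navigator),
    correction = utils::modifyList(list(sd_percentile = 25,
                                        magnitude_floor = 0.1),
                                   as.list(config$correction %||% list())),
    seed = config$seed %||% 1L,
    out_dir = config$out_dir %||% tempfile("spiral4d_run_")),
    class = "pipeline_config")
}

#' Run the full acquisition-to-analysis pipeline
#'
#' Executes design, simulation, gating, reconstruction, background
#' correction, plane-flow quantification, pathline decomposition and the
#' conservation evaluation on the configured phantom, writing all artifacts
#' and a manifest into the output directory. Deterministic for a fixed
#' seed.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param correct_background Apply static-tissue background correction.
#' @param verbose Print per-stage progress.
#' @return List with the reconstructed `series`, `ground_truth`, plane-flow
#'   `inlet`/`outlet` results, pathline `components`, `conservation`,
#'   `sample_stats`, `binned` fill statistics, and `manifest` (also written
#'   as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         correct_background = TRUE, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[spiral4d] ", ...)
  t_start <- Sys.time()
  params <- config$sequence
  say("designing spiral trajectory")
  traj <- design_spiral_interleaf(params, config$limits)
  field <- make_phantom(config$phantom)
  n_beats_nom <- nominal_scan_time(params)
  rr <- sample_rr_intervals(config$phantom$rr_mean, config$phantom$rr_sd,
                            n = ceiling(n_beats_nom / 0.05) + 10,
                            seed = config$seed)
  resp <- respiratory_trace(config$phantom$resp_amplitude,
                            config$phantom$resp_period)
  say("simulating acquisition (", n_beats_nom, " lines)")
  samples <- simulate_acquisition(field, traj, params, rr,
                                  nav = config$navigator, resp = resp,
                                  seed = config$seed + 1L)
  say("gating into ", config$gating$n_frames, " frames")
  binned <- bin_samples(samples, config$gating)
  say("gridding reconstruction")
  segs_img <- grid_reconstruct(binned, traj, config$gridding)
  series <- phase_difference_velocity(segs_img)
  corrected <- series
  if (correct_background) {
    say("background correction")
    stat <- detect_static_tissue(series, config$correction$sd_percentile,
                                 config$correction$magnitude_floor)
    model <- fit_background(series, stat)
    corrected <- subtract_background(series, model)
  }
  say("flow quantification and pathlines")
  n <- params$matrix
  truth <- rasterize_phantom(field, matrix = n, voxel = params$voxel,
                             n_slices = params$n_slices_recon,
                             slice_thickness = params$slice_thickness,
                             n_frames = config$gating$n_frames)
  masks <- phantom_masks(field, matrix = n, voxel = params$voxel,
                         n_slices = params$n_slices_recon,
                         slice_thickness = params$slice_thickness)
  inlet <- quantify_flow(corrected,
                         phantom_plane(field, corrected, "inlet",
                                       dilate_mm = params$voxel))
  outlet <- quantify_flow(corrected,
                          phantom_plane(field, corrected, "outlet",
                                        dilate_mm = params$voxel))
  segs <- chamber_segmentations(
    ed_mask = masks$chamber, es_mask = masks$chamber,
    inlet_region = masks$inlet_mouth, outlet_region = masks$outlet_mouth,
    ed_frame = config$gating$n_frames,
    es_frame = max(1, round(binned$t_sys / binned$frame_duration)))
  comp <- pathline_decomposition(corrected, segs)
  cons <- conservation_check(comp)
  say("writing artifacts")
  write_velocity_series(corrected, file.path(config$out_dir, "recon"))
  save_object(traj, file.path(config$out_dir, "trajectory.rds"))
  save_object(binned, file.path(config$out_dir, "binned.rds"))
  utils::write.csv(inlet$curve, file.path(config$out_dir, "inlet_flow.csv"),
                   row.names = FALSE)
  results <- list(
    inlet_net_volume = inlet$net_volume, outlet_net_volume = outlet$net_volume,
    peak_flow_rate = inlet$peak_flow_rate,
    peak_velocity = inlet$peak_velocity,
    inflow = comp$inflow, outflow = comp$outflow,
    direct = comp$direct, retained_inflow = comp$retained_inflow,
    delayed_ejection = comp$delayed_ejection, residual = comp$residual,
    conservation_relative_difference = cons$relative_difference,
    fill_fraction = binned$fill_fraction,
    navigator_efficiency = samples$efficiency)
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    parameters = list(sequence = unclass(params),
                      phantom = unclass(config$phantom),
                      gating = unclass(config$gating)),
    checksums = as.list(tools::md5sum(list.files(config$out_dir,
                                                 full.names = TRUE,
                                                 pattern = "\\.(nii.gz|csv|rds)$"))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(series = corrected, raw_series = series,
                 ground_truth = truth, masks = masks, inlet = inlet,
                 outlet = outlet, components = comp, conservation = cons,
                 sample_stats = actual_scan_time(samples), binned = binned,
                 trajectory = traj, results = results, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Export pathlines as CSV
#'
#' Long-format table (pathline id, step time, x, y, z) for external
#' viewers.
#'
#' @param pset A `pathline_set`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_pathlines_csv <- function(pset, path) {
  stopifnot(inherits(pset, "pathline_set"))
  d <- dim(pset$positions)
  df <- data.frame(
    pathline = rep(seq_len(d[2]), each = d[1]),
    time = rep(pset$times, d[2]),
    x = as.vector(pset$positions[, , 1]),
    y = as.vector(pset$positions[, , 2]),
    z = as.vector(pset$positions[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
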