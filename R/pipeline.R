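# End-to-end synthetic validation pipeline: generate -> mesh -> simulate ->
# process -> validate, with a provenance manifest.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration of the synthetic end-to-end
#' experiment. Accepts a YAML file path or a list; unspecified fields take
#' the documented defaults, which define the package's reference study
#' conditions (sphere-phantom geometry, clinical-style implantation, 0.3 ms
#' pulses at 1 kHz, gain 200, 2 uV noise).
#'
#' @param config list or YAML path; \code{NULL} for all defaults.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  def <- list(
    radii_mm = c(scalp = 92, skull = 86, csf = 80, gray = 78, white = 66),
    voxel_size_mm = 1,
    grid_margin_mm = 2,
    node_shift = 0.3,
    model_levels = c("3C", "4C", "5C"),
    truth_level = "5C",
    n_shafts = 8L,
    contacts_per_shaft = 12L,
    n_pairs = 20L,
    n_events_per_pair = 2L,
    inter_event_samples = 500L,
    pulse = list(duration_ms = 0.3, highpass_corner_hz = 80,
                 amplitude_gain = 200, onset_offset_ms = 0.4),
    noise_sd_uv = 2,
    bad_channels = character(),
    fs_hz = 1000,
    hp_hz = 10,
    epoch_window_ms = c(-100, 200),
    baseline_window_ms = c(-100, -10),
    variance_threshold_uv = 1e4,
    near_stim_mm = 5,
    rel_tol = 1e-8,
    scale_fit = "l1",
    pool = TRUE,
    bin_mm = 5,
    seed = 1L)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) def[[nm]] <- config[[nm]]
  if (!is.null(names(def$radii_mm)) || is.list(def$radii_mm))
    def$radii_mm <- unlist(def$radii_mm)
  def$model_levels <- as.character(unlist(def$model_levels))
  bad_lvl <- setdiff(def$model_levels, c("3C", "4C", "5C"))
  if (length(bad_lvl))
    stop("unknown model level(s): ", paste(bad_lvl, collapse = ", "))
  if (!def$truth_level %in% c("3C", "4C", "5C"))
    stop("unknown truth level: ", def$truth_level)
  if (!def$scale_fit %in% c("l1", "l2"))
    stop("scale_fit must be 'l1' or 'l2'")
  structure(def, class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config[order(names(unclass(config)))], f)
  unname(tools::md5sum(f))
}

#' Run the synthetic validation pipeline
#'
#' Executes the full chain: sphere phantom, electrode implantation,
#' stimulation plan, ground-truth analytic recording, hexahedral meshing,
#' one FEM potential table per head-model level (3C/4C/5C share the mesh;
#' only tissue conductivities change), measurement-side processing, and the
#' validation fit. All randomness derives from \code{config$seed}, so a
#' rerun with the same configuration reproduces every output bit-identically.
#'
#' @param config a \code{pipeline_config} (or anything accepted by
#'   \code{\link{pipeline_config}}).
#' @param out_dir optional output directory; when given, intermediates
#'   (volume, electrodes, plan, recording, tables), the report JSON, and a
#'   provenance manifest (config, its hash, seeds, package version) are
#'   written there.
#' @return list with the fitted \code{vc_validation} report, the
#'   intermediate objects, and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  config <- pipeline_config(config)
  stage <- "phantom"
  res <- list(config = config)
  tryCatch({
    vol <- sphere_phantom(config$radii_mm, config$voxel_size_mm,
                          config$grid_margin_mm)
    res$volume <- vol

    stage <- "electrodes"
    electrodes <- place_shafts(vol, config$n_shafts,
                               config$contacts_per_shaft,
                               seed = config$seed,
                               inside_radius_mm = max(config$radii_mm))
    plan <- make_stimulation_plan(electrodes, config$n_pairs,
                                  config$n_events_per_pair,
                                  config$inter_event_samples,
                                  seed = config$seed + 1L,
                                  max_midpoint_radius_mm =
                                    min(config$radii_mm) - 1)
    res$electrodes <- electrodes
    res$plan <- plan

    stage <- "simulate-recording"
    truth <- shell_model_for_profile(config$radii_mm, config$truth_level)
    pulse <- do.call(pulse_model, config$pulse)
    rec <- simulate_recording(electrodes, plan, truth, pulse,
                              noise_sd_uv = config$noise_sd_uv,
                              bad_channels = config$bad_channels,
                              seed = config$seed + 2L,
                              fs_hz = config$fs_hz)
    res$recording <- rec

    stage <- "process"
    meas <- measured_peak_table(rec, vol, electrodes, plan,
                                hp_hz = config$hp_hz,
                                epoch_window_ms = config$epoch_window_ms,
                                baseline_window_ms = config$baseline_window_ms,
                                variance_threshold_uv =
                                  config$variance_threshold_uv,
                                near_stim_mm = config$near_stim_mm)
    res$measured <- meas

    stage <- "mesh"
    mesh <- voxels_to_hex_mesh(vol, config$node_shift)
    res$mesh <- mesh

    stage <- "forward"
    sims <- list()
    for (lvl in config$model_levels) {
      sys <- assemble_stiffness(mesh, conductivity_profile(lvl))
      sims[[lvl]] <- simulate_potential_table(
        mesh, conductivity_profile(lvl), electrodes, plan,
        montage = meas$montage, rel_tol = config$rel_tol, system = sys)
    }
    res$simulated <- sims

    stage <- "validate"
    dist <- pair_channel_distances(electrodes, plan, meas$montage)
    report <- vc_validate(meas$table, sims, rms_uv = meas$rms_uv,
                          distances = dist,
                          sim_gain = rec$sampled_peak,
                          pool = config$pool,
                          objective = config$scale_fit,
                          bin_mm = config$bin_mm)
    res$report <- report

    manifest <- list(config = unclass(config),
                     config_hash = config_hash(config),
                     seeds = list(electrodes = config$seed,
                                  plan = config$seed + 1L,
                                  recording = config$seed + 2L),
                     package = "seegvc",
                     version = as.character(utils::packageVersion("seegvc")))
    res$manifest <- manifest

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_labeled_volume(vol, file.path(out_dir, "phantom.nii.gz"))
      write_electrodes(electrodes, file.path(out_dir, "electrodes"))
      write_stim_plan(plan, file.path(out_dir, "stim"))
      write_recording(rec, file.path(out_dir, "recording"))
      write_potential_table(meas$table, file.path(out_dir, "measured.tsv"))
      for (lvl in names(sims))
        write_potential_table(sims[[lvl]],
                              file.path(out_dir,
                                        sprintf("simulated_%s.tsv", lvl)))
      jsonlite::write_json(report_as_list(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    res
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Serializable form of a validation report
#'
#' Plain-list (JSON-ready) representation of a \code{vc_validation};
#' \code{report_from_list} restores the numeric content losslessly.
#'
#' @param report a \code{vc_validation}.
#' @export
report_as_list <- function(report) {
  list(scale = report$scale, rms_uv = report$rms_uv, q = report$q,
       levels = lapply(report$levels, function(l) {
         out <- list(median_rel_pct = l$median_rel_pct,
                     percentile_abs_uv = l$percentile_abs_uv,
                     cdf_value = l$cdf$value,
                     cdf_fraction = l$cdf$fraction)
         if (!is.null(l$distance_bins))
           out$distance_bins <- as.list(l$distance_bins)
         out
       }))
}

#' @rdname report_as_list
#' @param x a list produced by \code{report_as_list} (possibly after a JSON
#'   round trip).
#' @export
report_from_list <- function(x) {
  num <- function(col) {
    if (is.list(col))
      col <- lapply(col, function(e) if (is.null(e)) NA else e)
    suppressWarnings(as.numeric(unlist(col)))
  }
  x$scale <- num(x$scale)
  x$levels <- lapply(x$levels, function(l) {
    l$cdf_value <- num(l$cdf_value)
    l$cdf_fraction <- num(l$cdf_fraction)
    if (!is.null(l$distance_bins))
      l$distance_bins <- as.data.frame(lapply(l$distance_bins, num))
    l
  })
  x
}
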