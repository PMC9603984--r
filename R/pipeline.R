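#' Default pipeline configuration
#'
#' One flat, versioned key-value configuration driving
#' \code{\link{run_pipeline}}.  Defaults mirror the primary-screen design:
#' 13 frames at 15-min intervals, 8-of-13 frame rule, slope-SE cutoff 2.5,
#' median/IQR plate normalization over compound wells and a hit threshold of
#' 1 IQR above the plate median.  Serialized as YAML; every run writes its
#' resolved configuration next to its outputs.
#'
#' Keys (defaults in parentheses): \code{config_version}; \code{seed} (1);
#' simulation — \code{simulate} (TRUE), \code{n_plates} (4),
#' \code{plate_format} (384), \code{n_compounds} (320), \code{pooled} (TRUE),
#' \code{n_dmso}/\code{n_eact} (16), \code{n_active} (10),
#' \code{active_effect_iqr} (3: spiked active excess in nominal well-IQR
#' units), \code{plate_shift_sd} (0.8) and \code{plate_scale_spread} (0.15)
#' for per-plate artifacts, plus the \code{\link{sim_config}} fields
#' \code{n_frames} through \code{min_separation}; inputs —
#' \code{layout_csv}, \code{detections_csv} (used when \code{simulate} is
#' FALSE); analysis — \code{diameter_rule} ("mean"), \code{max_displacement}
#' (30), \code{memory} (5), \code{n_frames_total} (= \code{n_frames}),
#' \code{se_max} (2.5), \code{min_frames} (NULL: 8-of-13 scaling),
#' \code{control_policy} ("compounds"), \code{quantile_type} (7),
#' \code{hit_threshold} (1.0), \code{weighting} ("well").
#'
#' @return named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    config_version = "1",
    seed = 1L,
    # --- simulation design ---
    simulate = TRUE,
    n_plates = 4L,
    plate_format = 384L,
    n_compounds = 320L,
    pooled = TRUE,
    n_dmso = 16L,
    n_eact = 16L,
    n_active = 10L,
    active_effect_iqr = 3,
    plate_shift_sd = 0.8,
    plate_scale_spread = 0.15,
    # --- sim_config fields ---
    n_frames = 13L,
    frame_interval = 15,
    organoids_per_well = 15,
    baseline_area_mean = 300,
    baseline_area_sd = 75,
    slope_dmso = 2,
    slope_eact = 60,
    slope_compound = 2,
    slope_noise_sd = 2,
    area_obs_noise_sd = 8,
    detection_dropout_p = 0.05,
    bbox_jitter_sd = 0.5,
    min_area = 1,
    image_size = 700,
    min_separation = NULL,
    # --- external inputs (when simulate = FALSE) ---
    layout_csv = NULL,
    detections_csv = NULL,
    # --- analysis parameters ---
    diameter_rule = "mean",
    max_displacement = 30,
    memory = 5L,
    n_frames_total = NULL,
    se_max = 2.5,
    min_frames = NULL,
    control_policy = "compounds",
    quantile_type = 7,
    hit_threshold = 1.0,
    weighting = "well"
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param config named list of overrides (possibly partial).
#' @return the resolved full configuration list.
#' @export
resolve_config <- function(config = list()) {
  defs <- default_config()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- defs
  cfg[names(config)] <- config
  if (is.null(cfg$n_frames_total)) cfg$n_frames_total <- cfg$n_frames
  if (!cfg$simulate && (is.null(cfg$layout_csv) || is.null(cfg$detections_csv)))
    .stopf("simulate = FALSE requires layout_csv and detections_csv")
  cfg
}

#' @rdname resolve_config
#' @param path YAML file path.
#' @export
read_config <- function(path) resolve_config(yaml::read_yaml(path))

#' @rdname resolve_config
#' @param config configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

# sim_config from the flat pipeline config (+ per-plate artifacts and spikes)
.sim_from_pipeline <- function(cfg, plate_ids, compounds, actives) {
  shifts <- scales <- NULL
  if (cfg$plate_shift_sd > 0 || cfg$plate_scale_spread > 0) {
    art <- .with_seed(.hash31(cfg$seed, "plate-artifacts"), list(
      shift = rnorm(length(plate_ids), 0, cfg$plate_shift_sd),
      scale = exp(rnorm(length(plate_ids), 0, cfg$plate_scale_spread))))
    shifts <- setNames(art$shift, plate_ids)
    scales <- setNames(art$scale, plate_ids)
  }
  base <- sim_config(
    seed = cfg$seed, n_frames = cfg$n_frames, frame_interval = cfg$frame_interval,
    organoids_per_well = cfg$organoids_per_well,
    baseline_area_mean = cfg$baseline_area_mean, baseline_area_sd = cfg$baseline_area_sd,
    swell_effect = c(dmso_control = cfg$slope_dmso, eact_control = cfg$slope_eact,
                     compound = cfg$slope_compound),
    slope_noise_sd = cfg$slope_noise_sd, area_obs_noise_sd = cfg$area_obs_noise_sd,
    detection_dropout_p = cfg$detection_dropout_p, bbox_jitter_sd = cfg$bbox_jitter_sd,
    plate_shift = if (is.null(shifts)) 0 else shifts,
    plate_scale = if (is.null(scales)) 1 else scales,
    min_area = cfg$min_area, image_size = cfg$image_size,
    min_separation = cfg$min_separation)
  if (length(actives)) {
    delta <- cfg$active_effect_iqr * nominal_well_iqr(base)
    base$compound_effects <- setNames(rep(cfg$slope_compound + delta, length(actives)), actives)
  }
  base
}

# compound ordering that puts each spiked active in its own pooled well,
# paired with an inactive filler
.screen_compounds <- function(n_compounds, n_active) {
  ids <- sprintf("C%03d", seq_len(n_compounds))
  if (n_active == 0) return(list(order = ids, actives = character(0)))
  if (2L * n_active > n_compounds)
    .stopf("n_active (%d) too large for %d compounds in pooled wells", n_active, n_compounds)
  actives <- ids[seq_len(n_active)]
  fillers <- ids[seq(n_active + 1L, 2L * n_active)]
  rest <- ids[seq(2L * n_active + 1L, n_compounds)]
  list(order = c(as.vector(rbind(actives, fillers)), rest), actives = actives)
}

#' Run the full screening pipeline
#'
#' Executes simulate (or load) -> box-to-area conversion -> tracking ->
#' swell-rate fitting with QC -> well aggregation -> plate normalization and
#' hit calling, writing every stage's table, the resolved configuration, a
#' machine-readable JSON summary and a plain-text log into \code{out_dir}.
#' Identical configurations (including seed) produce byte-identical outputs.
#'
#' @param config configuration overrides (list) or a path to a YAML file; see
#'   \code{\link{default_config}}.
#' @param out_dir output directory (created; existing files overwritten).
#' @return the summary list, invisibly.  Key fields: organoid and exclusion
#'   counts per rule, dropped wells and plates, hit compounds and — for
#'   simulated runs with spiked actives — hit sensitivity and false-positive
#'   rate against ground truth.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (is.character(config)) read_config(config) else resolve_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- character(0)
  say <- function(fmt, ...) logf <<- c(logf, sprintf(fmt, ...))
  write_config(cfg, file.path(out_dir, "config.yaml"))

  actives <- character(0)
  truth_actives <- NULL
  if (cfg$simulate) {
    plate_ids <- sprintf("P%d", seq_len(cfg$n_plates))
    cp <- .screen_compounds(cfg$n_compounds, cfg$n_active)
    actives <- cp$actives
    layout <- do.call(rbind, lapply(plate_ids, function(p)
      screen_layout(p, cp$order, format = cfg$plate_format, pooled = cfg$pooled,
                    n_dmso = cfg$n_dmso, n_eact = cfg$n_eact)))
    layout <- validate_layout(layout)
    scfg <- .sim_from_pipeline(cfg, plate_ids, cp$order, actives)
    say("stage simulate: %d plate(s), %d wells, %d compounds (%d spiked active)",
        cfg$n_plates, nrow(layout), cfg$n_compounds, cfg$n_active)
    sim <- simulate_screen(layout, scfg)
    detections <- sim$detections
    say("stage simulate: %d detections from %d organoids (%d clipped areas)",
        nrow(detections), nrow(sim$truth$organoids), sim$n_clipped)
    write_truth(sim$truth, file.path(out_dir, "truth.csv"))
    truth_actives <- actives
  } else {
    layout <- read_layout(cfg$layout_csv)
    detections <- read_detections(cfg$detections_csv)
    say("stage load: %d detections, %d layout wells", nrow(detections), nrow(layout))
  }
  write_layout(layout, file.path(out_dir, "layout.csv"))
  write_detections(detections, file.path(out_dir, "detections.csv"))

  areas <- boxes_to_areas(detections, rule = cfg$diameter_rule)
  write_areas(areas, file.path(out_dir, "areas.csv"))
  say("stage areas: %d area observations (diameter rule: %s)", nrow(areas), cfg$diameter_rule)

  tracks <- link_tracks(areas, max_displacement = cfg$max_displacement, memory = cfg$memory)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  say("stage track: %d tracks (gate %g px/frame, memory %d)",
      length(unique(tracks$track_id)), cfg$max_displacement, cfg$memory)

  fit <- fit_swell(tracks, n_frames_total = cfg$n_frames_total,
                   se_max = cfg$se_max, min_frames = cfg$min_frames)
  write_fits(fit, file.path(out_dir, "fits.csv"))
  write_wells(fit, file.path(out_dir, "wells.csv"))
  qc <- table(factor(fit$fits$qc_status, c("included", "excluded_frames", "excluded_se")))
  say("stage quantify: %d organoids -> %d included, %d excluded (frame rule), %d excluded (SE rule)",
      nrow(fit$fits), qc[["included"]], qc[["excluded_frames"]], qc[["excluded_se"]])
  say("stage quantify: %d well(s) with no included organoid", sum(fit$wells$missing))

  scr <- screen_organoids(fit$wells, layout, threshold = cfg$hit_threshold,
                          control_policy = cfg$control_policy,
                          quantile_type = cfg$quantile_type, weighting = cfg$weighting)
  .write_csv(scr$normalized, file.path(out_dir, "normalized.csv"))
  .write_csv(scr$compounds, file.path(out_dir, "screen_table.csv"))
  hits <- scr$compounds$compound[scr$compounds$hit]
  writeLines(c("compound", hits), file.path(out_dir, "hit_compounds.csv"))
  writeLines(c("compound", scr$secondary_list), file.path(out_dir, "secondary_list.csv"))
  say("stage screen: %d hit compound(s) from %d hit well(s); %d plate(s) dropped",
      length(hits), nrow(scr$hit_wells), length(scr$dropped_plates))

  summary <- list(
    config_version = cfg$config_version, seed = cfg$seed,
    n_detections = nrow(detections), n_area_observations = nrow(areas),
    n_tracks = nrow(fit$fits),
    qc = list(included = unname(qc[["included"]]),
              excluded_frames = unname(qc[["excluded_frames"]]),
              excluded_se = unname(qc[["excluded_se"]])),
    n_missing_wells = sum(fit$wells$missing),
    dropped_plates = scr$dropped_plates,
    dropped_compounds = scr$dropped_compounds,
    n_compounds_scored = nrow(scr$compounds),
    n_hit_wells = nrow(scr$hit_wells),
    hit_compounds = hits,
    secondary_list = scr$secondary_list)
  if (!is.null(truth_actives)) {
    inactive <- setdiff(scr$compounds$compound, truth_actives)
    summary$truth <- list(
      active_compounds = truth_actives,
      sensitivity = if (length(truth_actives))
        mean(truth_actives %in% hits) else NA,
      false_positive_rate = if (length(inactive))
        mean(inactive %in% hits) else NA)
    say("stage evaluate: sensitivity %.3f, false-positive rate %.4f",
        summary$truth$sensitivity, summary$truth$false_positive_rate)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(logf, file.path(out_dir, "log.txt"))
  invisible(summary)
}
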