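#' Simulation configuration
#'
#' Parameters of the synthetic screen generator.  Defaults mirror the primary
#' screen design: 13 brightfield frames at 15-min intervals, a Poisson number
#' of organoids per well, organoid-level linear swelling with slope and
#' area-observation noise, per-frame detection dropout, bounding-box edge
#' jitter, and additive/multiplicative plate-level artifacts.
#'
#' @param seed integer master seed; per-well streams are derived from it so
#'   adding wells or plates does not perturb existing wells' draws.
#' @param n_frames number of time points (>= 2; default 13, the 3-h screen).
#' @param frame_interval minutes between frames (default 15).
#' @param organoids_per_well Poisson mean organoid count per well (default 15;
#'   the assay fixes no per-well count, see the methods vignette).
#' @param baseline_area_mean,baseline_area_sd baseline organoid area, pixel^2.
#' @param swell_effect named numeric map condition -> mean true slope in
#'   pixel^2 per time point, with entries \code{dmso_control},
#'   \code{eact_control} and \code{compound} (the default for compound wells
#'   without a per-compound entry in \code{compound_effects}).
#' @param compound_effects optional named numeric vector of per-compound mean
#'   slopes overriding \code{swell_effect["compound"]}.
#' @param slope_noise_sd organoid-to-organoid SD of the true slope.
#' @param area_obs_noise_sd per-frame additive SD of the observed area, pixel^2.
#' @param detection_dropout_p probability that a frame's detection is missed.
#' @param bbox_jitter_sd SD of independent Gaussian jitter on each box edge, px.
#' @param plate_shift named (by plate) or scalar additive slope offset per plate.
#' @param plate_scale named or scalar multiplicative slope factor per plate.
#' @param min_area floor for simulated areas, pixel^2; clipping is counted.
#' @param image_size side of the square well image, px.
#' @param min_separation minimum organoid center separation, px; \code{NULL}
#'   (default) uses twice the largest plausible organoid radius so noise-free
#'   tracking is unambiguous.  Set smaller explicitly to stress the tracker.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_frames = 13L,
                       frame_interval = 15,
                       organoids_per_well = 15,
                       baseline_area_mean = 300,
                       baseline_area_sd = 75,
                       swell_effect = c(dmso_control = 2, eact_control = 60, compound = 2),
                       compound_effects = NULL,
                       slope_noise_sd = 2,
                       area_obs_noise_sd = 8,
                       detection_dropout_p = 0.05,
                       bbox_jitter_sd = 0.5,
                       plate_shift = 0,
                       plate_scale = 1,
                       min_area = 1,
                       image_size = 700,
                       min_separation = NULL) {
  cfg <- list(seed = seed, n_frames = n_frames, frame_interval = frame_interval,
              organoids_per_well = organoids_per_well,
              baseline_area_mean = baseline_area_mean, baseline_area_sd = baseline_area_sd,
              swell_effect = swell_effect, compound_effects = compound_effects,
              slope_noise_sd = slope_noise_sd, area_obs_noise_sd = area_obs_noise_sd,
              detection_dropout_p = detection_dropout_p, bbox_jitter_sd = bbox_jitter_sd,
              plate_shift = plate_shift, plate_scale = plate_scale,
              min_area = min_area, image_size = image_size, min_separation = min_separation)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a configuration list to validate.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) .stopf("invalid configuration field '%s': %s", field, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "must be a single integer")
  chk(num1(cfg$n_frames) && cfg$n_frames >= 2, "n_frames", "must be >= 2")
  chk(num1(cfg$frame_interval) && cfg$frame_interval > 0, "frame_interval", "must be > 0")
  chk(num1(cfg$organoids_per_well) && cfg$organoids_per_well > 0, "organoids_per_well", "must be > 0")
  chk(num1(cfg$baseline_area_mean) && cfg$baseline_area_mean > 0, "baseline_area_mean", "must be > 0")
  chk(num1(cfg$baseline_area_sd) && cfg$baseline_area_sd >= 0, "baseline_area_sd", "must be >= 0")
  chk(is.numeric(cfg$swell_effect) && all(c("dmso_control", "eact_control", "compound")
      %in% names(cfg$swell_effect)), "swell_effect",
      "must be a named numeric vector with dmso_control, eact_control and compound entries")
  if (!is.null(cfg$compound_effects))
    chk(is.numeric(cfg$compound_effects) && !is.null(names(cfg$compound_effects)),
        "compound_effects", "must be a named numeric vector")
  chk(num1(cfg$slope_noise_sd) && cfg$slope_noise_sd >= 0, "slope_noise_sd", "must be >= 0")
  chk(num1(cfg$area_obs_noise_sd) && cfg$area_obs_noise_sd >= 0, "area_obs_noise_sd", "must be >= 0")
  chk(num1(cfg$detection_dropout_p) && cfg$detection_dropout_p >= 0 && cfg$detection_dropout_p <= 1,
      "detection_dropout_p", "must be a probability in [0, 1]")
  chk(num1(cfg$bbox_jitter_sd) && cfg$bbox_jitter_sd >= 0, "bbox_jitter_sd", "must be >= 0")
  chk(is.numeric(cfg$plate_shift), "plate_shift", "must be numeric (scalar or named by plate)")
  chk(is.numeric(cfg$plate_scale) && all(cfg$plate_scale > 0), "plate_scale", "must be positive")
  chk(num1(cfg$min_area) && cfg$min_area > 0, "min_area", "must be > 0")
  chk(num1(cfg$image_size) && cfg$image_size >= 32, "image_size", "must be >= 32")
  if (!is.null(cfg$min_separation))
    chk(num1(cfg$min_separation) && cfg$min_separation >= 0, "min_separation", "must be >= 0")
  cfg$n_frames <- as.integer(cfg$n_frames)
  class(cfg) <- "sim_config"
  cfg
}

# per-plate value lookup for plate_shift / plate_scale
.plate_param <- function(x, plate_id, default) {
  if (is.null(names(x))) {
    if (length(x) != 1L) .stopf("unnamed plate parameter must be scalar")
    return(unname(x))
  }
  if (plate_id %in% names(x)) unname(x[[plate_id]]) else default
}

#' Nominal well-rate interquartile range under a configuration
#'
#' Normal-approximation IQR of the per-well mean swell rate among wells that
#' share one true condition effect: the well-level SD combines the
#' organoid-to-organoid slope spread and the OLS slope noise induced by
#' per-frame area noise — direct area observation noise plus the area noise
#' implied by box-edge jitter at the baseline organoid diameter
#' (\code{(pi/2) * d * jitter_sd} via the disk-area delta method) — shrunk by
#' the expected organoid count.  Used to express spiked active effects in IQR
#' units when designing a synthetic screen.
#'
#' @param cfg a \code{sim_config}.
#' @return the nominal IQR of well mean swell rates, pixel^2 per time point.
#' @export
nominal_well_iqr <- function(cfg) {
  f <- 0:(cfg$n_frames - 1L)
  sxx <- sum((f - mean(f))^2)
  d_bar <- 2 * sqrt(cfg$baseline_area_mean / pi)
  area_var <- cfg$area_obs_noise_sd^2 + (pi * d_bar * cfg$bbox_jitter_sd / 2)^2
  per_org_var <- cfg$slope_noise_sd^2 + area_var / sxx
  well_sd <- sqrt(per_org_var / cfg$organoids_per_well)
  2 * stats::qnorm(0.75) * well_sd
}
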