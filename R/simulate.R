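#' Simulate a time-lapse organoid screen with known ground truth
#'
#' Generates per-frame bounding-box detections for every well of a layout.
#' Each organoid follows a linear area trajectory
#' \code{area(f) = baseline + slope * f + noise}, where the true slope is drawn
#' around its well's condition effect and then distorted by plate-level
#' artifacts (\code{plate_scale * slope + plate_shift}).  Areas are converted
#' to square boxes (side \code{2*sqrt(area/pi)}, the inverse of the disk-area
#' assumption used at analysis time), each edge jittered independently; frames
#' are dropped independently with the configured dropout probability.
#'
#' Pooled compound wells combine their two compounds additively: the well's
#' mean slope is the compound baseline effect plus each listed compound's
#' excess over that baseline.
#'
#' Random streams are split per (plate, well) from the master seed, so adding
#' wells or plates never perturbs existing wells' draws.
#'
#' @param layout a \code{\link{plate_layout}} (one or several plates).
#' @param cfg a \code{\link{sim_config}}.
#' @return a list with elements
#'   \item{detections}{data.frame \code{plate_id, well, frame, x_min, y_min,
#'     x_max, y_max, confidence} (0-based frames, half-open pixel boxes)}
#'   \item{truth}{list of \code{organoids} (one row per simulated organoid:
#'     center, baseline, \code{true_slope} after plate effects, condition,
#'     frames detected) and \code{frames} (per organoid-frame: noise-free
#'     \code{true_area}, observed \code{area}, \code{detected} flag,
#'     \code{organoid_id})}
#'   \item{n_clipped}{count of area observations clipped at the floor}
#' @export
simulate_screen <- function(layout, cfg) {
  layout <- validate_layout(as.data.frame(layout))
  cfg <- validate_sim_config(unclass(cfg))
  cond <- .condition_of(layout)
  eff_base <- cfg$swell_effect[["compound"]]

  # largest plausible radius fixes the placement margin and min separation
  max_eff <- max(cfg$swell_effect,
                 if (!is.null(cfg$compound_effects)) eff_base +
                   sum(pmax(cfg$compound_effects - eff_base, 0)) else -Inf)
  amax <- cfg$baseline_area_mean + 3 * cfg$baseline_area_sd +
    max(0, (max_eff + 3 * cfg$slope_noise_sd)) * (cfg$n_frames - 1) +
    3 * cfg$area_obs_noise_sd
  rmax <- sqrt(amax / pi)
  minsep <- if (is.null(cfg$min_separation)) 2 * rmax else cfg$min_separation
  margin <- rmax + 3 * cfg$bbox_jitter_sd + 1
  if (2 * margin >= cfg$image_size)
    .stopf("invalid configuration field 'image_size': %g too small for organoid radius %.1f",
           cfg$image_size, rmax)

  frames <- 0:(cfg$n_frames - 1L)
  det <- vector("list", nrow(layout))
  org <- vector("list", nrow(layout))
  frm <- vector("list", nrow(layout))
  n_clipped <- 0L

  for (i in seq_len(nrow(layout))) {
    plate <- layout$plate_id[i]; wl <- layout$well[i]
    mu <- switch(cond[i],
      dmso_control = cfg$swell_effect[["dmso_control"]],
      eact_control = cfg$swell_effect[["eact_control"]],
      compound = {
        cs <- stats::na.omit(c(layout$compound_1[i], layout$compound_2[i]))
        extra <- 0
        if (!is.null(cfg$compound_effects)) {
          hit <- intersect(cs, names(cfg$compound_effects))
          extra <- sum(cfg$compound_effects[hit] - eff_base)
        }
        eff_base + extra
      })
    pscale <- .plate_param(cfg$plate_scale, plate, 1)
    pshift <- .plate_param(cfg$plate_shift, plate, 0)

    res <- .with_seed(.hash31(cfg$seed, plate, wl), {
      n <- rpois(1L, cfg$organoids_per_well)
      centers <- .place_centers(n, cfg$image_size, margin, minsep)
      n <- nrow(centers)
      if (n == 0L) NULL else {
        raw_slope <- rnorm(n, mu, cfg$slope_noise_sd)
        slope <- pscale * raw_slope + pshift
        baseline <- pmax(rnorm(n, cfg$baseline_area_mean, cfg$baseline_area_sd),
                         cfg$min_area)
        true_area <- outer(baseline, rep(1, length(frames))) +
          outer(slope, frames)
        obs_area <- true_area +
          matrix(rnorm(n * length(frames), 0, cfg$area_obs_noise_sd), n)
        clip <- obs_area < cfg$min_area
        obs_area[clip] <- cfg$min_area
        keep <- matrix(runif(n * length(frames)) >= cfg$detection_dropout_p, n)
        side <- 2 * sqrt(obs_area / pi)
        jit <- function() matrix(rnorm(n * length(frames), 0, cfg$bbox_jitter_sd), n)
        x_min <- centers[, 1] - side / 2 + jit(); x_max <- centers[, 1] + side / 2 + jit()
        y_min <- centers[, 2] - side / 2 + jit(); y_max <- centers[, 2] + side / 2 + jit()
        deg <- x_max - x_min < 0.5
        if (any(deg)) { m <- (x_min + x_max) / 2; x_min[deg] <- m[deg] - 0.25; x_max[deg] <- m[deg] + 0.25 }
        deg <- y_max - y_min < 0.5
        if (any(deg)) { m <- (y_min + y_max) / 2; y_min[deg] <- m[deg] - 0.25; y_max[deg] <- m[deg] + 0.25 }
        confidence <- matrix(runif(n * length(frames), 0.7, 1), n)
        list(n = n, centers = centers, raw_slope = raw_slope, slope = slope,
             baseline = baseline, true_area = true_area, obs_area = obs_area,
             keep = keep, x_min = x_min, x_max = x_max, y_min = y_min,
             y_max = y_max, confidence = confidence, n_clip = sum(clip))
      }
    })
    if (is.null(res)) next
    n <- res$n
    n_clipped <- n_clipped + res$n_clip
    idx <- which(res$keep, arr.ind = TRUE)
    if (nrow(idx)) {
      d <- data.frame(
        plate_id = plate, well = wl, frame = frames[idx[, 2]],
        x_min = res$x_min[idx], y_min = res$y_min[idx],
        x_max = res$x_max[idx], y_max = res$y_max[idx],
        confidence = res$confidence[idx],
        stringsAsFactors = FALSE)
      d <- d[order(d$frame, d$y_min, d$x_min), ]
      det[[i]] <- d
    }
    org[[i]] <- data.frame(
      plate_id = plate, well = wl, organoid_id = seq_len(n),
      x = res$centers[, 1], y = res$centers[, 2],
      baseline = res$baseline, true_slope = res$slope,
      raw_slope = res$raw_slope, condition = cond[i],
      n_frames_detected = rowSums(res$keep), stringsAsFactors = FALSE)
    frm[[i]] <- data.frame(
      plate_id = plate, well = wl,
      organoid_id = rep(seq_len(n), times = length(frames)),
      frame = rep(frames, each = n),
      true_area = as.vector(res$true_area),
      area = as.vector(res$obs_area),
      detected = as.vector(res$keep), stringsAsFactors = FALSE)
  }

  detections <- do.call(rbind, det[!vapply(det, is.null, TRUE)])
  if (is.null(detections))
    detections <- data.frame(plate_id = character(), well = character(),
                             frame = integer(), x_min = numeric(), y_min = numeric(),
                             x_max = numeric(), y_max = numeric(), confidence = numeric())
  rownames(detections) <- NULL
  organoids <- do.call(rbind, org[!vapply(org, is.null, TRUE)])
  framesdf <- do.call(rbind, frm[!vapply(frm, is.null, TRUE)])
  rownames(organoids) <- rownames(framesdf) <- NULL
  list(detections = detections,
       truth = list(organoids = organoids, frames = framesdf),
       n_clipped = n_clipped)
}

# dart-throwing placement: uniform centers with a minimum pairwise separation;
# gives up on an organoid after 200 failed darts (dense configs) rather than loop
.place_centers <- function(n, image_size, margin, minsep) {
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  cx <- numeric(0); cy <- numeric(0)
  for (k in seq_len(n)) {
    for (try in seq_len(200L)) {
      x <- runif(1, margin, image_size - margin)
      y <- runif(1, margin, image_size - margin)
      if (!length(cx) || all((cx - x)^2 + (cy - y)^2 >= minsep^2)) {
        cx <- c(cx, x); cy <- c(cy, y); break
      }
    }
  }
  cbind(x = cx, y = cy)
}

#' Write / read simulated detections and ground truth
#'
#' Detections CSV dialect: \code{plate_id, well, frame, x_min, y_min, x_max,
#' y_max, confidence} with 0-based frames and half-open pixel boxes.  The truth
#' CSV mirrors the per-frame table plus \code{organoid_id} and
#' \code{true_slope}.
#'
#' @param detections detections data.frame.
#' @param path file path.
#' @export
write_detections <- function(detections, path) {
  .assert_cols(detections, c("plate_id", "well", "frame", "x_min", "y_min", "x_max", "y_max"),
               "detections")
  .write_csv(detections, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(plate_id = "character", well = "character"))
  .assert_cols(d, c("plate_id", "well", "frame", "x_min", "y_min", "x_max", "y_max"),
               "detections file")
  d
}

#' @rdname write_detections
#' @param truth the \code{truth} element returned by \code{\link{simulate_screen}}.
#' @export
write_truth <- function(truth, path) {
  tf <- merge(truth$frames,
              truth$organoids[, c("plate_id", "well", "organoid_id", "true_slope")],
              by = c("plate_id", "well", "organoid_id"))
  tf <- tf[order(tf$plate_id, tf$well, tf$organoid_id, tf$frame), ]
  .write_csv(tf, path)
  invisible(path)
}

#' Simulate electrophysiology and quenching traces
#'
#' \code{kind = "isc"}: a short-circuit current trace sampled every
#' \code{interval} seconds — piecewise-constant baseline with an additive step
#' of \code{amplitude} at \code{event_time} plus Gaussian noise (chemical
#' addition in a voltage-clamped epithelial monolayer).
#'
#' \code{kind = "yfp"}: a fluorescence trace constant at \code{initial} before
#' \code{event_time} (iodide injection), then piecewise-linear with the given
#' \code{segments} slopes (per second, on the normalized scale, scaled by
#' \code{initial}), floored at zero, plus noise — emulating halide-sensitive
#' YFP quenching.
#'
#' @param kind \code{"isc"} or \code{"yfp"}.
#' @param duration trace length, seconds.
#' @param interval sampling interval, seconds (10 for Ussing recordings).
#' @param event_time time of the chemical addition / injection, seconds.
#' @param amplitude isc step height, uA (before area normalization).
#' @param baseline isc baseline current, uA.
#' @param segments for yfp: data.frame with columns \code{duration} (s) and
#'   \code{slope} (normalized units per s) describing consecutive
#'   post-injection linear pieces; the last piece extends to the end.
#' @param initial initial raw fluorescence (gain), arbitrary units.
#' @param noise_sd additive Gaussian noise SD (trace units).
#' @param seed integer seed.
#' @return data.frame \code{time_s, value}.
#' @export
simulate_trace <- function(kind = c("isc", "yfp"), duration = 600, interval = 10,
                           event_time = 300, amplitude = 5, baseline = 10,
                           segments = data.frame(duration = Inf, slope = -0.05),
                           initial = 1, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  t <- seq(0, duration, by = interval)
  if (event_time <= 0 || event_time >= duration)
    .stopf("event time %g lies outside the trace (0, %g)", event_time, duration)
  .with_seed(seed, {
    if (kind == "isc") {
      v <- baseline + amplitude * (t > event_time)
    } else {
      .assert_cols(segments, c("duration", "slope"), "segments")
      v <- rep(initial, length(t))
      post <- t > event_time
      tp <- t[post] - event_time
      bounds <- cumsum(segments$duration)
      starts <- c(0, head(bounds, -1))
      level0 <- initial * (1 + cumsum(c(0, head(segments$slope * segments$duration, -1))))
      seg <- pmin(findInterval(tp, c(0, head(bounds, -1) + 1e-12)), nrow(segments))
      v[post] <- level0[seg] + initial * segments$slope[seg] * (tp - starts[seg])
      v <- pmax(v, 0)
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    data.frame(time_s = t, value = v)
  })
}
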