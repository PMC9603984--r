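#' Ordinary least-squares swell rate of one track
#'
#' Slope of area on frame index: the elementary per-organoid swell-rate
#' estimator.  Slope units are pixel^2 per time point; divide by the frame
#' interval for per-minute rates.
#'
#' @param frame integer frame indices (>= 2 distinct values).
#' @param area areas, pixel^2.
#' @return named vector \code{slope, intercept, slope_se, n}; for exactly two
#'   points the residual-based SE is undefined and reported as \code{Inf}.
#' @export
ols_slope <- function(frame, area) {
  keep <- is.finite(frame) & is.finite(area)
  frame <- frame[keep]; area <- area[keep]
  if (length(unique(frame)) < 2L)
    .stopf("cannot fit a swell rate from %d distinct frame(s); need at least 2", length(unique(frame)))
  n <- length(frame)
  fm <- mean(frame); am <- mean(area)
  sxx <- sum((frame - fm)^2)
  slope <- sum((frame - fm) * (area - am)) / sxx
  intercept <- am - slope * fm
  sse <- max(sum((area - intercept - slope * frame)^2), 0)
  se <- if (n <= 2L) Inf else sqrt(sse / (n - 2L) / sxx)
  c(slope = slope, intercept = intercept, slope_se = se, n = n)
}

#' Fit per-organoid swell rates with quality control
#'
#' The package's core model: for every track, ordinary least squares of
#' observed disk area on frame index gives a per-organoid swell rate (slope,
#' pixel^2 per time point) with its residual-based standard error; the two
#' quality-control rules then exclude organoids seen in too few frames or
#' fitted too noisily, and remaining rates are averaged per well.
#'
#' QC rules (frame rule checked first):
#' \enumerate{
#'   \item \code{excluded_frames} when a track is observed in fewer than
#'     \code{min_frames} of the \code{n_frames_total} time points.  The
#'     default reproduces the 8-of-13 rule and scales proportionally
#'     (\code{ceiling(8 * n_frames_total / 13)}) for other acquisition lengths.
#'   \item \code{excluded_se} when the slope standard error exceeds
#'     \code{se_max} (strictly; the default 2.5 keeps a fit with SE exactly
#'     2.5).  Two-point fits have undefined (infinite) SE and are excluded.
#' }
#'
#' @param tracks an \code{\link{organoid_tracks}} data.frame (or any table
#'   with \code{track_id, plate_id, well, frame, area}).
#' @param n_frames_total frames acquired (13 for the 3-h primary screen).
#' @param se_max slope-SE exclusion threshold, same units as the slope.
#' @param min_frames minimum observed frames; default
#'   \code{ceiling(8 * n_frames_total / 13)}.
#' @return an object of class \code{swell_fit}: list with \code{fits} (per
#'   track: \code{track_id, plate_id, well, slope, intercept, slope_se,
#'   n_frames_observed, qc_status}), \code{wells} (see
#'   \code{\link{aggregate_wells}}), the input \code{tracks} and the QC
#'   parameters.  Supports \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{residuals}, \code{predict} and \code{plot}.
#' @examples
#' tr <- data.frame(track_id = 1, plate_id = "P1", well = "A01",
#'                  frame = 0:2, x = 0, y = 0, area = c(100, 112, 124))
#' fit <- fit_swell(tr, n_frames_total = 3)
#' coef(fit)  # slope 12
#' @export
fit_swell <- function(tracks, n_frames_total = 13L, se_max = 2.5, min_frames = NULL) {
  .assert_cols(tracks, c("track_id", "plate_id", "well", "frame", "area"), "tracks")
  if (n_frames_total < 2) .stopf("n_frames_total must be >= 2")
  if (anyDuplicated(paste(tracks$track_id, tracks$frame)))
    .stopf("track(s) with duplicated frames; frames must be strictly increasing within a track")
  if (!nrow(tracks)) .stopf("no observations to fit")

  g <- factor(tracks$track_id, levels = unique(tracks$track_id))
  f <- tracks$frame; a <- tracks$area
  s <- rowsum(cbind(one = 1, f = f, a = a, ff = f * f, fa = f * a, aa = a * a), g)
  n <- s[, "one"]
  sxx <- s[, "ff"] - s[, "f"]^2 / n
  sxy <- s[, "fa"] - s[, "f"] * s[, "a"] / n
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  intercept <- (s[, "a"] - slope * s[, "f"]) / n
  sse <- pmax(s[, "aa"] - s[, "a"]^2 / n - slope^2 * sxx, 0)
  se <- ifelse(n > 2 & sxx > 0, sqrt(sse / (n - 2) / sxx), Inf)

  firsts <- !duplicated(g)
  fits <- data.frame(
    track_id = tracks$track_id[firsts],
    plate_id = tracks$plate_id[firsts],
    well = tracks$well[firsts],
    slope = unname(slope), intercept = unname(intercept),
    slope_se = unname(se), n_frames_observed = unname(as.integer(n)),
    stringsAsFactors = FALSE)
  fits$qc_status <- apply_qc(fits, n_frames_total = n_frames_total,
                             se_max = se_max, min_frames = min_frames)
  structure(list(fits = fits,
                 wells = aggregate_wells(fits),
                 tracks = as.data.frame(tracks),
                 params = list(n_frames_total = as.integer(n_frames_total),
                               se_max = se_max,
                               min_frames = if (is.null(min_frames))
                                 as.integer(ceiling(8 * n_frames_total / 13)) else as.integer(min_frames)),
                 call = match.call()),
            class = "swell_fit")
}

#' Apply the organoid quality-control rules
#'
#' @param fits data.frame with \code{n_frames_observed} and \code{slope_se}.
#' @inheritParams fit_swell
#' @return character vector: \code{included}, \code{excluded_frames} or
#'   \code{excluded_se} per fit (frame rule first; SE rule strict \code{>}).
#' @export
apply_qc <- function(fits, n_frames_total = 13L, se_max = 2.5, min_frames = NULL) {
  .assert_cols(fits, c("n_frames_observed", "slope_se"), "fits")
  if (is.null(min_frames)) min_frames <- ceiling(8 * n_frames_total / 13)
  ifelse(fits$n_frames_observed < min_frames, "excluded_frames",
         ifelse(fits$slope_se > se_max, "excluded_se", "included"))
}

#' Aggregate organoid fits to per-well swell rates
#'
#' The well score is the arithmetic mean swell rate over QC-included organoids
#' in that well; wells where every organoid was excluded get \code{NA} and are
#' flagged \code{missing} (dropped downstream, with a log entry).
#'
#' @param fits the \code{fits} table of a \code{\link{fit_swell}} object.
#' @return data.frame \code{plate_id, well, mean_swell_rate, n_included,
#'   n_excluded_frames, n_excluded_se, n_total, missing}.
#' @export
aggregate_wells <- function(fits) {
  .assert_cols(fits, c("plate_id", "well", "slope", "qc_status"), "fits")
  key <- paste(fits$plate_id, fits$well, sep = "|")
  u <- !duplicated(key)
  inc <- fits$qc_status == "included"
  sums <- rowsum(ifelse(inc, fits$slope, 0), key)
  ninc <- rowsum(as.numeric(inc), key)
  nef <- rowsum(as.numeric(fits$qc_status == "excluded_frames"), key)
  nes <- rowsum(as.numeric(fits$qc_status == "excluded_se"), key)
  ord <- match(key[u], rownames(sums))
  out <- data.frame(
    plate_id = fits$plate_id[u], well = fits$well[u],
    mean_swell_rate = ifelse(ninc[ord] > 0, sums[ord] / ninc[ord], NA_real_),
    n_included = as.integer(ninc[ord]),
    n_excluded_frames = as.integer(nef[ord]),
    n_excluded_se = as.integer(nes[ord]),
    stringsAsFactors = FALSE)
  out$n_total <- out$n_included + out$n_excluded_frames + out$n_excluded_se
  out$missing <- out$n_included == 0L
  out <- out[order(out$plate_id, out$well), ]
  rownames(out) <- NULL
  out
}
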