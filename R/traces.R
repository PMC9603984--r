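#' Short-circuit current change upon chemical addition
#'
#' From an Ussing-chamber trace sampled at regular intervals, the current
#' change is the mean of the \code{n_points} samples immediately after the
#' addition minus the mean of the \code{n_points} samples immediately before
#' it (the addition sample itself, if present, belongs to neither window),
#' normalized to 1 cm^2 of membrane.
#'
#' @param trace data.frame \code{time_s, value} (current in uA), increasing
#'   times.
#' @param event_time time of the chemical addition, seconds.
#' @param membrane_area exposed membrane area, cm^2 (default 1).
#' @param n_points samples averaged on each side (default 5).
#' @param gap samples skipped next to the event before each window (default
#'   0: windows are immediately adjacent).
#' @return change in short-circuit current, uA/cm^2.
#' @export
delta_isc <- function(trace, event_time, membrane_area = 1, n_points = 5L, gap = 0L) {
  .assert_cols(trace, c("time_s", "value"), "trace")
  if (membrane_area <= 0) .stopf("membrane_area must be > 0")
  if (is.unsorted(trace$time_s, strictly = TRUE)) .stopf("trace times must be strictly increasing")
  before <- which(trace$time_s < event_time)
  after <- which(trace$time_s > event_time)
  if (gap > 0) {
    before <- head(before, -min(gap, length(before)))
    after <- after[-seq_len(min(gap, length(after)))]
  }
  if (length(before) < n_points)
    .stopf("only %d sample(s) before the event at t=%g; %d required",
           length(before), event_time, n_points)
  if (length(after) < n_points)
    .stopf("only %d sample(s) after the event at t=%g; %d required",
           length(after), event_time, n_points)
  before <- before[seq(length(before) - n_points + 1L, length(before))]
  after <- after[seq_len(n_points)]
  (mean(trace$value[after]) - mean(trace$value[before])) / membrane_area
}

#' ΔIsc for a sequence of additions
#'
#' @param trace as in \code{\link{delta_isc}}.
#' @param events data.frame \code{label, time_s}.
#' @inheritParams delta_isc
#' @return data.frame \code{label, time_s, delta_isc}.
#' @export
delta_isc_events <- function(trace, events, membrane_area = 1, n_points = 5L, gap = 0L) {
  .assert_cols(events, c("label", "time_s"), "events")
  data.frame(label = events$label, time_s = events$time_s,
             delta_isc = vapply(events$time_s, function(tm)
               delta_isc(trace, tm, membrane_area, n_points, gap), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Fluorescence quenching rate
#'
#' YFP-quenching readout of anion conductance: after optional background
#' subtraction the post-injection trace is normalized to its initial
#' fluorescence (value 1 at injection); a linear slope is fitted in every
#' contiguous window of \code{window} samples sliding one sample at a time,
#' and the quenching rate is the magnitude of the most negative slope —
#' larger means faster quench.  Invariant to any positive gain on the raw
#' fluorescence.
#'
#' @param trace data.frame \code{time_s, value} (fluorescence, a.u.).
#' @param injection_time iodide injection time, seconds; samples from this
#'   time on are analysed.
#' @param window sliding-window width in samples (default 5, >= 2).
#' @param background optional background fluorescence subtracted first.
#' @return the quenching rate (per second, positive), with attributes
#'   \code{slopes} (all window slopes) and \code{window}.
#' @export
quench_rate <- function(trace, injection_time, window = 5L, background = NULL) {
  .assert_cols(trace, c("time_s", "value"), "trace")
  if (window < 2L) .stopf("window must span at least 2 samples")
  v <- trace$value
  if (!is.null(background)) v <- v - background
  post <- which(trace$time_s >= injection_time)
  if (length(post) < window)
    .stopf("only %d post-injection sample(s); window of %d required", length(post), window)
  f0 <- v[post[1L]]
  if (!(f0 > 0))
    .stopf("initial fluorescence at injection must be > 0 (got %g); check background subtraction", f0)
  norm <- v[post] / f0
  tt <- trace$time_s[post]
  n <- length(post)
  starts <- seq_len(n - window + 1L)
  slopes <- vapply(starts, function(s) {
    ix <- s:(s + window - 1L)
    unname(ols_slope(tt[ix], norm[ix])["slope"])
  }, numeric(1))
  structure(abs(min(slopes)), slopes = slopes, window = window)
}

#' Normalize quenching rates to a control condition
#'
#' @param qr quenching rate(s).
#' @param control_qr quenching rate(s) of the control condition; their mean
#'   is the denominator.
#' @return relative quenching rate(s): 1 equals the control mean.
#' @export
normalize_to_control <- function(qr, control_qr) {
  if (!length(control_qr) || all(is.na(control_qr)))
    .stopf("no control quenching rates supplied")
  m <- mean(control_qr, na.rm = TRUE)
  if (m == 0) .stopf("mean control quenching rate is zero; cannot normalize")
  qr / m
}

#' Read a trace CSV
#'
#' Dialect: columns \code{time_s, value}, extra metadata columns carried
#' through.
#'
#' @param path file path.
#' @export
read_trace <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(tr, c("time_s", "value"), "trace file")
  tr
}
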