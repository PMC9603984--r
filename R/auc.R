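#' Normalize a well's total-area curve to its starting value
#'
#' Conventional fluorescent (calcein) quantification: the per-well total
#' organoid area over time, expressed as percent of the t = 0 value
#' (100\% baseline).  Invariant to camera gain.
#'
#' @param time sampling times, minutes (must include 0; strictly increasing).
#' @param total_area total organoid area per time point, pixel^2.
#' @return numeric vector of percentages with value 100 at t = 0.
#' @export
normalize_curve <- function(time, total_area) {
  if (length(time) != length(total_area)) .stopf("time and total_area lengths differ")
  if (is.unsorted(time, strictly = TRUE)) .stopf("times must be strictly increasing")
  i0 <- which(time == 0)
  if (!length(i0)) .stopf("curve has no t = 0 sample")
  if (!(total_area[i0] > 0)) .stopf("total area at t = 0 must be > 0, got %g", total_area[i0])
  100 * total_area / total_area[i0]
}

#' Area under a normalized swelling curve
#'
#' Trapezoidal integral of (normalized - baseline) from 0 to \code{t_end}
#' (default 120 min), in percent-minutes.  With the default baseline of
#' 100\% a non-swelling well scores 0 and shrinkage is negative.  If the
#' series extends past \code{t_end} it is linearly interpolated at
#' \code{t_end} and truncated.
#'
#' @param time sampling times, minutes, covering [0, \code{t_end}].
#' @param normalized normalized percent series (see \code{\link{normalize_curve}}).
#' @param t_end integration endpoint, minutes.
#' @param baseline percent level subtracted before integration; set 0 to
#'   integrate the raw percent curve.
#' @return signed AUC, percent-minutes.
#' @export
compute_auc <- function(time, normalized, t_end = 120, baseline = 100) {
  if (length(time) != length(normalized)) .stopf("time and normalized lengths differ")
  if (is.unsorted(time, strictly = TRUE)) .stopf("times must be strictly increasing")
  if (min(time) > 0 || max(time) < t_end)
    .stopf("series [%g, %g] does not cover [0, %g]", min(time), max(time), t_end)
  keep <- time <= t_end
  tt <- time[keep]; vv <- normalized[keep]
  if (max(tt) < t_end) {
    vt <- approx(time, normalized, xout = t_end)$y
    tt <- c(tt, t_end); vv <- c(vv, vt)
  }
  keep0 <- tt >= 0
  pracma::trapz(tt[keep0], vv[keep0] - baseline)
}

#' Baseline-correct AUC values against same-plate DMSO wells
#'
#' @param auc AUC value(s) to correct.
#' @param dmso_aucs AUC values of the DMSO-treated wells of the same plate
#'   (averaged before subtraction).
#' @return corrected AUC(s).
#' @export
baseline_correct <- function(auc, dmso_aucs) {
  if (!length(dmso_aucs) || all(is.na(dmso_aucs)))
    .stopf("no DMSO AUC values available for baseline correction")
  auc - mean(dmso_aucs, na.rm = TRUE)
}

#' Per-well AUC table from a curve file
#'
#' Computes the normalized-area AUC for every well of a curve table and,
#' when a layout is given, the DMSO baseline-corrected AUC (mean same-plate
#' DMSO AUC subtracted; plates without a DMSO well raise an error naming the
#' plate).
#'
#' @param curves data.frame \code{plate_id, well, time_min, total_area}.
#' @param t_end integration endpoint, minutes (default 120).
#' @param layout optional \code{\link{plate_layout}} identifying DMSO wells.
#' @param baseline percent baseline, see \code{\link{compute_auc}}.
#' @return data.frame \code{plate_id, well, auc} and, with a layout,
#'   \code{auc_baseline_corrected}.
#' @export
auc_table <- function(curves, t_end = 120, layout = NULL, baseline = 100) {
  .assert_cols(curves, c("plate_id", "well", "time_min", "total_area"), "curves")
  key <- paste(curves$plate_id, curves$well, sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(curves)), key), function(ix) {
    ix <- ix[order(curves$time_min[ix])]
    norm <- normalize_curve(curves$time_min[ix], curves$total_area[ix])
    data.frame(plate_id = curves$plate_id[ix[1]], well = curves$well[ix[1]],
               auc = compute_auc(curves$time_min[ix], norm, t_end = t_end,
                                 baseline = baseline),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$plate_id, out$well), ]
  rownames(out) <- NULL
  if (!is.null(layout)) {
    layout <- validate_layout(as.data.frame(layout))
    out$auc_baseline_corrected <- NA_real_
    for (p in unique(out$plate_id)) {
      dwells <- layout$well[layout$plate_id == p & layout$role == "dmso"]
      sel <- out$plate_id == p
      dm <- out$auc[sel & out$well %in% dwells]
      if (!length(dm))
        .stopf("plate %s has no DMSO well; cannot baseline-correct", p)
      out$auc_baseline_corrected[sel] <- baseline_correct(out$auc[sel], dm)
    }
  }
  out
}
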