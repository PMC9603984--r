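#' @export
print.swell_fit <- function(x, ...) {
  f <- x$fits
  cat("Per-organoid swell-rate fit (area ~ frame, OLS)\n")
  cat(sprintf("  %d tracks in %d wells on %d plate(s)\n",
              nrow(f), nrow(x$wells), length(unique(f$plate_id))))
  cat(sprintf("  QC: %d included, %d excluded (<%d frames), %d excluded (slope SE > %g)\n",
              sum(f$qc_status == "included"), sum(f$qc_status == "excluded_frames"),
              x$params$min_frames, sum(f$qc_status == "excluded_se"), x$params$se_max))
  inc <- f$slope[f$qc_status == "included"]
  if (length(inc))
    cat(sprintf("  included swell rates [px^2/time point]: median %.2f, IQR %.2f\n",
                median(inc), stats::IQR(inc)))
  invisible(x)
}

#' @export
summary.swell_fit <- function(object, ...) {
  f <- object$fits
  inc <- f$slope[f$qc_status == "included"]
  structure(list(
    n_tracks = nrow(f),
    qc = table(factor(f$qc_status, c("included", "excluded_frames", "excluded_se"))),
    slope_summary = if (length(inc)) summary(inc) else NULL,
    wells = object$wells,
    params = object$params,
    n_missing_wells = sum(object$wells$missing)
  ), class = "summary.swell_fit")
}

#' @export
print.summary.swell_fit <- function(x, ...) {
  cat("Swell-rate fit summary\n")
  cat("  QC status:\n")
  print(x$qc)
  if (!is.null(x$slope_summary)) {
    cat("  Included swell rates (px^2/time point):\n")
    print(x$slope_summary)
  }
  cat(sprintf("  Wells: %d (%d with no included organoid)\n",
              nrow(x$wells), x$n_missing_wells))
  invisible(x)
}

#' @export
coef.swell_fit <- function(object, ...) {
  setNames(object$fits$slope, object$fits$track_id)
}

#' @export
fitted.swell_fit <- function(object, ...) {
  i <- match(object$tracks$track_id, object$fits$track_id)
  object$fits$intercept[i] + object$fits$slope[i] * object$tracks$frame
}

#' @export
residuals.swell_fit <- function(object, ...) {
  object$tracks$area - fitted(object)
}

#' Predict areas from a swell-rate fit
#'
#' @param object a \code{\link{fit_swell}} object.
#' @param newdata data.frame with \code{track_id} and \code{frame}; defaults
#'   to the observed track/frame pairs.
#' @param ... unused.
#' @return predicted areas, pixel^2.
#' @export
predict.swell_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  .assert_cols(newdata, c("track_id", "frame"), "newdata")
  i <- match(newdata$track_id, object$fits$track_id)
  if (anyNA(i))
    .stopf("unknown track_id(s): %s",
           paste(unique(newdata$track_id[is.na(i)]), collapse = ", "))
  object$fits$intercept[i] + object$fits$slope[i] * newdata$frame
}

#' Plot per-organoid area trajectories with their fitted swell rates
#'
#' @param x a \code{\link{fit_swell}} object.
#' @param plate_id,well restrict to one well (defaults to the first well).
#' @param ... passed to \code{plot}.
#' @export
plot.swell_fit <- function(x, plate_id = NULL, well = NULL, ...) {
  tr <- x$tracks
  if (is.null(plate_id)) plate_id <- tr$plate_id[1]
  if (is.null(well)) well <- tr$well[tr$plate_id == plate_id][1]
  tr <- tr[tr$plate_id == plate_id & tr$well == well, ]
  if (!nrow(tr)) .stopf("no tracks in %s %s", plate_id, well)
  f <- x$fits[x$fits$plate_id == plate_id & x$fits$well == well, ]
  cols <- hcl.colors(max(3L, nrow(f)), "Dark 3")
  plot(range(tr$frame), range(tr$area), type = "n",
       xlab = "time point", ylab = expression(area ~ (px^2)),
       main = sprintf("%s %s", plate_id, well), ...)
  for (k in seq_len(nrow(f))) {
    tk <- tr[tr$track_id == f$track_id[k], ]
    inc <- f$qc_status[k] == "included"
    lines(tk$frame, tk$area, col = if (inc) cols[k] else "grey70",
          lty = if (inc) 1 else 3)
    points(tk$frame, tk$area, col = if (inc) cols[k] else "grey70", pch = 16, cex = 0.5)
    if (is.finite(f$slope[k]))
      abline(f$intercept[k], f$slope[k], col = if (inc) cols[k] else "grey80", lwd = 0.5)
  }
  invisible(x)
}

#' @rdname write_tracks
#' @param fit a \code{\link{fit_swell}} object.
#' @export
write_fits <- function(fit, path) {
  .write_csv(fit$fits, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
write_wells <- function(fit, path) {
  .write_csv(fit$wells, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_wells <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(plate_id = "character", well = "character"))
  .assert_cols(w, c("plate_id", "well", "mean_swell_rate"), "wells file")
  w
}
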