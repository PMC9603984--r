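#' Disk-area estimate from a bounding box
#'
#' Organoid surface area is estimated from a detector bounding box under a
#' disk-shape assumption: an effective diameter is reduced from the box width
#' and height (arithmetic mean by default, exact for square boxes) and the
#' area is that disk's, \code{pi * (d/2)^2}.  Boxes are 0-based, half-open
#' (\code{width = x_max - x_min}).
#'
#' @param box numeric vector \code{c(x_min, y_min, x_max, y_max)} or a
#'   data.frame/matrix with those columns (vectorized).
#' @param rule how a non-square box is reduced to a diameter: \code{"mean"}
#'   (default), \code{"min"}, \code{"max"} or \code{"geometric_mean"} of the
#'   two extents.
#' @return a data.frame with columns \code{x}, \code{y} (box center) and
#'   \code{area} (pixel^2).
#' @examples
#' area_from_box(c(0, 0, 10, 10))        # pi * 25
#' area_from_box(c(0, 0, 8, 12))         # same: mean extent 10
#' @export
area_from_box <- function(box, rule = c("mean", "min", "max", "geometric_mean")) {
  rule <- match.arg(rule)
  if (is.null(dim(box))) box <- matrix(box, nrow = 1,
                                       dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  box <- as.data.frame(box)
  .assert_cols(box, c("x_min", "y_min", "x_max", "y_max"), "box")
  w <- box$x_max - box$x_min
  h <- box$y_max - box$y_min
  bad <- !(w > 0 & h > 0)
  if (any(bad))
    .stopf("invalid box with zero/negative extent at row(s): %s",
           paste(which(bad), collapse = ", "))
  d <- switch(rule,
              mean = (w + h) / 2,
              min = pmin(w, h),
              max = pmax(w, h),
              geometric_mean = sqrt(w * h))
  data.frame(x = (box$x_min + box$x_max) / 2,
             y = (box$y_min + box$y_max) / 2,
             area = pi * (d / 2)^2)
}

#' Convert a detections table to area observations
#'
#' Applies \code{\link{area_from_box}} to every detection, carrying plate,
#' well, frame and (unused by default) confidence through.
#'
#' @param detections data.frame with \code{plate_id, well, frame, x_min,
#'   y_min, x_max, y_max} (optional \code{confidence}).
#' @param rule diameter rule, see \code{\link{area_from_box}}.
#' @return data.frame \code{plate_id, well, frame, x, y, area} (+ confidence).
#' @export
boxes_to_areas <- function(detections, rule = c("mean", "min", "max", "geometric_mean")) {
  .assert_cols(detections, c("plate_id", "well", "frame", "x_min", "y_min", "x_max", "y_max"),
               "detections")
  ca <- area_from_box(detections[, c("x_min", "y_min", "x_max", "y_max")], rule = rule)
  out <- data.frame(plate_id = detections$plate_id, well = detections$well,
                    frame = detections$frame, x = ca$x, y = ca$y, area = ca$area,
                    stringsAsFactors = FALSE)
  if ("confidence" %in% names(detections)) out$confidence <- detections$confidence
  out
}

#' @rdname boxes_to_areas
#' @param areas area-observation table to write.
#' @param path file path.
#' @export
write_areas <- function(areas, path) {
  .write_csv(areas, path)
  invisible(path)
}

#' @rdname boxes_to_areas
#' @export
read_areas <- function(path) {
  a <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(plate_id = "character", well = "character"))
  .assert_cols(a, c("plate_id", "well", "frame", "x", "y", "area"), "areas file")
  a
}
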