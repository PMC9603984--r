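#' Render synthetic brightfield-like frames from detections
#'
#' Draws each detected organoid as a bright ring with a darker lumen on a
#' noisy background, one grayscale image per (plate, well, frame) — geometry
#' sufficient to exercise a blob detector and the tracker, with no attempt at
#' photorealistic organoid texture.
#'
#' @param detections detections data.frame (see \code{\link{write_detections}}
#'   for the dialect).
#' @param image_size side of the square image, px.
#' @param background,ring_intensity,lumen_intensity gray levels in [0, 1].
#' @param noise_sd background Gaussian noise SD (gray levels).
#' @param ring_width ring thickness as a fraction of the radius.
#' @param dir if non-NULL, write each frame as a 16-bit grayscale TIFF named
#'   \code{<plate>_<well>_f<frame>.tif} into this directory (requires the
#'   \pkg{tiff} package) and return the paths instead of matrices.
#' @param seed seed for the background noise.
#' @return a named list of \code{image_size x image_size} matrices in [0, 1]
#'   indexed \code{"<plate>|<well>|<frame>"} (rows are y, columns x), or file
#'   paths when \code{dir} is given.
#' @export
render_frames <- function(detections, image_size = 700, background = 0.2,
                          ring_intensity = 0.9, lumen_intensity = 0.35,
                          noise_sd = 0.02, ring_width = 0.25, dir = NULL,
                          seed = 1L) {
  .assert_cols(detections, c("plate_id", "well", "frame", "x_min", "y_min", "x_max", "y_max"),
               "detections")
  out_of_bounds <- detections$x_min < 0 | detections$y_min < 0 |
    detections$x_max > image_size | detections$y_max > image_size
  if (any(out_of_bounds))
    .stopf("detection box(es) outside the %d px image bounds at row(s): %s",
           image_size, paste(which(out_of_bounds), collapse = ", "))
  key <- paste(detections$plate_id, detections$well, detections$frame, sep = "|")
  groups <- split(seq_len(nrow(detections)), key)
  xs <- matrix(rep(seq_len(image_size) - 0.5, each = image_size), image_size)  # col = x
  ys <- matrix(rep(seq_len(image_size) - 0.5, times = image_size), image_size) # row = y
  imgs <- .with_seed(seed, lapply(groups, function(rows) {
    img <- matrix(background + rnorm(image_size^2, 0, noise_sd), image_size)
    for (r in rows) {
      cx <- (detections$x_min[r] + detections$x_max[r]) / 2
      cy <- (detections$y_min[r] + detections$y_max[r]) / 2
      rad <- ((detections$x_max[r] - detections$x_min[r]) +
              (detections$y_max[r] - detections$y_min[r])) / 4
      d2 <- (xs - cx)^2 + (ys - cy)^2
      inner <- rad * (1 - ring_width)
      img[d2 <= inner^2] <- lumen_intensity
      img[d2 > inner^2 & d2 <= rad^2] <- ring_intensity
    }
    pmin(pmax(img, 0), 1)
  }))
  if (is.null(dir)) return(imgs)
  if (!requireNamespace("tiff", quietly = TRUE))
    .stopf("writing TIFF frames requires the 'tiff' package")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(imgs), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    p <- file.path(dir, sprintf("%s_%s_f%02d.tif", parts[1], parts[2], as.integer(parts[3])))
    tiff::writeTIFF(imgs[[k]], p, bits.per.sample = 16L)
    p
  }, character(1))
  paths
}

#' Detect bright blobs in a grayscale frame
#'
#' Classical stand-in for a learned organoid detector on rendered frames:
#' threshold (Otsu by default), fill ring interiors, label connected
#' components, discard small components and emit tight bounding boxes.
#' Thresholding, hole filling and labelling are delegated to \pkg{EBImage}.
#'
#' @param img numeric matrix in [0, 1] (rows y, columns x), or a path to a
#'   grayscale TIFF.
#' @param min_area minimum component size in pixels; smaller blobs (noise
#'   speckle) are discarded.
#' @param threshold \code{"otsu"} or a fixed numeric threshold in (0, 1).
#' @param min_contrast minimum separation between the mean intensities above
#'   and below the threshold (gray levels).  Otsu always yields a threshold,
#'   even on a foreground-free noise image where it merely splits the noise;
#'   requiring a real intensity gap between the two classes rejects such
#'   frames as empty.
#' @return a data.frame of detections \code{x_min, y_min, x_max, y_max,
#'   confidence, area_px} (0-based half-open boxes), sorted by
#'   \code{(y_min, x_min)}; zero rows for a blank image.
#' @export
detect_blobs <- function(img, min_area = 50, threshold = "otsu", min_contrast = 0.1) {
  if (is.character(img)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      .stopf("reading TIFF frames requires the 'tiff' package")
    img <- tiff::readTIFF(img)
    if (length(dim(img)) == 3L) img <- img[, , 1]
  }
  if (!is.matrix(img) || !is.numeric(img)) .stopf("img must be a numeric matrix")
  if (!requireNamespace("EBImage", quietly = TRUE))
    .stopf("detect_blobs requires the 'EBImage' package")
  th <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) < .Machine$double.eps) Inf  # flat image: nothing to detect
    else EBImage::otsu(EBImage::Image(img), range = rng)
  } else as.numeric(threshold)
  mask <- img > th
  if (any(mask) && any(!mask) &&
      mean(img[mask]) - mean(img[!mask]) < min_contrast)
    mask[] <- FALSE
  if (!any(mask))
    return(data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), confidence = numeric(), area_px = numeric()))
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  labels <- EBImage::bwlabel(filled)
  lab <- as.integer(EBImage::imageData(labels))
  dim(lab) <- dim(img)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  if (!length(keep))
    return(data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), confidence = numeric(), area_px = numeric()))
  boxes <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    # rows are y, columns x; half-open 0-based box covering the pixels
    c(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
      x_max = max(idx[, 2]), y_max = max(idx[, 1]), area_px = nrow(idx))
  }, numeric(5)))
  out <- as.data.frame(boxes)
  out$confidence <- 1
  out <- out[order(out$y_min, out$x_min), c("x_min", "y_min", "x_max", "y_max", "confidence", "area_px")]
  rownames(out) <- NULL
  out
}

#' Detect blobs across a directory of rendered frames
#'
#' Applies \code{\link{detect_blobs}} to every \code{*.tif} frame written by
#' \code{\link{render_frames}}, recovering plate, well and frame from the
#' file names.
#'
#' @param dir directory of \code{<plate>_<well>_f<frame>.tif} files.
#' @inheritParams detect_blobs
#' @return a detections data.frame in the standard dialect.
#' @export
detect_frames <- function(dir, min_area = 50, threshold = "otsu") {
  files <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  if (!length(files)) .stopf("no .tif frames found in %s", dir)
  res <- lapply(files, function(f) {
    m <- regmatches(basename(f), regexec("^(.+)_([A-P][0-9]{2})_f([0-9]+)\\.tif$", basename(f)))[[1]]
    if (!length(m)) .stopf("frame file name not in <plate>_<well>_f<frame>.tif form: %s", basename(f))
    d <- detect_blobs(f, min_area = min_area, threshold = threshold)
    if (!nrow(d)) return(NULL)
    cbind(data.frame(plate_id = m[2], well = m[3], frame = as.integer(m[4]),
                     stringsAsFactors = FALSE),
          d[, c("x_min", "y_min", "x_max", "y_max", "confidence")])
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
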