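#' Well names of a microtiter plate
#'
#' @param format plate format, 384 (rows A-P, columns 1-24) or 96 (A-H, 1-12).
#' @return character vector of well names in row-major order ("A01", "A02", ...).
#' @export
well_names <- function(format = 384) {
  format <- match.arg(as.character(format), c("384", "96"))
  nr <- if (format == "384") 16L else 8L
  nc <- if (format == "384") 24L else 12L
  as.vector(t(outer(LETTERS[seq_len(nr)], sprintf("%02d", seq_len(nc)), paste0)))
}

#' Build a screening plate layout
#'
#' Lays out compound wells (pooled pairs for the 384-well primary screen, one
#' compound per well for the 96-well secondary screen) followed by DMSO
#' negative-control and Eact positive-control wells, filled row-major from A01.
#'
#' @param plate_id plate identifier.
#' @param compounds character vector of compound names to place.
#' @param format 384 or 96.
#' @param pooled if TRUE, two distinct compounds share each well (384-well
#'   primary-screen design); if FALSE one compound per well.
#' @param n_dmso,n_eact number of DMSO / Eact control wells.
#' @return a \code{plate_layout} data.frame with columns \code{plate_id},
#'   \code{well}, \code{role} (\code{compound}/\code{dmso}/\code{eact}),
#'   \code{compound_1}, \code{compound_2} (NA where absent).
#' @export
screen_layout <- function(plate_id, compounds, format = 384, pooled = (format == 384),
                          n_dmso = 16L, n_eact = 16L) {
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) .stopf("compounds must be distinct")
  if (pooled) {
    if (length(compounds) %% 2L != 0L)
      .stopf("pooled layout needs an even number of compounds, got %d", length(compounds))
    c1 <- compounds[seq(1L, length(compounds), by = 2L)]
    c2 <- compounds[seq(2L, length(compounds), by = 2L)]
  } else {
    c1 <- compounds
    c2 <- rep(NA_character_, length(compounds))
  }
  wells <- well_names(format)
  n_cw <- length(c1)
  n_total <- n_cw + n_dmso + n_eact
  if (n_total > length(wells))
    .stopf("layout needs %d wells but a %s-well plate has %d", n_total, format, length(wells))
  used <- wells[seq_len(n_total)]
  layout <- data.frame(
    plate_id = plate_id,
    well = used,
    role = c(rep("compound", n_cw), rep("dmso", n_dmso), rep("eact", n_eact)),
    compound_1 = c(c1, rep(NA_character_, n_dmso + n_eact)),
    compound_2 = c(c2, rep(NA_character_, n_dmso + n_eact)),
    stringsAsFactors = FALSE
  )
  validate_layout(layout)
}

#' Validate a plate layout
#'
#' Checks the layout invariants: one condition per well, valid roles, pooled
#' compound wells carry two distinct compounds, control wells carry none.
#'
#' @param layout a layout data.frame (see \code{\link{screen_layout}}).
#' @return the layout, classed \code{plate_layout}, invisibly usable downstream.
#' @export
validate_layout <- function(layout) {
  .assert_cols(layout, c("plate_id", "well", "role"), "layout")
  if (!"compound_1" %in% names(layout)) layout$compound_1 <- NA_character_
  if (!"compound_2" %in% names(layout)) layout$compound_2 <- NA_character_
  layout$compound_1[!is.na(layout$compound_1) & layout$compound_1 == ""] <- NA_character_
  layout$compound_2[!is.na(layout$compound_2) & layout$compound_2 == ""] <- NA_character_
  bad <- !layout$role %in% c("compound", "dmso", "eact")
  if (any(bad)) .stopf("unknown role(s): %s", paste(unique(layout$role[bad]), collapse = ", "))
  key <- paste(layout$plate_id, layout$well)
  if (anyDuplicated(key))
    .stopf("duplicate well(s) in layout: %s", paste(unique(key[duplicated(key)]), collapse = ", "))
  cw <- layout$role == "compound"
  if (any(cw & is.na(layout$compound_1)))
    .stopf("compound well(s) without compound_1: %s", paste(layout$well[cw & is.na(layout$compound_1)], collapse = ", "))
  same <- cw & !is.na(layout$compound_2) & layout$compound_1 == layout$compound_2
  if (any(same))
    .stopf("compound wells with two identical compounds: %s", paste(layout$well[same], collapse = ", "))
  ctrl <- !cw & (!is.na(layout$compound_1) | !is.na(layout$compound_2))
  if (any(ctrl))
    .stopf("control well(s) carrying compounds: %s", paste(layout$well[ctrl], collapse = ", "))
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Read / write layout CSV
#'
#' CSV dialect: columns \code{plate_id, well, role, compound_1, compound_2};
#' role is one of \code{compound}, \code{dmso}, \code{eact}.
#'
#' @param path file path.
#' @return \code{read_layout}: a validated \code{plate_layout}.
#' @export
read_layout <- function(path) {
  validate_layout(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(plate_id = "character", well = "character")))
}

#' @rdname read_layout
#' @param layout layout to write.
#' @export
write_layout <- function(layout, path) {
  write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# condition label for a layout row, used to look up simulated swell effects
.condition_of <- function(layout) {
  ifelse(layout$role == "dmso", "dmso_control",
         ifelse(layout$role == "eact", "eact_control", "compound"))
}
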