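#' Link area observations into per-organoid tracks
#'
#' Particle tracking across the time-lapse, per well: for each consecutive
#' frame, existing tracks are matched to the new frame's observations by a
#' minimum-total-displacement one-to-one assignment (Hungarian algorithm via
#' \code{clue::solve_LSAP}) restricted to candidates within the displacement
#' gate.  Unmatched observations start new tracks; a track may skip up to
#' \code{memory} consecutive frames and still re-link (its gate grows
#' proportionally with the gap).  Cost is the Euclidean center displacement;
#' area change does not enter the cost.
#'
#' Output is deterministic and independent of input row order: observations
#' are processed in canonical \code{(frame, y, x)} order and track ids are
#' relabelled by (plate, well, first frame, first y, first x).
#'
#' @param areas area observations: data.frame \code{plate_id, well, frame, x,
#'   y, area} (0-based contiguous frame indices within each well).
#' @param max_displacement gate, px per frame step (default 30).
#' @param memory maximum consecutive missed frames a track survives
#'   (default 5: an organoid may miss 5 of 13 frames and still satisfy the
#'   8-of-13 inclusion rule, so the linker must survive 5).
#' @return an \code{organoid_tracks} data.frame \code{track_id, plate_id,
#'   well, frame, x, y, area}, sorted by track then frame.
#' @export
link_tracks <- function(areas, max_displacement = 30, memory = 5L) {
  .assert_cols(areas, c("plate_id", "well", "frame", "x", "y", "area"), "areas")
  if (max_displacement <= 0) .stopf("max_displacement must be > 0")
  if (memory < 0) .stopf("memory must be >= 0")
  key <- paste(areas$plate_id, areas$well, sep = "|")
  dupkey <- paste(key, areas$frame, areas$x, areas$y)
  if (anyDuplicated(dupkey))
    .stopf("duplicate (frame, center) observation(s) in well(s): %s",
           paste(unique(key[duplicated(dupkey)]), collapse = ", "))
  wells <- sort(unique(key))
  pieces <- vector("list", length(wells))
  next_id <- 0L
  for (wi in seq_along(wells)) {
    rows <- which(key == wells[wi])
    tr <- .link_well(areas$frame[rows], areas$x[rows], areas$y[rows],
                     max_displacement, memory)
    # tr: list of integer vectors of local obs indices (each a track)
    # canonical order: first frame, then y, x of the first observation
    first <- vapply(tr, function(ix) ix[1L], integer(1))
    ord <- order(areas$frame[rows][first], areas$y[rows][first], areas$x[rows][first])
    tr <- tr[ord]
    n_obs <- lengths(tr)
    gidx <- rows[unlist(tr)]
    pieces[[wi]] <- data.frame(
      track_id = next_id + rep(seq_along(tr), n_obs),
      plate_id = areas$plate_id[gidx], well = areas$well[gidx],
      frame = areas$frame[gidx], x = areas$x[gidx], y = areas$y[gidx],
      area = areas$area[gidx], stringsAsFactors = FALSE)
    next_id <- next_id + length(tr)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(track_id = integer(), plate_id = character(), well = character(),
                      frame = integer(), x = numeric(), y = numeric(), area = numeric())
  rownames(out) <- NULL
  attr(out, "params") <- list(max_displacement = max_displacement, memory = memory)
  class(out) <- c("organoid_tracks", "data.frame")
  out
}

# frame-by-frame linking within one well; returns list of obs-index vectors
.link_well <- function(frame, x, y, max_disp, memory) {
  tracks <- list()          # integer vectors of obs indices
  for (f in sort(unique(frame))) {
    obs <- which(frame == f)
    obs <- obs[order(y[obs], x[obs])]
    active <- if (length(tracks))
      which(f - vapply(tracks, function(ix) frame[ix[length(ix)]], numeric(1)) <= memory + 1 &
            f - vapply(tracks, function(ix) frame[ix[length(ix)]], numeric(1)) > 0)
    else integer(0)
    if (length(active)) {
      lastf <- vapply(tracks[active], function(ix) frame[ix[length(ix)]], numeric(1))
      lastx <- vapply(tracks[active], function(ix) x[ix[length(ix)]], numeric(1))
      lasty <- vapply(tracks[active], function(ix) y[ix[length(ix)]], numeric(1))
      ordt <- order(lasty, lastx)   # canonical tie-break order
      active <- active[ordt]; lastf <- lastf[ordt]; lastx <- lastx[ordt]; lasty <- lasty[ordt]
      d <- sqrt(outer(lastx, x[obs], "-")^2 + outer(lasty, y[obs], "-")^2)
      gate <- max_disp * (f - lastf)          # per-track gate grows with the gap
      ok <- d <= gate                          # nt x no logical
      match_t <- .assign(d, ok, max_disp * (memory + 1))
      for (ti in seq_along(active))
        if (!is.na(match_t[ti]))
          tracks[[active[ti]]] <- c(tracks[[active[ti]]], obs[match_t[ti]])
      unmatched <- setdiff(seq_along(obs), match_t[!is.na(match_t)])
    } else unmatched <- seq_along(obs)
    for (j in unmatched) tracks[[length(tracks) + 1L]] <- obs[j]
  }
  tracks
}

# one-to-one minimum-cost assignment of tracks (rows) to observations
# (columns) honouring the gate; returns per-row matched column or NA.
# Trivial bijective cases shortcut the LAP solver.
.assign <- function(d, ok, nomatch_cost) {
  nt <- nrow(d); no <- ncol(d)
  if (!any(ok)) return(rep(NA_integer_, nt))
  rs <- rowSums(ok); cs <- colSums(ok)
  if (all(rs <= 1L) && all(cs <= 1L)) {    # unambiguous: mutual singletons
    out <- rep(NA_integer_, nt)
    for (i in which(rs == 1L)) out[i] <- which(ok[i, ])
    return(out)
  }
  LARGE <- 1e8
  cost <- ifelse(ok, d, LARGE)
  m <- matrix(LARGE, nt + no, nt + no)
  m[seq_len(nt), seq_len(no)] <- cost
  for (i in seq_len(nt)) m[i, no + i] <- nomatch_cost       # leave track unmatched
  for (j in seq_len(no)) m[nt + j, j] <- nomatch_cost       # leave obs unmatched
  m[nt + seq_len(no), no + seq_len(nt)] <- 0
  sol <- as.integer(clue::solve_LSAP(m))
  out <- rep(NA_integer_, nt)
  for (i in seq_len(nt)) {
    j <- sol[i]
    if (j <= no && ok[i, j]) out[i] <- j
  }
  out
}

#' Read / write track CSV
#'
#' Dialect: \code{track_id, plate_id, well, frame, x, y, area}.
#'
#' @param tracks an \code{organoid_tracks} data.frame.
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  .write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(plate_id = "character", well = "character"))
  .assert_cols(t, c("track_id", "plate_id", "well", "frame", "x", "y", "area"), "tracks file")
  class(t) <- c("organoid_tracks", "data.frame")
  t
}
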