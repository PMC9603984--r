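#' Plate-normalize well swell rates
#'
#' Robust per-plate normalization making wells comparable across plates and
#' donors: \code{norm_rate = (raw - median_plate) / IQR_plate}, with the
#' median and interquartile range computed over the plate's compound wells
#' (controls excluded under the default policy, since the hit threshold is
#' defined relative to the compound distribution) and applied to every well
#' including controls.  Quantiles use linear interpolation between order
#' statistics (\code{stats::quantile} type 7).
#'
#' @param wells well scores for one plate: data.frame \code{plate_id, well,
#'   mean_swell_rate} (wells with \code{NA} rate are dropped).
#' @param layout the plate's \code{\link{plate_layout}} (for well roles).
#' @param control_policy \code{"compounds"} (default: reference set is the
#'   compound wells) or \code{"all"} (controls included in the reference).
#' @param quantile_type passed to \code{stats::quantile} (default 7).
#' @return data.frame \code{plate_id, well, role, raw_rate, norm_rate}.
#' @export
normalize_plate <- function(wells, layout, control_policy = c("compounds", "all"),
                            quantile_type = 7) {
  control_policy <- match.arg(control_policy)
  .assert_cols(wells, c("plate_id", "well", "mean_swell_rate"), "wells")
  layout <- validate_layout(as.data.frame(layout))
  plate <- unique(wells$plate_id)
  if (length(plate) != 1L) .stopf("normalize_plate expects a single plate, got: %s",
                                  paste(plate, collapse = ", "))
  wells <- wells[!is.na(wells$mean_swell_rate), ]
  lay <- layout[layout$plate_id == plate, ]
  role <- lay$role[match(wells$well, lay$well)]
  if (anyNA(role))
    .stopf("well(s) missing from layout of plate %s: %s", plate,
           paste(wells$well[is.na(role)], collapse = ", "))
  eligible <- if (control_policy == "compounds") role == "compound" else rep(TRUE, nrow(wells))
  if (sum(eligible) < 4L)
    .stopf("plate %s has only %d eligible well(s); at least 4 are required to normalize",
           plate, sum(eligible))
  ref <- wells$mean_swell_rate[eligible]
  med <- unname(quantile(ref, 0.5, type = quantile_type))
  iqr <- unname(diff(quantile(ref, c(0.25, 0.75), type = quantile_type)))
  if (iqr <= 0)
    .stopf("degenerate plate %s: swell-rate IQR is zero, cannot normalize", plate)
  data.frame(plate_id = plate, well = wells$well, role = role,
             raw_rate = wells$mean_swell_rate,
             norm_rate = (wells$mean_swell_rate - med) / iqr,
             stringsAsFactors = FALSE)
}

#' Average plate-normalized rates per compound
#'
#' Pools normalized rates across plates, replicates and donors: every well
#' containing a compound contributes its \code{norm_rate} (a pooled well's
#' rate is attributed fully to both of its compounds), and the compound's
#' score is the unweighted arithmetic mean.  Compounds whose every well was
#' lost upstream are reported in the \code{dropped_compounds} attribute.
#'
#' @param normalized normalized wells (rbind of \code{\link{normalize_plate}}
#'   outputs).
#' @param layout layout covering all plates.
#' @param weighting \code{"well"} (default, unweighted over wells) or
#'   \code{"plate"} (per-plate means first, then averaged — equal plate/donor
#'   weight regardless of replicate count).
#' @return a \code{screen_table} data.frame \code{compound, mean_norm_rate,
#'   n_measurements, wells} (semicolon-separated source wells), sorted by
#'   decreasing score, with attribute \code{dropped_compounds}.
#' @export
average_conditions <- function(normalized, layout, weighting = c("well", "plate")) {
  weighting <- match.arg(weighting)
  .assert_cols(normalized, c("plate_id", "well", "norm_rate"), "normalized wells")
  layout <- validate_layout(as.data.frame(layout))
  cw <- layout[layout$role == "compound", ]
  long <- rbind(
    data.frame(plate_id = cw$plate_id, well = cw$well, compound = cw$compound_1,
               stringsAsFactors = FALSE),
    data.frame(plate_id = cw$plate_id, well = cw$well, compound = cw$compound_2,
               stringsAsFactors = FALSE))
  long <- long[!is.na(long$compound), ]
  m <- merge(long, normalized[, c("plate_id", "well", "norm_rate")],
             by = c("plate_id", "well"))
  all_compounds <- sort(unique(long$compound))
  if (!nrow(m)) {
    tab <- data.frame(compound = character(), mean_norm_rate = numeric(),
                      n_measurements = integer(), wells = character())
    attr(tab, "dropped_compounds") <- all_compounds
    class(tab) <- c("screen_table", "data.frame")
    return(tab)
  }
  if (weighting == "plate") {
    pm <- aggregate(norm_rate ~ compound + plate_id, m, mean)
    agg <- aggregate(norm_rate ~ compound, pm, mean)
  } else {
    agg <- aggregate(norm_rate ~ compound, m, mean)
  }
  cnt <- aggregate(norm_rate ~ compound, m, length)
  m <- m[order(m$plate_id, m$well), ]
  src <- vapply(split(paste(m$plate_id, m$well, sep = ":"), m$compound),
                function(w) paste(sort(unique(w)), collapse = ";"), character(1))
  tab <- data.frame(compound = agg$compound,
                    mean_norm_rate = agg$norm_rate,
                    n_measurements = cnt$norm_rate[match(agg$compound, cnt$compound)],
                    wells = unname(src[agg$compound]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_norm_rate, tab$compound), ]
  rownames(tab) <- NULL
  attr(tab, "dropped_compounds") <- setdiff(all_compounds, tab$compound)
  class(tab) <- c("screen_table", "data.frame")
  tab
}

#' Flag screening hits
#'
#' A compound is a hit when its mean plate-normalized swell rate is strictly
#' greater than the threshold — 1.0 by default, i.e. one interquartile range
#' above the plate median.
#'
#' @param table a \code{screen_table} from \code{\link{average_conditions}}.
#' @param threshold dimensionless hit threshold (default 1.0).
#' @return the table with a logical \code{hit} column.
#' @export
call_hits <- function(table, threshold = 1.0) {
  .assert_cols(table, c("compound", "mean_norm_rate"), "screen table")
  table$hit <- table$mean_norm_rate > threshold
  table
}

#' Deconvolve pooled hit wells into a compound list
#'
#' Every hit well of a pooled (two-compounds-per-well) screen contributes both
#' of its compounds to the secondary-screening list; duplicates are removed.
#'
#' @param hit_wells data.frame \code{plate_id, well} of wells called hits.
#' @param layout pooled-format layout.
#' @return character vector of distinct compounds, in first-appearance order
#'   of the sorted hit wells.
#' @export
deconvolve_pairs <- function(hit_wells, layout) {
  .assert_cols(hit_wells, c("plate_id", "well"), "hit wells")
  layout <- validate_layout(as.data.frame(layout))
  hit_wells <- unique(hit_wells[, c("plate_id", "well")])
  hit_wells <- hit_wells[order(hit_wells$plate_id, hit_wells$well), ]
  i <- match(paste(hit_wells$plate_id, hit_wells$well),
             paste(layout$plate_id, layout$well))
  if (anyNA(i))
    .stopf("hit well(s) missing from layout: %s",
           paste(paste(hit_wells$plate_id, hit_wells$well)[is.na(i)], collapse = ", "))
  if (any(layout$role[i] != "compound"))
    .stopf("hit well(s) are not compound wells: %s",
           paste(paste(hit_wells$plate_id, hit_wells$well)[layout$role[i] != "compound"],
                     collapse = ", "))
  cs <- as.vector(rbind(layout$compound_1[i], layout$compound_2[i]))
  unique(cs[!is.na(cs)])
}

#' Screen-level analysis: normalize, average, call hits
#'
#' Runs the full screen statistics over all plates: per-plate median/IQR
#' normalization, per-compound averaging across plates and donors, hit
#' calling at the IQR threshold, and deconvolution of pooled hit wells.
#' Plates that cannot be normalized (zero IQR, too few wells) are dropped and
#' reported rather than aborting the screen.
#'
#' @param wells well scores across all plates (see \code{\link{aggregate_wells}}).
#' @param layout layout covering all plates.
#' @param threshold hit threshold on the mean normalized rate (default 1.0).
#' @inheritParams normalize_plate
#' @inheritParams average_conditions
#' @return an object of class \code{organoid_screen}: list with
#'   \code{normalized} (all wells), \code{compounds} (the hit-flagged
#'   \code{screen_table}), \code{hit_wells} (compound wells with
#'   \code{norm_rate > threshold}), \code{secondary_list} (deconvolved
#'   compounds from hit wells), \code{dropped_plates},
#'   \code{dropped_compounds}, \code{missing_wells} and the parameters.
#' @export
screen_organoids <- function(wells, layout, threshold = 1.0,
                             control_policy = c("compounds", "all"),
                             quantile_type = 7, weighting = c("well", "plate")) {
  control_policy <- match.arg(control_policy)
  weighting <- match.arg(weighting)
  layout <- validate_layout(as.data.frame(layout))
  plates <- unique(wells$plate_id)
  normalized <- list(); dropped <- character(0); msgs <- character(0)
  for (p in plates) {
    res <- tryCatch(
      normalize_plate(wells[wells$plate_id == p, ], layout,
                      control_policy = control_policy, quantile_type = quantile_type),
      error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- c(dropped, p); msgs <- c(msgs, conditionMessage(res))
    } else normalized[[p]] <- res
  }
  normalized <- do.call(rbind, normalized)
  if (is.null(normalized))
    .stopf("no plate could be normalized: %s", paste(msgs, collapse = "; "))
  rownames(normalized) <- NULL
  tab <- call_hits(average_conditions(normalized, layout, weighting = weighting),
                   threshold = threshold)
  hw <- normalized[normalized$role == "compound" & normalized$norm_rate > threshold,
                   c("plate_id", "well", "norm_rate")]
  rownames(hw) <- NULL
  missing_wells <- if ("missing" %in% names(wells))
    wells[wells$missing, c("plate_id", "well")] else
    wells[is.na(wells$mean_swell_rate), c("plate_id", "well")]
  structure(list(normalized = normalized, compounds = tab, hit_wells = hw,
                 secondary_list = if (nrow(hw)) deconvolve_pairs(hw, layout) else character(0),
                 dropped_plates = dropped, dropped_plate_errors = msgs,
                 dropped_compounds = attr(tab, "dropped_compounds"),
                 missing_wells = missing_wells,
                 params = list(threshold = threshold, control_policy = control_policy,
                               quantile_type = quantile_type, weighting = weighting)),
            class = "organoid_screen")
}

#' @export
print.organoid_screen <- function(x, ...) {
  cat("Organoid fluid-secretion screen\n")
  cat(sprintf("  %d wells on %d plate(s); %d compound(s) scored\n",
              nrow(x$normalized), length(unique(x$normalized$plate_id)),
              nrow(x$compounds)))
  cat(sprintf("  hits (mean normalized rate > %g): %d compounds from %d hit wells\n",
              x$params$threshold, sum(x$compounds$hit), nrow(x$hit_wells)))
  if (length(x$dropped_plates))
    cat("  dropped plates:", paste(x$dropped_plates, collapse = ", "), "\n")
  if (length(x$dropped_compounds))
    cat(sprintf("  dropped compounds (no surviving well): %d\n", length(x$dropped_compounds)))
  invisible(x)
}

#' @export
summary.organoid_screen <- function(object, ...) {
  hits <- object$compounds[object$compounds$hit, ]
  structure(list(n_compounds = nrow(object$compounds), n_hits = nrow(hits),
                 hits = hits, secondary_list = object$secondary_list,
                 dropped_plates = object$dropped_plates,
                 dropped_compounds = object$dropped_compounds,
                 params = object$params),
            class = "summary.organoid_screen")
}

#' @export
print.summary.organoid_screen <- function(x, ...) {
  cat(sprintf("Screen summary: %d/%d compounds above threshold %g\n",
              x$n_hits, x$n_compounds, x$params$threshold))
  if (nrow(x$hits)) print(head(x$hits[, c("compound", "mean_norm_rate", "n_measurements")], 20))
  cat(sprintf("Secondary-screening list: %d compounds\n", length(x$secondary_list)))
  invisible(x)
}

#' Plot compound scores of a screen
#'
#' Rank-ordered mean normalized swell rates with the hit threshold line —
#' hits highlighted.
#'
#' @param x an \code{\link{screen_organoids}} object.
#' @param ... passed to \code{plot}.
#' @export
plot.organoid_screen <- function(x, ...) {
  tab <- x$compounds[order(x$compounds$mean_norm_rate), ]
  plot(seq_len(nrow(tab)), tab$mean_norm_rate,
       col = ifelse(tab$hit, "forestgreen", "grey40"),
       pch = 16, cex = 0.6, xlab = "compound rank",
       ylab = "mean plate-normalized swell rate", ...)
  abline(h = x$params$threshold, lty = 2, col = "red3")
  legend("topleft", legend = c("hit", "non-hit"), col = c("forestgreen", "grey40"),
         pch = 16, bty = "n")
  invisible(x)
}
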