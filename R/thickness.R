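#' TSNIT sector layout
#'
#' Angular spans of the six peripapillary sectors on the unrolled circle,
#' measured along the TSNIT axis with A-scan 0 at the temporal meridian:
#' temporal spans 90 degrees centred on 0 (315-45), nasal spans 90 degrees
#' centred on 180 (135-225), and the four superior/inferior sectors are the
#' adjacent 45-degree wedges. Spans are half-open `[start, end)`, disjoint,
#' and cover the full circle.
#'
#' @param spans Optional data frame with columns `sector`, `start`, `end`
#'   (degrees) to override the default layout.
#' @return An object of class `sector_layout`.
#' @export
sector_layout <- function(spans = NULL) {
  if (is.null(spans)) {
    spans <- data.frame(
      sector = c("temporal", "temporal_superior", "nasal_superior",
                 "nasal", "nasal_inferior", "temporal_inferior"),
      start = c(315, 45, 90, 135, 225, 270),
      end = c(45, 90, 135, 225, 270, 315),
      stringsAsFactors = FALSE
    )
  }
  widths <- (spans$end - spans$start) %% 360
  widths[widths == 0] <- 360
  if (abs(sum(widths) - 360) > 1e-9) {
    stop("sector layout must cover the circle: spans sum to ", sum(widths),
         " degrees")
  }
  probe <- seq(0, 359.75, by = 0.25)
  hits <- vapply(probe, function(a) {
    sum(vapply(seq_len(nrow(spans)), function(i) {
      angle_in_span(a, spans$start[i], spans$end[i])
    }, logical(1)))
  }, numeric(1))
  if (any(hits != 1)) {
    stop("sector layout spans must be disjoint and cover every angle")
  }
  structure(list(spans = spans), class = "sector_layout")
}

# membership of an angle in a sector span. OD uses half-open [start, end);
# for OS the mirrored mapping reverses orientation, which flips which end of
# the interval is closed, so mirrored membership uses (start, end].
angle_in_span <- function(angle, start, end, right_closed = FALSE) {
  width <- (end - start) %% 360
  if (width == 0) width <- 360
  a <- (angle - start) %% 360
  if (right_closed) a > 0 & a <= width else a < width
}

#' Clean a predicted binary mask
#'
#' Fills interior holes and removes connected components (8-connectivity)
#' smaller than `min_component_px` — the gaps and speckles a raw network
#' prediction can contain.
#'
#' @param mask An [rnfl_mask()] (or binary matrix).
#' @param min_component_px Components below this pixel area are removed.
#' @param fill_holes Fill interior holes first.
#' @return A cleaned object of the same class as the input.
#' @export
clean_mask <- function(mask, min_component_px = 25L, fill_holes = TRUE) {
  px <- if (inherits(mask, "rnfl_mask")) mask$pixels else as.matrix(mask)
  if (!all(px %in% c(0, 1))) stop("clean_mask: mask must be binary")
  storage.mode(px) <- "integer"
  if (fill_holes && any(px > 0L)) {
    px <- matrix(as.integer(EBImage::fillHull(px) > 0), nrow(px), ncol(px))
  }
  if (min_component_px > 1L && any(px > 0L)) {
    lab <- label8_cpp(px)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_component_px)
    px <- matrix(as.integer(lab %in% keep), nrow(px), ncol(px))
  }
  if (inherits(mask, "rnfl_mask")) {
    mask$pixels <- px
    mask
  } else {
    px
  }
}

#' Per-A-scan RNFL thickness from a binary mask
#'
#' Two estimators over each column (A-scan) of the mask:
#' \describe{
#'   \item{`column`}{pixel count in the column times the axial spacing — the
#'     default reporting estimator.}
#'   \item{`edt`}{twice the maximum Euclidean distance-to-background over the
#'     column's foreground pixels, times the axial spacing — the
#'     distance-transform cross-check. For a horizontal band of height `h`
#'     the two agree within one axial pixel; where the band slopes steeply
#'     the distance transform reads local (perpendicular) thickness and
#'     under-reads columns thicker than their neighbourhood, which is why
#'     `column` is the reporting default.}
#' }
#' Empty columns yield 0.
#'
#' @param mask An [rnfl_mask()] (or binary matrix, in which case
#'   `axial_spacing_um` must be supplied).
#' @param method `"column"` or `"edt"`.
#' @param axial_spacing_um Axial calibration when `mask` is a plain matrix.
#' @return An [rnfl_profile()] with one value per A-scan.
#' @export
thickness_profile <- function(mask, method = c("column", "edt"),
                              axial_spacing_um = NULL) {
  method <- match.arg(method)
  if (inherits(mask, "rnfl_mask")) {
    px <- mask$pixels
    spacing <- mask$axial_spacing_um
  } else {
    px <- as.matrix(mask)
    spacing <- axial_spacing_um
    if (is.null(spacing)) stop("axial_spacing_um required for a plain matrix")
  }
  if (!all(px %in% c(0, 1))) stop("thickness_profile: mask must be binary")
  vals <- if (method == "column") {
    colSums(px) * spacing
  } else {
    if (any(px > 0)) {
      dm <- EBImage::distmap(px, metric = "euclidean")
      2 * apply(as.matrix(dm), 2, max) * spacing
    } else {
      numeric(ncol(px))
    }
  }
  rnfl_profile(vals, axial_spacing_um = spacing)
}

#' Seven-sector TSNIT thickness report
#'
#' The average is the plain mean over all A-scans; each sector is the mean
#' over the A-scans whose angle falls in its half-open span. For left eyes
#' (`OS`) the angular mapping is mirrored (`theta -> (180 - theta) mod 360`)
#' so nasal/temporal labels stay anatomically correct while superior remains
#' superior. When the profile length is a multiple of 8 the average equals
#' the angular-width-weighted mean of the six sectors exactly (the sectors
#' partition the circle).
#'
#' @param profile An [rnfl_profile()] (or numeric vector).
#' @param layout A [sector_layout()].
#' @param eye `"OD"` or `"OS"`.
#' @return An object of class `sector_thickness`: a list with `average_um`,
#'   `nasal_um`, `temporal_um`, `nasal_inferior_um`, `temporal_inferior_um`,
#'   `nasal_superior_um`, `temporal_superior_um`.
#' @export
sector_thickness <- function(profile, layout = sector_layout(),
                             eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  stopifnot(inherits(layout, "sector_layout"))
  vals <- profile_values(profile)
  n <- length(vals)
  if (n < 6L) stop("profile must have at least 6 A-scans")
  theta <- (seq_len(n) - 1) * 360 / n
  if (eye == "OS") theta <- (180 - theta) %% 360

  means <- vapply(seq_len(nrow(layout$spans)), function(i) {
    in_span <- angle_in_span(theta, layout$spans$start[i],
                             layout$spans$end[i],
                             right_closed = (eye == "OS"))
    if (!any(in_span)) return(NA_real_)
    mean(vals[in_span])
  }, numeric(1))
  names(means) <- layout$spans$sector

  structure(list(
    average_um = mean(vals),
    nasal_um = means[["nasal"]],
    temporal_um = means[["temporal"]],
    nasal_inferior_um = means[["nasal_inferior"]],
    temporal_inferior_um = means[["temporal_inferior"]],
    nasal_superior_um = means[["nasal_superior"]],
    temporal_superior_um = means[["temporal_superior"]]
  ), class = "sector_thickness")
}

#' @export
print.sector_thickness <- function(x, ...) {
  cat(sprintf(
    paste0("sector_thickness (um): avg %.1f | T %.1f TS %.1f NS %.1f ",
           "N %.1f NI %.1f TI %.1f\n"),
    x$average_um, x$temporal_um, x$temporal_superior_um, x$nasal_superior_um,
    x$nasal_um, x$nasal_inferior_um, x$temporal_inferior_um))
  invisible(x)
}

#' @export
as.data.frame.sector_thickness <- function(x, ...) {
  data.frame(avg_um = x$average_um, n_um = x$nasal_um, t_um = x$temporal_um,
             ni_um = x$nasal_inferior_um, ti_um = x$temporal_inferior_um,
             ns_um = x$nasal_superior_um, ts_um = x$temporal_superior_um)
}
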