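#' Grayscale circumpapillary B-scan
#'
#' A thin container for a 2-D intensity grid (rows = axial depth, columns =
#' A-scans in TSNIT order) with axial calibration and eye laterality.
#'
#' @param pixels Numeric matrix with intensities in \[0,1\].
#' @param axial_spacing_um Micrometres per axial pixel.
#' @param eye `"OD"` or `"OS"`.
#' @param scan_id Identifier string.
#' @return An object of class `bscan_image`.
#' @export
bscan_image <- function(pixels, axial_spacing_um, eye = "OD",
                        scan_id = "scan") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0) stop("bscan_image: empty pixel grid")
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("bscan_image: intensities must lie in [0, 1]")
  }
  if (axial_spacing_um <= 0) stop("bscan_image: axial_spacing_um must be > 0")
  structure(list(pixels = pixels, axial_spacing_um = axial_spacing_um,
                 width_ascans = ncol(pixels), eye = match.arg(eye, c("OD", "OS")),
                 scan_id = scan_id),
            class = "bscan_image")
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("bscan_image '%s': %d x %d px, %.2f um/px axial, eye %s\n",
              x$scan_id, nrow(x$pixels), ncol(x$pixels),
              x$axial_spacing_um, x$eye))
  invisible(x)
}

#' Binary RNFL segmentation mask
#'
#' @param pixels Matrix with values in \{0, 1\} (logical or numeric).
#' @param axial_spacing_um Micrometres per axial pixel.
#' @param eye `"OD"` or `"OS"`.
#' @return An object of class `rnfl_mask`.
#' @export
rnfl_mask <- function(pixels, axial_spacing_um, eye = "OD") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L))) {
    stop("rnfl_mask: values must be 0 or 1")
  }
  if (axial_spacing_um <= 0) stop("rnfl_mask: axial_spacing_um must be > 0")
  structure(list(pixels = pixels, axial_spacing_um = axial_spacing_um,
                 eye = match.arg(eye, c("OD", "OS"))),
            class = "rnfl_mask")
}

#' @export
print.rnfl_mask <- function(x, ...) {
  cat(sprintf("rnfl_mask: %d x %d px, %d foreground px, %.2f um/px, eye %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$axial_spacing_um, x$eye))
  invisible(x)
}

#' Per-A-scan RNFL thickness profile
#'
#' Thickness in µm along the unrolled circle, starting at the temporal
#' meridian and running in TSNIT direction.
#'
#' @param values_um Nonnegative thickness values, one per A-scan.
#' @param axial_spacing_um Axial calibration carried along for quantization
#'   checks.
#' @return An object of class `rnfl_profile`.
#' @export
rnfl_profile <- function(values_um, axial_spacing_um = NA_real_) {
  values_um <- as.numeric(values_um)
  if (any(values_um < 0)) stop("rnfl_profile: thickness must be nonnegative")
  structure(list(values_um = values_um, n_ascans = length(values_um),
                 start_meridian = "temporal", direction = "TSNIT",
                 axial_spacing_um = axial_spacing_um),
            class = "rnfl_profile")
}

profile_values <- function(profile) {
  if (inherits(profile, "rnfl_profile")) profile$values_um
  else as.numeric(profile)
}

#' @export
print.rnfl_profile <- function(x, ...) {
  cat(sprintf(
    "rnfl_profile: %d A-scans (TSNIT from temporal), mean %.1f um, range [%.1f, %.1f]\n",
    x$n_ascans, mean(x$values_um), min(x$values_um), max(x$values_um)))
  invisible(x)
}

#' Circle-average thickness of a profile
#'
#' @param profile An [rnfl_profile()] or numeric vector.
#' @return Mean thickness in µm.
#' @export
circle_average <- function(profile) mean(profile_values(profile))

# ---- PNG I/O ----------------------------------------------------------------

#' Write a grayscale image to 8-bit PNG
#' @param pixels Matrix in \[0,1\].
#' @param path Output file.
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 1), path)
  invisible(path)
}

#' Write a binary mask to PNG with values \{0, 255\}
#' @param pixels Matrix in \{0,1\}.
#' @param path Output file.
#' @export
write_mask_png <- function(pixels, path) {
  png::writePNG(matrix(as.numeric(pixels > 0), nrow(pixels), ncol(pixels)),
                path)
  invisible(path)
}

#' Read a grayscale B-scan from PNG or TIFF
#'
#' 8- and 16-bit inputs are normalized to \[0,1\] by the readers (division by
#' the dtype maximum); multi-channel images are averaged to grayscale.
#'
#' @param path Input file (`.png`, `.tif`, `.tiff`).
#' @param axial_spacing_um Axial calibration to attach.
#' @param eye Laterality to attach.
#' @param scan_id Identifier; defaults to the file name.
#' @return A [bscan_image()].
#' @export
read_bscan <- function(path, axial_spacing_um = 3.87, eye = "OD",
                       scan_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  bscan_image(px, axial_spacing_um = axial_spacing_um, eye = eye,
              scan_id = scan_id %||% basename(path))
}

#' Read a binary mask from PNG
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path Input PNG.
#' @param axial_spacing_um Axial calibration to attach.
#' @param eye Laterality to attach.
#' @return An [rnfl_mask()].
#' @export
read_mask <- function(path, axial_spacing_um = 3.87, eye = "OD") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  rnfl_mask((px > 0.5) * 1L, axial_spacing_um = axial_spacing_um, eye = eye)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
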