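#' Morphological speckle denoising
#'
#' Grayscale morphological opening followed by closing with a square
#' structuring element (default 3x3). Opening removes bright speckle grains —
#' the dominant OCT artifact — and the subsequent closing removes the dark
#' pits opening cannot reach. The composition is idempotent, never widens the
#' intensity range, and leaves calibration metadata untouched.
#'
#' @param image A [bscan_image()] (or plain matrix in \[0,1\]).
#' @param kernel_px Odd side length of the square kernel.
#' @return A denoised object of the same class as the input.
#' @export
denoise_morphological <- function(image, kernel_px = 3L) {
  if (kernel_px < 1L || kernel_px %% 2L == 0L) {
    stop("kernel_px must be an odd integer >= 1")
  }
  px <- if (inherits(image, "bscan_image")) image$pixels else as.matrix(image)
  if (kernel_px > 1L) {
    kern <- EBImage::makeBrush(kernel_px, shape = "box")
    px <- EBImage::closing(EBImage::opening(px, kern), kern)
    px <- pmin(pmax(px, 0), 1)
  }
  if (inherits(image, "bscan_image")) {
    image$pixels <- px
    image
  } else {
    px
  }
}

#' Scale-and-pad transform record
#'
#' Records exactly how an image was brought to the network grid so that a
#' predicted mask can be mapped back to the original dimensions.
#'
#' @param scale_factor Isotropic resampling factor applied before padding
#'   (1 when no resampling was needed).
#' @param pad_top,pad_left Zero rows/columns added at the top/left (the
#'   bottom/right get the remainder).
#' @param original_height,original_width Input dimensions.
#' @param target Network grid side.
#' @return An object of class `scale_info`.
#' @export
scale_info <- function(scale_factor, pad_top, pad_left,
                       original_height, original_width, target = 256L) {
  structure(list(scale_factor = scale_factor, pad_top = as.integer(pad_top),
                 pad_left = as.integer(pad_left),
                 original_height = as.integer(original_height),
                 original_width = as.integer(original_width),
                 target = as.integer(target)),
            class = "scale_info")
}

#' Prepare a B-scan for the network
#'
#' Brings an image to the square network grid (default 256x256). Images no
#' larger than the target are zero-padded symmetrically (the extra pixel of
#' an odd margin goes to the bottom/right); larger images are first
#' downscaled isotropically (bilinear) so the larger dimension equals the
#' target — scaled dimensions use ceiling — then zero-padded. The returned
#' [scale_info()] inverts the transform exactly.
#'
#' @param image A [bscan_image()] or matrix.
#' @param target Side of the square network input.
#' @return A list with `input` (target x target matrix) and `scale`
#'   (a [scale_info()]).
#' @export
prepare_input <- function(image, target = 256L) {
  px <- if (inherits(image, "bscan_image")) image$pixels else as.matrix(image)
  h <- nrow(px)
  w <- ncol(px)
  if (h == 0 || w == 0) stop("prepare_input: empty image")

  sf <- 1
  if (h > target || w > target) {
    sf <- target / max(h, w)
    sh <- as.integer(ceiling(h * sf))
    sw <- as.integer(ceiling(w * sf))
    px <- as.matrix(EBImage::resize(px, w = sh, h = sw, filter = "bilinear"))
  }
  sh <- nrow(px)
  sw <- ncol(px)
  pad_top <- (target - sh) %/% 2L
  pad_left <- (target - sw) %/% 2L
  canvas <- matrix(0, target, target)
  canvas[pad_top + seq_len(sh), pad_left + seq_len(sw)] <- px
  list(input = canvas,
       scale = scale_info(sf, pad_top, pad_left, h, w, target))
}

#' Map a network-grid mask back to original image dimensions
#'
#' Inverts [prepare_input()]: removes the zero padding, then (when the image
#' was downscaled) upsamples by nearest-neighbour index mapping so the output
#' stays strictly binary.
#'
#' @param mask_px Binary matrix on the network grid.
#' @param scale The [scale_info()] returned by [prepare_input()].
#' @return A binary matrix of the original dimensions.
#' @export
restore_mask <- function(mask_px, scale) {
  stopifnot(inherits(scale, "scale_info"))
  if (nrow(mask_px) != scale$target || ncol(mask_px) != scale$target) {
    stop("restore_mask: mask dims (", nrow(mask_px), "x", ncol(mask_px),
         ") do not match the network grid (", scale$target, ")")
  }
  sh <- as.integer(ceiling(scale$original_height * scale$scale_factor))
  sw <- as.integer(ceiling(scale$original_width * scale$scale_factor))
  core <- mask_px[scale$pad_top + seq_len(sh), scale$pad_left + seq_len(sw),
                  drop = FALSE]
  if (scale$scale_factor == 1) {
    return(core)
  }
  ri <- pmin(sh, floor((seq_len(scale$original_height) - 1) * sh /
                         scale$original_height) + 1L)
  ci <- pmin(sw, floor((seq_len(scale$original_width) - 1) * sw /
                         scale$original_width) + 1L)
  core[ri, ci, drop = FALSE]
}
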