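# shared fixtures: everything is generated in code, no files on disk

# small fast phantom grid for unit tests
small_spec <- function(...) {
  phantom_spec(width_ascans = 64L, height_px = 64L, ilm_depth_px = 14L,
               ilm_undulation_px = 2, group_preset = "control", ...)
}

# deterministic flat-band mask: height h starting at row r0, full width
flat_band_mask <- function(h, H = 32L, W = 24L, r0 = 8L, spacing = 3.87) {
  px <- matrix(0L, H, W)
  px[r0:(r0 + h - 1L), ] <- 1L
  rnfl_mask(px, axial_spacing_um = spacing)
}

# random blobby binary mask (no structural assumptions)
random_mask <- function(H, W, p = 0.3) {
  matrix(rbinom(H * W, 1L, p), H, W)
}

# brute-force pixel enumeration of the confusion counts (independent oracle)
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}
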