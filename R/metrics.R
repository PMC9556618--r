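#' Pixel-wise segmentation agreement metrics
#'
#' Confusion counts with `truth` as reference, and the derived Dice
#' coefficient (`2 tp / (2 tp + fp + fn)`), sensitivity (`tp / (tp + fn)`),
#' and specificity (`tn / (tn + fp)`). When both masks are empty the Dice is
#' 1.0 by convention and the result is flagged (`empty_pair`).
#'
#' @param pred,truth Binary masks ([rnfl_mask()] or matrices) of identical
#'   dimensions.
#' @return An object of class `segmentation_metrics`: a list with `dice`,
#'   `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`, `empty_pair`.
#' @export
segmentation_metrics <- function(pred, truth) {
  p <- if (inherits(pred, "rnfl_mask")) pred$pixels else as.matrix(pred)
  t <- if (inherits(truth, "rnfl_mask")) truth$pixels else as.matrix(truth)
  if (!all(dim(p) == dim(t))) {
    stop("segmentation_metrics: grid dims differ (",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t), collapse = "x"),
         ")")
  }
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1))) {
    stop("segmentation_metrics: masks must be binary")
  }
  p <- p > 0
  t <- t > 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  tn <- sum(!p & !t)
  empty_pair <- (tp + fp + fn) == 0
  dice <- if (empty_pair) 1.0 else 2 * tp / (2 * tp + fp + fn)
  sens <- if ((tp + fn) == 0) NA_real_ else tp / (tp + fn)
  spec <- if ((tn + fp) == 0) NA_real_ else tn / (tn + fp)
  structure(list(dice = dice, sensitivity = sens, specificity = spec,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 empty_pair = empty_pair),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf(
    "segmentation_metrics: dice %.4f, sens %.4f, spec %.4f (tp %d fp %d tn %d fn %d)%s\n",
    x$dice, x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn,
    if (x$empty_pair) " [empty pair: dice = 1 by convention]" else ""))
  invisible(x)
}

#' Mean absolute error
#'
#' @param estimates,truths Numeric vectors of equal length (>= 1).
#' @return `mean(abs(estimates - truths))`.
#' @export
mae <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    stop("mae: length mismatch (", length(estimates), " vs ",
         length(truths), ")")
  }
  if (length(estimates) < 1L) stop("mae: empty input")
  mean(abs(estimates - truths))
}

#' Sample Pearson correlation
#'
#' A thin wrapper over [stats::cor()] that enforces the contract used for
#' thickness agreement reporting: at least three pairs and nonzero variance
#' on both sides.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: length mismatch")
  if (length(x) < 3L) stop("pearson_r: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: undefined correlation (zero variance)")
  }
  stats::cor(x, y)
}

#' Evaluate predicted masks against ground truth over a dataset
#'
#' Per-scan Dice/sensitivity/specificity, reported individually and averaged
#' across scans (the per-scan framing); a pooled-pixel mode accumulates the
#' confusion counts over all scans before deriving the metrics.
#'
#' @param preds,truths Lists of binary masks, matched by position.
#' @param scan_ids Identifiers for the report rows.
#' @param mode `"per_scan"` (default) or `"pooled"` for the summary.
#' @return A list with `per_scan` (data frame scan_id, dice, sensitivity,
#'   specificity) and `summary` (means and SDs; pooled values when
#'   `mode = "pooled"`).
#' @export
evaluate_masks <- function(preds, truths, scan_ids = NULL,
                           mode = c("per_scan", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(truths))
  n <- length(preds)
  scan_ids <- scan_ids %||% sprintf("scan_%04d", seq_len(n))
  ms <- lapply(seq_len(n), function(i) segmentation_metrics(preds[[i]],
                                                            truths[[i]]))
  per_scan <- data.frame(
    scan_id = scan_ids,
    dice = vapply(ms, `[[`, numeric(1), "dice"),
    sensitivity = vapply(ms, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(ms, `[[`, numeric(1), "specificity"),
    stringsAsFactors = FALSE
  )
  summary <- if (mode == "per_scan") {
    list(mode = "per_scan",
         dice_mean = mean(per_scan$dice), dice_sd = stats::sd(per_scan$dice),
         sensitivity_mean = mean(per_scan$sensitivity, na.rm = TRUE),
         specificity_mean = mean(per_scan$specificity, na.rm = TRUE))
  } else {
    tp <- sum(vapply(ms, `[[`, numeric(1), "tp"))
    fp <- sum(vapply(ms, `[[`, numeric(1), "fp"))
    tn <- sum(vapply(ms, `[[`, numeric(1), "tn"))
    fn <- sum(vapply(ms, `[[`, numeric(1), "fn"))
    list(mode = "pooled",
         dice_mean = if (tp + fp + fn == 0) 1.0 else 2 * tp / (2 * tp + fp + fn),
         sensitivity_mean = tp / (tp + fn),
         specificity_mean = tn / (tn + fp))
  }
  list(per_scan = per_scan, summary = summary)
}
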