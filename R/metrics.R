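#' Tissue area of a binary mask
#'
#' Area in mm^2 as pixel count times the squared pixel spacing; matrix and
#' FOV never change across resolutions, so the native spacing applies to
#' every mask regardless of effective resolution.
#'
#' @param mask logical (or 0/1) matrix.
#' @param dx_mm pixel spacing (mm), > 0.
#' @return area in mm^2.
#' @export
tissue_area <- function(mask, dx_mm) {
  .assert_binary(mask)
  if (dx_mm <= 0) .stopf("dx_mm must be > 0")
  dx_mm^2 * sum(mask > 0)
}

#' Signed relative myocardial area error (percent)
#'
#' 100 * (A_network - A_ref) / A_ref for myocardial tissue.
#'
#' @param pred_area,ref_area areas in mm^2; `ref_area` must be > 0.
#' @return percent error.
#' @export
myo_error <- function(pred_area, ref_area) {
  if (ref_area <= 0) .stopf("reference myocardial area must be > 0")
  100 * (pred_area - ref_area) / ref_area
}

#' Signed scar area error in percentage points of reference myocardium
#'
#' 100 * (A_network(SCAR) - A_ref(SCAR)) / A_ref(MYO); both terms share the
#' reference myocardial area as denominator, so the result is a difference
#' of relative scar areas in percentage points (p.p.).
#'
#' @param pred_scar_area,ref_scar_area scar areas in mm^2.
#' @param ref_myo_area reference myocardial area in mm^2, > 0.
#' @return signed error in percentage points.
#' @export
scar_error <- function(pred_scar_area, ref_scar_area, ref_myo_area) {
  if (ref_myo_area <= 0) .stopf("reference myocardial area must be > 0")
  100 * (pred_scar_area - ref_scar_area) / ref_myo_area
}

#' Sorensen-Dice coefficient with the empty-mask convention
#'
#' 2 * |pred AND ref| / (|pred| + |ref|); when both masks are empty the
#' score is defined as 1 (the network correctly indicated absence).
#'
#' @param pred,ref binary masks of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  .assert_binary(pred, "pred"); .assert_binary(ref, "ref")
  if (!all(dim(pred) == dim(ref))) .stopf("mask shape mismatch")
  p <- pred > 0; r <- ref > 0
  denom <- sum(p) + sum(r)
  if (denom == 0) return(1)
  2 * sum(p & r) / denom
}

#' Median / IQR summary of a metric distribution
#'
#' Median, first and third quartile by the linear-interpolation (type 7)
#' quantile convention, and IQR = Q3 - Q1. The IQR is the study's indicator
#' of network precision.
#'
#' @param values numeric vector, length >= 1 (NAs dropped).
#' @return a `summary_stats` list: `median`, `q1`, `q3`, `iqr`, `n`.
#' @export
summarize_errors <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) .stopf("no values to summarize")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                 n = length(values)),
            class = "summary_stats")
}

#' Gaussian kernel density estimate of a metric distribution
#'
#' Thin wrapper over [stats::density()] (Gaussian kernel, 512-point grid)
#' used to visualise error and Dice histograms; the returned curve
#' integrates to 1 within 1e-3.
#'
#' @param values numeric vector, length >= 2.
#' @param bandwidth bandwidth; default Silverman's rule-of-thumb (`"nrd0"`).
#' @return list with `x`, `y` grids.
#' @export
density_estimate <- function(values, bandwidth = "nrd0") {
  values <- values[!is.na(values)]
  if (length(values) < 2) .stopf("need at least 2 values for a density estimate")
  if (sd(values) == 0) {
    warning("zero-variance input: density degenerates to a spike")
    bandwidth <- 1e-3 * max(abs(values[1]), 1)
  }
  d <- density(values, bw = bandwidth, kernel = "gaussian", n = 512)
  list(x = d$x, y = d$y)
}

#' Per-slice error metrics of a prediction against reference labels
#'
#' Network myocardium is the union of predicted myocardium and scar classes
#' (scar lies within myocardium anatomically); reference myocardium likewise
#' contains the reference scar.
#'
#' @param pred_myo,pred_scar predicted binary masks (myo includes scar).
#' @param ref a `reference_labels`.
#' @return a `slice_errors` list: `delta_myo` (%), `delta_scar` (p.p.),
#'   `dice_myo`, `dice_scar`.
#' @export
slice_errors <- function(pred_myo, pred_scar, ref) {
  px <- ref$pixel_mm
  a_ref_myo <- tissue_area(ref$myo, px)
  a_ref_scar <- tissue_area(ref$scar, px)
  a_p_myo <- tissue_area(pred_myo, px)
  a_p_scar <- tissue_area(pred_scar, px)
  structure(list(delta_myo = myo_error(a_p_myo, a_ref_myo),
                 delta_scar = scar_error(a_p_scar, a_ref_scar, a_ref_myo),
                 dice_myo = dice(pred_myo, ref$myo),
                 dice_scar = dice(pred_scar, ref$scar)),
            class = "slice_errors")
}
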