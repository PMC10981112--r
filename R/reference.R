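#' Remote-region signal statistics
#'
#' Mean and standard deviation of the magnitude signal over the remote
#' healthy-myocardium ROI. The sample SD (denominator n-1) is used; at the
#' ROI sizes involved the difference to the population SD is negligible, but
#' the choice is fixed and documented.
#'
#' @param magnitude 2D numeric array of magnitudes.
#' @param remote_roi logical mask, same shape, with at least 2 pixels.
#' @return a `remote_stats` list: `mu_remote`, `sigma_remote`, `n_pixels`.
#' @export
remote_statistics <- function(magnitude, remote_roi) {
  .assert_binary(remote_roi, "remote_roi")
  if (!all(dim(magnitude) == dim(remote_roi))) .stopf("magnitude/ROI shape mismatch")
  vals <- magnitude[remote_roi > 0]
  if (length(vals) < 2) .stopf("remote ROI must contain at least 2 pixels")
  structure(list(mu_remote = mean(vals), sigma_remote = sd(vals),
                 n_pixels = length(vals)),
            class = "remote_stats")
}

#' n-SD scar threshold
#'
#' tau = mu_remote + n_sd * sigma_remote; n_sd defaults to 5 (the SD5
#' convention).
#'
#' @param stats a [remote_statistics()] result.
#' @param n_sd non-negative multiplier (default 5).
#' @return a `threshold_spec` list: `n_sd`, `tau`.
#' @export
sd_threshold <- function(stats, n_sd = 5) {
  stopifnot(inherits(stats, "remote_stats"))
  if (n_sd < 0) .stopf("n_sd must be >= 0")
  structure(list(n_sd = n_sd, tau = stats$mu_remote + n_sd * stats$sigma_remote),
            class = "threshold_spec")
}

#' Threshold scar within the myocardium
#'
#' Pixels strictly above `tau` (ties go to healthy) and inside the myocardium
#' mask are labelled scar.
#'
#' @param magnitude 2D numeric array.
#' @param myo logical myocardium mask, same shape.
#' @param tau threshold (or a `threshold_spec`).
#' @return logical scar mask.
#' @export
threshold_scar <- function(magnitude, myo, tau) {
  if (inherits(tau, "threshold_spec")) tau <- tau$tau
  .assert_binary(myo, "myo")
  if (!all(dim(magnitude) == dim(myo))) .stopf("magnitude/myo shape mismatch")
  magnitude > tau & myo > 0
}

# binary dilation / erosion by a structuring element given as offset list
.se_offsets <- function(struct_elem = "square3") {
  if (is.matrix(struct_elem)) {
    stopifnot(nrow(struct_elem) %% 2 == 1, ncol(struct_elem) %% 2 == 1)
    ci <- (nrow(struct_elem) + 1) / 2; cj <- (ncol(struct_elem) + 1) / 2
    w <- which(struct_elem > 0, arr.ind = TRUE)
    return(cbind(w[, 1] - ci, w[, 2] - cj))
  }
  switch(struct_elem,
         square3 = as.matrix(expand.grid(di = -1:1, dj = -1:1)),
         cross3 = rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
         .stopf("unknown structuring element '%s'", struct_elem))
}

.shift_mask <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- base::matrix(FALSE, H, W)
  si <- max(1, 1 - di):min(H, H - di)
  sj <- max(1, 1 - dj):min(W, W - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

#' Binary dilation
#' @param mask logical matrix.
#' @param struct_elem `"square3"` (3x3, default), `"cross3"`, or an odd-sized
#'   0/1 matrix.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, struct_elem = "square3") {
  .assert_binary(mask)
  mask <- mask > 0
  off <- .se_offsets(struct_elem)
  out <- base::matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) out <- out | .shift_mask(mask, off[k, 1], off[k, 2])
  out
}

#' Binary erosion
#' @inheritParams dilate_mask
#' @return logical matrix.
#' @export
erode_mask <- function(mask, struct_elem = "square3") {
  .assert_binary(mask)
  mask <- mask > 0
  off <- .se_offsets(struct_elem)
  out <- base::matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) out <- out & .shift_mask(mask, -off[k, 1], -off[k, 2])
  out
}

#' Morphological denoising of a binary scar mask
#'
#' Opening (erosion then dilation) removes isolated pixels mislabelled as
#' scar; a subsequent dilation of the opened mask intersected with the
#' original mask re-includes individual pixels adjacent to the surviving
#' scar clusters. The result is always a subset of the input.
#'
#' @param scar_raw logical scar mask.
#' @param struct_elem structuring element (see [dilate_mask()]); 3x3 square
#'   by default (8-connectivity) — the smallest element that removes
#'   isolated pixels.
#' @return logical denoised mask.
#' @export
denoise_mask <- function(scar_raw, struct_elem = "square3") {
  .assert_binary(scar_raw, "scar_raw")
  scar_raw <- scar_raw > 0
  opened <- dilate_mask(erode_mask(scar_raw, struct_elem), struct_elem)
  dilate_mask(opened, struct_elem) & scar_raw
}

#' Build reference (REF) labels for a slice
#'
#' Composes remote statistics, the n-SD threshold, scar thresholding inside
#' the (ground-truth) myocardium and morphological denoising. References are
#' computed at the native acquisition resolution and reused unchanged when
#' evaluating all degraded test resolutions.
#'
#' @param slice a `phantom_slice` at native resolution.
#' @param n_sd threshold multiplier (default 5, i.e. SD5).
#' @param struct_elem structuring element for denoising.
#' @return a `reference_labels` list: `myo`, `scar_raw`, `scar`, `tau`,
#'   `n_sd`, `pixel_mm`.
#' @export
build_reference <- function(slice, n_sd = 5, struct_elem = "square3") {
  stopifnot(inherits(slice, "phantom_slice"))
  if (abs(slice$dx_mm - slice$pixel_mm) > 1e-9)
    warning("building reference masks on a degraded slice; the protocol computes them at native resolution")
  mag <- Mod(slice$image)
  st <- remote_statistics(mag, slice$remote_roi)
  th <- sd_threshold(st, n_sd)
  raw <- threshold_scar(mag, slice$gt_myo, th)
  structure(list(myo = slice$gt_myo, scar_raw = raw,
                 scar = denoise_mask(raw, struct_elem),
                 tau = th$tau, n_sd = n_sd, pixel_mm = slice$pixel_mm),
            class = "reference_labels")
}

#' Red-green overlay of reference labels
#'
#' Returns an H x W x 3 RGB array with healthy myocardium in green and scar
#' in red (the usual RG mask convention), for quick visual checks.
#'
#' @param ref a `reference_labels`.
#' @return numeric array `c(H, W, 3)` in `[0, 1]`.
#' @export
rg_overlay <- function(ref) {
  healthy <- ref$myo & !ref$scar
  out <- array(0, c(nrow(ref$myo), ncol(ref$myo), 3))
  out[, , 1][ref$scar] <- 1
  out[, , 2][healthy] <- 1
  out
}

#' Reference-mask statistics over a cohort
#'
#' Builds SD5 reference labels for every slice and tabulates myocardial and
#' reference scar areas, the scar fraction and scar-free status — the inputs
#' to the cohort-level reference summaries (mean relative scar area and
#' scar-free slice proportion).
#'
#' @param cohort a `phantom_cohort`.
#' @param n_sd threshold multiplier (default 5).
#' @param struct_elem structuring element for denoising.
#' @return data.frame with one row per slice.
#' @export
cohort_reference_stats <- function(cohort, n_sd = 5, struct_elem = "square3") {
  stopifnot(inherits(cohort, "phantom_cohort"))
  rows <- lapply(cohort$slices, function(s) {
    ref <- build_reference(s, n_sd = n_sd, struct_elem = struct_elem)
    a_myo <- tissue_area(ref$myo, ref$pixel_mm)
    a_scar <- tissue_area(ref$scar, ref$pixel_mm)
    data.frame(volume_id = s$volume_id, slice_id = s$slice_id,
               myo_area_mm2 = a_myo, ref_scar_area_mm2 = a_scar,
               ref_scar_frac = if (a_myo > 0) a_scar / a_myo else NA_real_,
               ref_scar_free = a_scar == 0)
  })
  do.call(rbind, rows)
}
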