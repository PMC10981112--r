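#' k-space grid description for resolution degradation
#'
#' @param matrix pixels per side (square matrix).
#' @param fov_mm field of view (mm); pixel spacing is `fov_mm / matrix`.
#' @param native_dx_mm acquisition (native) resolution; defaults to the
#'   pixel spacing, matching an acquisition at 0.7 mm on a 128 matrix.
#' @return a `resolution_spec` list with `pixel_mm` derived.
#' @export
resolution_spec <- function(matrix = 128, fov_mm = matrix * 0.7,
                            native_dx_mm = fov_mm / matrix) {
  if (matrix <= 0 || fov_mm <= 0) .stopf("matrix and fov_mm must be positive")
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 pixel_mm = fov_mm / matrix, native_dx_mm = native_dx_mm),
            class = "resolution_spec")
}

# centred k-space sample coordinates (cycles/mm); DC at index matrix/2 + 1
.kgrid <- function(spec) {
  M <- spec$matrix
  ((seq_len(M) - 1) - M / 2) / spec$fov_mm
}

# centred isotropic Gaussian low-pass with unit DC gain, as an M x M matrix
.gauss_filter <- function(sigma_k, spec) {
  k <- .kgrid(spec)
  g <- exp(-k^2 / (2 * sigma_k^2))
  outer(g, g)
}

# swap quadrants: centred <-> DFT order (even sizes, so shift = inverse shift)
.fftshift2 <- function(m) {
  h <- nrow(m) / 2; w <- ncol(m) / 2
  m[c((h + 1):nrow(m), 1:h), c((w + 1):ncol(m), 1:w)]
}

#' Measure the PSF full-width-at-half-maximum of a k-space filter
#'
#' The PSF is the inverse Fourier transform of the filter on a zero-padded
#' grid (padding factor >= 8 for sub-pixel accuracy). The FWHM is read off
#' the central row profile of the PSF magnitude through its peak, with
#' linear interpolation of the half-maximum crossings, and returned in mm.
#'
#' @param filter centred k-space filter, `matrix x matrix`.
#' @param spec a [resolution_spec()] describing the grid the filter lives on.
#' @param pad_factor zero-padding factor (default 8).
#' @return FWHM in mm.
#' @export
measure_psf_fwhm <- function(filter, spec, pad_factor = 8) {
  M <- spec$matrix
  if (!all(dim(filter) == c(M, M))) .stopf("filter does not match the spec grid")
  P <- M * pad_factor
  big <- base::matrix(0 + 0i, P, P)
  lo <- P / 2 - M / 2 + 1
  big[lo:(lo + M - 1), lo:(lo + M - 1)] <- filter
  psf <- .fftshift2(fft(.fftshift2(big), inverse = TRUE))
  mag <- Mod(psf)
  peak <- unname(which(mag == max(mag), arr.ind = TRUE)[1, ])
  profile <- mag[peak[1], ]
  half <- profile[peak[2]] / 2
  # grid spacing of the padded image: FOV is unchanged, sampling is denser
  dgrid <- spec$fov_mm / P

  right <- .half_crossing(profile, peak[2], half, +1L)
  left <- .half_crossing(profile, peak[2], half, -1L)
  if (is.na(left) || is.na(right))
    .stopf("PSF half-maximum not bracketed within the padded FOV")
  (right + left) * dgrid
}

# distance (in grid samples) from `center` to the half-maximum crossing in
# direction dir (+1/-1), linearly interpolated
.half_crossing <- function(profile, center, half, dir) {
  n <- length(profile)
  i <- center
  repeat {
    j <- i + dir
    if (j < 1 || j > n) return(NA_real_)
    if (profile[j] <= half) {
      f <- (profile[i] - half) / (profile[i] - profile[j])
      return(abs(i - center) + f)
    }
    i <- j
  }
}

#' Calibrate a Gaussian k-space low-pass to a target effective resolution
#'
#' Effective resolution is defined as the FWHM of the PSF obtained by inverse
#' Fourier transform of the Gaussian low-pass. Because the filter is truncated
#' at the sampled k-space edge, the continuous-Gaussian closed form
#' (FWHM = sqrt(2 log 2) / (pi * sigma_k)) only seeds a monotone bisection on
#' `sigma_k`; the returned design is verified by [measure_psf_fwhm()].
#' A target equal to the native resolution returns an identity design
#' (no filtering), mirroring the treatment of the acquisition resolution as
#' the unfiltered original.
#'
#' @param target_dx_mm requested effective resolution (mm); must be >= native.
#' @param spec a [resolution_spec()].
#' @param tol relative calibration tolerance (default 1%); bisection itself
#'   converges to 10 times tighter than `tol`.
#' @return a `filter_design`: `sigma_k`, `target_dx_mm`, `measured_fwhm_mm`,
#'   `is_identity`, `filter` (centred matrix), and the `spec`.
#' @export
calibrate_filter <- function(target_dx_mm, spec, tol = 0.01) {
  stopifnot(inherits(spec, "resolution_spec"))
  if (target_dx_mm < spec$native_dx_mm - 1e-12)
    .stopf("cannot sharpen: target %.3f mm below native %.3f mm", target_dx_mm, spec$native_dx_mm)
  if (abs(target_dx_mm - spec$native_dx_mm) < 1e-12) {
    return(structure(list(sigma_k = Inf, target_dx_mm = target_dx_mm,
                          measured_fwhm_mm = target_dx_mm, is_identity = TRUE,
                          filter = base::matrix(1, spec$matrix, spec$matrix), spec = spec),
                     class = "filter_design"))
  }
  sigma0 <- sqrt(2 * log(2)) / (pi * target_dx_mm)
  lo <- sigma0 / 8; hi <- sigma0 * 8
  f <- function(s) measure_psf_fwhm(.gauss_filter(s, spec), spec) - target_dx_mm
  flo <- f(lo); fhi <- f(hi)
  # FWHM decreases as sigma_k grows: f(lo) > 0 > f(hi) required
  if (flo < 0 || fhi > 0)
    .stopf("target %.3f mm not bracketed (truncation-limited range [%.3f, %.3f] mm)",
           target_dx_mm, fhi + target_dx_mm, flo + target_dx_mm)
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (abs(fm) / target_dx_mm < tol / 10) {
      lo <- hi <- mid
      break
    }
    if (fm > 0) lo <- mid else hi <- mid
  }
  sigma <- sqrt(lo * hi)
  filt <- .gauss_filter(sigma, spec)
  measured <- measure_psf_fwhm(filt, spec)
  if (abs(measured - target_dx_mm) / target_dx_mm > tol)
    .stopf("calibration did not converge: measured %.4f mm vs target %.4f mm", measured, target_dx_mm)
  structure(list(sigma_k = sigma, target_dx_mm = target_dx_mm,
                 measured_fwhm_mm = measured, is_identity = FALSE,
                 filter = filt, spec = spec),
            class = "filter_design")
}

#' @export
print.filter_design <- function(x, ...) {
  cat(sprintf("filter_design: target %.3f mm, measured FWHM %.4f mm%s\n",
              x$target_dx_mm, x$measured_fwhm_mm,
              if (x$is_identity) " (identity)" else sprintf(", sigma_k %.4f cyc/mm", x$sigma_k)))
  invisible(x)
}

#' Apply a calibrated k-space low-pass to a complex image
#'
#' Forward FFT, pointwise multiplication with the centred filter, inverse
#' FFT; FOV and matrix size are unchanged. Unit DC gain preserves the complex
#' mean of the image to floating tolerance. Identity designs return the input
#' untouched.
#'
#' @param image complex (or numeric) matrix matching the design's grid.
#' @param design a `filter_design` from [calibrate_filter()].
#' @return complex matrix of the same shape.
#' @export
apply_lowpass <- function(image, design) {
  stopifnot(inherits(design, "filter_design"))
  M <- design$spec$matrix
  if (!all(dim(image) == c(M, M))) .stopf("image shape does not match the filter design")
  if (any(!is.finite(Re(image))) || any(!is.finite(Im(image)))) .stopf("non-finite input image")
  if (design$is_identity) return(image + 0i)
  F <- fft(image)
  Ff <- F * .fftshift2(design$filter)
  fft(Ff, inverse = TRUE) / length(Ff)
}

#' Degrade a phantom slice to a lower effective resolution
#'
#' Low-pass filters the complex image while leaving all masks (and the remote
#' ROI) untouched: reference masks live at native resolution and are reused
#' for every degraded copy. The effective resolution is recorded in `dx_mm`.
#'
#' @param slice a `phantom_slice` at native resolution.
#' @param target_dx_mm requested effective resolution (mm).
#' @param design optional pre-calibrated `filter_design` (avoids repeated
#'   calibration in sweeps); must match `target_dx_mm`.
#' @return the degraded `phantom_slice`.
#' @export
degrade_slice <- function(slice, target_dx_mm, design = NULL) {
  stopifnot(inherits(slice, "phantom_slice"))
  M <- nrow(slice$image)
  if (is.null(design)) {
    spec <- resolution_spec(matrix = M, fov_mm = M * slice$pixel_mm,
                            native_dx_mm = slice$pixel_mm)
    design <- calibrate_filter(target_dx_mm, spec)
  } else if (abs(design$target_dx_mm - target_dx_mm) > 1e-9) {
    .stopf("supplied design targets %.3f mm, not %.3f mm", design$target_dx_mm, target_dx_mm)
  }
  slice$image <- apply_lowpass(slice$image, design)
  slice$dx_mm <- target_dx_mm
  slice
}

# per-session cache of calibrated designs keyed by (matrix, fov, native, dx)
.design_cache <- new.env(parent = emptyenv())

#' Calibrated filter designs for a set of resolutions, cached per grid
#'
#' @param dxs vector of target resolutions (mm).
#' @param spec a [resolution_spec()].
#' @return named list of `filter_design` objects keyed by resolution.
#' @export
filter_bank <- function(dxs, spec) {
  out <- list()
  for (dx in dxs) {
    key <- sprintf("%d|%.6f|%.6f|%.6f", spec$matrix, spec$fov_mm, spec$native_dx_mm, dx)
    if (is.null(.design_cache[[key]]))
      .design_cache[[key]] <- calibrate_filter(dx, spec)
    out[[sprintf("%.1f", dx)]] <- .design_cache[[key]]
  }
  out
}
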