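spec64 <- resolution_spec(matrix = 64, fov_mm = 64 * 0.7)

test_that("FWHM measurement matches the continuous-Gaussian closed form", {
  # wide PSF (narrow k-space Gaussian): truncation negligible, closed form
  # FWHM = sqrt(2 log 2) / (pi sigma_k) applies
  spec <- resolution_spec(matrix = 128, fov_mm = 128 * 0.7)
  for (target in c(2.8, 4)) {
    sigma <- sqrt(2 * log(2)) / (pi * target)
    k <- ((seq_len(128) - 1) - 64) / spec$fov_mm
    g <- exp(-k^2 / (2 * sigma^2))
    expect_equal(measure_psf_fwhm(outer(g, g), spec), target, tolerance = 0.01)
  }
})

test_that("identity (all-ones) filter has the sinc mainlobe FWHM", {
  # rect truncation window: |sinc| mainlobe FWHM = 1.2067 pixels
  f <- measure_psf_fwhm(base::matrix(1, 64, 64), spec64)
  expect_equal(f / spec64$pixel_mm, 1.2067, tolerance = 0.01)
})

test_that("narrower k-space Gaussian gives strictly wider PSF", {
  f1 <- measure_psf_fwhm(scarres:::.gauss_filter(0.2, spec64), spec64)
  f2 <- measure_psf_fwhm(scarres:::.gauss_filter(0.1, spec64), spec64)
  expect_gt(f2, f1)
})

test_that("filter calibration hits its target within tolerance", {
  for (dx in c(1.1, 1.7)) {
    d <- calibrate_filter(dx, spec64)
    expect_lt(abs(d$measured_fwhm_mm - dx) / dx, 0.01)
    expect_false(d$is_identity)
    # unit DC gain at k = 0
    expect_equal(d$filter[33, 33], 1)
  }
  expect_true(calibrate_filter(0.7, spec64)$is_identity)
  expect_error(calibrate_filter(0.5, spec64), "sharpen")
})

test_that("apply_lowpass: identity, DC gain, linearity, energy, shape errors", {
  set.seed(1)
  M <- 64
  x <- base::matrix(complex(real = rnorm(M^2), imaginary = rnorm(M^2)), M, M)
  y <- base::matrix(complex(real = rnorm(M^2), imaginary = rnorm(M^2)), M, M)
  id <- calibrate_filter(0.7, spec64)
  expect_equal(apply_lowpass(x, id), x)
  d <- calibrate_filter(1.3, spec64)
  # constant image: only the DC component, filter gain 1
  cimg <- base::matrix(3 + 2i, M, M)
  expect_equal(apply_lowpass(cimg, d), cimg, tolerance = 1e-12)
  # complex mean preserved (unit DC gain)
  expect_equal(mean(apply_lowpass(x, d)), mean(x), tolerance = 1e-10)
  # linearity
  lhs <- apply_lowpass(2 * x + (1 - 1i) * y, d)
  rhs <- 2 * apply_lowpass(x, d) + (1 - 1i) * apply_lowpass(y, d)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # energy never increases (filter magnitude <= 1)
  expect_lte(sum(Mod(apply_lowpass(x, d))^2), sum(Mod(x)^2))
  expect_error(apply_lowpass(x[1:32, 1:32], d), "shape")
  x[1, 1] <- NaN
  expect_error(apply_lowpass(x, d), "finite")
})

test_that("filtering equals spatial-domain circular convolution with the PSF", {
  set.seed(2)
  M <- 32
  spec <- resolution_spec(matrix = M, fov_mm = M * 0.7)
  d <- calibrate_filter(1.5, spec)
  x <- base::matrix(complex(real = rnorm(M^2), imaginary = rnorm(M^2)), M, M)
  got <- apply_lowpass(x, d)
  # oracle: PSF from the (DFT-ordered) filter, then explicit circular
  # convolution by shift-and-accumulate in the spatial domain
  psf <- fft(scarres:::.fftshift2(d$filter), inverse = TRUE) / M^2
  ora <- base::matrix(0 + 0i, M, M)
  for (p in 0:(M - 1)) for (q in 0:(M - 1)) {
    if (Mod(psf[p + 1, q + 1]) < 1e-300) next
    rows <- ((seq_len(M) - 1 + p) %% M) + 1
    cols <- ((seq_len(M) - 1 + q) %% M) + 1
    ora[rows, cols] <- ora[rows, cols] + x * psf[p + 1, q + 1]
  }
  expect_lt(max(Mod(got - ora)) / max(Mod(ora)), 1e-10)
})

test_that("degrade_slice filters the image only and records metadata", {
  s <- one_slice(scar_frac = 0.25, noise_sd = 0)
  s17 <- degrade_slice(s, 1.7)
  expect_identical(s17$gt_myo, s$gt_myo)
  expect_identical(s17$gt_scar, s$gt_scar)
  expect_identical(s17$remote_roi, s$remote_roi)
  expect_equal(s17$dx_mm, 1.7)
  expect_equal(dim(s17$image), dim(s$image))
  s07 <- degrade_slice(s, 0.7)
  expect_equal(s07$image, s$image + 0i)

  # edge widening: 10-90% width of the scar-to-remote step grows with blur
  edge_width <- function(sl) {
    mag <- Mod(sl$image)
    # profile along the row through the scar centroid
    ij <- which(s$gt_scar, arr.ind = TRUE)
    r <- round(mean(ij[, 1]))
    prof <- mag[r, ]
    rng <- range(prof)
    sum(prof > rng[1] + 0.1 * diff(rng) & prof < rng[1] + 0.9 * diff(rng))
  }
  expect_gt(edge_width(s17), edge_width(s))
})

test_that("the seven-resolution sweep leaves shape and FOV constant", {
  s <- one_slice(scar_frac = 0.2)
  for (dx in c(0.7, 0.9, 1.1, 1.2, 1.3, 1.5, 1.7)) {
    out <- degrade_slice(s, dx)
    expect_equal(dim(out$image), c(64, 64))
    expect_equal(out$pixel_mm, 0.7)
  }
})
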