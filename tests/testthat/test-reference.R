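test_that("remote statistics: forced arithmetic and error cases", {
  img <- base::matrix(0, 4, 4)
  roi <- base::matrix(FALSE, 4, 4)
  roi[1:2] <- TRUE
  img[1] <- 1; img[2] <- 3
  st <- remote_statistics(img, roi)
  expect_equal(st$mu_remote, 2)
  expect_equal(st$sigma_remote, sqrt(2))      # sample SD
  expect_equal(st$n_pixels, 2L)

  img[1:2] <- 1
  st2 <- remote_statistics(img, roi)
  expect_equal(st2$mu_remote, 1)
  expect_equal(st2$sigma_remote, 0)

  expect_error(remote_statistics(img, base::matrix(FALSE, 4, 4)), "2 pixels")
  roi1 <- base::matrix(FALSE, 4, 4); roi1[1] <- TRUE
  expect_error(remote_statistics(img, roi1), "2 pixels")
})

test_that("SD threshold follows tau = mu + n * sigma with default n = 5", {
  st <- structure(list(mu_remote = 1, sigma_remote = 0.1, n_pixels = 10L),
                  class = "remote_stats")
  expect_equal(sd_threshold(st)$n_sd, 5)
  expect_equal(sd_threshold(st)$tau, 1.5)
  st0 <- structure(list(mu_remote = 2, sigma_remote = 0, n_pixels = 10L),
                   class = "remote_stats")
  expect_equal(sd_threshold(st0, 3)$tau, 2)
  expect_error(sd_threshold(st, -1), ">= 0")
})

test_that("scar thresholding is strict and restricted to the myocardium", {
  img <- base::matrix(1, 4, 4)
  myo <- base::matrix(TRUE, 4, 4)
  expect_equal(sum(threshold_scar(img, myo, 1)), 0)       # ties go to healthy
  expect_equal(sum(threshold_scar(img, myo, 0.5)), 16)
  myo[1, ] <- FALSE
  expect_equal(sum(threshold_scar(img, myo, 0.5)), 12)
  expect_error(threshold_scar(img, myo[1:2, ], 0.5), "mismatch")
})

test_that("morphological denoising removes isolated pixels, keeps adjacent ones", {
  m <- base::matrix(FALSE, 12, 12)
  m[2, 2] <- TRUE                              # isolated pixel
  expect_equal(sum(denoise_mask(m)), 0)

  blk <- base::matrix(FALSE, 12, 12)
  blk[5:7, 5:7] <- TRUE                        # 3x3 block survives opening
  blk[8, 6] <- TRUE                            # 4-adjacent pixel: re-included
  out <- denoise_mask(blk)
  expect_true(all(out[5:7, 5:7]))
  expect_true(out[8, 6])
  expect_equal(sum(out), 10)

  empty <- base::matrix(FALSE, 5, 5)
  expect_equal(sum(denoise_mask(empty)), 0)
})

test_that("denoising is idempotent on block-shaped masks and is a subset", {
  set.seed(9)
  for (i in 1:20) {
    m <- base::matrix(FALSE, 24, 24)
    for (b in 1:3) {
      r <- sample(1:18, 1); c <- sample(1:18, 1)
      m[r:(r + sample(3:6, 1)), c:(c + sample(3:6, 1))] <- TRUE
    }
    d1 <- denoise_mask(m)
    expect_true(all(m[d1]))                    # subset of the input
    expect_identical(denoise_mask(d1), d1)     # idempotent once isolated px gone
  }
})

test_that("raising n_sd never increases scar area", {
  s <- one_slice(scar_frac = 0.2, noise_sd = 0.1)
  mag <- Mod(s$image)
  st <- remote_statistics(mag, s$remote_roi)
  areas <- sapply(1:8, function(n) sum(threshold_scar(mag, s$gt_myo, sd_threshold(st, n))))
  expect_true(all(diff(areas) <= 0))
})

test_that("build_reference recovers ground truth on noise-free slices", {
  s0 <- one_slice(scar_frac = 0, noise_sd = 0)
  expect_equal(sum(build_reference(s0)$scar), 0)
  s <- one_slice(scar_frac = 0.25, noise_sd = 0)
  ref <- build_reference(s)
  expect_gte(dice(ref$scar, s$gt_scar), 0.95)
  # composition invariant
  expect_true(all(ref$scar_raw[ref$scar]))
  expect_true(all(ref$myo[ref$scar_raw]))
})

test_that("scar subset chain holds across a noisy cohort", {
  refs <- small_refs()
  for (r in refs) {
    expect_true(all(r$scar_raw[r$scar]))
    expect_true(all(r$myo[r$scar_raw]))
  }
})

test_that("low SNR biases SD5 towards underestimation", {
  cfg_lo <- small_phantom_config(seed = 3, noise_sd = 0.02)
  cfg_hi <- small_phantom_config(seed = 3, noise_sd = 0.15)
  set.seed(3)
  vp <- sample_volume_params(cfg_lo, 1L)
  area <- function(cfg, r) {
    set.seed(1000 + r)
    s <- generate_slice(cfg, vp, 1L, scar_frac = 0.2)
    sum(build_reference(s)$scar)
  }
  lo <- sapply(1:100, function(r) area(cfg_lo, r))
  hi <- sapply(1:100, function(r) area(cfg_hi, r))
  expect_lt(mean(hi), mean(lo))
})

test_that("RG overlay encodes healthy green and scar red", {
  s <- one_slice(scar_frac = 0.25, noise_sd = 0)
  ref <- build_reference(s)
  rg <- rg_overlay(ref)
  expect_equal(dim(rg), c(64, 64, 3))
  expect_true(all(rg[, , 1][ref$scar] == 1))
  expect_true(all(rg[, , 2][ref$myo & !ref$scar] == 1))
  expect_equal(sum(rg[, , 3]), 0)
})
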