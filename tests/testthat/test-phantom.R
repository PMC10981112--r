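test_that("cohort generation is deterministic and serialization is byte-identical", {
  cfg <- small_phantom_config(n_volumes = 2, slices_per_volume = c(2, 2), seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize_cohort(a), serialize_cohort(b))
  # a different seed changes the images
  cfg2 <- small_phantom_config(n_volumes = 2, slices_per_volume = c(2, 2), seed = 43)
  c <- generate_cohort(cfg2)
  expect_false(identical(a$slices[[1]]$image, c$slices[[1]]$image))
})

test_that("mask invariants hold across a large slice sample", {
  cohort <- default_cohort()
  expect_gte(length(cohort$slices), 1000)
  for (s in cohort$slices) {
    expect_true(all(dim(s$gt_myo) == dim(s$image)))
    expect_true(all(s$gt_scar[s$gt_scar] & s$gt_myo[s$gt_scar]))   # scar within myo
    expect_true(all(s$gt_myo[s$remote_roi]))                       # remote within myo
    expect_false(any(s$remote_roi & s$gt_scar))                    # disjoint from scar
    expect_gte(sum(s$remote_roi), 2)
  }
})

test_that("cohort moments recover the configured targets", {
  s <- default_cohort_summary()
  cfg <- default_cohort()$config
  expect_gte(s$n_slices, 500)
  expect_lt(abs(s$myo_area_mean - cfg$myo_area_mean_mm2) / cfg$myo_area_mean_mm2, 0.05)
  expect_lt(abs(s$scar_free_prop - cfg$p_scar_free), 0.05)
  # scar fraction mean close to target; SD order-of-magnitude right
  expect_lt(abs(s$scar_frac_mean - cfg$scar_frac_mean), 0.02)
  expect_gt(s$scar_frac_sd, 0.05)
  expect_lte(max(s$per_slice$scar_frac, na.rm = TRUE), cfg$scar_frac_max + 0.02)
})

test_that("two cohorts with different seeds share moments but not images", {
  build <- function(seed) cohort_summary(generate_cohort(
    small_phantom_config(n_volumes = 18, slices_per_volume = c(28, 28), seed = seed)))
  s1 <- build(101); s2 <- build(102)
  expect_gte(s1$n_slices, 500)
  expect_lt(abs(s1$myo_area_mean - s2$myo_area_mean) / s1$myo_area_mean, 0.1)
  expect_lt(abs(s1$scar_free_prop - s2$scar_free_prop), 0.1)
})

test_that("minimal cohort and degenerate scar inputs behave", {
  cfg <- small_phantom_config(n_volumes = 1, slices_per_volume = c(1, 1), seed = 1)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$slices, 1)

  s0 <- one_slice(scar_frac = 0)            # forced scar-free
  expect_equal(sum(s0$gt_scar), 0)

  sc <- one_slice(scar_frac = 0.2, noise_sd = 0)
  expect_gt(sum(sc$gt_scar), 0)
})

test_that("infeasible geometry errors out", {
  cfg <- small_phantom_config(seed = 1)
  set.seed(1)
  vp <- sample_volume_params(cfg, 1L)
  # scar sector spanning nearly the full ring leaves no remote ROI
  expect_error(generate_slice(cfg, vp, 1L, scar_frac = 0.95), "remote ROI|room")
  # a wall thicker than the half-FOV cannot fit any annulus
  big <- phantom_config(n_volumes = 1, slices_per_volume = c(1, 1), matrix = 64,
                        myo_area_mean_mm2 = 420, myo_area_sd_mm2 = 1,
                        wall_mm = c(50, 50), seed = 1)
  set.seed(2)
  vpb <- sample_volume_params(big, 1L)
  expect_error(generate_slice(big, vpb, 1L), "FOV")
})

test_that("complex noise model: exact at zero noise, Rician second moment otherwise", {
  s0 <- one_slice(scar_frac = 0.2, noise_sd = 0)
  cfg <- small_phantom_config(seed = 3, noise_sd = 0)
  # noiseless magnitude inside the remote ROI equals the configured level
  # (the smooth phase does not change the magnitude)
  expect_lt(max(abs(Mod(s0$image[s0$remote_roi]) - cfg$intensity["myo"])), 1e-9)
  sn <- one_slice(scar_frac = 0.2, noise_sd = 0.05)
  # E|S + n|^2 = |S|^2 + 2 sigma^2 for complex Gaussian noise
  m2 <- mean(Mod(sn$image[sn$remote_roi])^2)
  expect_equal(m2, 0.2^2 + 2 * 0.05^2, tolerance = 0.1)
})

test_that("cohort_summary applies the pixel-count area rule", {
  sl <- toy_slice(n_myo = 2000, pixel_mm = 0.7)
  cohort <- structure(list(slices = list(sl), config = phantom_config(
    n_volumes = 1, slices_per_volume = c(1, 1))), class = "phantom_cohort")
  s <- cohort_summary(cohort)
  expect_equal(s$per_slice$myo_area_mm2, 2000 * 0.49)
  expect_equal(s$scar_frac_mean, 0)
  expect_equal(s$scar_free_prop, 1)
})

test_that("HDF5 export writes a readable file", {
  skip_if_not_installed("rhdf5")
  cohort <- generate_cohort(small_phantom_config(n_volumes = 1,
                                                 slices_per_volume = c(2, 2)))
  path <- tempfile(fileext = ".h5")
  write_cohort_h5(cohort, path)
  expect_true(file.exists(path))
  re <- rhdf5::h5read(path, "/vol001/slice001_re")
  expect_equal(re, Re(cohort$slices[[1]]$image))
  rhdf5::h5closeAll()
})
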