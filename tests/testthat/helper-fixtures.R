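# Shared fixtures, built once per test run and cached in an environment so
# expensive cohorts (the 36-volume default) are generated a single time.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small-heart phantom world: 64x64 at native 0.7 mm, used wherever the full
# 128 matrix is not the point (keeps network tests fast)
small_phantom_config <- function(n_volumes = 4, slices_per_volume = c(3, 3),
                                 seed = 7, ...) {
  phantom_config(n_volumes = n_volumes, slices_per_volume = slices_per_volume,
                 matrix = 64, myo_area_mean_mm2 = 420, myo_area_sd_mm2 = 100,
                 wall_mm = c(5, 7), seed = seed, ...)
}

default_cohort <- function() {
  fixture("default_cohort", function() generate_cohort(phantom_config()))
}

default_cohort_summary <- function() {
  fixture("default_cohort_summary", function() cohort_summary(default_cohort()))
}

small_cohort <- function() {
  fixture("small_cohort", function() generate_cohort(small_phantom_config(
    n_volumes = 6, slices_per_volume = c(4, 4), seed = 7)))
}

small_refs <- function() {
  fixture("small_refs", function() lapply(small_cohort()$slices, build_reference))
}

# one deterministic native slice with a guaranteed scar sector
one_slice <- function(scar_frac = 0.2, noise_sd = 0.02, seed = 3, matrix = 64) {
  cfg <- if (matrix == 64) small_phantom_config(seed = seed, noise_sd = noise_sd)
  else phantom_config(seed = seed, noise_sd = noise_sd)
  set.seed(seed)
  vp <- sample_volume_params(cfg, 1L)
  generate_slice(cfg, vp, 1L, scar_frac = scar_frac)
}

# hand-built minimal phantom_slice for metric plumbing tests
toy_slice <- function(n_myo = 2000, matrix = 128, pixel_mm = 0.7) {
  myo <- base::matrix(FALSE, matrix, matrix)
  myo[seq_len(n_myo)] <- TRUE
  remote <- base::matrix(FALSE, matrix, matrix)
  remote[1:2] <- TRUE
  structure(list(image = base::matrix(0 + 0i, matrix, matrix), gt_myo = myo,
                 gt_scar = base::matrix(FALSE, matrix, matrix),
                 remote_roi = remote, pixel_mm = pixel_mm, dx_mm = pixel_mm,
                 volume_id = 1L, slice_id = 1L),
            class = "phantom_slice")
}
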