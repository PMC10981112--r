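#' Configuration for the synthetic short-axis LGE phantom cohort
#'
#' Defines the stated world the generator emulates: a cohort of short-axis
#' late-gadolinium-enhancement-like 2D slices with an annular left-ventricular
#' myocardium, hyperenhanced scar sectors, a remote healthy-tissue ROI, bright
#' blood pool, and complex Gaussian noise (Rician magnitude). Defaults follow
#' the cohort statistics of the post-mortem porcine study being emulated:
#' 36 volumes, 128x128 matrix at 0.7 mm in-plane, mean (SD) myocardial area
#' 1136 (349) mm^2, scar 5% (9%) of myocardium up to 53%, and ~30% scar-free
#' slices.
#'
#' @param n_volumes number of volumes (subjects).
#' @param slices_per_volume integer range `c(min, max)`; per-volume slice
#'   counts are drawn uniformly from it. The default gives ~2050 slices over
#'   36 volumes, the scale of the emulated cohort.
#' @param matrix image matrix size (pixels per side, square).
#' @param pixel_mm in-plane pixel spacing at native resolution (mm).
#' @param myo_area_mean_mm2,myo_area_sd_mm2 target cohort moments of per-slice
#'   myocardial area (mm^2).
#' @param scar_frac_mean,scar_frac_sd target cohort moments of the per-slice
#'   scar fraction of myocardial area (fractions, not percent).
#' @param scar_frac_min,scar_frac_max truncation bounds of the conditional
#'   scar-fraction distribution given scar is present. The lower bound keeps
#'   present scars wide enough (>= 3 px) to survive the 3x3 morphological
#'   opening used for reference masks.
#' @param p_scar_free probability that a slice carries no scar.
#' @param intensity named magnitudes (arbitrary units) for
#'   `background`, `blood`, `myo` (remote myocardium) and `scar`.
#'   Scar must exceed remote myocardium.
#' @param noise_sd standard deviation of the complex Gaussian noise added
#'   independently to real and imaginary channels.
#' @param wall_mm wall-thickness range (mm) at the cohort mean area; scaled
#'   with sqrt(area) per volume so large hearts keep plausible rings.
#' @param remote_width_deg angular width of the remote ROI sector (degrees).
#' @param subendo_prob probability a volume's scar is subendocardial rather
#'   than transmural.
#' @param subendo_depth transmural depth fraction of subendocardial scar.
#' @param p_large_infarct probability a volume belongs to the large-infarct
#'   severity class (the emulated cohort had scar extending up to ~53% of
#'   myocardium in ~10% of subjects).
#' @param large_scar_mean conditional mean slice scar fraction in
#'   large-infarct volumes.
#' @param seed RNG seed used by [generate_cohort()].
#'
#' @return a `phantom_config` list with the derived calibration of the
#'   conditional scar-fraction distribution attached.
#' @export
#' @examples
#' cfg <- phantom_config(n_volumes = 2, slices_per_volume = c(3, 3))
#' cohort <- generate_cohort(cfg)
#' length(cohort$slices)
phantom_config <- function(n_volumes = 36,
                           slices_per_volume = c(50, 64),
                           matrix = 128,
                           pixel_mm = 0.7,
                           myo_area_mean_mm2 = 1136,
                           myo_area_sd_mm2 = 349,
                           scar_frac_mean = 0.05,
                           scar_frac_sd = 0.09,
                           scar_frac_min = 0.02,
                           scar_frac_max = 0.53,
                           p_scar_free = 0.30,
                           intensity = c(background = 0.05, blood = 0.80,
                                         myo = 0.20, scar = 1.00),
                           noise_sd = 0.02,
                           wall_mm = c(7, 11),
                           remote_width_deg = 40,
                           subendo_prob = 0.4,
                           subendo_depth = 0.6,
                           p_large_infarct = 0.10,
                           large_scar_mean = 0.30,
                           seed = 1L) {
  if (length(slices_per_volume) == 1) slices_per_volume <- rep(slices_per_volume, 2)
  if (matrix <= 0 || matrix %% 2 != 0) .stopf("matrix must be a positive even integer")
  if (pixel_mm <= 0) .stopf("pixel_mm must be > 0")
  if (p_scar_free < 0 || p_scar_free > 1) .stopf("p_scar_free must lie in [0, 1]")
  need <- c("background", "blood", "myo", "scar")
  if (!all(need %in% names(intensity))) .stopf("intensity must name %s", paste(need, collapse = ", "))
  if (intensity["scar"] <= intensity["myo"]) .stopf("scar intensity must exceed remote myocardium intensity")
  if (n_volumes < 1 || any(slices_per_volume < 1)) .stopf("need at least one volume and slice")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")

  cfg <- list(
    n_volumes = as.integer(n_volumes),
    slices_per_volume = as.integer(slices_per_volume),
    matrix = as.integer(matrix),
    pixel_mm = pixel_mm,
    fov_mm = matrix * pixel_mm,
    myo_area_mean_mm2 = myo_area_mean_mm2,
    myo_area_sd_mm2 = myo_area_sd_mm2,
    scar_frac_mean = scar_frac_mean,
    scar_frac_sd = scar_frac_sd,
    scar_frac_min = scar_frac_min,
    scar_frac_max = scar_frac_max,
    p_scar_free = p_scar_free,
    intensity = intensity,
    noise_sd = noise_sd,
    wall_mm = wall_mm,
    remote_width_deg = remote_width_deg,
    subendo_prob = subendo_prob,
    subendo_depth = subendo_depth,
    p_large_infarct = p_large_infarct,
    large_scar_mean = large_scar_mean,
    seed = as.integer(seed)
  )
  cfg$scar_model <- .calibrate_scar_model(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

# Mean of LN(mu, sigma) truncated to (a, b)
.trunc_lnorm_mean <- function(mu, sigma, a, b) {
  la <- (log(a) - mu) / sigma
  lb <- (log(b) - mu) / sigma
  z <- pnorm(lb) - pnorm(la)
  exp(mu + sigma^2 / 2) * (pnorm(lb - sigma) - pnorm(la - sigma)) / z
}

# Conditional (scar-present) slice fraction model: a two-component severity
# mixture at volume level. A small share of volumes (p_large_infarct) are
# "large infarcts" whose slice fractions centre on large_scar_mean (reaching
# the ~53% cap); the remaining volumes carry ordinary infarcts whose meanlog
# is solved so that the cohort mean scar fraction hits its configured target:
#   E[f] = (1 - p_scar_free) * (p_L * m_L + (1 - p_L) * m_S).
.calibrate_scar_model <- function(cfg) {
  a <- cfg$scar_frac_min; b <- cfg$scar_frac_max
  none <- list(p_large = 0, a = a, b = b,
               small = list(meanlog = NA_real_, sdlog = 0.9, a = a, b = b),
               large = list(meanlog = NA_real_, sdlog = 0.5, a = a, b = b))
  if (cfg$p_scar_free >= 1 || cfg$scar_frac_mean <= 0) return(none)
  target <- cfg$scar_frac_mean / (1 - cfg$p_scar_free)
  if (target <= a || target >= b)
    .stopf("conditional scar fraction target %.3f outside truncation bounds (%.3f, %.3f)",
           target, a, b)
  solve_mu <- function(m, s) uniroot(function(mu) .trunc_lnorm_mean(mu, s, a, b) - m,
                                     lower = log(a) - 2.5 * s, upper = log(b) + 2.5 * s,
                                     tol = 1e-10)$root
  p_l <- cfg$p_large_infarct
  m_l <- cfg$large_scar_mean
  m_s <- (target - p_l * m_l) / (1 - p_l)
  if (p_l <= 0 || m_s <= 1.05 * a || m_l >= b) {  # degenerate mixture: single component
    p_l <- 0
    m_s <- target
  }
  out <- list(p_large = p_l, a = a, b = b,
              small = list(meanlog = solve_mu(m_s, 0.9), sdlog = 0.9, a = a, b = b))
  out$large <- if (p_l > 0)
    list(meanlog = solve_mu(m_l, 0.5), sdlog = 0.5, a = a, b = b)
  else out$small
  out
}

# inverse-CDF draw from the truncated lognormal (uses current RNG stream)
.r_trunc_lnorm <- function(n, ln) {
  pa <- pnorm((log(ln$a) - ln$meanlog) / ln$sdlog)
  pb <- pnorm((log(ln$b) - ln$meanlog) / ln$sdlog)
  u <- runif(n, pa, pb)
  exp(ln$meanlog + ln$sdlog * qnorm(u))
}

#' Sample per-volume geometry for the phantom generator
#'
#' Draws the anatomy shared by all slices of one volume: base myocardial
#' area, wall thickness, ring centre, low-order boundary perturbation,
#' scar sector direction/type and the axial window of slices that carry
#' scar. Uses the current RNG stream.
#'
#' @param config a [phantom_config()].
#' @param volume_id integer identifier.
#' @return a `volume_params` list consumed by [generate_slice()].
#' @export
sample_volume_params <- function(config, volume_id = 1L) {
  n_slices <- if (config$slices_per_volume[1] == config$slices_per_volume[2])
    config$slices_per_volume[1]
  else sample(seq(config$slices_per_volume[1], config$slices_per_volume[2]), 1)

  sd_b <- 0.8 * config$myo_area_sd_mm2      # between-volume share of area SD
  mu <- config$myo_area_mean_mm2
  area_vol <- .clamp(rnorm(1, mu, sd_b), 0.35 * mu, mu + 3.5 * config$myo_area_sd_mm2)
  wall <- runif(1, config$wall_mm[1], config$wall_mm[2]) * sqrt(area_vol / mu)

  # scar-bearing axial window: expectation of scar-free slices = p_scar_free
  len <- round((1 - config$p_scar_free) * n_slices)
  start <- if (len >= n_slices || len == 0) 1L else sample(seq_len(n_slices - len + 1), 1)
  list(
    volume_id = as.integer(volume_id),
    n_slices = as.integer(n_slices),
    area_vol = area_vol,
    wall = wall,
    center = rnorm(2, 0, 1.2),                       # mm jitter of ring centre
    pert_amp = rnorm(3, 0, 0.4),                     # boundary Fourier orders 2:4, mm
    pert_phase = runif(3, 0, 2 * pi),
    scar_theta0 = runif(1, 0, 2 * pi),
    subendo = runif(1) < config$subendo_prob,
    large_infarct = runif(1) < config$scar_model$p_large,
    scar_window = c(start, start + max(len, 0) - 1L)
  )
}

#' Generate one phantom slice
#'
#' Rasterises a perturbed-annulus myocardium with optional angular scar
#' sector, places a remote ROI opposite the scar, applies a smooth low-order
#' polynomial phase and adds complex Gaussian noise (so the magnitude is
#' Rician). Randomness is taken from the current RNG stream; seed it for
#' reproducibility (as [generate_cohort()] does).
#'
#' @param config a [phantom_config()].
#' @param volume_params output of [sample_volume_params()].
#' @param slice_id slice index within the volume (drives the area profile
#'   and whether the slice lies in the scar-bearing window).
#' @param scar_frac optional override of the scar fraction of myocardial
#'   area for this slice; `0` forces a scar-free slice. Default `NULL`
#'   draws from the calibrated truncated-lognormal model.
#' @return a `phantom_slice`: complex `image`, logical `gt_myo`, `gt_scar`,
#'   `remote_roi`, plus `pixel_mm`, effective-resolution metadata `dx_mm`,
#'   `volume_id`, `slice_id`.
#' @export
generate_slice <- function(config, volume_params, slice_id = 1L, scar_frac = NULL) {
  vp <- volume_params
  M <- config$matrix
  px <- config$pixel_mm
  fov <- config$fov_mm

  sd_w <- 0.6 * config$myo_area_sd_mm2
  area <- .clamp(vp$area_vol + rnorm(1, 0, sd_w), 0.25 * config$myo_area_mean_mm2,
                 config$myo_area_mean_mm2 + 4 * config$myo_area_sd_mm2)
  wall <- vp$wall
  margin <- max(abs(vp$center)) + sum(abs(vp$pert_amp)) + 1
  r_out_max <- fov / 2 - margin
  area_max <- pi * wall * (2 * r_out_max - wall)   # largest annulus that fits
  if (area_max <= 0)
    .stopf("ring exceeds FOV: wall %.1f mm cannot fit inside half-FOV %.1f mm", wall, fov / 2)
  area <- min(area, area_max)                      # truncates the extreme right tail
  r_in <- (area / (pi * wall) - wall) / 2
  if (r_in < 2.5) {                                # apical slices: thin the wall to keep a lumen
    r_in <- 2.5
    wall <- -r_in + sqrt(r_in^2 + area / pi)
  }
  if (wall < 1) .stopf("slice geometry degenerate: wall %.2f mm too thin", wall)
  r_out <- r_in + wall
  if (r_out + margin > fov / 2 + 1e-9)
    .stopf("ring exceeds FOV: outer radius %.1f mm + margin %.1f mm > %.1f mm", r_out, margin, fov / 2)

  # pixel-centred coordinates (mm), 0-based indexing convention
  coord <- (seq_len(M) - 1 - M / 2 + 0.5) * px
  X <- base::matrix(coord, M, M, byrow = TRUE)
  Y <- base::matrix(coord, M, M)
  dxm <- X - vp$center[1]
  dym <- Y - vp$center[2]
  r <- sqrt(dxm^2 + dym^2)
  th <- atan2(dym, dxm)

  psi <- rnorm(1, 0, 0.1)                       # per-slice twist of the shape
  delta <- 0
  for (j in 1:3)
    delta <- delta + vp$pert_amp[j] * cos((j + 1) * (th + psi) + vp$pert_phase[j])
  rin_t <- r_in + delta
  rout_t <- r_out + delta

  gt_myo <- r >= rin_t & r < rout_t
  blood <- r < rin_t

  # scar sector
  in_window <- slice_id >= vp$scar_window[1] && slice_id <= vp$scar_window[2]
  if (is.null(scar_frac)) {
    comp <- if (isTRUE(vp$large_infarct)) config$scar_model$large else config$scar_model$small
    scar_frac <- if (in_window && !is.na(comp$meanlog)) .r_trunc_lnorm(1, comp) else 0
  }
  gt_scar <- base::matrix(FALSE, M, M)
  theta0 <- vp$scar_theta0 + rnorm(1, 0, 0.1)
  remote_halfw <- (config$remote_width_deg * pi / 180) / 2
  if (scar_frac > 0) {
    depth <- config$subendo_depth
    subendo <- vp$subendo
    # subendocardial scars whose radial extent would fall below ~3 px cannot
    # survive the 3x3 morphological opening of the reference pipeline; such
    # slices revert to transmural scar
    r_d0 <- sqrt(r_in^2 + depth * (r_out^2 - r_in^2))
    if (subendo && (r_d0 - r_in) < 3 * px) subendo <- FALSE
    alpha <- if (subendo) 2 * pi * scar_frac / depth else 2 * pi * scar_frac
    alpha_cap <- 2 * pi - 2 * remote_halfw - 0.5
    if (subendo && alpha > alpha_cap) {           # too wide: fall back to transmural
      subendo <- FALSE
      alpha <- 2 * pi * scar_frac
    }
    if (alpha > alpha_cap)
      .stopf("scar sector (%.2f rad) would leave no room for a remote ROI", alpha)
    # floor on the angular width so the arc spans >= ~4 px at the sector's
    # narrowest point (the inner radius); narrower scars cannot survive the
    # 3x3 opening of the reference pipeline up to a 1-px boundary ring
    alpha <- min(max(alpha, 4.2 * px / max(r_in, 1e-6)), alpha_cap)
    ad <- .angdiff(th, theta0)
    gt_scar <- gt_myo & ad <= alpha / 2
    if (subendo) {
      r_d <- sqrt(pmax(rin_t, 0)^2 + depth * (rout_t^2 - pmax(rin_t, 0)^2))
      gt_scar <- gt_scar & r <= r_d
    }
  }

  remote_roi <- gt_myo & !gt_scar & .angdiff(th, theta0 + pi) <= remote_halfw
  if (sum(remote_roi) < 2) .stopf("remote ROI empty or single-pixel; scar spans the ring")

  ii <- config$intensity
  mag <- base::matrix(ii["background"], M, M)
  mag[blood] <- ii["blood"]
  mag[gt_myo] <- ii["myo"]
  mag[gt_scar] <- ii["scar"]

  # smooth low-order polynomial phase over the FOV
  u <- X / fov; v <- Y / fov
  cph <- c(runif(1, -pi, pi), runif(2, -2, 2), runif(3, -1, 1))
  phase <- cph[1] + cph[2] * u + cph[3] * v + cph[4] * u^2 + cph[5] * v^2 + cph[6] * u * v
  img <- mag * exp(1i * phase)
  if (config$noise_sd > 0)
    img <- img + complex(real = rnorm(M * M, 0, config$noise_sd),
                         imaginary = rnorm(M * M, 0, config$noise_sd))

  structure(list(image = img, gt_myo = gt_myo, gt_scar = gt_scar,
                 remote_roi = remote_roi, pixel_mm = px, dx_mm = px,
                 volume_id = vp$volume_id, slice_id = as.integer(slice_id)),
            class = "phantom_slice")
}

.angdiff <- function(theta, theta0) {
  abs(((theta - theta0 + pi) %% (2 * pi)) - pi)
}

#' Generate a phantom cohort
#'
#' Seeds the RNG from `config$seed` (Mersenne-Twister / inversion, restoring
#' the caller's RNG state afterwards) and draws per-volume geometry followed
#' by per-slice phantoms, so identical configs yield byte-identical cohorts.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_cohort`: `slices` (list of `phantom_slice`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  slices <- list()
  for (v in seq_len(config$n_volumes)) {
    vp <- sample_volume_params(config, v)
    for (s in seq_len(vp$n_slices))
      slices[[length(slices) + 1L]] <- generate_slice(config, vp, s)
  }
  structure(list(slices = slices, config = config), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d slices over %d volumes, %dx%d @ %.2f mm\n",
              length(x$slices), x$config$n_volumes, x$config$matrix,
              x$config$matrix, x$config$pixel_mm))
  invisible(x)
}

#' Per-slice and cohort-level ground-truth statistics
#'
#' Myocardial area (mm^2, pixel count times pixel area), scar fraction of
#' myocardium and the proportion of scar-free slices, with cohort mean/SD of
#' each — the quantities used to check the generator against its configured
#' targets.
#'
#' @param cohort a `phantom_cohort`.
#' @return a list with `per_slice` (data.frame) and scalar summaries.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (length(cohort$slices) == 0) .stopf("empty cohort")
  rows <- lapply(cohort$slices, function(s) {
    a_myo <- tissue_area(s$gt_myo, s$pixel_mm)
    a_scar <- tissue_area(s$gt_scar, s$pixel_mm)
    data.frame(volume_id = s$volume_id, slice_id = s$slice_id,
               myo_area_mm2 = a_myo, scar_area_mm2 = a_scar,
               scar_frac = if (a_myo > 0) a_scar / a_myo else NA_real_,
               scar_free = a_scar == 0)
  })
  per_slice <- do.call(rbind, rows)
  list(per_slice = per_slice,
       myo_area_mean = mean(per_slice$myo_area_mm2),
       myo_area_sd = sd(per_slice$myo_area_mm2),
       scar_frac_mean = mean(per_slice$scar_frac),
       scar_frac_sd = sd(per_slice$scar_frac),
       scar_free_prop = mean(per_slice$scar_free),
       n_slices = nrow(per_slice))
}

#' Canonical text serialization of a cohort
#'
#' Produces a deterministic character vector (full double precision) so that
#' "same config + seed implies byte-identical cohort" can be checked and the
#' cohort stored as plain text if needed.
#'
#' @param cohort a `phantom_cohort`.
#' @return character vector of lines.
#' @export
serialize_cohort <- function(cohort) {
  cfg <- cohort$config
  hdr <- sprintf("scarres-cohort v1 seed=%d volumes=%d matrix=%d pixel=%.17g noise=%.17g",
                 cfg$seed, cfg$n_volumes, cfg$matrix, cfg$pixel_mm, cfg$noise_sd)
  out <- c(hdr)
  for (s in cohort$slices) {
    out <- c(out,
             sprintf("slice %d %d", s$volume_id, s$slice_id),
             paste(sprintf("%.17g", Re(s$image)), collapse = " "),
             paste(sprintf("%.17g", Im(s$image)), collapse = " "),
             paste(as.integer(s$gt_myo), collapse = ""),
             paste(as.integer(s$gt_scar), collapse = ""),
             paste(as.integer(s$remote_roi), collapse = ""))
  }
  out
}

#' Write / read a cohort as HDF5
#'
#' One group per volume; per slice the complex image is stored as two float
#' channels plus uint8 masks; pixel spacing and the generator seed are file
#' attributes. Requires the suggested `rhdf5` package.
#'
#' @param cohort a `phantom_cohort`.
#' @param path output `.h5` file.
#' @return `path`, invisibly.
#' @export
write_cohort_h5 <- function(cohort, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) .stopf("rhdf5 is required for HDF5 export")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(cohort$config$pixel_mm, fid, "pixel_mm")
  rhdf5::h5writeAttribute(cohort$config$seed, fid, "seed")
  for (s in cohort$slices) {
    g <- sprintf("/vol%03d", s$volume_id)
    if (!rhdf5::H5Lexists(fid, g)) rhdf5::h5createGroup(fid, g)
    base <- sprintf("%s/slice%03d_", g, s$slice_id)
    rhdf5::h5write(Re(s$image), fid, paste0(base, "re"))
    rhdf5::h5write(Im(s$image), fid, paste0(base, "im"))
    rhdf5::h5write(array(as.integer(s$gt_myo), dim(s$gt_myo)), fid, paste0(base, "myo"))
    rhdf5::h5write(array(as.integer(s$gt_scar), dim(s$gt_scar)), fid, paste0(base, "scar"))
    rhdf5::h5write(array(as.integer(s$remote_roi), dim(s$remote_roi)), fid, paste0(base, "remote"))
  }
  invisible(path)
}
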