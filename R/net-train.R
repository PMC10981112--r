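#' Training configuration for the scar segmentation network
#'
#' Mirrors the full-scale protocol (Adam 1e-3 with beta1 0.9 / beta2 0.999,
#' batch 16, multi-class Dice loss, 100 epochs, encoder depth 5 with decoder
#' channels 256...16) while defaulting to a desk-scale variant that trains in
#' seconds-to-minutes on one CPU. `train_resolutions_mm` is either a single
#' resolution or the full mixed-resolution set; with more than one entry a
#' fresh resolution is drawn per sample per epoch and the image degraded on
#' the fly.
#'
#' @param encoder_depth downsampling steps.
#' @param decoder_channels coarse-to-fine widths, length `encoder_depth`.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size training batch size.
#' @param epochs training epochs; 0 returns the initialised model unchanged.
#' @param train_resolutions_mm numeric vector of training resolutions (mm).
#' @param augment_params list of augmentation knobs: `elastic_grid` (control
#'   points per side), `elastic_sd_px` (displacement SD in pixels),
#'   `gamma_range` (intensity gamma), `noise_sd_max` (max added Gaussian
#'   noise after normalisation to the unit interval).
#' @param seed seed controlling initialisation, shuffling, augmentation and
#'   resolution draws.
#' @return a `train_config` list.
#' @export
train_config <- function(encoder_depth = 3,
                         decoder_channels = c(32, 16, 8),
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 16, epochs = 20,
                         train_resolutions_mm = 0.7,
                         augment_params = list(elastic_grid = 4,
                                               elastic_sd_px = 2,
                                               gamma_range = c(0.75, 1.35),
                                               noise_sd_max = 0.04),
                         seed = 1L) {
  if (length(decoder_channels) != encoder_depth)
    .stopf("decoder_channels must have length encoder_depth")
  if (lr <= 0) .stopf("lr must be > 0")
  if (length(train_resolutions_mm) == 0) .stopf("train_resolutions_mm must be nonempty")
  structure(list(encoder_depth = encoder_depth,
                 decoder_channels = decoder_channels,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss = "multiclass_dice",
                 train_resolutions_mm = train_resolutions_mm,
                 augment_params = augment_params,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Volume-wise cross-validation folds
#'
#' Shuffles volumes with the given seed and partitions them into `k`
#' near-equal test sets; every volume lands in exactly one test set and
#' slices always follow their volume (36 volumes at k = 5 gives test sizes
#' 8, 7, 7, 7, 7).
#'
#' @param x a `phantom_cohort` or a vector of volume ids.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @param strata optional vector of volume-level labels (named by volume id,
#'   or in the order of the sorted volume ids). When given, volumes are
#'   dealt into folds within each stratum, so rare classes (e.g. the few
#'   large-infarct volumes) are spread across folds instead of landing in a
#'   single test set — the usual stratified-CV practice for small cohorts.
#' @return list of `fold_split` objects (`fold_id`, `train_volume_ids`,
#'   `test_volume_ids`).
#' @export
make_folds <- function(x, k = 5, seed = 1L, strata = NULL) {
  vols <- if (inherits(x, "phantom_cohort"))
    sort(unique(vapply(x$slices, `[[`, 0L, "volume_id")))
  else sort(unique(as.integer(x)))
  n <- length(vols)
  if (n < k) .stopf("need at least k = %d volumes, got %d", k, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  if (is.null(strata)) {
    perm <- sample(vols)
    sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    tests <- lapply(seq_len(k), function(i) perm[starts[i]:stops[i]])
  } else {
    if (length(strata) != n) .stopf("strata must label every volume")
    if (!is.null(names(strata))) strata <- strata[as.character(vols)]
    # shuffle within stratum, then deal volumes to folds cyclically so each
    # fold receives its share of every class
    perm <- unlist(lapply(split(vols, strata),
                          function(v) if (length(v) > 1) sample(v) else v),
                   use.names = FALSE)
    tests <- split(perm, rep_len(seq_len(k), n))
  }
  lapply(seq_len(k), function(i) {
    test <- sort(tests[[i]])
    structure(list(fold_id = i, train_volume_ids = setdiff(vols, test),
                   test_volume_ids = test),
              class = "fold_split")
  })
}

#' Preprocess a magnitude image for the network
#'
#' Crops to a square window centred at the LV (identity for inputs already
#' at the target size) and min-max normalises to `[0, 1]` per image; the
#' identical normalisation is applied at train and test time. A constant
#' image maps to all zeros with a warning.
#'
#' @param image 2D numeric magnitude image.
#' @param size target side length; default `nrow(image)` (no crop).
#' @param center LV centre as `c(row, col)`; default the image centre.
#'   For phantoms the ground-truth myocardium centroid is used upstream.
#' @return list with `image` (normalised crop) and the crop index ranges
#'   `rows`, `cols` (so masks can be cropped identically).
#' @export
preprocess <- function(image, size = nrow(image), center = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (size > H || size > W) .stopf("crop size exceeds image")
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  start <- round(center) - size %/% 2
  start <- c(.clamp(start[1], 0, H - size), .clamp(start[2], 0, W - size))
  rows <- start[1] + seq_len(size)
  cols <- start[2] + seq_len(size)
  crop <- image[rows, cols, drop = FALSE]
  rng <- range(crop)
  if (rng[2] == rng[1]) {
    warning("constant image: normalised output is all zeros")
    crop[] <- 0
  } else {
    crop <- (crop - rng[1]) / (rng[2] - rng[1])
  }
  list(image = crop, rows = rows, cols = cols)
}

#' Draw a training resolution
#'
#' Uniform draw from the configured set (a singleton set yields
#' single-resolution training). Uses the current RNG stream.
#'
#' @param train_resolutions_mm nonempty numeric vector.
#' @return one resolution (mm).
#' @export
sample_resolution <- function(train_resolutions_mm) {
  if (length(train_resolutions_mm) == 0) .stopf("empty resolution set")
  if (length(train_resolutions_mm) == 1) return(train_resolutions_mm)
  train_resolutions_mm[sample.int(length(train_resolutions_mm), 1)]
}

# bilinear interpolation basis from g control points to n grid positions
.lin_basis <- function(n, g) {
  pos <- seq(1, n, length.out = g)
  A <- base::matrix(0, n, g)
  for (r in seq_len(n)) {
    j <- findInterval(r, pos, rightmost.closed = TRUE)
    j <- min(j, g - 1)
    w <- (r - pos[j]) / (pos[j + 1] - pos[j])
    A[r, j] <- 1 - w
    A[r, j + 1] <- w
  }
  A
}

# backward-warp an image by per-pixel displacements (bilinear; clamped)
.warp_bilinear <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  Rm <- base::matrix(seq_len(H), H, W) + dy
  Cm <- base::matrix(seq_len(W), H, W, byrow = TRUE) + dx
  Rm <- .clamp(Rm, 1, H); Cm <- .clamp(Cm, 1, W)
  r0 <- pmin(floor(Rm), H - 1); c0 <- pmin(floor(Cm), W - 1)
  fr <- Rm - r0; fc <- Cm - c0
  idx <- function(r, c) (c - 1) * H + r
  img[idx(r0, c0)] * (1 - fr) * (1 - fc) +
    img[idx(r0 + 1, c0)] * fr * (1 - fc) +
    img[idx(r0, c0 + 1)] * (1 - fr) * fc +
    img[idx(r0 + 1, c0 + 1)] * fr * fc
}

.warp_nearest <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  Rm <- .clamp(round(base::matrix(seq_len(H), H, W) + dy), 1, H)
  Cm <- .clamp(round(base::matrix(seq_len(W), H, W, byrow = TRUE) + dx), 1, W)
  out <- img[(Cm - 1) * H + Rm]
  base::matrix(out, H, W)
}

#' Randomly augment an image/mask training pair
#'
#' Elastic deformation from a random coarse displacement grid (applied
#' identically to image and mask, bilinear for the image and
#' nearest-neighbour for the mask so no new labels appear), followed by an
#' intensity gamma transform and added Gaussian noise on the image only.
#' Draws from the current RNG stream.
#'
#' @param sample list with `image` (numeric matrix, `[0,1]`-normalised) and
#'   `mask` (integer label matrix).
#' @param params augmentation knobs; see [train_config()]. A zero
#'   `elastic_sd_px` yields an identity geometric transform.
#' @return augmented `list(image, mask)`.
#' @export
augment <- function(sample, params = train_config()$augment_params) {
  img <- sample$image; mask <- sample$mask
  H <- nrow(img); W <- ncol(img)
  g <- params$elastic_grid
  sdpx <- params$elastic_sd_px
  if (sdpx > 0) {
    A <- .lin_basis(H, g); B <- .lin_basis(W, g)
    dx <- A %*% base::matrix(rnorm(g * g, 0, sdpx), g, g) %*% t(B)
    dy <- A %*% base::matrix(rnorm(g * g, 0, sdpx), g, g) %*% t(B)
    img <- .warp_bilinear(img, dx, dy)
    mask <- .warp_nearest(mask, dx, dy)
  }
  gam <- runif(1, params$gamma_range[1], params$gamma_range[2])
  img <- pmax(img, 0)^gam
  nsd <- runif(1, 0, params$noise_sd_max)
  if (nsd > 0) img <- img + base::matrix(rnorm(H * W, 0, nsd), H, W)
  list(image = img, mask = mask)
}

# 3-class label raster from reference labels:
# 0 background (incl. blood pool), 1 healthy myocardium, 2 scar
.ref_labels_raster <- function(ref) {
  lab <- base::matrix(0L, nrow(ref$myo), ncol(ref$myo))
  lab[ref$myo] <- 1L
  lab[ref$scar] <- 2L
  lab
}

.onehot <- function(lab, K = 3) {
  out <- array(0, c(nrow(lab), ncol(lab), K))
  for (k in seq_len(K)) out[, , k] <- (lab == (k - 1)) * 1
  out
}

#' Train the scar segmentation network
#'
#' Per epoch and sample: draw a training resolution (multi-resolution
#' training degrades the complex image on the fly through the calibrated
#' k-space low-pass), take the magnitude, min-max normalise, augment, and
#' optimise the multi-class Dice loss with Adam. Deterministic given the
#' config seed (single-threaded).
#'
#' @param slices list of native-resolution `phantom_slice` objects.
#' @param refs matching list of `reference_labels` (the 3-class training
#'   labels are rasterised from them).
#' @param config a [train_config()].
#' @param verbose print per-epoch loss.
#' @return a trained `scar_net` with `$log` (per-epoch loss and soft Dice
#'   per class) and `$res_draws` (resolutions drawn during training).
#' @export
train_network <- function(slices, refs, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(slices) < 1) .stopf("need at least one training slice")
  if (length(slices) != length(refs)) .stopf("slices and refs must align")

  native <- slices[[1]]$pixel_mm
  M <- nrow(slices[[1]]$image)
  spec <- resolution_spec(matrix = M, fov_mm = M * native, native_dx_mm = native)
  res_set <- config$train_resolutions_mm
  if (any(res_set < native - 1e-9)) .stopf("training resolutions below native")
  designs <- filter_bank(res_set, spec)

  labs <- lapply(refs, .ref_labels_raster)
  present <- sort(unique(unlist(lapply(labs, unique))))
  if (length(present) < 3)
    warning("not all 3 classes present in the training labels; Dice smoothing keeps the loss defined")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  model <- unet_init(in_channels = 1, n_classes = 3,
                     encoder_depth = config$encoder_depth,
                     decoder_channels = config$decoder_channels,
                     seed = sample.int(2^31 - 1, 1))
  # head bias at log class priors: keeps the rare scar class alive under the
  # Dice loss instead of being crushed to zero probability early in training
  prior <- tabulate(unlist(labs) + 1L, nbins = 3)
  prior <- pmax(prior / sum(prior), 1e-4)
  model$params$head$b <- log(prior)
  model$config <- config
  if (config$epochs == 0) {
    model$log <- data.frame(epoch = integer(), loss = numeric())
    model$res_draws <- numeric()
    return(model)
  }

  st <- .adam_init(model$params)
  n <- length(slices)
  log_rows <- vector("list", config$epochs)
  res_draws <- numeric(0)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_dice <- c(0, 0, 0); nb <- 0
    for (bstart in seq(1, n, by = config$batch_size)) {
      bidx <- ord[bstart:min(bstart + config$batch_size - 1, n)]
      probs <- onehots <- caches <- vector("list", length(bidx))
      for (j in seq_along(bidx)) {
        i <- bidx[j]
        dx <- sample_resolution(res_set)
        res_draws <- c(res_draws, dx)
        img <- slices[[i]]$image
        dsn <- designs[[sprintf("%.1f", dx)]]
        if (!dsn$is_identity) img <- apply_lowpass(img, dsn)
        pre <- preprocess(Mod(img))
        aug <- augment(list(image = pre$image, mask = labs[[i]]),
                       config$augment_params)
        fw <- .unet_forward(model, aug$image, want_cache = TRUE)
        probs[[j]] <- fw$probs
        onehots[[j]] <- .onehot(aug$mask)
        caches[[j]] <- fw$cache
      }
      dl <- .dice_loss_batch(probs, onehots)
      grads <- NULL
      for (j in seq_along(bidx)) {
        dz <- .softmax_bwd(probs[[j]], dl$dprobs[[j]])
        grads <- .grad_add(grads, .unet_backward(model, caches[[j]], dz))
      }
      upd <- .adam_step(model$params, grads, st, config$lr, config$beta1, config$beta2)
      model$params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + dl$loss
      ep_dice <- ep_dice + dl$dice
      nb <- nb + 1
    }
    log_rows[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb,
                                 dice_bg = ep_dice[1] / nb,
                                 dice_myo = ep_dice[2] / nb,
                                 dice_scar = ep_dice[3] / nb)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  soft-dice scar %.3f",
                      ep, ep_loss / nb, ep_dice[3] / nb))
  }
  model$log <- do.call(rbind, log_rows)
  model$res_draws <- res_draws
  model
}

# --- dihedral group helpers (square inputs) ---------------------------------

.rot90m <- function(m) {                 # 90 degrees counter-clockwise
  mt <- t(m)
  mt[rev(seq_len(nrow(mt))), , drop = FALSE]
}

.dihedral_mat <- function(m, k, flip) {
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  k <- k %% 4
  while (k > 0) { m <- .rot90m(m); k <- k - 1 }
  m
}

.dihedral_inv_mat <- function(m, k, flip) {
  kk <- (4 - k %% 4) %% 4
  while (kk > 0) { m <- .rot90m(m); kk <- kk - 1 }
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

.dihedral_arr <- function(a, k, flip, inverse = FALSE) {
  f <- if (inverse) .dihedral_inv_mat else .dihedral_mat
  out <- NULL
  for (c in seq_len(dim(a)[3])) {
    m <- f(a[, , c], k, flip)
    if (is.null(out)) out <- array(0, c(dim(m), dim(a)[3]))
    out[, , c] <- m
  }
  out
}

#' Predict class probabilities for one image (no TTA)
#'
#' @param model a trained `scar_net`.
#' @param image preprocessed (normalised) square magnitude image.
#' @return `(H, W, 3)` array of class probabilities.
#' @export
predict_probs <- function(model, image) {
  .unet_forward(model, image)$probs
}

#' Predict with 8-fold dihedral test-time augmentation
#'
#' The input is transformed by the 8 elements of the dihedral group (4
#' right-angle rotations composed with an optional horizontal flip; vertical
#' flips arise as rotation-flip compositions), each copy is predicted, each
#' prediction is mapped back through the inverse transform, and the
#' probability maps are averaged. The label mask is the per-pixel argmax;
#' the predicted scar mask is then denoised with the same morphological
#' operations as the reference masks (removed scar pixels revert to healthy
#' myocardium).
#'
#' @param model a trained `scar_net`.
#' @param image preprocessed square magnitude image.
#' @param postprocess apply the reference-style morphological denoising to
#'   the predicted scar (default TRUE).
#' @param struct_elem structuring element for the denoising.
#' @return a `slice_prediction`: `prob_maps` (H, W, 3), `label_mask`
#'   (integers 0/1/2), `myo_mask` (myocardium incl. scar), `scar_mask`.
#' @export
predict_tta <- function(model, image, postprocess = TRUE, struct_elem = "square3") {
  acc <- NULL
  for (flip in c(FALSE, TRUE)) {
    for (k in 0:3) {
      tin <- .dihedral_mat(image, k, flip)
      pr <- .unet_forward(model, tin)$probs
      pr <- .dihedral_arr(pr, k, flip, inverse = TRUE)
      acc <- if (is.null(acc)) pr else acc + pr
    }
  }
  prob <- acc / 8
  lab <- apply(prob, c(1, 2), which.max) - 1L
  scar <- lab == 2L
  if (postprocess) {
    kept <- denoise_mask(scar, struct_elem)
    lab[scar & !kept] <- 1L
    scar <- kept
  }
  structure(list(prob_maps = prob, label_mask = lab,
                 myo_mask = lab >= 1L, scar_mask = scar),
            class = "slice_prediction")
}
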