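test_that("volume-wise folds partition 36 volumes into 8,7,7,7,7", {
  folds <- make_folds(1:36, k = 5, seed = 2)
  sizes <- sort(vapply(folds, function(f) length(f$test_volume_ids), 0L),
                decreasing = TRUE)
  expect_equal(sizes, c(8L, 7L, 7L, 7L, 7L))
  tests <- unlist(lapply(folds, `[[`, "test_volume_ids"))
  expect_equal(sort(tests), 1:36)               # each volume in exactly one test set
  for (f in folds) {
    expect_length(intersect(f$train_volume_ids, f$test_volume_ids), 0)
    expect_equal(sort(c(f$train_volume_ids, f$test_volume_ids)), 1:36)
  }
  expect_error(make_folds(1:4, k = 5), "at least")
})

test_that("preprocess crops around the centre and min-max normalises", {
  x <- base::matrix(runif(128 * 128), 128, 128)
  p <- preprocess(x)
  expect_equal(dim(p$image), c(128, 128))
  expect_equal(range(p$image), c(0, 1))

  big <- base::matrix(seq(0, 1, length.out = 192 * 192), 192, 192)
  pb <- preprocess(big, size = 128, center = c(96, 96))
  expect_equal(pb$rows, 33:160)
  expect_equal(pb$cols, 33:160)
  expect_equal(pb$image,
               (big[33:160, 33:160] - min(big[33:160, 33:160])) /
                 diff(range(big[33:160, 33:160])))

  y <- base::matrix(c(2, 10, 6, 2), 2, 2)
  expect_equal(preprocess(y)$image[1, 2], 0.5)   # 6 maps to 0.5

  expect_warning(pz <- preprocess(base::matrix(1, 8, 8)), "constant")
  expect_true(all(pz$image == 0))
})

test_that("augmentation: identity limit, reproducibility, label preservation", {
  img <- base::matrix(runif(64 * 64), 64, 64)
  mask <- base::matrix(sample(0:2, 64 * 64, TRUE), 64, 64)
  idp <- list(elastic_grid = 4, elastic_sd_px = 0, gamma_range = c(1, 1),
              noise_sd_max = 0)
  out <- augment(list(image = img, mask = mask), idp)
  expect_equal(out$image, img)
  expect_identical(out$mask, mask)

  set.seed(5); a1 <- augment(list(image = img, mask = mask))
  set.seed(5); a2 <- augment(list(image = img, mask = mask))
  expect_identical(a1, a2)

  set.seed(6)
  for (i in 1:100) {
    a <- augment(list(image = img, mask = mask))
    expect_true(all(unique(as.vector(a$mask)) %in% unique(as.vector(mask))))
  }
})

test_that("resolution sampling is uniform over the configured set", {
  expect_equal(sample_resolution(1.2), 1.2)
  expect_error(sample_resolution(numeric(0)), "empty")
  set.seed(8)
  res <- c(0.7, 0.9, 1.1, 1.2, 1.3, 1.5, 1.7)
  draws <- replicate(7000, sample_resolution(res))
  tab <- table(factor(draws, levels = res))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("backprop matches finite differences on a tiny net", {
  set.seed(42)
  H <- 8
  img <- base::matrix(runif(H * H), H, H)
  lab <- base::matrix(sample(0:2, H * H, TRUE), H, H)
  model <- unet_init(encoder_depth = 2, decoder_channels = c(4, 3), seed = 7)
  fw <- scarres:::.unet_forward(model, img, want_cache = TRUE)
  oh <- scarres:::.onehot(lab)
  dl <- scarres:::.dice_loss_batch(list(fw$probs), list(oh))
  dz <- scarres:::.softmax_bwd(fw$probs, dl$dprobs[[1]])
  gr <- scarres:::.unet_backward(model, fw$cache, dz)
  lossfun <- function(m)
    scarres:::.dice_loss_batch(list(scarres:::.unet_forward(m, img)$probs), list(oh))$loss
  h <- 1e-6
  for (nm in c("enc1", "bott", "up2", "mer1", "head")) for (f in c("W", "b")) {
    for (i in sample(length(model$params[[nm]][[f]]), 3)) {
      mp <- model; mp$params[[nm]][[f]][i] <- mp$params[[nm]][[f]][i] + h
      mm <- model; mm$params[[nm]][[f]][i] <- mm$params[[nm]][[f]][i] - h
      num <- (lossfun(mp) - lossfun(mm)) / (2 * h)
      ana <- gr[[nm]][[paste0("d", f)]][i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
    }
  }
})

test_that("probabilities are a valid softmax field", {
  model <- unet_init(encoder_depth = 2, decoder_channels = c(6, 4), seed = 2)
  x <- base::matrix(runif(32 * 32), 32, 32)
  p <- predict_probs(model, x)
  expect_equal(dim(p), c(32, 32, 3))
  expect_equal(p[, , 1] + p[, , 2] + p[, , 3],
               base::matrix(1, 32, 32), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("TTA average is equivariant under the dihedral group", {
  model <- unet_init(encoder_depth = 2, decoder_channels = c(6, 4), seed = 3)
  x <- base::matrix(runif(32 * 32), 32, 32)
  base_pred <- predict_tta(model, x, postprocess = FALSE)$prob_maps
  rot <- scarres:::.rot90m(x)
  rot_pred <- predict_tta(model, rot, postprocess = FALSE)$prob_maps
  expect_equal(rot_pred, scarres:::.dihedral_arr(base_pred, 1, FALSE),
               tolerance = 1e-5)
  fl <- x[, rev(seq_len(ncol(x)))]
  fl_pred <- predict_tta(model, fl, postprocess = FALSE)$prob_maps
  expect_equal(fl_pred, scarres:::.dihedral_arr(base_pred, 0, TRUE),
               tolerance = 1e-5)
})

test_that("TTA of a constant-output model returns that constant", {
  model <- unet_init(encoder_depth = 2, decoder_channels = c(6, 4), seed = 4)
  for (nm in names(model$params)) model$params[[nm]]$W[] <- 0
  model$params$head$b <- c(2, 0, -2)
  x <- base::matrix(runif(16 * 16), 16, 16)
  pr <- predict_tta(model, x, postprocess = FALSE)$prob_maps
  expected <- exp(c(2, 0, -2)) / sum(exp(c(2, 0, -2)))
  for (k in 1:3)
    expect_equal(pr[, , k], base::matrix(expected[k], 16, 16), tolerance = 1e-12)
})

test_that("training is seeded-deterministic and epochs = 0 is a no-op", {
  cohort <- small_cohort()
  refs <- small_refs()
  idx <- 1:4
  tc <- train_config(encoder_depth = 2, decoder_channels = c(6, 4), epochs = 2,
                     batch_size = 2, seed = 21)
  m1 <- train_network(cohort$slices[idx], refs[idx], tc)
  m2 <- train_network(cohort$slices[idx], refs[idx], tc)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)

  tc0 <- train_config(encoder_depth = 2, decoder_channels = c(6, 4), epochs = 0, seed = 21)
  m0 <- train_network(cohort$slices[idx], refs[idx], tc0)
  init <- unet_init(encoder_depth = 2, decoder_channels = c(6, 4),
                    seed = m0$init_seed)
  expect_identical(m0$params$enc1$W, init$params$enc1$W)
  expect_equal(nrow(m0$log), 0)
})

test_that("a small network overfits a small phantom set", {
  cohort <- small_cohort()
  refs <- small_refs()
  tc <- train_config(encoder_depth = 2, decoder_channels = c(16, 8), epochs = 60,
                     batch_size = 4, lr = 2e-3, seed = 13)
  model <- train_network(cohort$slices, refs, tc)
  # loss decreases over training
  expect_lt(model$log$loss[5], model$log$loss[1])
  expect_lt(tail(model$log$loss, 1), 0.5 * model$log$loss[1])
  # training-set scar Dice on scar-bearing slices
  has_scar <- vapply(refs, function(r) sum(r$scar) > 0, TRUE)
  ds <- vapply(which(has_scar), function(i) {
    pre <- preprocess(Mod(cohort$slices[[i]]$image))
    dice(predict_tta(model, pre$image)$scar_mask, refs[[i]]$scar)
  }, 0)
  expect_gt(mean(ds), 0.7)
})
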