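#' Configuration of a train-resolution x test-resolution sweep
#'
#' @param phantom a [phantom_config()] for the cohort (or NULL when a cohort
#'   is passed to [run_sweep()] directly).
#' @param train a [train_config()] used as the base for every network; its
#'   `train_resolutions_mm` is overridden per training setting.
#' @param train_settings list of settings: a single resolution (mm) or the
#'   string `"mixed"` for the 7-resolution multi-resolution protocol.
#' @param test_resolutions_mm resolutions the test slices are degraded to.
#' @param mixed_set the resolution set used by `"mixed"` training; defaults
#'   to the canonical 7 resolutions 0.7-1.7 mm.
#' @param k_folds volume-wise cross-validation folds.
#' @param stratify_folds when TRUE, folds are stratified by volume severity
#'   (volumes containing a slice with reference scar fraction >= 0.2 form
#'   their own stratum). With very small cohorts this stops the few
#'   large-infarct volumes from all landing in one test set, which would
#'   confound the resolution effect with a severity-distribution shift.
#' @param use_folds fold indices actually trained (default all); training a
#'   subset keeps desk-scale runs cheap while the partition stays intact.
#' @param seeds one or more seeds; the whole sweep is repeated per seed.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(phantom = phantom_config(),
                         train = train_config(),
                         train_settings = list(0.7, 1.7, "mixed"),
                         test_resolutions_mm = c(0.7, 1.2, 1.7),
                         mixed_set = c(0.7, 0.9, 1.1, 1.2, 1.3, 1.5, 1.7),
                         k_folds = 5,
                         use_folds = NULL,
                         stratify_folds = FALSE,
                         seeds = 1L) {
  if (!is.null(phantom)) {
    if (any(test_resolutions_mm < phantom$pixel_mm - 1e-9))
      .stopf("test resolutions below native")
    if (k_folds > phantom$n_volumes)
      .stopf("more folds than volumes")
  }
  structure(list(phantom = phantom, train = train,
                 train_settings = train_settings,
                 test_resolutions_mm = test_resolutions_mm,
                 mixed_set = mixed_set, k_folds = as.integer(k_folds),
                 use_folds = use_folds, stratify_folds = isTRUE(stratify_folds),
                 seeds = as.integer(seeds)),
            class = "sweep_config")
}

#' Run the resolution sweep experiment
#'
#' Generates (or reuses) a phantom cohort, builds SD5 reference labels at
#' native resolution, constructs volume-wise folds, trains one network per
#' (seed, training setting, fold) and evaluates it with 8-fold TTA on every
#' test resolution; test slices are degraded from the stored native data at
#' evaluation time (never double-filtered). Per-slice signed errors and Dice
#' scores are computed against the native-resolution references, then
#' summarised as median/IQR per (training setting, test resolution).
#'
#' @param config a [sweep_config()].
#' @param cohort optional pre-generated `phantom_cohort`.
#' @param refs optional matching list of `reference_labels`.
#' @param verbose print progress.
#' @return a `sweep_result`: `per_slice` (data.frame), `summary`
#'   (data.frame of median/IQR per metric), `folds`, `config`.
#' @export
run_sweep <- function(config, cohort = NULL, refs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$phantom)
  if (is.null(refs)) refs <- lapply(cohort$slices, build_reference)
  vols <- vapply(cohort$slices, `[[`, 0L, "volume_id")
  strata <- NULL
  if (isTRUE(config$stratify_folds)) {
    frac <- vapply(seq_along(refs), function(i)
      sum(refs[[i]]$scar) / max(sum(refs[[i]]$myo), 1), 0)
    uvol <- sort(unique(vols))
    strata <- vapply(uvol, function(v) any(frac[vols == v] >= 0.2), TRUE)
    names(strata) <- uvol
  }
  folds <- make_folds(cohort, k = config$k_folds, seed = config$seeds[1],
                      strata = strata)
  use <- if (is.null(config$use_folds)) seq_along(folds) else config$use_folds

  native <- cohort$slices[[1]]$pixel_mm
  M <- nrow(cohort$slices[[1]]$image)
  spec <- resolution_spec(matrix = M, fov_mm = M * native, native_dx_mm = native)
  test_designs <- filter_bank(config$test_resolutions_mm, spec)

  rows <- list()
  for (seed in config$seeds) {
    for (ts in config$train_settings) {
      ts_label <- if (identical(ts, "mixed")) "mixed" else sprintf("%.1f", ts)
      res_set <- if (identical(ts, "mixed")) config$mixed_set else ts
      for (fi in use) {
        fold <- folds[[fi]]
        tr_idx <- which(vols %in% fold$train_volume_ids)
        te_idx <- which(vols %in% fold$test_volume_ids)
        tcfg <- config$train
        tcfg$train_resolutions_mm <- res_set
        tcfg$seed <- as.integer((seed * 1000003L + fi * 101L) %% (2^31 - 1))
        if (verbose)
          message(sprintf("seed %d / train %s / fold %d: training on %d slices",
                          seed, ts_label, fi, length(tr_idx)))
        model <- train_network(cohort$slices[tr_idx], refs[tr_idx], tcfg)
        for (dx in config$test_resolutions_mm) {
          dsn <- test_designs[[sprintf("%.1f", dx)]]
          for (i in te_idx) {
            s <- cohort$slices[[i]]
            img <- if (dsn$is_identity) s$image else apply_lowpass(s$image, dsn)
            pre <- preprocess(Mod(img))
            pred <- predict_tta(model, pre$image)
            err <- slice_errors(pred$myo_mask, pred$scar_mask, refs[[i]])
            rows[[length(rows) + 1L]] <- data.frame(
              seed = seed, train_setting = ts_label, fold = fi,
              test_dx = dx, volume_id = s$volume_id, slice_id = s$slice_id,
              delta_myo = err$delta_myo, delta_scar = err$delta_scar,
              dice_myo = err$dice_myo, dice_scar = err$dice_scar)
          }
        }
      }
    }
  }
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 summary = .sweep_summary(per_slice),
                 folds = folds, config = config),
            class = "sweep_result")
}

.sweep_summary <- function(per_slice) {
  keys <- unique(per_slice[, c("seed", "train_setting", "test_dx")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    sub <- per_slice[per_slice$seed == keys$seed[r] &
                       per_slice$train_setting == keys$train_setting[r] &
                       per_slice$test_dx == keys$test_dx[r], ]
    row <- keys[r, ]
    for (m in c("delta_myo", "delta_scar", "dice_myo", "dice_scar")) {
      st <- summarize_errors(sub[[m]])
      row[[paste0(m, "_median")]] <- st$median
      row[[paste0(m, "_iqr")]] <- st$iqr
    }
    row$n <- nrow(sub)
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d per-slice rows, settings {%s}, test dx {%s}\n",
              nrow(x$per_slice),
              paste(unique(x$per_slice$train_setting), collapse = ", "),
              paste(unique(x$per_slice$test_dx), collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write summary tables and figures for a sweep result
#'
#' Emits (a) per-slice metrics and median/IQR tables of the signed errors
#' per (training setting, test resolution), (b) the matching Dice summaries,
#' (c) scar-error IQR versus test-resolution curves per training setting and
#' (d) the scar-error median/IQR aggregated over all test resolutions, as
#' CSV plus PNG. Missing grid cells are reported explicitly and flagged in
#' the return value.
#'
#' @param result a `sweep_result`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `files` and `missing_cells`.
#' @export
report_sweep <- function(result, outdir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ps <- result$per_slice
  sm <- result$summary
  files <- character(0)

  w <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  w(ps, "per_slice_metrics.csv")
  w(sm, "summary_by_train_test.csv")

  # grid completeness
  settings <- unique(vapply(result$config$train_settings,
                            function(t) if (identical(t, "mixed")) "mixed" else sprintf("%.1f", t), ""))
  grid <- expand.grid(train_setting = settings,
                      test_dx = result$config$test_resolutions_mm,
                      stringsAsFactors = FALSE)
  have <- paste(sm$train_setting, sm$test_dx)
  missing <- grid[!paste(grid$train_setting, grid$test_dx) %in% have, ]
  if (nrow(missing) > 0) {
    w(missing, "missing_cells.csv")
    warning(sprintf("%d sweep grid cells missing; see missing_cells.csv", nrow(missing)))
  }

  # scar-error IQR vs test resolution, one curve per training setting
  # (pooled over seeds by averaging their IQRs)
  curves <- aggregate(delta_scar_iqr ~ train_setting + test_dx, sm, mean)
  w(curves, "scar_iqr_curves.csv")

  # aggregated over all test resolutions, per training setting
  agg <- do.call(rbind, lapply(split(ps, ps$train_setting), function(sub) {
    st <- summarize_errors(sub$delta_scar)
    data.frame(train_setting = sub$train_setting[1], median = st$median,
               q1 = st$q1, q3 = st$q3, iqr = st$iqr, n = st$n)
  }))
  w(agg, "scar_error_pooled.csv")

  png_path <- file.path(outdir, "scar_iqr_curves.png")
  png(png_path, width = 800, height = 600)
  tab <- tryCatch({
    xs <- sort(unique(curves$test_dx))
    mat <- sapply(split(curves, curves$train_setting),
                  function(sub) sub$delta_scar_iqr[order(sub$test_dx)])
    matplot(xs, mat, type = "b", pch = 19, lty = 1,
            xlab = "test resolution dx [mm]", ylab = "scar error IQR [p.p.]",
            main = "Network precision vs test resolution")
    legend("topleft", legend = colnames(mat), col = seq_len(ncol(mat)),
           pch = 19, lty = 1, title = "train dx")
  }, error = function(e) NULL)
  dev.off()
  files <- c(files, png_path)

  png_path2 <- file.path(outdir, "scar_error_boxes.png")
  png(png_path2, width = 1000, height = 400)
  op <- par(mfrow = c(1, length(settings)))
  for (s in settings) {
    sub <- ps[ps$train_setting == s, ]
    boxplot(delta_scar ~ test_dx, sub, xlab = "test dx [mm]",
            ylab = "scar error [p.p.]", main = sprintf("train %s", s))
    abline(h = 0, lty = 2)
  }
  par(op)
  dev.off()
  files <- c(files, png_path2)

  invisible(list(files = files, missing_cells = missing))
}
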