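# scarres

Resolution robustness of neural-network myocardial scar segmentation in
late gadolinium enhancement (LGE) cardiac MRI — a fully synthetic,
end-to-end testable re-creation of the point-spread-function (PSF) mismatch
experiment.

## The scientific problem

LGE imaging makes infarcted myocardium hyperintense; scar burden is
quantified by segmenting the left-ventricular myocardium and thresholding
enhanced tissue at

τ = μ_remote + 5·σ_remote   ("SD5"),

with statistics taken over a remote, non-enhancing myocardial region.
U-Net segmenters automate this, but their training data fixes an implicit
*effective* in-plane resolution Δx — the full width at half maximum (FWHM)
of the imaging PSF — which can differ from the test data's even when
field-of-view and matrix size (the *apparent* resolution) are identical.
The package studies exactly that mismatch:

* k-space of a complex-valued slice is multiplied with a calibrated 2D
  Gaussian low-pass, degrading Δx from 0.7 mm up to 1.7 mm at constant
  128×128 matrix and FOV;
* SD5 reference masks (with morphological denoising) are built once, at
  native resolution, and reused for every test resolution;
* 3-class U-Nets (background / healthy myocardium / scar) are trained at
  Δx_train ∈ {0.7, 1.2, 1.7} mm or at a mix of 7 resolutions, with Dice
  loss, Adam, elastic/intensity/noise augmentation and 8-fold dihedral
  test-time augmentation, under volume-wise cross-validation;
* predictions are scored per slice by the signed myocardial area error
  ΔMYO = 100·(A_net − A_ref)/A_ref (%), the signed scar error
  ΔSCAR = 100·(A_net(SCAR) − A_ref(SCAR))/A_ref(MYO) (percentage points),
  and Dice (empty∧empty ≡ 1); distributions are summarised by median and
  IQR, the IQR being the indicator of network precision.

Because the original post-mortem porcine cohort is not public, the package
ships a phantom generator whose defaults emulate that cohort's statistics
(36 volumes ≈ 2050 slices, myocardial area 1136 ± 349 mm², scar 5 ± 9 % of
myocardium up to 53 %, ~30 % scar-free slices, Rician magnitude noise).
Everything downstream is tested against this known ground truth. The
neural network is implemented from first principles (C++ im2col
convolutions, hand-written backprop verified against finite differences)
since no deep-learning framework is assumed.

## Worked example

```r
library(scarres)

# an 8-volume small-heart cohort (64x64 @ 0.7 mm) with known ground truth
cfg <- phantom_config(n_volumes = 8, slices_per_volume = c(6, 6), matrix = 64,
                      myo_area_mean_mm2 = 420, myo_area_sd_mm2 = 100,
                      wall_mm = c(5, 7), p_large_infarct = 0, seed = 7)
cohort <- generate_cohort(cfg)
refs <- lapply(cohort$slices, build_reference)
stats <- cohort_reference_stats(cohort)
cat(sprintf("%d slices: mean SD5 scar %.1f%% of myocardium, %.0f%% scar-free\n",
            nrow(stats), 100 * mean(stats$ref_scar_frac),
            100 * mean(stats$ref_scar_free)))

# calibrate a 1.7 mm effective-resolution k-space low-pass
design <- calibrate_filter(1.7, resolution_spec(matrix = 64, fov_mm = 64 * 0.7))
print(design)

# train at native resolution on 6 volumes, test on the held-out 2
tc <- train_config(encoder_depth = 2, decoder_channels = c(16, 8),
                   epochs = 60, batch_size = 4, lr = 2e-3, seed = 1)
vols <- sapply(cohort$slices, `[[`, "volume_id")
train_idx <- which(vols <= 6); test_idx <- which(vols > 6)
model <- train_network(cohort$slices[train_idx], refs[train_idx], tc)

for (dx in c(0.7, 1.7)) {
  errs <- sapply(test_idx, function(i) {
    si <- degrade_slice(cohort$slices[[i]], dx)
    pred <- predict_tta(model, preprocess(Mod(si$image))$image)
    e <- slice_errors(pred$myo_mask, pred$scar_mask, refs[[i]])
    c(e$delta_scar, e$dice_scar)
  })
  st <- summarize_errors(errs[1, ])
  cat(sprintf("test dx %.1f mm: median dSCAR %+.2f p.p. (IQR %.2f), median scar Dice %.2f\n",
              dx, st$median, st$iqr, median(errs[2, ])))
}
```

Output (R 4.3, one CPU, ~3 min):

```
48 slices: mean SD5 scar 4.4% of myocardium, 33% scar-free
filter_design: target 1.700 mm, measured FWHM 1.7003 mm, sigma_k 0.2209 cyc/mm
test dx 0.7 mm: median dSCAR +0.66 p.p. (IQR 1.83), median scar Dice 0.96
test dx 1.7 mm: median dSCAR +0.00 p.p. (IQR 0.76), median scar Dice 0.93
```

Reading the numbers: the SD5 reference pipeline reports scar burden near
the generator's configured 5% with a third of slices scar-free; the
calibrated filter's PSF FWHM matches its 1.7 mm target to 0.02%; and the
trained network's held-out scar error sits near zero percentage points
with high Dice. A 12-slice held-out set is far too small to expose the
resolution-mismatch *trend* — that is what `run_sweep()` /
`report_sweep()` (full train-resolution x test-resolution grid over
cross-validation folds) and the criterion-6 acceptance test (three
replicated sweeps with majority voting) are for.

## Layout

* `R/phantom.R` — cohort generator (`phantom_config`, `generate_cohort`)
* `R/psf.R` — Gaussian k-space low-pass, PSF-FWHM calibration, degradation
* `R/reference.R` — remote statistics, SD5 threshold, morphology, references
* `R/net-layers.R`, `R/net-train.R`, `src/conv_ops.cpp` — the U-Net,
  training loop, TTA prediction
* `R/metrics.R` — areas, signed errors, Dice, median/IQR, KDE
* `R/sweep.R` — experiment runner and reporting
* `inst/cli/scarres.R` — command-line front end
  (`generate`, `degrade`, `reference`, `sweep`, `report`)
* `vignettes/resolution-robustness.Rmd` — model, assumptions, design notes

The worked-example numbers above and everything in the vignette are
produced by the package itself; no external data is required anywhere.
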