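# fluorograde

Virtual staining and Gleason grading for two-channel DRAQ5/Eosin
fluorescence microscopy of prostate tissue, as a tested, reusable R
package.

Fresh prostate specimens can be imaged without physical staining using a
confocal two-channel readout: **DRAQ5** (far-red DNA probe, nuclei) and
**Eosin** (fluorescence mode, cytoplasm/stroma). This package implements
the full analysis pipeline around that modality, for image-analysis
researchers who want to reproduce, stress-test or extend it:

* **Bidirectional virtual staining.** Fluorescence → brightfield H&E by
  per-pixel Beer–Lambert recoloring,
  `out_c = 255 · exp(−(OD_H[c]·d^γ_d + OD_E[c]·e^γ_e))` with γ > 1, and
  H&E → synthetic DRAQ5/Eosin (multi-Otsu nuclei masking, reversal with 0
  preserved, Gaussian noise of variance 1e-4, disk dilation, σ = 0.5
  smoothing, 12-bit scaling, z-normalization) for pretraining on H&E
  archives.
* **Deterministic preprocessing.** Sliding-paraboloid rolling-ball
  background subtraction (radius 50 px), CLAHE, exact multi-Otsu
  thresholding (dynamic program over 255-bin histograms), physical-size
  cropping (245.52 µm tiles; `edge_px = round(µm / pitch)`), nearest
  resizing, per-crop z-normalization.
* **Ground truth.** Epithelial gating, modal crop labels with the 15% /
  75% removal rules, 5% slide-level grade presence, low/high-grade task
  mappings and 3-class cancer segmentation targets.
* **Patient-atomic balanced folds.** 1000-permutation search minimizing the
  MSE of per-fold class ratios against 1.
* **Compact models.** A two-channel CNN classifier and 4/6-contraction
  U-Nets with the published augmentation schedule (3500 crops: 1000 flips,
  1500 rotations, 500 noise with variance ~ U(0, 0.5), 500 blur+noise with
  σ ~ U(0, 5)), Adam training with best-validation-epoch selection, and
  transfer-learning defaults. The training engine is BLAS-backed base R —
  no external deep-learning framework is required.
* **Metrics.** Dice, Jaccard, accuracy, Cohen kappa (unweighted and
  quadratic-weighted), Mann–Whitney ROC AUC.
* **Standardization harness.** Gradient-magnitude sharpness scoring and
  z-stack focus ranking, a parametric acquisition simulator (defocus blur,
  1/√averaging noise, resampling, lens PSF), hierarchical 64→32→16 px
  phase-correlation mask realignment, and per-condition robustness reports.
* **A seeded tissue phantom** (glands, lumens, nuclei rings, fused islands,
  nuclear sheets, per-region grade labels in both modalities) so every
  stage is testable without any external data.

## Worked example

```r
library(fluorograde)

cfg <- pipeline_config("desk", seed = 1)      # 24 phantom cores, 64-px inputs
art <- run_pipeline(cfg, stages = c("phantom", "crops", "folds",
                                    "train", "evaluate"))
length(art$kept)          # crops surviving the 15%/75% labeling rules
art$folds$mse             # balance score of the selected 5-fold split
art$metrics$HIGH_VS_HEALTHY
art$metrics$CANCER_SEG
```

One actual run of the above printed:

```
[1] 179
[1] 0.207476
MetricsReport [HIGH_VS_HEALTHY]  n=27  acc=1.0000  kappa=1.0000  auc=1.0000
MetricsReport [CANCER_SEG]  n=31  acc=0.9770  kappa=0.9597  dice(bg/healthy/cancer)=0.984/0.961/0.972
```

Reading: 179 of 216 phantom crops received a clean grade label; the chosen
patient-atomic split balances high-grade vs healthy crop counts to an MSE of
0.21 against perfectly even folds; the held-out fold's 27 classifier crops
are separated perfectly (the phantom's grade caricatures are deliberately
learnable), and the cancer-segmentation U-Net reaches per-class Dice of
0.98 / 0.96 / 0.97 (background / healthy / cancer) on 31 held-out crops.
These are sanity-floor results on synthetic tissue, not clinical estimates.

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/fluorograde demo --seed 1 --out runs/demo
```

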