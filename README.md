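# csfnet

Classification of feline ocular disease images with CSF-Net, an
attention-guided multi-color-space fusion network, implemented entirely in R.

## The problem

Common feline eye diseases — blepharitis, conjunctivitis, corneal
sequestrum, corneal ulcer, non-ulcerative keratitis — are visually similar
and are photographed under wildly varying illumination, which defeats plain
RGB classifiers. CSF-Net attacks both problems at once: each image *I* is
decomposed into three complementary color representations,

    I_RGB, I_HSV, I_YCbCr

(raw intensities; chroma decoupled from brightness; luma plus
color-difference channels), each is encoded by an independent
MobileNetV3-Small branch *f*(·),

    F_RGB = f(I_RGB),  F_HSV = f(I_HSV),  F_YCbCr = f(I_YCbCr),   F_* ∈ R^1024,

and the concatenation **F** = [F_RGB; F_HSV; F_YCbCr] ∈ R^3072 is refined by
single-head scaled dot-product self-attention

    Q = F W_q,  K = F W_k,  V = F W_v,
    Attention(Q, K, V) = softmax(QKᵀ / √d_k) V,      d_k = 3072,

before a fully connected head (3072 → 1024 → 512 → 6, batch-norm + ReLU +
dropout) produces class probabilities ŷ = softmax(f_MLP(F)). Training uses
inverse-frequency weighted cross-entropy

    L = −(1/N) Σ_n w_{y_n} log softmax(z_n)_{y_n},   w_c = N / (N_c · C),

stratified 5-fold cross-validation, Adam (lr 1e-4, batch 16, ≤ 50 epochs),
early stopping on validation loss (patience 10) and checkpoint selection on
validation macro-F1. Evaluation reports accuracy, macro precision / recall /
F1, one-vs-one macro-AUC, normalized confusion matrices and paired t-tests
across folds; Grad-CAM exposes the image regions behind each prediction.

Because no deep-learning framework is assumed, the package contains its own
small neural-network engine (im2col + BLAS convolutions, manual
backpropagation, Adam), a parameter-exact MobileNetV3-Small, ablation
variants (RGB-only, no-attention, SE / CBAM-channel / ECA / NAM gates), and
a reproducible synthetic eye-image generator so that the entire pipeline is
testable without any external dataset.

## Worked example

```r
library(csfnet)

spec <- synthetic_spec(n_per_class = 20, image_size = 64, seed = 7,
                       nuisance_strength = 0.5)
manifest <- generate_dataset(spec, "demo-data")
print(manifest)
#> Dataset manifest: 120 images, 6 classes
#>   Blepharitis                20
#>   Regular                    20
#>   ...

mconfig <- model_config(backbone = "tinycnn", feature_dim = 128,
                        head_hidden = c(128, 64), image_size = 64)
tconfig <- train_config(epochs_max = 4, batch_size = 16, lr = 1e-3,
                        patience = 4, seed = 7)
cv <- run_cross_validation(manifest, "csfnet", mconfig, tconfig, k = 2,
                           run_dir = "demo-run")
cv$aggregate
#>      metric      mean         sd       formatted
#> 1  accuracy 0.5666667 0.02357023 0.5667 ± 0.0236
#> 2 precision 0.6188129 0.08744485 0.6188 ± 0.0874
#> 3    recall 0.5666667 0.02357023 0.5667 ± 0.0236
#> 4        f1 0.5476022 0.02164759 0.5476 ± 0.0216
#> 5      mauc 0.8736667 0.02168461 0.8737 ± 0.0217
```

Four epochs on 60 training images already lift accuracy to 0.57 against a
1/6 ≈ 0.17 chance level, with a macro one-vs-one AUC of 0.87 — the planted
chromatic (conjunctivitis redness) and luminance (sequestrum plaque, ulcer
blob, keratitis haze) signals are being picked up across the color spaces.
Per-fold reports carry the confusion matrix and per-class summaries:

```r
cv$fold_reports[[1]]
#> Evaluation report (fold 1, n = 60)
#>   accuracy 0.5833  precision 0.6806  recall 0.5833  F1 0.5629  mAUC 0.8890
```

The default full-size model is the published architecture:

```r
build_variant("csfnet", model_config())
#> CSF-Net model, variant 'csfnet'
#>   backbone: mobilenetv3-small (d = 1024), branches: 3
#>   fusion: nn_attention (tokens = 1, d_k = 3072)
#>   trainable parameters: 36,552,038
```

Grad-CAM overlays for a trained checkpoint:

```r
ck <- cv$fold_reports[[1]]$train_state$checkpoint
probs <- cmd_predict(ck, manifest$filepath[1], gradcam_out = "demo-run/cam")
```

A command-line interface wrapping the same functions lives at
`inst/cli/csfnet.R` (`synth`, `train`, `ablate`, `evaluate`, `predict`,
`gradcam`; each accepts `--config`, `--seed`, `--out`).

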