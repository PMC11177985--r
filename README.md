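# strain2infarct

Non-invasive identification of myocardial infarct regions from
left-ventricular (LV) strain maps.

After a myocardial infarction, scar tissue stops contracting, which leaves
a clear regional signature in the circumferential, radial and longitudinal
(CRL) components of the end-systolic Green–Lagrange strain tensor. The
clinical reference for locating scar — late gadolinium enhancement cardiac
MR — requires an invasive contrast agent; strain can be computed from
plain cine imaging. This package implements a full desk-scale pipeline
that learns the mapping *strain → infarct mask* and is aimed at
researchers in cardiac mechanics and medical image analysis:

1. **Synthetic strain library** (`generator_config()`, `build_library()`):
   592 examples by default, with infarct size fractions Latin-hypercube
   sampled in [0.05, 0.60], region stiffness within ±30 % of the mean,
   four base parameter sets emulating 1–4 weeks post-MI, depressed strain
   inside the infarct, sigmoid border zones, correlated noise, and a
   smoothed/biased "high-fidelity" domain variant emulating human-CMR
   strain quality.
2. **AHA bullseye preprocessing** (`preprocess_library()`,
   `augment_rotations()`, `split_dataset()`): strains at four short-axis
   levels are flattened into concentric rings of a square bullseye image;
   intensities are fixed affine maps of strain into [0, 1] with channels
   R = circumferential, G = radial, B = longitudinal; the rotation group
   {90°, 180°, 270°} gives exact fourfold augmentation.
3. **Segmentation networks** (`build_unet()` and variants): UNet
   (exactly 1,941,105 trainable parameters in the reference 16–256-channel
   configuration), attention UNet, dense UNet and residual attention UNet,
   all per-pixel sigmoid classifiers `H×W×3 → H×W×1`, running on a compact
   CNN engine (C++/Armadillo im2col convolutions + a reverse-mode autodiff
   tape) with Adam, early stopping, and BCE / soft-Dice / soft-IoU losses.
4. **Multi-fidelity composite** (`build_multifidelity()`,
   `train_multifidelity()`, `ablate_lf_count()`): `y_H = F_l(x_H, y_L) +
   F_nl(x_H, y_L)` where `y_L` is the UNet prediction and `F_l`, `F_nl`
   are single 10×10 convolutions (linear / leaky-ReLU), trained jointly on
   `MSE_L + MSE_H + λ Σ β²` with one high-fidelity example plus its three
   rotations.
5. **Cardiac mechanics utilities**: the transversely isotropic Fung-type
   constitutive model with active fiber stress
   (`total_cauchy_stress()`: `T = (1/J) F̄ (∂W_dev/∂Ē) F̄ᵀ + (∂W_vol/∂J) I
   + (1/J) F S_act Fᵀ`, `W_dev = c(e^Q − 1)`,
   `Q = B₁Ē₁₁² + B₂(Ē₂₂²+Ē₃₃²+Ē₂₃²) + B₃(Ē₁₂²+Ē₁₃²)`,
   `S_act = T_a/(2E_f+1) N⊗N`, `T_a = T_Ca(1 + β(√(2E_f+1) − 1))`), and
   Green–Lagrange strain kinematics from per-frame displacement fields
   (`F = Π F_i`, `F_i = I + ∂u/∂X`, `E = ½(FᵀF − I)`, `E_CRL = Q E Qᵀ`).

## Worked example

Generate a small library, train a scaled-down UNet on 32×32 bullseye
images, and evaluate it:

```r
library(strain2infarct)

lib  <- build_library(generator_config(n_examples = 8, seed = 3))
print(lib)
imgs <- augment_rotations(preprocess_library(lib, size = 32))
sp   <- split_dataset(imgs, c(0.7, 0.15, 0.15), seed = 1)

model <- build_unet(network_config("unet", 32, base_channels = 4, seed = 1))
model <- train_model(model, sp$train, sp$val, loss = "bce", epochs = 60,
                     batch_size = 8, lr = 3e-3, patience = 60, seed = 1)
ev <- evaluate_model(model, sp$test)
round(unlist(ev$metrics), 3)
```

Output from this exact script:

```
Synthetic strain library: 8 examples, 4 base models, domain low_fidelity
  infarct size fraction: [0.112, 0.547]; stiffness: [0.76, 1.28]
 accuracy precision    recall       iou       dsc
    0.953     0.996     0.705     0.703     0.826
```

Accuracy is the fraction of correctly classified pixels; precision and
recall are over predicted/true infarct pixels; IoU (Jaccard) and DSC
(Dice/F1) measure the spatial overlap between the predicted and true
infarct masks — here the scaled model recovers ~83 % Dice overlap after a
minute of CPU training (precise on predicted scar, still missing part of
the border zone at this tiny training budget). The full-scale protocol (592 examples, 128×128,
width-16 networks, 100 epochs, batch 128) uses the same functions.

A thin command-line wrapper is installed with the package
(`system.file("cli", "strain2infarct", package = "strain2infarct")`) with
subcommands `generate`, `preprocess`, `train`, `evaluate`,
`compare-sizes`, `compare-losses`, `compare-archs`, `mf-train`.

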