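# fusionseg

3D brain-tumor segmentation with a dual-decoder fusion network, in R.

Glioblastoma studies delineate three tumor subregions — necrotic core (NC),
peritumoral edema (ED) and enhancing tumor (ET) — on co-registered
multimodal MRI (FLAIR, T1, contrast-enhanced T1, T2). `fusionseg` is a
self-contained implementation of **FusionNet**, an encoder–decoder
architecture that shares one VGG16-style 3D convolutional encoder (13
layers in five blocks) between two complementary decoders:

* a **U-Net-style decoder** using skip connections (upsample, concatenate
  the encoder feature map, convolve), which recovers boundary detail;
* a **SegNet-style decoder** using the recorded max-pooling indices for
  sparse unpooling, which is memory-light;

and joins their full-resolution outputs with a **fusion head** — additive
(FusionNet-A), elementwise multiplicative (FusionNet-M) or concatenating
(FusionNet-C) — before a shared 1×1×1 voxelwise softmax classifier.
Training minimizes voxelwise cross-entropy

```
L = -(1 / HWD) Σ_h Σ_w Σ_d Σ_c  y[h,w,d,c] · log ŷ[h,w,d,c]
```

with plain SGD and an exponentially decaying learning rate
(`lr0 · decay^epoch`; defaults 0.01 and 0.8). Evaluation reports, per
subregion and aggregated as mean ± SD over subjects: recall, precision,
Dice `2TP/(2TP+FP+FN)`, lesion false positive rate `FP/(FP+TN)`, average
relative volume difference, and the average symmetric surface distance
(ASSD) between region boundaries in mm. Undefined values (e.g. ASSD of an
empty prediction) propagate as `NaN` and are excluded from cohort means
rather than averaged.

Everything runs on CPU at desk scale: the whole network — 3D convolution,
batch norm, pooling with indices, unpooling, trilinear upsampling, and
analytic backpropagation — is implemented here with C++ kernels, and a
**phantom generator** produces synthetic multimodal glioma volumes (nested
NC/ET/ED ellipsoids with realistic per-sequence contrast) so no external
data are needed. Supporting modules cover zero-padding to cubic inputs
(240×240×155 → 256³), the sixfold flip/rotation augmentation scheme
(500 → 3,000 training samples), seed-deterministic cohort splitting
(611 → 500/31/80), modality-subset sweeps (15 combinations), NIfTI I/O
and slice overlays (NC red, ED green, ET yellow).

## Worked example

Generate a 20-phantom cohort, split it, augment the training set sixfold,
train a small FusionNet-A for five epochs and evaluate on the held-out
subjects:

```r
library(fusionseg)

cohort <- generate_cohort(20, master_seed = 3, edge = 32,
                          modalities = c("FLAIR", "ceT1"),
                          radii = c(10, 6.5, 3.5), center_jitter = 2)
ids <- vapply(cohort, `[[`, character(1), "subject_id")
sp <- split_cohort(ids, c(14, 3, 3), seed = 3)
train_set <- expand_training_set(cohort[match(sp$train, ids)])  # 84 samples

cfg <- fusionnet_config(in_channels = 2, num_classes = 4, base_width = 4,
                        num_blocks = 3, fusion_mode = "A", input_edge = 32)
model <- build_fusionnet(cfg, seed = 3)
fit <- train_fusionnet(model, train_set,
                       train_config(lr0 = 0.05, decay = 0.8, epochs = 5,
                                    batch_size = 5, seed = 3),
                       val_samples = cohort[match(sp$val, ids)],
                       verbose = TRUE)
report <- evaluate_model(fit$best_model, cohort[match(sp$test, ids)])
as.data.frame(report)[, c("method", "subregion", "recall", "precision",
                          "dice", "assd")]
```

Output (about two minutes on one CPU core):

```
epoch 1: lr 0.05, train loss 1.1498, val mean dice 0.006
epoch 2: lr 0.04, train loss 0.5207, val mean dice 0.028
epoch 3: lr 0.032, train loss 0.3923, val mean dice 0.073
epoch 4: lr 0.0256, train loss 0.3362, val mean dice 0.155
epoch 5: lr 0.02048, train loss 0.3027, val mean dice 0.204
       method subregion    recall precision      dice      assd
1 FusionNet-A        NC 0.00±0.00 0.00±0.00 0.00±0.00 3.26±0.10
2 FusionNet-A        ED 0.54±0.01 0.72±0.01 0.62±0.01 0.63±0.01
3 FusionNet-A        ET 0.00±0.00 0.00±0.00 0.00±0.00       NaN
```

The training loss falls steadily and after five epochs the network has
learned the large edema shell (ED Dice 0.62, surface distance 0.63 mm)
but not yet the small NC/ET cores — their rows show the empty-prediction
conventions: recall/precision/Dice 0, and `NaN` for a surface distance
that has no predicted surface to measure. Longer budgets (or the
200-step single-phantom overfit in the acceptance script, which reaches
whole-tumor Dice ≈ 0.99) recover the inner structures.

A command-line front end over the same functions is installed at
`inst/cli/fusionseg.R` with subcommands `phantom`, `train`, `predict`,
`evaluate` and `overlay`.

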