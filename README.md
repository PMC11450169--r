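# hemafuse

Fine-grained classification of single blood-cell images with a layer-fused
Vision Transformer, a dynamic-margin sub-center ArcFace loss, and optional
masked-autoencoder (MAE) self-supervised pre-training — implemented
entirely in R, with a synthetic stained-cell image generator so the whole
pipeline runs and is tested without any external dataset.

## Who this is for and what it does

Morphological differentials on blood smears hinge on subtle distinctions —
granulocyte maturation stages, erythroblast stages — in small, strongly
imbalanced datasets. `hemafuse` packages a classification method designed
for that regime:

- **Backbone**: a class-token-free ViT (pre-norm blocks, fixed 2-D
  sine–cosine positions). Instead of reading out one final token, each of
  the L encoder layers is mean-pooled over tokens, the L pooled vectors
  are gated by a Squeeze-and-Excitation bottleneck *over layers*
  (L → max(1, L/4) → L, sigmoid gates), and the gate-weighted sum over
  layers is the classification feature — so early-layer color/contour
  texture cues and late-layer semantics all feed the decision:

  f = Σ_l w_l · meanpool(layer_l),  w = σ(W₂ · relu(W₁ · squeeze))

- **Loss**: dynamic-margin sub-center ArcFace. Class j scores by its best
  of K = 3 unit-norm prototypes, cos θ_j = max_k ŵ_jk·x̂, and training
  minimizes

  L = −log [ e^{s·cos(θ_y + m_y)} / (e^{s·cos(θ_y + m_y)} + Σ_{j≠y} e^{s·cos θ_j}) ],  s = 64

  with a per-class margin m_c = (a−b)·n_c^{−1/2} + b (a = 0.5, b = 0.05)
  computed from the training-set class counts — rare classes get larger
  margins.

- **Pre-training**: MAE — 75% of patches masked, encoder on visible
  patches only, light decoder reconstructs masked pixels, loss on masked
  patches only — then encoder-weight transfer into the classifier by
  parameter key.

- **Plus**: the full augmentation pipeline (bicubic 224 resize, random
  flip, 2-op random enhancement at magnitude 9/10, random erasing
  p = 0.25), linear-warmup + cosine AdamW schedules, per-class
  precision/recall/F1 and confusion matrices, embedding export, parameter
  and multiply-accumulate accounting, and a config-file-driven CLI.

All neural forward *and backward* passes are written in this package and
checked against finite differences in the test suite.

## Worked example

Generate a 4-class synthetic dataset, pre-train an MAE, transfer, train
the fusion classifier, evaluate:

```r
library(hemafuse)

specs <- list(
  cell_class_spec("lymphoid",   40, hue = 220, nucleus_lobes = 1, nucleus_fraction = 0.6,  granularity = 2),
  cell_class_spec("eosino",     40, hue = 20,  nucleus_lobes = 2, nucleus_fraction = 0.35, granularity = 10),
  cell_class_spec("segmented",  40, hue = 300, nucleus_lobes = 4, nucleus_fraction = 0.35, granularity = 4),
  cell_class_spec("monocytoid", 40, hue = 120, nucleus_lobes = 1, nucleus_fraction = 0.45, granularity = 3))
records <- generate_dataset(specs, image_size_range = c(48, 96), seed = 11)

cfg <- backbone_config(image_size = 32, patch_size = 8, depth = 2,
                       dim = 32, heads = 4, mlp_ratio = 2)
mae <- build_mae(cfg, dec_depth = 1, dec_dim = 16, dec_heads = 4, seed = 4)
pre <- train_mae(mae, records_split(records, "train"),
                 steps = 150, batch_size = 8, seed = 5)

model <- transfer_weights(pre$model,
                          build_classifier(cfg, n_classes = 4, n_subcenters = 3, seed = 2))
fit <- train_classifier(model,
                        records_split(records, "train"),
                        records_split(records, "val"),
                        loss_type = "dynamic-subcenter",
                        epochs = 15, batch_size = 32,
                        schedule = schedule_config(base_lr = 1e-3, warmup_epochs = 2,
                                                   total_epochs = 15, weight_decay = 5e-4),
                        augment = augment_config(target_size = 32), seed = 3)
evaluate(fit$model, records_split(records, "val"))
```

Output (~1 minute on one CPU core):

```
accuracy: 100.00% (n = 33)
macro precision / recall / F1: 100.00% / 100.00% / 100.00%
confusion matrix (rows = true):
     [,1] [,2] [,3] [,4]
[1,]    5    0    0    0
[2,]    0   10    0    0
[3,]    0    0    9    0
[4,]    0    0    0    9
```

The pre-training log shows the masked-patch MSE falling from 1.007 to
0.681 over 150 steps; per-class margins for counts (800, 435, 165) come
out as `compute_margins(c(800, 435, 165))$margins` = (0.0659, 0.0716,
0.0850) — the rarest class gets the largest margin.

Architecture accounting at the full ViT-Base/16 preset:

```r
fusion  <- build_classifier(vit_base_config(FALSE), 10, 3, fusion = TRUE,  head = "dsa",    seed = 1)
vanilla <- build_classifier(vit_base_config(TRUE),  10,    fusion = FALSE, head = "linear", seed = 1)
count_params(fusion)  / 1e6   # 85.82 (M parameters, no class token, SE gate, 10x3 prototype bank)
count_params(vanilla) / 1e6   # 85.81 (class token + 10-class linear head)
count_flops(vanilla)  / 1e9   # 16.87 (GMACs, 197 tokens)
count_flops(fusion)   / 1e9   # 16.78 (GMACs, 196 tokens)
```

## Command line

A thin CLI over the same functions ships in `inst/cli/hemafuse`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hemafuse", package = "hemafuse"))')
Rscript $CLI synth    --out data/ --scale 5 --seed 1
Rscript $CLI pretrain --data data/ --out mae.rds --config run.yaml --recon-out recon.png
Rscript $CLI train    --data data/ --out clf.rds --init mae.rds --loss dynamic-subcenter
Rscript $CLI evaluate --data data/ --model clf.rds --out report.json --confusion conf.csv
Rscript $CLI embed    --data data/ --model clf.rds --out embeddings.tsv
Rscript $CLI count    --classes 10
```

`--config` takes one YAML file with sections
`{data, augment, backbone, fusion, loss, mae, schedule, train}`; every key
has a full-scale default (see `default_run_config()`) and individual
flags override it. Image folders follow the `root/<class>/<name>.png`
layout with an optional `splits.csv`.

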