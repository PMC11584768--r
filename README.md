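# dranet

Binary semantic segmentation of histology-style images in R, built around
two adaptive-context mechanisms on top of a compact group-normalized
residual encoder/decoder:

* an **ordered shift MLP** block — channels are ranked by pooled importance
  (`score = MLP(avgpool) + MLP(maxpool)`), split into groups, and each
  group is displaced a different number of pixels along the height and then
  the width axis before pointwise channel MLPs (with a depthwise 3×3
  positional encoding) mix the shifted context;
* a **dynamic regional attention (DRA)** gate — the feature map is
  collapsed to one channel, partitioned into `k` non-overlapping regions by
  the similarity measure

  S = sqrt((d_f/m)² + (d_s/s)²),  s = sqrt(H·W/k),

  with `d_f` the feature-value distance and `d_s` the pixel distance; each
  region is replaced by its mean and a sigmoid turns the fused map into an
  H×W attention gate. Two search modes are available: *local*
  (superpixel-style, centers searched within a 2s×2s window) and *global*
  (feature-only 1-D k-means).

Training uses the compound loss `0.5·BCE + Dice`; evaluation reports IoU,
Dice, Recall, Specificity and Precision (%). A deterministic synthetic
generator produces stain-tinted textured scenes with exact masks so the
whole pipeline is testable without external data; directory trees of real
images (PNG/TIFF + PNG masks, split lists) are supported for full-scale
runs. The forward/backward passes are implemented in the package itself
over gemm-based convolution kernels (RcppArmadillo); no external deep
learning runtime is required.

Intended users: computational-pathology and biomedical-imaging researchers
who want a fully inspectable, dependency-light reference implementation of
region-adaptive attention for segmentation.

## Worked example

```r
library(dranet)

# profile the four ablation variants at the reference input size
for (v in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
  cfg <- model_config(input_size = 224, use_mlp = v[1], use_dra = v[2])
  print(count_parameters(assemble(cfg))$parameters_millions)
}
#> [1] 14.32
#> [1] 15.27
#> [1] 14.33
#> [1] 15.28

# train on synthetic scenes and evaluate held-out images
train_samples <- lapply(1:32, function(i) {
  sp <- scene_preset("easy", size = c(96L, 96L)); sp$seed <- 1000L + i
  generate_sample(sp)
})
test_samples <- lapply(1:8, function(i) {
  sp <- scene_preset("easy", size = c(96L, 96L)); sp$seed <- 9000L + i
  generate_sample(sp)
})
fit <- train(model_config(input_size = 96L),
             train_config(epochs = 10L, input_size = 96L, seed = 5L),
             samples = train_samples, verbose = FALSE)
print(evaluate(fit$model, samples = test_samples)$aggregate)
#> IoU 94.21%  Dice 97.00%  Recall 98.14%  Specificity 99.32%  Precision 96.02%
```

The four numbers in the first block are the trainable-parameter budgets
(millions) of the convolutional baseline, baseline + ordered shift MLP,
baseline + DRA, and the full model. The metrics line reports pixel-overlap
quality of the trained model on unseen synthetic scenes: IoU/Dice measure
foreground overlap, Recall the fraction of true foreground recovered,
Specificity the background kept clean, Precision the purity of the
predicted foreground.

A region partition can be inspected directly:

```r
p <- matrix(rnorm(64 * 64), 64, 64)
part <- partition_regions(p, dra_config(k = 5, mode = "local"))
visualize_regions(p, part, "regions.png", focus = list(c(32, 32)))
```

## Command line

A thin CLI over the package functions is installed at `exec/dranet`:

```sh
dranet make-synthetic --out data/ --preset glas_like --n-train 32 --n-test 8
dranet train --data data/ --checkpoint ck.rds --epochs 30 --size 96 --seed 42
dranet evaluate --checkpoint ck.rds --data data/ --out results/
dranet profile --variant both --json profile.json
dranet sweep-k --data data/ --k 5,10,15,20,25 --epochs 2 --out sweep.csv
dranet visualize-regions --image data/images/train_0001_seed5001.png --out regions.png
```

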