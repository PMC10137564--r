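# ctrseg — automated cardiothoracic ratio from chest radiograph segmentation

`ctrseg` turns a posterior-anterior (PA) chest radiograph into a
cardiothoracic ratio (CTR) and a cardiomegaly call, the way it is done in
clinical deep-learning pipelines for hemodialysis units:

1. **Segmentation** — a U-Net-style encoder-decoder with a 34-layer
   residual encoder (six downsamplings, so the bottleneck is 1/64 of the
   input; concatenation skip connections; a 3×3 head with one filter per
   class and per-pixel softmax) labels every pixel background / lung /
   heart. Training uses SGD (learning rate 1e-4, momentum 0.99) on the
   sum-of-Jaccard loss with a seven-transform augmentation battery.
2. **Geometry** — from the predicted mask, the CTR is the maximal
   transverse cardiac extent divided by the maximal transverse thoracic
   extent (outer lung borders):
   `CTR = cardiac width / thoracic width`, with cardiomegaly called at
   `CTR > 50%`. Stray segmentation blobs are removed first (two largest
   lung components, one largest heart component); a mask missing a
   structure raises a "needs human review" error instead of a number.
3. **Evaluation** — per-class IoU/Dice (`IoU = TP/(TP+FP+FN)`,
   `Dice = 2·PPV·TPR/(PPV+TPR)`), mIoU and average Dice over the anatomy,
   CTR agreement (R², mean ± SD absolute difference in percentage points,
   ≥ 2 pp bias count, Bland–Altman limits, paired t-tests) and diagnostic
   performance (accuracy, sensitivity, specificity, ROC/AUC).

Because no imaging data ships with the package, a **synthetic chest
phantom** generator produces seeded PA-like images (two elongated lung
fields, a cardiac ellipse, optional catheter/pacemaker/effusion
confounders) whose cardiac and thoracic spans — and hence true CTR — are
known analytically, making every stage of the pipeline testable on a
desktop. The deep-learning machinery itself (convolutions, batch-norm,
backpropagation, the SGD loop) is implemented in the package with compiled
kernels and is verified by finite-difference gradient checks.

## Worked example

```r
library(ctrseg)

# 1. a seeded phantom dataset with analytically known CTRs
params <- phantom_params(width_px = 64, height_px = 64,
                         artifact_flags = c("catheter", "pacemaker", "effusion"))
train <- attr(generate_dataset(200, params, seed = 1001, "data/train"), "manifest")
val   <- attr(generate_dataset(50,  params, seed = 1002, "data/val"),   "manifest")
test  <- attr(generate_dataset(50,  params, seed = 1003, "data/test"),  "manifest")

# 2. train the reduced network (~3 min on one CPU core)
ckpt <- train_segnet(model_config(input_size_px = 64, base_width = 8),
                     train_config(epochs = 15, batch_size = 8,
                                  input_size_px = 64, seed = 7),
                     train, val, verbose = TRUE)

# 3. predict, measure, evaluate
preds <- lapply(test$image_path, function(p) predict_mask(ckpt, p))
ev <- evaluate_run(test, preds)
ev
#> <ctr_evaluation> 50 images (50 with valid CTR)
#> <seg_metrics> mIoU 0.9567, ADC 0.9779 (averaged over lung, heart)
#> CTR agreement: R^2 0.9784, mean |diff| 0.89 +/- 0.67 pp, >= 2 pp bias: 3/50
#> <diagnostic_report> accuracy 0.960, sensitivity 0.882, specificity 1.000,
#>   AUC 0.998 (CTR > 0.50, n = 50)
```

The printed numbers mean: pixel overlap between predicted and reference
anatomy (mIoU/average Dice over lung + heart), agreement between predicted
and true CTRs (R² of the regression, mean absolute difference in CTR
percentage points, how many images miss by ≥ 2 pp), and cardiomegaly
screening quality against the true-CTR labels.

Single images work the same way: `compute_ctr(predict_mask(ckpt, "x.png"))`
returns the spans, the extremal columns, and the ratio;
`classify_cardiomegaly(0.534)` is `TRUE`.

A command-line interface wraps the same pipeline
(`simulate`, `train`, `predict`, `ctr`, `evaluate`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ctrseg.R", package = "ctrseg"))')
Rscript $CLI simulate --n 50 --seed 7 --out data/sim
Rscript $CLI ctr --mask data/sim/mask_0001.png
```

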