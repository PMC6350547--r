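# pollentrain

Training framework for four-class thyroid SPECT image classification:
Graves' disease, Hashimoto disease, subacute thyroiditis, and normal.
It implements, in plain R with a few Rcpp kernels:

* a **weighted DenseNet**: dense blocks where every skip connection
  carries a trainable scalar, so layer *l* computes
  `y_l = F_l(x_0·k_{l,0}, …, x_{l-1}·k_{l,l-1}; W_l)` with all
  `k_{l,i}` initialized to 1 (the standard dense block) and learned by
  backprop, and transitions that downsample with a dilated (rate-2,
  stride-2) 3×3 convolution instead of pooling;
* a **per-minibatch learning-rate search** by the flower pollination
  algorithm: before each SGD commit `w ← w − l·∇w`, the rate `l` is
  optimized to minimize the post-update loss of the current minibatch,
  alternating Lévy-flight global moves `l_i ← l_i + γ·L·(l_best − l_i)`
  (γ = 0.1, tail exponent 1.5) and local moves
  `l_i ← l_i + ε·(l_1 − l_2)`; seeding the incumbent rate into the
  population makes every committed step at least as good, on its own
  minibatch, as the incumbent would have been;
* **mixup balancing**: classes are lifted to a common size by virtual
  samples `X′ = αX_i + (1−α)X_j`, `Y′ = αY_i + (1−α)Y_j` with
  `α ~ U[0.5, 1]`, then split into train/test per class;
* a **per-class evaluation suite**: confusion matrix (columns = actual
  class), one-vs-rest recall / precision / accuracy / specificity / F1,
  and macro averages, as JSON + CSV reports.

Because clinical thyroid-SPECT archives are not publicly deposited, the
package includes a seeded synthetic generator of SPECT-like scintigrams
(two-lobed gland patterns with class-specific size, uptake level and
patchiness) so the entire pipeline is runnable and testable end to end.

## Worked example

A desk-scale run — 200 synthetic images per class at 32×32, balanced to
250 per class by mixup, split 175/75, small architecture, up to 3
epochs with the learning-rate search on every minibatch:

```r
library(pollentrain)
run <- run_pipeline(list(
  seed = 42,
  dataset = list(counts = list(graves = 200, hashimoto = 200,
                               subacute = 200, normal = 200)),
  augmentation = list(target_per_class = 250, train_per_class = 175,
                      test_per_class = 75),
  training = list(max_epochs = 3,
                  fpa = list(n_iterations = 3, n_pollen = 6))
), run_dir = "run_desk")

run$history$epochs
#>   epoch  val_loss val_macro_precision improved
#> 1     1 0.7478280           0.8240741     TRUE
#> 2     2 0.5675453           0.8333333     TRUE
#> 3     3 0.5842582           0.7779570    FALSE

run$evaluation$cm
#>            actual
#> predicted   graves hashimoto subacute normal
#>   graves        75         1        0      0
#>   hashimoto      0        73        2     75
#>   subacute       0         1       73      0
#>   normal         0         0        0      0
```

Reading the output: each column of the confusion matrix is an actual
class (75 test samples per class), each row a predicted class. The
three disease classes are recovered almost perfectly; the normal class
— whose synthetic uptake level sits closest to Hashimoto's — is
absorbed into the hashimoto column, and its precision is reported as
undefined (no normal predictions) rather than 0. The test-set macro
precision over the defined classes is 0.82, far above the 0.25
four-class chance level. Per-step records in `run$history$steps` show
the committed learning rate chosen by the search and verify
`loss_after <= incumbent_loss` at every step.

The run directory contains the resolved configuration, the raw-data
manifest, the checkpoint, step/epoch histories (CSV), and the
evaluation report (`report.json`, `metrics.csv` — one row per metric,
one column per class, percentages with two decimals).

A thin CLI covering the pipeline stages lives at
`inst/cli/pollen-train.R`:

```sh
Rscript inst/cli/pollen-train.R generate --counts graves=780,hashimoto=438,subacute=810,normal=860 --size 255 --seed 1 --out data
Rscript inst/cli/pollen-train.R run --config cfg.yaml --out run1
Rscript inst/cli/pollen-train.R diagnose --model run1/checkpoint.rds --images data
```

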