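---
title: "Weighted dense connectivity and flower-pollination learning-rate search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted dense connectivity and flower-pollination learning-rate search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Thyroid scintigraphy (SPECT) distinguishes diffuse hyperfunction
(Graves' disease), chronic autoimmune thyroiditis (Hashimoto disease),
subacute thyroiditis, and the normal gland largely by the pattern and
intensity of tracer uptake in the two lobes. `pollentrain` implements a
four-class image classifier for this setting built around two ideas:

1. **Weighted dense connectivity.** In a dense block, layer $l$ receives
   the feature maps of all previous layers. Here every skip connection
   carries its own trainable scalar, so layer $l$ computes
   $$y_l = F_l(x_0 \cdot k_{l,0},\, x_1 \cdot k_{l,1},\, \ldots,\,
   x_{l-1} \cdot k_{l,l-1};\, W_l),$$
   where the $k_{l,i}$ start at exactly 1.0 (the standard dense block)
   and are learned jointly with the convolution weights. A block with
   $L$ layers owns $L(L-1)/2$ of these scalars. The transitions between
   blocks downsample by a 3×3 convolution with dilation 2 and stride 2
   instead of pooling, preserving the 2× reduction while widening the
   receptive field.

2. **Per-minibatch learning-rate search.** Plain SGD commits
   $w \leftarrow w - l\,\nabla w$ without checking whether the step
   helped the current minibatch. Here, before each commit, the scalar
   learning rate $l$ is optimized by the flower pollination algorithm
   (FPA) to minimize the *post-update loss of that same minibatch*,
   re-using the already-computed gradient. Candidate rates ("pollens")
   evolve by global moves $l_i \leftarrow l_i + \gamma L (l_{best} -
   l_i)$ with a Lévy-flight step $L$ (tail exponent 1.5, $\gamma=0.1$),
   or local moves $l_i \leftarrow l_i + \varepsilon (l_1 - l_2)$ with
   $\varepsilon \sim U[0,1]$, switched with probability $P_C$. Because
   the previously committed rate is seeded into the population and
   acceptance is greedy, the committed update is provably never worse on
   its minibatch than the incumbent rate would have been.

Class imbalance is handled by mixup: virtual samples
$X' = \alpha X_i + (1-\alpha) X_j$, $Y' = \alpha Y_i + (1-\alpha) Y_j$
with $\alpha \sim U[0.5, 1]$ lift every class to a common size with soft
labels; training minimizes soft-target cross entropy.

# The synthetic data generator

Clinical SPECT archives of this kind are not publicly deposited, so the
package ships a parametric generator (`generate_dataset()`) that emulates
the *shape* of the learning problem: stylized anterior scintigrams —
two soft-edged elliptical lobes joined by an isthmus on a dark
background — whose class signal follows the clinical picture:

* **normal** — moderate, even uptake (level ≈ 0.50–0.60) in
  normal-sized lobes;
* **graves** — gland enlarged 1.3–1.5×, uniformly elevated uptake
  (0.80–0.92);
* **hashimoto** — normal size, base level 0.46–0.56 modulated by 4–7
  multiplicative hot/cold patches (factors 0.35–0.6 and 1.4–1.7);
* **subacute** — strongly suppressed uptake (0.12–0.20).

All geometry and intensity parameters are drawn from seeded uniform
distributions, plus additive Gaussian pixel noise (sd 0.03), and the
result is clamped to [0, 1]. The default per-class counts follow the
clinical study the framework targets (780/438/810/860), balanced by
mixup to 2000 per class and split 1400/600 into train and test.

What the generator does *not* emulate: SPECT acquisition physics
(attenuation, scatter, collimator blur), anatomical variability beyond
ellipse jitter, and the hard inter-class ambiguity of real scans.
Passing tests on this data therefore demonstrate that the architecture,
optimizer and pipeline work end to end and that the method's invariants
hold — not that clinical accuracy figures would be reproduced.

# Numerical and design choices

**Transform order inside a dense layer.** The composite transform is
convolution → batch norm → ReLU. The order matters for the skip
weights: batch normalization is invariant to a per-channel scale, so a
scalar multiplying a feature map that feeds *directly* into a
normalizer receives an exactly-zero gradient and could never train.
Placing the convolution first mixes channels before normalization and
gives the skip weights a real gradient path; at initialization
($k = 1$) the network still equals the standard dense architecture,
which the test suite verifies against an independent direct-loop
reference implementation.

**Block wiring.** Layer 0 of each block transforms the block input;
layer $l \ge 1$ sees the outputs of layers $0..l-1$, so layer $l$ has
exactly $l$ skip weights. The block output is the concatenation of all
layer outputs; transitions compress channels with a 1×1 convolution
(factor 0.5) before downsampling.

**Skip weights are scalars, not per-channel vectors.** One $k$ per
concatenated feature map keeps the parameter count negligible and
matches the formulation above; a per-channel variant would blur into
the batch-norm gain parameters.

**FPA defaults.** $N = 10$ iterations, $m = 10$ pollens, $P_C = 0.8$
(the value customary in the FPA literature), search interval
$[10^{-4}, 0.5]$, $\gamma = 0.1$, Lévy exponent 1.5 via Mantegna's
algorithm. The initial population is uniform on the interval — read as
the canonical distribution confined to an interval — with one pollen
replaced by the incumbent rate. Out-of-bounds candidates are clamped to
the nearest bound (deterministic, keeps pressure at the boundary);
acceptance is greedy per pollen, and the global best is tracked over
all evaluations, so the best-fitness trace is nonincreasing. Inside the
training loop the per-step search uses a smaller population
($m = 6$, $N = 3$ by default in the pipeline configuration) because each
fitness evaluation costs one forward pass; the search cost per step is
$m(N+1)$ forwards. `fpa_every_k_steps = Inf` disables the search and
reduces the loop to plain fixed-rate SGD, which the tests exploit to
verify the loop against an independent SGD reference.

**Fitness definition.** The fitness of a candidate rate is the loss of
the *same* minibatch at $w - l\,\nabla w$, evaluated with the same
dropout mask and with batch statistics recomputed from the minibatch,
so the fitness is a deterministic function of $l$ during one search.
Running batch-norm statistics are committed only once per step, from
the gradient-computing forward pass.

**Training.** Plain SGD per the update rule above (no momentum or
weight decay, which the source method does not specify); minibatch size
5; soft-target cross entropy; dropout (default rate 0.2) on the
classifier head only; early stopping on a per-class stratified
validation split (default 10% of the training set) with configurable
patience; the best-validation model is returned. The incumbent rate for
step $t$ is the rate committed at step $t-1$ (initially `lr_init`).

**Mixup conventions.** A mixed sample counts toward the class of its
dominant component $X_i$ (well-defined because $\alpha \ge 0.5$); the
true class of a sample at evaluation time is the argmax of its label
vector. Augment-then-split follows the source procedure by default; a
`split_first` flag partitions the originals first and augments each
side from its own images only, for leakage-free evaluation.

**Evaluation.** The confusion matrix uses columns for the actual class
and rows for the predicted class. The five per-class one-vs-rest
metrics are recall, precision, accuracy, specificity and F1; a metric
with a zero denominator is reported as an explicit null (never 0 or 1),
and macro averages skip undefined entries while reporting how many were
skipped. Report tables print percentages rounded half-even to two
decimals.

**Problem sizes.** The default desk-scale configuration trains a
2-block × 3-layer, growth-8 network on 32×32 images; the test suite's
end-to-end run uses 200 images per class balanced to 250, with up to 3
epochs. These sizes were chosen so the whole suite runs comfortably on
one CPU; the clinically-sized DenseNet121-like configuration
(`arch = "clinical"`, 255×255 input) is available through the same
configuration surface.

# Known limitations

* The synthetic classes are far more separable than clinical scans; the
  end-to-end accuracy of the desk-scale run says nothing about clinical
  performance.
* The per-minibatch guarantee is exactly that — per minibatch. It does
  not imply monotone validation loss, and the search adds $m(N+1)$
  forward passes per step.
* `load_pretrained()` transfers tensors by name and shape; a checkpoint
  from a different architecture will only partially match (skip weights
  and dilated-downsampling convolutions always keep their
  initialization), which is the intended, conservative behavior.
* Batch-norm running statistics are momentum-averaged (0.1) from
  training batches; with very short runs the evaluation-mode statistics
  lag the training-mode ones.

# A worked desk-scale example

```{r example}
library(pollentrain)

run <- run_pipeline(list(
  seed = 42,
  dataset = list(counts = list(graves = 200, hashimoto = 200,
                               subacute = 200, normal = 200)),
  augmentation = list(target_per_class = 250, train_per_class = 175,
                      test_per_class = 75),
  training = list(max_epochs = 3)
), run_dir = "run_desk")

run$evaluation$cm          # 4x4 confusion matrix, columns = actual
run$evaluation$macro       # macro-averaged metrics
head(run$history$steps)    # per-step committed rate and losses
```

Every committed step in `run$history$steps` satisfies
`loss_after <= incumbent_loss`: the flower-pollination search never
loses to the incumbent learning rate on the step's own minibatch.
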