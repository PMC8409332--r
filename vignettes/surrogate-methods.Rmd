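---
title: "Surrogate models of posture-dependent muscle kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate models of posture-dependent muscle kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Musculoskeletal simulations need, at every control step, the musculotendon
length $L_l(\theta)$ of each muscle $l$ and its moment arm about every
joint it spans, as functions of the limb posture $\theta$ (the vector of
joint angles). Computing these from geometric muscle-path models is
accurate but slow; real-time applications such as prosthetic control need
the transformation in about a millisecond. `mskSurrogate` implements the
machine-learning route: generate a large posture/kinematics dataset from a
mechanistic reference model, train fast learned surrogates (per-channel
gradient-boosted trees, or fully connected neural networks), and quantify
their accuracy with normalized error metrics.

## The polynomial reference model

The reference model is a *synthetic stand-in* with the structure of a full
human arm-and-hand model: 18 rotational degrees of freedom (DOFs), 33
muscles, and 99 moment-arm channels. Each muscle's length is a
multivariate polynomial in the angles of the joints it spans (1-6 joints,
3 on average; total polynomial power at most 5), and its moment arm about
spanned joint $j$ is the analytic partial derivative

$$MA_{l,j}(\theta) = -\,\frac{\partial L_l(\theta)}{\partial \theta_j},$$

with the sign convention that a positive moment arm means the muscle
shortens as the joint angle increases (configurable through `ma_sign`;
published arm models do not all agree on a convention). This
length-derivative relation is the defining property of the model family:
moment arms are never stored separately, they are always the exact
gradient of the length surface, and the package's tests verify the
analytic derivatives against central finite differences at
$10^{-5}$ rad steps.

Because the coefficients of validated anatomical polynomial models are not
generally available, `build_default_model()` samples coefficients
randomly, with choices made once for realism rather than convenience:

* **Coupling distribution.** 11 muscles span 2 DOFs, 15 span 3, 4 span 4,
  2 span 5 and 1 spans 6 ("thumb-like"), giving 33 muscles, a mean span
  of exactly 3, and 99 channels.
* **Term structure.** Every muscle gets a constant term, all first-order
  terms in its spanned DOFs, and 3 random higher-order terms (total power
  2-5) per spanned DOF. Guaranteed first-order terms keep every
  moment-arm channel bounded away from zero, as real levers are.
* **Coefficient magnitudes.** A per-muscle amplitude $A$ is drawn
  log-uniformly from 2-50 mm; a term of total power $p$ gets a
  $N(0, (A \cdot 0.5^p)^2)$ coefficient. The geometric decay keeps the
  length surface smooth and low-order-dominated, as anatomical polynomial
  fits are, while still exercising quintic curvature.
* **Units and ranges.** Millimetres and radians throughout; every joint
  defaults to $[-\pi/2, \pi/2]$ (per-joint configurable — printed
  anatomical ranges vary by joint and model). Resulting length excursions
  span roughly 9-320 mm across muscles and base lengths 70-400 mm,
  bracketing real arm and hand muscles, including few-millimetre ranges
  for small thumb muscles.
* **Positivity.** The constant term is raised until a conservative
  lower bound (constant minus the summed worst-case magnitude of every
  other term over the workspace) stays above 10 mm, so lengths are
  positive everywhere, not just on a probe sample.

Models are seed-deterministic and serialize losslessly to JSON.

## Datasets and the split protocol

`sample_postures()` draws each joint angle independently and uniformly
over its range; `generate_dataset()` pairs the postures with the exact
model outputs (n x 18 postures, n x 33 lengths, n x 99 moment arms).
`split_dataset()` carves out the test set first and then splits the rest
80/20 into training and validation, with the three sets in the ratio
5 : 80 : 20. At the full protocol scale this yields exactly 50,000 test,
800,000 training and 200,000 validation rows (a 1,050,000-row total: the
test set holds 5% as many rows as the data that remains for model
development). Sizes round half-up, so small datasets still populate all
three sets. Hyperparameter tuning uses a separate 70/30 split
(`tuning_split()`).

## Boosted-tree surrogates

`train_gbm()` fits **one ensemble per output channel** — 33 length and 99
moment-arm models for the default reference — each mapping the full
18-dimensional posture to one scalar. Trees grow leaf-wise with a leaf
cap, the canonical growth strategy for this family; the engine is xgboost
with `grow_policy = "lossguide"`, which implements it. A constant
parameter block is shared by all channels (boosting seed 2523252,
single-threaded serial learner, MSE metric, early stopping after 200
stagnant validation rounds, bagging and feature fractions 0.8). Tunable
hyperparameters and their search ranges are: leaves per tree 20-100,
minimum samples per leaf 10-100, maximum depth 1-100, with the learning
rate searched on (0.01, 0.2] (log scale) — untuned channels use the
engine defaults (31 leaves, 20 samples/leaf, learning rate 0.1, 100
boosting rounds).

`tune_gbm_channel()` performs sequential model-based (Bayesian)
optimization over this space: a Gaussian-process surrogate with a
squared-exponential kernel on the unit-scaled parameters, expected
improvement maximized over random candidates, and a Latin-hypercube
initial design that always contains the engine-default point first — so
the tuned configuration can never be worse than the untuned baseline on
the tuning split. The default budget is 50 evaluations per channel;
tuning fits use up to 1,000 boosting rounds under early stopping.

## Neural-network surrogates

`train_ann()` trains one fully connected network per target block:
reference architectures (18, 1024, 512, 33) for lengths and
(18, 2048, 1024, 99) for moment arms, with ReLU hidden layers. Weights
start from Xavier initialization (zero-mean normal, variance
$2/(n_{in}+n_{out})$), biases at zero.

Three protocol details deserve explanation:

* **Output layer and standardization.** ReLU on the *output* layer cannot
  represent signed moment arms, so the output layer is affine and targets
  are standardized per channel on the training rows (de-standardized at
  prediction). This is the working interpretation of an all-ReLU
  description that is not satisfiable for signed targets.
* **Worst-percentile cost.** The training cost pools the elementwise
  errors of a batch across all channels, keeps the largest 30% (ties at
  the cutoff included), and averages them. It reduces to the plain mean
  error at 100%, and `loss_percentile = 5` gives a worst-5% variant; the
  cut can also be applied within each channel (`loss_per_channel =
  TRUE`). Two elementwise error kinds are supported. `"abs"` is the
  function default and matches the "mean of the worst errors" reading
  literally. The package's own benchmark protocol trains with
  `loss_kind = "squared"` — the worst-percentile *RMSE* reading — for an
  optimization reason as much as a semantic one: absolute-error
  subgradients have residual-independent magnitude, so an adaptive
  optimizer keeps taking fixed-size steps near the optimum and stalls at
  a floor proportional to the learning rate, whereas squared-error
  gradients vanish with the residual and let the plateau schedule
  converge measurably further on the worst muscles. Backpropagation uses
  the exact subgradient of either cost; the test suite checks it against
  numerical differentiation away from ReLU kinks and percentile ties.
* **Plateau schedule.** Optimization is mini-batch Adam (batch 256,
  initial rate 0.001). When the validation cost fails to improve by more
  than $10^{-6}$ for 2 consecutive epochs, the rate is multiplied by 0.8.
  The returned network is the best-validation snapshot, and the per-epoch
  trace (costs, learning rate, train/validation normalized errors) feeds
  `overfit_monitor()`, which flags a train-versus-held-out gap above 0.4
  percentage points that persists through the end of training.

Dropout (inverted, on hidden layers) and input standardization are
implemented but off by default: both were evaluated and excluded from the
default pipeline as not improving accuracy on these smooth targets.

## Error metrics

Length errors are normalized by each muscle's length range over the
workspace, moment-arm errors by each channel's maximum absolute moment
arm, both estimated by dense uniform sampling ($10^5$ probes by default;
`compute_normalization()`). `Mmax` is a maximum of the *absolute* value,
so sign conventions do not affect it. The headline metrics are

$$\mathrm{RMSE}_L = \frac{100}{m}\sum_{l=1}^{m}\frac{1}{n}\sum_{i=1}^{n}
\sqrt{\left(\frac{x_{r,l,i}-x_{p,l,i}}{L\!\max_l - L\!\min_l}\right)^2}\;\%,$$

and its analogue with $M\!\max_l$ for moment arms. Note the root applies
to a *single* squared term, so the quantity is a range-normalized mean
absolute error; it is implemented exactly in this form (the name is kept
for continuity with the literature), with a conventional per-channel
root-mean-square variant behind `kind = "rms"`. Per-muscle values are
exposed (`per_muscle = TRUE`) because the worst muscle, not the average,
limits downstream use. Quartile summaries (`error_distribution()`) use
linear interpolation between order statistics (R quantile type 7).
Degenerate channels (zero length range) are excluded with a warning.

A useful inversion: a muscle whose full range is 6 mm and whose
normalized error is 0.3% has an absolute error of
$0.003 \times 6\,\mathrm{mm} = 0.018$ mm — normalized percentages should
always be read against the channel's physical range.

`extreme_posture_test()` re-evaluates a surrogate with every joint drawn
from the outer quartiles of its range (each joint independently; the
alternative — all joints extreme simultaneously — probes only the corner
set, which uniform training data barely covers and which is not the
region of interest for whole-workspace use). `dataset_size_sweep()`
retrains a fresh surrogate per training-set size against one fixed test
set, tracing the accuracy/data trade-off (typically $10^3$-$10^6$
log-spaced). `latency_benchmark()` times repeated single-posture
evaluations; latency is hardware-dependent and is reported, never
asserted.

## Desk-scale protocol sizes

The package's own verification runs (test suite and
`scripts/acceptance.R`) use reduced problem sizes chosen to fit an
ordinary single-CPU session while preserving every protocol element:

* length network: hidden widths reduced proportionally to (640, 320),
  105,000 samples (80,000 training rows after the split), 120 epochs
  with the squared percentile cost;
* moment-arm surrogate: one boosted-tree ensemble per channel; channels
  of muscles spanning 4 or more DOFs (the hardest derivative surfaces)
  train on the full 80,000-row split with up to 700 rounds, the rest on
  30,000 rows with 300 rounds (leaf-wise trees, 60 leaves, learning rate
  0.12);
* boosted-tree bound checks: a 5-muscle subset (one muscle per
  spanned-DOF count) at 10,000 samples;
* sweep: a 2-joint toy model at sizes $10^3$-$10^5$.

The network training hot loop (one epoch of batch-256 Adam on the
percentile cost) runs through a compiled kernel operating in place on
flat parameter vectors; it is verified in the tests to reproduce the
reference R implementation to machine precision.

At these scales the surrogates do not reach the terminal accuracy that
full-scale training (millions of samples, hours of optimization) attains;
the quantities checked are the protocol's *outer bounds* and trends, not
its best-case means.

## Known limitations

* The reference model is synthetic. Its polynomial structure matches the
  family used for anatomical fits, but its coefficients are random; tests
  passing here show the pipeline learns smooth polynomial kinematics, not
  that it reproduces any particular limb.
* Uniform posture sampling has no kinematic correlations; real motion
  data concentrates on low-dimensional manifolds, which changes both
  training coverage and error geometry.
* The neural-network trainer is plain R on BLAS. It is exact (gradient
  checks to $10^{-4}$) but not fast; full-scale (1024/512-width, $10^6$+
  samples) training is better done on a GPU framework, for which the
  checkpoint format records everything needed.
* Boosted-tree surrogates are piecewise constant; their moment-arm
  predictions are not the exact derivative of their length predictions.
  Only the reference model has that consistency property.
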