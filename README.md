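# mskSurrogate

Machine-learning surrogates for posture-dependent musculoskeletal
kinematics.

Musculoskeletal control pipelines — simulation, motor-intent decoding,
powered-prosthesis control — repeatedly need the musculotendon length
$L_l(\theta)$ of every muscle and its moment arms
$MA_{l,j}(\theta) = -\,\partial L_l/\partial\theta_j$ as functions of the
joint-angle vector $\theta$. Mechanistic path models are accurate but too
slow for real-time loops. This package implements the surrogate-modelling
route for an 18-DOF, 33-muscle, 99-moment-arm-channel arm-and-hand
structure:

* **`synth model`** — a generator of polynomial reference models (length =
  posture polynomial of total power ≤ 5; moment arms = exact analytic
  partial derivatives), seed-deterministic, JSON-serializable, with
  physiological magnitudes in mm and rad;
* **`dataset`** — uniform posture sampling, exact model evaluation, the
  5 : 80 : 20 test/train/validation split protocol and a 70/30 tuning
  split;
* **`surrogate gbm`** — one leaf-wise gradient-boosted regression-tree
  ensemble per output channel (132 for the default model), with a fixed
  parameter block (boosting seed 2523252, MSE metric, early stopping
  after 200 stagnant rounds, 0.8 bagging/feature fractions) and
  Gaussian-process Bayesian hyperparameter tuning over leaves 20–100,
  min samples/leaf 10–100, depth 1–100;
* **`surrogate ann`** — fully connected networks (reference shapes
  18–1024–512–33 for lengths, 18–2048–1024–99 for moment arms), Xavier
  initialization, batch-256 Adam on a worst-percentile cost (mean of the
  largest 30% of pooled errors), plateau learning-rate decay (×0.8 after
  2 stagnant epochs from 0.001), best-snapshot restore, overfitting
  monitor;
* **`evaluation`** — range-normalized length errors and `Mmax`-normalized
  moment-arm errors (in %), per-channel quartile summaries,
  extreme-posture testing on the outer quartiles of each joint range,
  dataset-size sweeps and latency benchmarks.

The metric definitions, the split protocol, the loss and the schedule are
described in detail in `vignettes/surrogate-methods.Rmd`.

## Worked example

```r
library(mskSurrogate)

model <- build_default_model(seed = 1)
model
#> <msk_model> 18 DOFs, 33 muscles, 99 moment-arm channels (seed 1, MA sign -1)

norms <- compute_normalization(model, n_probe = 1e5, seed = 18)
ds    <- generate_dataset(model, 20000, seed = 2)
sp    <- split_dataset(20000, seed = 3)
sapply(sp, length)
#>       test      train validation 
#>        952      15238       3810

sur  <- train_gbm(ds, sp, params = gbm_hyperparams(num_leaves = 60,
                                                   min_data_in_leaf = 10,
                                                   learning_rate = 0.12,
                                                   num_iterations = 350))
rep  <- evaluate_surrogate(model, sur,
                           ds$postures[sp$test, ], norms,
                           surrogate_id = "gbm-20k")
rep
#> <msk_report> gbm-20k on msk-18j-33m-99ch-seed1 (n = 952)
#>   normalized length error:     0.537%
#>   normalized moment-arm error: 0.8757%
```

The two numbers are the headline metrics: the mean over muscles of the
mean range-normalized absolute length error, and the mean over channels
of the mean `Mmax`-normalized absolute moment-arm error, both in percent
of each channel's physical scale (a 0.54% error on a muscle with a 6 mm
range is 0.032 mm). `rmse_length(..., per_muscle = TRUE)` exposes the
per-muscle values; `error_distribution()` gives medians, quartile ranges
and worst-case spans per channel.

A complete seeded pipeline (model → data → split → train → evaluate, all
artifacts written with provenance) is available as `run_pipeline()` or
from the shell:

```sh
Rscript inst/cli/mskkit.R pipeline --out run1 --n 20000 --family gbm --seed 1
Rscript inst/cli/mskkit.R gen-model --seed 1 --out model.json
Rscript inst/cli/mskkit.R sweep --model model.json --family gbm \
    --sizes 1e3,1e4,1e5 --out sweep.csv
```

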