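#' Constant parameter block shared by all boosted-tree channels
#'
#' These settings are held fixed across every channel model: the boosting
#' seed, single-threaded serial tree learning on pre-partitioned data, the
#' mean-squared-error training metric, early stopping after 200 stagnant
#' validation rounds, and 0.8 bagging/feature subsampling fractions.
#'
#' @return named list of fixed parameters.
#' @export
gbm_fixed_params <- function() {
  list(seed = 2523252L, tree_learner = "serial", pre_partition = TRUE,
       is_unbalance = FALSE, early_stopping_rounds = 200L, metric = "mse",
       bagging_fraction = 0.8, feature_fraction = 0.8)
}

#' Boosted-tree hyperparameters
#'
#' Tunable hyperparameters of one leaf-wise boosted regression-tree channel
#' model. The tuning ranges are: `num_leaves` 20-100, `min_data_in_leaf`
#' 10-100, `max_depth` 1-100; `learning_rate` is searched on (0.01, 0.2].
#' Defaults (31 leaves, 20 samples per leaf, learning rate 0.1, 100 boosting
#' iterations) are the engine defaults used when a channel is not tuned.
#'
#' @param num_leaves maximum leaves per tree.
#' @param min_data_in_leaf minimum samples per leaf.
#' @param max_depth maximum tree depth (split levels).
#' @param learning_rate boosting shrinkage.
#' @param num_iterations maximum boosting rounds (early stopping governs the
#'   effective count when a validation set is supplied).
#' @return object of class `gbm_hyperparams`.
#' @export
gbm_hyperparams <- function(num_leaves = 31L, min_data_in_leaf = 20L,
                            max_depth = 100L, learning_rate = 0.1,
                            num_iterations = 100L) {
  p <- list(num_leaves = as.integer(num_leaves),
            min_data_in_leaf = as.integer(min_data_in_leaf),
            max_depth = as.integer(max_depth),
            learning_rate = as.numeric(learning_rate),
            num_iterations = as.integer(num_iterations))
  stopifnot(p$num_leaves >= 2L, p$min_data_in_leaf >= 1L,
            p$max_depth >= 1L, p$learning_rate > 0, p$num_iterations >= 1L)
  structure(p, class = "gbm_hyperparams")
}

gbm_tuning_ranges <- function() {
  list(num_leaves = c(20L, 100L), min_data_in_leaf = c(10L, 100L),
       max_depth = c(1L, 100L), learning_rate = c(0.01, 0.2))
}

# map the module-surface hyperparameters onto the xgboost engine:
# leaf-wise (lossguide) growth with a leaf cap, min_child_weight acts as the
# minimum samples per leaf under squared loss, bagging/feature fractions map
# to subsample/colsample_bytree, single-thread serial learner.
gbm_engine_params <- function(params, fixed, nthread = 1L) {
  list(objective = "reg:squarederror",
       tree_method = "hist", grow_policy = "lossguide",
       max_leaves = params$num_leaves,
       max_depth = params$max_depth,
       min_child_weight = params$min_data_in_leaf,
       eta = params$learning_rate,
       subsample = fixed$bagging_fraction,
       colsample_bytree = fixed$feature_fraction,
       seed = fixed$seed, nthread = as.integer(nthread))
}

#' Fit one boosted-tree channel
#'
#' Trains a single leaf-wise gradient-boosted regression-tree ensemble
#' mapping the full posture vector to one scalar output channel (one muscle
#' length or one moment-arm component). When a validation set is given,
#' boosting stops once the validation mean-squared error has not improved
#' for `gbm_fixed_params()$early_stopping_rounds` rounds, and predictions
#' use the best round.
#'
#' @param x,y training postures (n x d matrix) and channel targets.
#' @param x_valid,y_valid optional validation data for early stopping.
#' @param params a [gbm_hyperparams()].
#' @param fixed the constant block, see [gbm_fixed_params()].
#' @param nthread engine threads (1 keeps training deterministic).
#' @return object of class `gbm_channel` with the fitted booster, the best
#'   iteration and the staged validation scores (`evaluation_log`).
#' @export
fit_gbm_channel <- function(x, y, x_valid = NULL, y_valid = NULL,
                            params = gbm_hyperparams(),
                            fixed = gbm_fixed_params(), nthread = 1L) {
  stopifnot(inherits(params, "gbm_hyperparams"))
  x <- as.matrix(x)
  if (nrow(x) == 0L || length(y) != nrow(x)) stop("empty or mismatched data")
  if (!all(is.finite(y))) stop("non-finite training targets")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  evals <- list()
  if (!is.null(x_valid)) {
    if (!all(is.finite(y_valid))) stop("non-finite validation targets")
    evals <- list(validation = xgboost::xgb.DMatrix(as.matrix(x_valid),
                                                    label = y_valid,
                                                    nthread = nthread))
  }
  booster <- xgboost::xgb.train(
    params = gbm_engine_params(params, fixed, nthread),
    data = dtrain, nrounds = params$num_iterations, evals = evals,
    early_stopping_rounds = if (length(evals))
      fixed$early_stopping_rounds else NULL,
    verbose = 0)
  at <- xgboost::xgb.attributes(booster)
  best_iter <- if (!is.null(at$best_iteration))
    as.integer(at$best_iteration) else params$num_iterations
  log <- attributes(booster)$evaluation_log
  structure(list(booster = booster, best_iteration = best_iter,
                 evaluation_log = if (!is.null(log)) as.data.frame(log),
                 params = params),
            class = "gbm_channel")
}

#' @export
predict.gbm_channel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  stats::predict(object$booster, newdata,
                 iterationrange = c(1L, object$best_iteration))
}

#' Tune one channel's hyperparameters by Bayesian optimization
#'
#' Searches `num_leaves`, `min_data_in_leaf`, `max_depth` and
#' `learning_rate` (log scale) with a Gaussian-process expected-improvement
#' optimizer, minimizing the validation mean-squared error of a fit on an
#' internal 70/30 train/validation split of the supplied data. The engine
#' defaults are always evaluated first, so the tuned point is never worse
#' than the untuned baseline on the tuning split. Fits during tuning use
#' `num_iterations = 1000` with early stopping.
#'
#' @param x,y channel data (postures and scalar targets).
#' @param seed seed for the split and the optimizer.
#' @param budget total number of hyperparameter evaluations (default 50).
#' @param fixed constant block, see [gbm_fixed_params()].
#' @param nthread engine threads.
#' @return a [gbm_hyperparams()] with attributes `history` (evaluated
#'   points and validation MSE) and `best_mse`.
#' @export
tune_gbm_channel <- function(x, y, seed = 1L, budget = 50L,
                             fixed = gbm_fixed_params(), nthread = 1L) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty tuning data")
  rng <- gbm_tuning_ranges()
  ts <- tuning_split(nrow(x), seed = seed)
  xtr <- x[ts$train, , drop = FALSE]; ytr <- y[ts$train]
  xva <- x[ts$validation, , drop = FALSE]; yva <- y[ts$validation]

  decode <- function(u) {
    gbm_hyperparams(
      num_leaves = round(rng$num_leaves[1] + u[1] * diff(rng$num_leaves)),
      min_data_in_leaf = round(rng$min_data_in_leaf[1] +
                                 u[2] * diff(rng$min_data_in_leaf)),
      max_depth = round(rng$max_depth[1] + u[3] * diff(rng$max_depth)),
      learning_rate = exp(log(rng$learning_rate[1]) +
                            u[4] * diff(log(rng$learning_rate))),
      num_iterations = 1000L)
  }
  history <- list()
  objective <- function(u) {
    p <- decode(u)
    fit <- fit_gbm_channel(xtr, ytr, xva, yva, params = p, fixed = fixed,
                           nthread = nthread)
    mse <- mean((predict(fit, xva) - yva)^2)
    history[[length(history) + 1L]] <<-
      data.frame(num_leaves = p$num_leaves,
                 min_data_in_leaf = p$min_data_in_leaf,
                 max_depth = p$max_depth, learning_rate = p$learning_rate,
                 mse = mse)
    mse
  }
  # engine defaults as the first (baseline) evaluation
  dflt <- gbm_hyperparams()
  u0 <- c((dflt$num_leaves - rng$num_leaves[1]) / diff(rng$num_leaves),
          (dflt$min_data_in_leaf - rng$min_data_in_leaf[1]) /
            diff(rng$min_data_in_leaf),
          (dflt$max_depth - rng$max_depth[1]) / diff(rng$max_depth),
          (log(dflt$learning_rate) - log(rng$learning_rate[1])) /
            diff(log(rng$learning_rate)))
  res <- bayes_opt(objective, d = 4L, budget = budget, seed = seed,
                   init_x01 = matrix(pmin(pmax(u0, 0), 1), 1))
  out <- decode(res$x)
  attr(out, "history") <- do.call(rbind, history)
  attr(out, "best_mse") <- res$value
  out
}

#' Train boosted-tree surrogates for every output channel
#'
#' Fits one boosted-tree ensemble per output channel: one per muscle length
#' and one per moment-arm component (132 ensembles for the default
#' 33-muscle/99-channel model). Channels may be restricted to a muscle
#' subset; moment-arm channels of a muscle follow its spanned-DOF order.
#'
#' @param dataset an `msk_dataset`.
#' @param split an `msk_split` (train rows fit the trees, validation rows
#'   drive early stopping, test rows are never touched).
#' @param muscles integer muscle indices to train (default all).
#' @param blocks which target blocks to train.
#' @param params a [gbm_hyperparams()] shared by all channels, or `NULL`
#'   with `tune = TRUE`.
#' @param tune if `TRUE`, tune each channel with [tune_gbm_channel()] on its
#'   training rows before the final fit.
#' @param tune_budget evaluations per channel when tuning.
#' @param seed tuning seed.
#' @param nthread engine threads.
#' @param verbose print one line per channel.
#' @return object of class `msk_gbm` holding the per-channel ensembles,
#'   channel metadata and (when tuned) per-channel hyperparameters.
#' @export
train_gbm <- function(dataset, split, muscles = NULL,
                      blocks = c("lengths", "moment_arms"),
                      params = gbm_hyperparams(), tune = FALSE,
                      tune_budget = 50L, seed = 1L, nthread = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(dataset, "msk_dataset"), inherits(split, "msk_split"))
  blocks <- match.arg(blocks, several.ok = TRUE)
  nm <- ncol(dataset$lengths)
  if (is.null(muscles)) muscles <- seq_len(nm)
  ch_names <- colnames(dataset$moment_arms)
  ch_muscle <- ma_channel_muscle(ch_names, colnames(dataset$lengths))
  channels <- which(ch_muscle %in% muscles)

  xtr <- dataset$postures[split$train, , drop = FALSE]
  xva <- dataset$postures[split$validation, , drop = FALSE]

  fit_one <- function(y, label) {
    p <- params
    if (tune) {
      p <- tune_gbm_channel(xtr, y[split$train], seed = seed,
                            budget = tune_budget, nthread = nthread)
      p$num_iterations <- 1000L
    }
    fit <- fit_gbm_channel(xtr, y[split$train], xva, y[split$validation],
                           params = p, nthread = nthread)
    if (verbose)
      msg_stage("train-gbm", label, ": best iteration ", fit$best_iteration)
    fit
  }

  length_models <- NULL
  if ("lengths" %in% blocks)
    length_models <- lapply(muscles, function(i)
      fit_one(dataset$lengths[, i], colnames(dataset$lengths)[i]))
  ma_models <- NULL
  if ("moment_arms" %in% blocks)
    ma_models <- lapply(channels, function(c)
      fit_one(dataset$moment_arms[, c], ch_names[c]))

  structure(list(length_models = length_models, ma_models = ma_models,
                 muscles = muscles, channels = channels,
                 length_names = colnames(dataset$lengths)[muscles],
                 ma_names = ch_names[channels],
                 model_id = dataset$provenance$model_id,
                 tuned = tune, seed = as.integer(seed)),
            class = "msk_gbm")
}

# recover the owning muscle index of each moment-arm channel from the
# canonical "<muscle>@<joint>" channel names
ma_channel_muscle <- function(ch_names, muscle_names) {
  owner <- sub("@.*$", "", ch_names)
  match(owner, muscle_names)
}

#' Predict lengths and moment arms with a boosted-tree surrogate
#'
#' @param object an `msk_gbm` from [train_gbm()].
#' @param postures posture matrix (n x n_joints); n = 0 gives empty outputs.
#' @param ... ignored.
#' @return list with matrices `lengths` (n x muscles trained) and
#'   `moment_arms` (n x channels trained), in canonical channel order;
#'   `NULL` for an untrained block.
#' @export
predict.msk_gbm <- function(object, postures, ...) {
  postures <- as.matrix(postures)
  pred_block <- function(models, nms) {
    if (is.null(models)) return(NULL)
    out <- matrix(NA_real_, nrow(postures), length(models),
                  dimnames = list(NULL, nms))
    if (nrow(postures) > 0L)
      for (j in seq_along(models)) out[, j] <- predict(models[[j]], postures)
    out
  }
  list(lengths = pred_block(object$length_models, object$length_names),
       moment_arms = pred_block(object$ma_models, object$ma_names))
}

#' Save / load a boosted-tree surrogate bundle
#'
#' The bundle is a directory with one serialized ensemble per channel plus a
#' JSON manifest recording channel order, hyperparameters and seeds.
#'
#' @param surrogate an `msk_gbm`.
#' @param dir bundle directory.
#' @return `load_gbm` returns the `msk_gbm`; `save_gbm` returns `dir`
#'   invisibly.
#' @export
save_gbm <- function(surrogate, dir) {
  stopifnot(inherits(surrogate, "msk_gbm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(format = "mskSurrogate-gbm", model_id = surrogate$model_id,
                   muscles = surrogate$muscles, channels = surrogate$channels,
                   length_names = surrogate$length_names,
                   ma_names = surrogate$ma_names,
                   tuned = surrogate$tuned, seed = surrogate$seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  saveRDS(surrogate, file.path(dir, "ensembles.rds"), version = 2)
  invisible(dir)
}

#' @rdname save_gbm
#' @export
load_gbm <- function(dir) {
  s <- readRDS(file.path(dir, "ensembles.rds"))
  stopifnot(inherits(s, "msk_gbm"))
  s
}
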