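#' Configuration of a fully connected surrogate network
#'
#' Architecture and training protocol of the multilayer perceptron
#' surrogates. The reference architectures are `c(18, 1024, 512, 33)` for
#' the 33 muscle lengths and `c(18, 2048, 1024, 99)` for the 99 moment
#' arms; hidden widths may be reduced proportionally for desk-scale runs.
#' Hidden layers use ReLU activations; the output layer is affine and the
#' targets are standardized per channel (zero mean, unit variance on the
#' training rows), de-standardized at prediction, so that signed moment
#' arms are representable.
#'
#' Training minimizes the worst-percentile cost ([percentile_cost()], by
#' default the mean of the largest 30% of pooled absolute errors) by Adam
#' on mini-batches of 256 samples. The learning rate starts at 0.001 and is
#' multiplied by 0.8 whenever the validation cost has failed to improve by
#' more than `min_delta` for `lr_patience` consecutive epochs; the returned
#' network is the best-validation-cost snapshot. Dropout on hidden layers
#' and input standardization are available but off by default.
#'
#' @param layer_sizes integer vector of layer widths, input first, output
#'   last (at least one hidden layer).
#' @param batch_size mini-batch size.
#' @param lr_init initial learning rate.
#' @param lr_decay_factor multiplicative decay on plateau (0.8 = reduce by
#'   20%).
#' @param lr_patience plateau length in epochs before a decay.
#' @param loss_percentile upper error fraction (%) averaged by the cost;
#'   100 recovers the plain mean error.
#' @param loss_kind elementwise error inside the cost: absolute or squared.
#' @param loss_per_channel apply the percentile cut within each channel
#'   instead of pooling the block (see [percentile_cost()]).
#' @param max_epochs training epoch budget.
#' @param seed seed for initialization and batch shuffling.
#' @param dropout hidden-unit drop probability (0 disables).
#' @param input_norm standardize inputs with training-set statistics.
#' @param min_delta minimum validation-cost decrease that counts as an
#'   improvement.
#' @return object of class `ann_config`.
#' @export
ann_config <- function(layer_sizes, batch_size = 256L, lr_init = 1e-3,
                       lr_decay_factor = 0.8, lr_patience = 2L,
                       loss_percentile = 30, loss_kind = c("abs", "squared"),
                       loss_per_channel = FALSE,
                       max_epochs = 500L, seed = 1L, dropout = 0,
                       input_norm = FALSE, min_delta = 1e-6) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L),
            batch_size >= 1L, lr_init > 0,
            lr_decay_factor > 0, lr_decay_factor < 1,
            loss_percentile > 0, loss_percentile <= 100,
            dropout >= 0, dropout < 1)
  structure(list(layer_sizes = layer_sizes,
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 loss_percentile = loss_percentile,
                 loss_kind = match.arg(loss_kind),
                 loss_per_channel = isTRUE(loss_per_channel),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), dropout = dropout,
                 input_norm = isTRUE(input_norm), min_delta = min_delta),
            class = "ann_config")
}

#' Xavier (Glorot) weight initialization
#'
#' Each layer's weights are drawn from a zero-mean normal distribution with
#' variance `2 / (n_in + n_out)`; biases start at zero.
#'
#' @param layer_sizes integer vector of layer widths.
#' @param seed seed.
#' @return list of layers, each a list with matrix `W` (n_in x n_out) and
#'   vector `b`.
#' @export
init_ann_weights <- function(layer_sizes, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  lapply(seq_len(length(layer_sizes) - 1L), function(l) {
    n_in <- layer_sizes[l]; n_out <- layer_sizes[l + 1L]
    list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))),
                    n_in, n_out),
         b = numeric(n_out))
  })
}

# flat parameter vector layout: [W1, b1, W2, b2, ...], column-major W
flatten_weights <- function(weights) {
  unlist(lapply(weights, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

unflatten_weights <- function(theta, layer_sizes) {
  out <- vector("list", length(layer_sizes) - 1L)
  off <- 0L
  for (l in seq_along(out)) {
    n_in <- layer_sizes[l]; n_out <- layer_sizes[l + 1L]
    W <- matrix(theta[off + seq_len(n_in * n_out)], n_in, n_out)
    off <- off + n_in * n_out
    b <- theta[off + seq_len(n_out)]
    off <- off + n_out
    out[[l]] <- list(W = W, b = b)
  }
  out
}

# forward pass keeping pre-activation masks for backprop; drop_masks is an
# optional list of inverted-dropout masks per hidden layer
ann_forward_cache <- function(weights, X, drop_masks = NULL) {
  L <- length(weights)
  acts <- vector("list", L + 1L)
  relu <- vector("list", L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    A <- sweep(acts[[l]] %*% weights[[l]]$W, 2, weights[[l]]$b, `+`)
    if (l < L) {
      relu[[l]] <- A > 0
      A <- A * relu[[l]]
      if (!is.null(drop_masks)) A <- A * drop_masks[[l]]
    }
    acts[[l + 1L]] <- A
  }
  list(acts = acts, relu = relu, output = acts[[L + 1L]])
}

#' Forward pass of a surrogate network
#'
#' Affine-plus-ReLU on hidden layers, affine identity output.
#'
#' @param weights layer list from [init_ann_weights()].
#' @param X input matrix (n x layer_sizes\[1\]).
#' @return output matrix (n x last layer width).
#' @export
ann_forward <- function(weights, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(weights[[1L]]$W))
    stop("input width (", ncol(X), ") does not match layer 1 (",
         nrow(weights[[1L]]$W), ")")
  ann_forward_cache(weights, X)$output
}

#' Worst-percentile regression cost
#'
#' Pools the elementwise prediction errors over the whole batch-by-channel
#' grid, keeps the largest `upper_fraction` percent of them (ties at the
#' cutoff are all included), and returns their mean. With
#' `upper_fraction = 100` this is the ordinary mean error. This cost focuses
#' training on the worst-approximated posture/channel pairs.
#'
#' @param predictions,targets matrices of equal shape (or vectors).
#' @param upper_fraction percentage of largest errors to average (default
#'   30).
#' @param kind elementwise error: `"abs"` (default) or `"squared"`.
#' @param per_channel if `TRUE`, take the worst `upper_fraction` percent
#'   within each channel (column) separately and average the per-channel
#'   costs, instead of pooling all errors before the cut.
#' @return scalar cost.
#' @examples
#' percentile_cost(rep(0, 10), -(1:10), upper_fraction = 30) # mean(8,9,10)
#' @export
percentile_cost <- function(predictions, targets, upper_fraction = 30,
                            kind = c("abs", "squared"),
                            per_channel = FALSE) {
  kind <- match.arg(kind)
  if (length(predictions) == 0L) stop("empty batch")
  if (length(predictions) != length(targets)) stop("shape mismatch")
  if (upper_fraction <= 0 || upper_fraction > 100)
    stop("upper_fraction must be in (0, 100]")
  top_mean <- function(e) {
    k <- max(1L, ceiling(upper_fraction / 100 * length(e)))
    cut <- sort(e, decreasing = TRUE)[k]
    mean(e[e >= cut])
  }
  e <- abs(predictions - targets)
  if (kind == "squared") e <- e^2
  if (per_channel && !is.null(dim(e)))
    mean(apply(e, 2, top_mean))
  else top_mean(as.numeric(e))
}

# cost and gradient w.r.t. predictions (subgradient at ties/kinks)
percentile_cost_grad <- function(pred, targ, upper_fraction, kind,
                                 per_channel = FALSE) {
  d <- pred - targ
  e <- abs(d)
  if (kind == "squared") e <- e^2
  if (per_channel) {
    m <- ncol(pred)
    k <- max(1L, ceiling(upper_fraction / 100 * nrow(pred)))
    sel <- apply(e, 2, function(col) col >= sort(col, decreasing = TRUE)[k])
    K <- colSums(sel)
    w <- sweep(sel, 2, m * K, `/`)   # d cost / d e, averaged over channels
    cost <- mean(colSums(e * sel) / K)
  } else {
    k <- max(1L, ceiling(upper_fraction / 100 * length(e)))
    cut <- sort(e, decreasing = TRUE)[k]
    sel <- e >= cut
    w <- sel / sum(sel)
    cost <- sum(e[sel]) / sum(sel)
  }
  g <- if (kind == "abs") sign(d) * w else 2 * d * w
  list(cost = cost, grad = matrix(g, nrow(pred), ncol(pred)))
}

# full backward pass; returns cost and per-layer gradients. The plain
# pooled-percentile case (no dropout) runs through the compiled kernel;
# dropout and the per-channel cut use the reference R path.
ann_cost_and_grad <- function(weights, X, Y, upper_fraction = 30,
                              kind = "abs", drop_masks = NULL,
                              per_channel = FALSE) {
  if (is.null(drop_masks) && !per_channel) {
    res <- .ann_cost_grad_cpp(lapply(weights, `[[`, "W"),
                              lapply(weights, `[[`, "b"),
                              X, Y, upper_fraction, kind == "squared")
    grads <- lapply(seq_along(weights), function(l)
      list(W = res$gW[[l]], b = as.numeric(res$gb[[l]])))
    return(list(cost = res$cost, grads = grads))
  }
  fw <- ann_forward_cache(weights, X, drop_masks)
  cg <- percentile_cost_grad(fw$output, Y, upper_fraction, kind, per_channel)
  L <- length(weights)
  grads <- vector("list", L)
  delta <- cg$grad
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(fw$acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- tcrossprod(delta, weights[[l]]$W) * fw$relu[[l - 1L]]
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[l - 1L]]
    }
  }
  list(cost = cg$cost, grads = grads)
}

#' Train a surrogate network on one target block
#'
#' Trains the multilayer perceptron mapping postures to either all muscle
#' lengths or all moment-arm channels, following the protocol in
#' [ann_config()]: standardized targets, mini-batch Adam on the
#' worst-percentile cost, plateau learning-rate decay, best-validation
#' snapshot restore. Training aborts with a diagnostic if the cost becomes
#' non-finite.
#'
#' @param config an [ann_config()]; its output width must match the chosen
#'   block.
#' @param dataset an `msk_dataset`.
#' @param split an `msk_split`; training rows fit the weights, validation
#'   rows drive the schedule and snapshot, test rows are never touched.
#' @param block target block to learn.
#' @param norms optional [compute_normalization()] constants; when given,
#'   the trace additionally records range-/maximum-normalized mean errors
#'   (%) on the validation rows and on an equally sized training subsample,
#'   which is what [overfit_monitor()] inspects.
#' @param verbose print one line per epoch.
#' @return object of class `msk_ann`: best weights, standardization
#'   constants, config, and a `trace` data.frame with per-epoch training
#'   cost, validation cost, learning rate and (with `norms`) the
#'   train/validation error gap.
#' @export
train_ann <- function(config, dataset, split,
                      block = c("lengths", "moment_arms"), norms = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "ann_config"), inherits(dataset, "msk_dataset"),
            inherits(split, "msk_split"))
  block <- match.arg(block)
  X <- dataset$postures
  Y <- dataset[[block]]
  if (ncol(X) != config$layer_sizes[1L])
    stop("input layer width must equal the posture dimension")
  if (ncol(Y) != config$layer_sizes[length(config$layer_sizes)])
    stop("output layer width must equal the number of ", block, " channels")

  itr <- split$train; iva <- split$validation
  mu_y <- colMeans(Y[itr, , drop = FALSE])
  sd_y <- apply(Y[itr, , drop = FALSE], 2, stats::sd)
  sd_y[!is.finite(sd_y) | sd_y == 0] <- 1
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, `/`)
  mu_x <- rep(0, ncol(X)); sd_x <- rep(1, ncol(X))
  if (config$input_norm) {
    mu_x <- colMeans(X[itr, , drop = FALSE])
    sd_x <- apply(X[itr, , drop = FALSE], 2, stats::sd)
    sd_x[!is.finite(sd_x) | sd_x == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, `/`)

  # denominators for normalized-% trace columns
  denom <- NULL
  if (!is.null(norms))
    denom <- if (block == "lengths") norms$Lmax - norms$Lmin else norms$Mmax

  weights <- init_ann_weights(config$layer_sizes, seed = config$seed)
  L <- length(weights)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  lr <- config$lr_init
  q <- config$loss_percentile
  bs <- config$batch_size
  fused <- config$dropout == 0 && !config$loss_per_channel
  if (fused) {
    theta <- flatten_weights(weights)
    mvec <- numeric(length(theta))
    vvec <- numeric(length(theta))
  } else {
    adam <- lapply(weights, function(w)
      list(mW = w$W * 0, vW = w$W * 0, mb = w$b * 0, vb = w$b * 0))
  }

  old <- local_seed(config$seed + 1L)
  on.exit(restore_seed(old), add = TRUE)

  val_chunked <- function(W, idx) {
    pred <- predict_std(W, Xs[idx, , drop = FALSE])
    percentile_cost(pred, Ys[idx, , drop = FALSE], q, config$loss_kind,
                    per_channel = config$loss_per_channel)
  }
  predict_std <- function(W, x) ann_forward_cache(W, x)$output
  norm_err_pct <- function(W, idx) {
    p <- predict_std(W, Xs[idx, , drop = FALSE])
    p <- sweep(sweep(p, 2, sd_y, `*`), 2, mu_y, `+`)
    err <- abs(p - Y[idx, , drop = FALSE])
    100 * mean(colMeans(err) / denom)
  }

  best_val <- Inf; best_weights <- weights; stagnant <- 0L
  trace <- NULL
  tr_probe <- itr[seq_len(min(length(itr), length(iva)))]
  n_batches <- max(1L, length(itr) %/% bs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(itr)
    if (fused) {
      res <- .ann_adam_epoch_cpp(theta, mvec, vvec, Xs, Ys,
                                 ord - 1L, bs, t_step, lr, q,
                                 config$loss_kind == "squared",
                                 beta1, beta2, eps, config$layer_sizes)
      if (res$diverged)
        stop("training diverged: non-finite cost at epoch ", epoch,
             ", batch ", res$at_batch)
      batch_costs <- res$costs
      t_step <- res$t
      weights <- unflatten_weights(theta, config$layer_sizes)
    } else {
      batch_costs <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        ii <- ord[((b - 1L) * bs + 1L):min(b * bs, length(ord))]
        drop_masks <- NULL
        if (config$dropout > 0) {
          drop_masks <- lapply(seq_len(L - 1L), function(l)
            matrix(stats::rbinom(length(ii) * config$layer_sizes[l + 1L], 1L,
                                 1 - config$dropout) / (1 - config$dropout),
                   length(ii), config$layer_sizes[l + 1L]))
        }
        cg <- ann_cost_and_grad(weights, Xs[ii, , drop = FALSE],
                                Ys[ii, , drop = FALSE], q, config$loss_kind,
                                drop_masks, config$loss_per_channel)
        if (!is.finite(cg$cost))
          stop("training diverged: non-finite cost at epoch ", epoch,
               ", batch ", b)
        batch_costs[b] <- cg$cost
        t_step <- t_step + 1L
        c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
        for (l in seq_len(L)) {
          a <- adam[[l]]; g <- cg$grads[[l]]
          a$mW <- beta1 * a$mW + (1 - beta1) * g$W
          a$vW <- beta2 * a$vW + (1 - beta2) * g$W^2
          a$mb <- beta1 * a$mb + (1 - beta1) * g$b
          a$vb <- beta2 * a$vb + (1 - beta2) * g$b^2
          weights[[l]]$W <- weights[[l]]$W -
            lr * (a$mW / c1) / (sqrt(a$vW / c2) + eps)
          weights[[l]]$b <- weights[[l]]$b -
            lr * (a$mb / c1) / (sqrt(a$vb / c2) + eps)
          adam[[l]] <- a
        }
      }
    }
    val_cost <- val_chunked(weights, iva)
    if (!is.finite(val_cost))
      stop("training diverged: non-finite validation cost at epoch ", epoch)
    row <- data.frame(epoch = epoch, lr = lr,
                      train_cost = mean(batch_costs), val_cost = val_cost)
    if (!is.null(denom)) {
      row$train_err_pct <- norm_err_pct(weights, tr_probe)
      row$val_err_pct <- norm_err_pct(weights, iva)
      row$gap_pct <- abs(row$train_err_pct - row$val_err_pct)
    }
    trace <- rbind(trace, row)
    if (verbose)
      msg_stage("train-ann", sprintf(
        "epoch %d lr %.2e train %.4f val %.4f", epoch, lr,
        row$train_cost, val_cost))
    if (val_cost < best_val - config$min_delta) {
      best_val <- val_cost; best_weights <- weights; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= config$lr_patience) {
        lr <- lr * config$lr_decay_factor
        stagnant <- 0L
      }
    }
  }

  structure(list(weights = best_weights, config = config, block = block,
                 mu_y = mu_y, sd_y = sd_y, mu_x = mu_x, sd_x = sd_x,
                 channel_names = colnames(Y), best_val_cost = best_val,
                 trace = trace,
                 model_id = dataset$provenance$model_id),
            class = "msk_ann")
}

#' Predict with a trained surrogate network
#'
#' @param object an `msk_ann` from [train_ann()].
#' @param postures posture matrix (n x n_joints).
#' @param ... ignored.
#' @return n x channels matrix on the original target scale (mm or mm/rad).
#' @export
predict.msk_ann <- function(object, postures, ...) {
  postures <- as.matrix(postures)
  if (nrow(postures) == 0L)
    return(matrix(numeric(0), 0L, length(object$mu_y),
                  dimnames = list(NULL, object$channel_names)))
  x <- sweep(sweep(postures, 2, object$mu_x), 2, object$sd_x, `/`)
  p <- ann_forward(object$weights, x)
  p <- sweep(sweep(p, 2, object$sd_y, `*`), 2, object$mu_y, `+`)
  colnames(p) <- object$channel_names
  p
}

#' Overfitting monitor
#'
#' Reports the per-epoch gap between the training and held-out error series
#' of a training trace and flags sustained divergence: a gap above
#' `threshold` (percentage points when the trace carries normalized errors)
#' that persists through the last `sustain` or more epochs. Large transient
#' gaps early in training, before both error series settle, do not raise
#' the flag.
#'
#' @param trace a `trace` data.frame from [train_ann()] (or an `msk_ann`),
#'   using columns `train_err_pct`/`val_err_pct` when present and the raw
#'   costs otherwise.
#' @param threshold gap threshold (default 0.4).
#' @param sustain consecutive epochs required to raise the flag.
#' @return list with `flag`, the `gap` series, and `worst` (largest gap).
#' @export
overfit_monitor <- function(trace, threshold = 0.4, sustain = 3L) {
  if (inherits(trace, "msk_ann")) trace <- trace$trace
  if (is.null(trace) || nrow(trace) == 0L) stop("empty training trace")
  gap <- if (all(c("train_err_pct", "val_err_pct") %in% names(trace)))
    abs(trace$train_err_pct - trace$val_err_pct)
  else abs(trace$train_cost - trace$val_cost)
  over <- gap > threshold
  r <- rle(over)
  last <- length(r$values)
  flag <- r$values[last] && r$lengths[last] >= sustain
  list(flag = flag, gap = gap, worst = max(gap))
}

#' Save / load a network checkpoint
#'
#' Portable checkpoint holding layer shapes, weights, standardization
#' constants, configuration and seed.
#'
#' @param ann an `msk_ann`.
#' @param path checkpoint file (`.rds`).
#' @return `load_ann` returns the `msk_ann`; `save_ann` returns `path`
#'   invisibly.
#' @export
save_ann <- function(ann, path) {
  stopifnot(inherits(ann, "msk_ann"))
  saveRDS(ann, path, version = 2)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  a <- readRDS(path)
  stopifnot(inherits(a, "msk_ann"))
  a
}
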