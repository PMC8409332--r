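test_that("Xavier initialization has the prescribed variance", {
  w <- init_ann_weights(c(18L, 1024L), seed = 2)
  expect_equal(stats::var(as.numeric(w[[1]]$W)), 2 / (18 + 1024),
               tolerance = 0.05)
  se <- sqrt(2 / (18 + 1024)) / sqrt(length(w[[1]]$W))
  expect_lt(abs(mean(w[[1]]$W)), 3 * se)
  expect_equal(w[[1]]$b, numeric(1024))
  expect_identical(init_ann_weights(c(4L, 8L, 2L), seed = 7),
                   init_ann_weights(c(4L, 8L, 2L), seed = 7))
})

test_that("forward pass matches hand and per-neuron computation", {
  # zero weights -> zero output
  w0 <- init_ann_weights(c(2L, 3L, 1L), seed = 1)
  w0 <- lapply(w0, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(as.numeric(ann_forward(w0, matrix(c(1, 2), 1))), 0)
  # single hidden unit, hand-set weights: relu(2x - 1) * 3 + 0.5
  w <- list(list(W = matrix(2, 1, 1), b = -1),
            list(W = matrix(3, 1, 1), b = 0.5))
  expect_equal(as.numeric(ann_forward(w, matrix(c(0, 1, 2)))),
               c(0.5, 3.5, 9.5))
  # 3-layer toy net against a naive per-neuron loop oracle
  w3 <- init_ann_weights(c(3L, 4L, 3L, 2L), seed = 9)
  x <- withr::with_seed(10, matrix(rnorm(15), 5, 3))
  naive <- t(apply(x, 1, function(row) {
    a <- row
    for (l in seq_along(w3)) {
      z <- numeric(ncol(w3[[l]]$W))
      for (j in seq_along(z))
        z[j] <- sum(a * w3[[l]]$W[, j]) + w3[[l]]$b[j]
      a <- if (l < length(w3)) pmax(z, 0) else z
    }
    a
  }))
  expect_equal(unname(ann_forward(w3, x)), naive)
  expect_error(ann_forward(w3, matrix(0, 2, 5)), "input width")
})

test_that("percentile cost averages the worst errors", {
  expect_equal(percentile_cost(rep(0, 10), -(1:10), upper_fraction = 30), 9)
  expect_equal(percentile_cost(1:5, 1:5), 0)
  e <- withr::with_seed(3, rnorm(100))
  expect_equal(percentile_cost(e, rep(0, 100), upper_fraction = 100),
               mean(abs(e)))
  # ties at the cutoff are all included
  expect_equal(percentile_cost(c(0, 0, 0, 0), c(1, 1, 1, 2),
                               upper_fraction = 25), 2)
  expect_error(percentile_cost(numeric(0), numeric(0)), "empty")
})

test_that("percentile cost equals brute-force sort-and-average", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(5:400, 1)
      q <- runif(1, 1, 100)
      p <- rnorm(n); t <- rnorm(n)
      e <- sort(abs(p - t), decreasing = TRUE)
      k <- max(1, ceiling(q / 100 * n))
      brute <- mean(e[e >= e[k]])
      expect_equal(percentile_cost(p, t, upper_fraction = q), brute)
    }
  })
})

test_that("per-channel percentile cost averages channelwise worst errors", {
  withr::with_seed(16, {
    p <- matrix(rnorm(60), 20, 3); t <- matrix(rnorm(60), 20, 3)
    brute <- mean(apply(abs(p - t), 2, function(e) {
      s <- sort(e, decreasing = TRUE)
      k <- ceiling(0.3 * length(e))
      mean(e[e >= s[k]])
    }))
    expect_equal(percentile_cost(p, t, 30, per_channel = TRUE), brute)
    # gradient of the per-channel variant also passes a numerical check
    w <- init_ann_weights(c(2L, 4L, 3L), seed = 26)
    x <- matrix(rnorm(12), 6, 2); y <- matrix(rnorm(18), 6, 3)
    cg <- mskSurrogate:::ann_cost_and_grad(w, x, y, 40, "abs",
                                           per_channel = TRUE)
    h <- 1e-6
    wp <- w; wp[[1]]$W[2] <- wp[[1]]$W[2] + h
    wm <- w; wm[[1]]$W[2] <- wm[[1]]$W[2] - h
    num <- (mskSurrogate:::ann_cost_and_grad(wp, x, y, 40, "abs",
                                             per_channel = TRUE)$cost -
              mskSurrogate:::ann_cost_and_grad(wm, x, y, 40, "abs",
                                               per_channel = TRUE)$cost) /
      (2 * h)
    expect_equal(cg$grads[[1]]$W[2], num, tolerance = 1e-4)
  })
})

test_that("percentile cost is monotone in every single error", {
  withr::with_seed(15, {
    p <- rnorm(50); t <- rnorm(50)
    base <- percentile_cost(p, t, 30)
    for (i in sample(50, 10)) {
      p2 <- p
      p2[i] <- t[i] + 2 * (p[i] - t[i]) + sign(p[i] - t[i]) * 0.5
      expect_gte(percentile_cost(p2, t, 30), base)
    }
  })
})

test_that("compiled and reference training paths agree to machine precision", {
  sizes <- c(3L, 8L, 4L, 2L)
  w0 <- init_ann_weights(sizes, seed = 1)
  withr::with_seed(9, {
    n <- 600
    X <- matrix(runif(n * 3, -1, 1), n)
    Y <- cbind(X[, 1] + 0.5 * X[, 2], X[, 3]^2)
    ord <- sample.int(n)
  })
  # one epoch through the fused in-place kernel
  theta <- mskSurrogate:::flatten_weights(w0)
  mv <- numeric(length(theta)); vv <- numeric(length(theta))
  res <- mskSurrogate:::.ann_adam_epoch_cpp(theta, mv, vv, X, Y, ord - 1L,
                                            100L, 0L, 1e-3, 30, FALSE,
                                            0.9, 0.999, 1e-8, sizes)
  expect_false(res$diverged)
  # the same epoch through the reference R path (identity dropout masks
  # force it), with explicit Adam bookkeeping
  w <- w0
  adam <- lapply(w, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                     mb = l$b * 0, vb = l$b * 0))
  masks <- lapply(c(8, 4), function(k) matrix(1, 100, k))
  t_ <- 0
  for (b in 1:6) {
    ii <- ord[((b - 1) * 100 + 1):(b * 100)]
    cg <- mskSurrogate:::ann_cost_and_grad(w, X[ii, ], Y[ii, ], 30, "abs",
                                           drop_masks = masks)
    expect_equal(res$costs[b], cg$cost)
    t_ <- t_ + 1; c1 <- 1 - 0.9^t_; c2 <- 1 - 0.999^t_
    for (l in 1:3) {
      a <- adam[[l]]; g <- cg$grads[[l]]
      a$mW <- 0.9 * a$mW + 0.1 * g$W; a$vW <- 0.999 * a$vW + 0.001 * g$W^2
      a$mb <- 0.9 * a$mb + 0.1 * g$b; a$vb <- 0.999 * a$vb + 0.001 * g$b^2
      w[[l]]$W <- w[[l]]$W - 1e-3 * (a$mW / c1) / (sqrt(a$vW / c2) + 1e-8)
      w[[l]]$b <- w[[l]]$b - 1e-3 * (a$mb / c1) / (sqrt(a$vb / c2) + 1e-8)
      adam[[l]] <- a
    }
  }
  expect_equal(theta, mskSurrogate:::flatten_weights(w), tolerance = 1e-14)
})

test_that("backpropagated gradients match numerical differentiation", {
  w <- init_ann_weights(c(2L, 4L, 3L), seed = 20)
  x <- withr::with_seed(21, matrix(rnorm(12), 6, 2))
  y <- withr::with_seed(22, matrix(rnorm(18), 6, 3))
  cg <- mskSurrogate:::ann_cost_and_grad(w, x, y, upper_fraction = 40,
                                         kind = "abs")
  h <- 1e-6
  for (l in 1:2) {
    for (idx in c(1, 3)) {
      wp <- w; wp[[l]]$W[idx] <- wp[[l]]$W[idx] + h
      wm <- w; wm[[l]]$W[idx] <- wm[[l]]$W[idx] - h
      num <- (mskSurrogate:::ann_cost_and_grad(wp, x, y, 40, "abs")$cost -
                mskSurrogate:::ann_cost_and_grad(wm, x, y, 40, "abs")$cost) /
        (2 * h)
      expect_equal(cg$grads[[l]]$W[idx], num, tolerance = 1e-4)
    }
  }
})

# small shared training run on a linear 1-joint target
linear_training_run <- function(max_epochs = 50L, seed = 5L) {
  m <- one_muscle_model(c(10, 4), matrix(c(0L, 1L), 2, 1), lo = -1, hi = 1)
  ds <- generate_dataset(m, 3000, seed = 2)
  sp <- split_dataset(3000, seed = 3)
  no <- compute_normalization(m, 1e4, seed = 4)
  cfg <- ann_config(c(1L, 16L, 8L, 1L), max_epochs = max_epochs, seed = seed)
  net <- train_ann(cfg, ds, sp, block = "lengths", norms = no)
  list(model = m, ds = ds, sp = sp, no = no, net = net)
}

run <- linear_training_run()

test_that("a linearly generated target is recovered to <0.1% error", {
  pred <- predict(run$net, run$ds$postures[run$sp$validation, , drop = FALSE])
  err <- rmse_length(run$ds$lengths[run$sp$validation, , drop = FALSE],
                     pred, run$no)
  expect_lt(err, 0.1)
})

test_that("the learning-rate schedule decays by 20% on plateaus", {
  tr <- run$net$trace
  expect_true(all(diff(tr$lr) <= 1e-15))
  decays <- unique(round(tr$lr / 0.001, 10))
  expect_true(all(abs(sapply(seq_along(decays) - 1, function(k) 0.8^k) -
                        decays) < 1e-10))
  expect_equal(0.001 * 0.8, 8e-4)
})

test_that("training is seed-reproducible end to end", {
  run2 <- linear_training_run(max_epochs = 5L)
  run3 <- linear_training_run(max_epochs = 5L)
  expect_identical(run2$net$weights, run3$net$weights)
  expect_identical(run2$net$trace, run3$net$trace)
})

test_that("the overfitting monitor flags sustained divergence only", {
  mon <- overfit_monitor(run$net, threshold = 0.4)
  expect_false(mon$flag)
  expect_equal(mon$gap,
               abs(run$net$trace$train_err_pct - run$net$trace$val_err_pct))
  fake <- data.frame(epoch = 1:6, lr = 1e-3,
                     train_cost = rep(0.1, 6), val_cost = rep(0.1, 6),
                     train_err_pct = rep(0.2, 6),
                     val_err_pct = c(0.2, 0.2, 1.2, 1.3, 1.4, 1.5))
  expect_true(overfit_monitor(fake, threshold = 0.4)$flag)
  same <- fake; same$val_err_pct <- same$train_err_pct
  m2 <- overfit_monitor(same, threshold = 0.4)
  expect_false(m2$flag)
  expect_equal(m2$gap, rep(0, 6))
})

test_that("network checkpoints round-trip", {
  f <- withr::local_tempfile(fileext = ".rds")
  save_ann(run$net, f)
  net2 <- load_ann(f)
  x <- run$ds$postures[1:5, , drop = FALSE]
  expect_identical(predict(net2, x), predict(run$net, x))
})
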