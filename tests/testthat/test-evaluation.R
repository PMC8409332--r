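make_norms <- function(Lmin, Lmax, Mmax) {
  structure(list(Lmin = Lmin, Lmax = Lmax, Mmax = Mmax,
                 degenerate = rep(FALSE, length(Lmin)),
                 n_probe = 1e4, seed = 1L), class = "msk_norms")
}

test_that("normalized length error matches hand arithmetic", {
  no <- make_norms(0, 10, 1)
  # one muscle, two samples, errors 0 and 1 over range 10 -> 5%
  expect_equal(rmse_length(matrix(c(10, 12)), matrix(c(10, 13)), no), 5)
  expect_equal(rmse_length(matrix(c(10, 12)), matrix(c(10, 12)), no), 0)
})

test_that("normalized moment-arm error matches hand arithmetic", {
  no <- make_norms(0, 1, 10)
  expect_equal(rmse_moment_arm(matrix(5), matrix(4), no), 10)
  expect_equal(rmse_moment_arm(matrix(5), matrix(5), no), 0)
})

test_that("block metrics agree with brute-force double loops", {
  withr::with_seed(30, {
    ref <- matrix(rnorm(15, 100, 10), 5, 3)
    pred <- ref + rnorm(15, 0, 1)
    rng <- c(5, 8, 12); mmax <- c(2, 4, 6)
    no <- make_norms(rep(0, 3), rng, mmax)
    brute_l <- 0
    for (l in 1:3) {
      acc <- 0
      for (i in 1:5) acc <- acc + sqrt(((ref[i, l] - pred[i, l]) / rng[l])^2)
      brute_l <- brute_l + acc / 5
    }
    expect_equal(rmse_length(ref, pred, no), 100 * brute_l / 3,
                 tolerance = 1e-12)
    brute_m <- mean(sapply(1:3, function(l)
      mean(abs(ref[, l] - pred[, l]) / mmax[l])))
    expect_equal(rmse_moment_arm(ref, pred, no), 100 * brute_m,
                 tolerance = 1e-12)
    # rms variant differs once per-sample errors vary
    expect_gt(rmse_length(ref, pred, no, kind = "rms"),
              rmse_length(ref, pred, no))
  })
})

test_that("metrics are zero iff predictions match and ignore permutations", {
  withr::with_seed(31, {
    ref <- matrix(rnorm(40, 50, 5), 10, 4)
    pred <- ref + rnorm(40, 0, 0.5)
    no <- make_norms(rep(0, 4), rep(10, 4), rep(3, 4))
    perm <- c(3, 1, 4, 2)
    no_p <- make_norms(rep(0, 4), rep(10, 4)[perm], rep(3, 4)[perm])
    expect_equal(rmse_length(ref[, perm], pred[, perm], no_p),
                 rmse_length(ref, pred, no))
    expect_equal(rmse_length(ref, ref, no), 0)
    expect_gt(rmse_length(ref, pred, no), 0)
  })
})

test_that("degenerate muscles are excluded with a warning", {
  no <- structure(list(Lmin = c(0, 5), Lmax = c(10, 5), Mmax = c(1, 0),
                       degenerate = c(FALSE, TRUE), n_probe = 1e4,
                       seed = 1L), class = "msk_norms")
  ref <- matrix(1, 4, 2); pred <- ref + 1
  expect_warning(v <- rmse_length(ref, pred, no), "degenerate")
  expect_equal(v, 10)
  expect_warning(rmse_moment_arm(ref, pred, no), "degenerate")
})

test_that("error distributions summarize quartiles correctly", {
  # constant 0.1% error everywhere
  ref <- matrix(0, 10, 2)
  pred <- matrix(0.001, 10, 2)
  d <- error_distribution(ref, pred, denom = c(1, 1))
  expect_equal(d$median, c(0.1, 0.1))
  expect_equal(d$q1, d$q3)
  expect_equal(d$iqr, c(0, 0))
  # errors 1..100 (% units): Q1 = 25.75, Q3 = 75.25 under linear
  # interpolation between order statistics
  d2 <- error_distribution(matrix(0, 100, 1), matrix((1:100) / 100),
                           denom = 1)
  expect_equal(d2$q1, 25.75)
  expect_equal(d2$q3, 75.25)
  # summaries match recomputation from the stored raw errors
  err <- attr(d2, "errors")
  expect_equal(d2$median, unname(apply(err, 2, stats::median)))
  expect_equal(d2$max, unname(apply(err, 2, max)))
})

test_that("extreme postures live in the outer quartiles of each joint", {
  m <- toy2_model()
  x <- extreme_postures(m, 2000, seed = 8)
  for (j in 1:2) {
    lo <- m$joints$theta_min[j]; hi <- m$joints$theta_max[j]
    R <- hi - lo
    inner <- x[, j] > lo + R / 4 & x[, j] < hi - R / 4
    expect_false(any(inner))
    expect_true(all(x[, j] >= lo & x[, j] <= hi))
  }
})

test_that("extreme-posture marginal follows the two-interval uniform law", {
  ramp <- one_muscle_model(1, matrix(1L, 1, 1), lo = 0, hi = 1)
  x <- sort(extreme_postures(ramp, 1e5, seed = 9)[, 1])
  # CDF: u/0.5 mass on [0, 0.25], flat, then symmetric on [0.75, 1]
  cdf <- function(t) ifelse(t < 0.25, 2 * t,
                            ifelse(t < 0.75, 0.5, 0.5 + 2 * (t - 0.75)))
  n <- length(x)
  D <- max(pmax(abs(seq_len(n) / n - cdf(x)),
                abs(cdf(x) - (seq_len(n) - 1) / n)))
  expect_lt(D, 0.01)
})

test_that("a perfect surrogate has zero extreme-posture error", {
  m <- toy2_model()
  no <- compute_normalization(m, 1e4, seed = 10)
  res <- extreme_posture_test(m, m, no, n = 1000, seed = 11)
  expect_equal(res$rmse_length, 0)
  expect_equal(res$rmse_moment_arm, 0)
  expect_error(extreme_posture_test(m, m, no, n = 100), ">= 1000")
})

test_that("latency benchmark records and summarizes raw durations", {
  m <- toy2_model()
  x <- sample_postures(m, 10, seed = 1)
  b <- latency_benchmark(m, x, n_evals = 100)
  expect_equal(b$n_evals, 100L)
  expect_length(b$durations_ms, 100)
  expect_true(all(b$durations_ms > 0))
  expect_equal(b$mean_ms, mean(b$durations_ms))
  expect_equal(b$sd_ms, stats::sd(b$durations_ms))
  expect_error(latency_benchmark(m, x, n_evals = 10), ">= 100")
})

test_that("evaluation reports bundle metrics, summaries and metadata", {
  m <- toy2_model()
  no <- compute_normalization(m, 1e4, seed = 12)
  x <- sample_postures(m, 500, seed = 13)
  rep <- evaluate_surrogate(m, m, x, no, surrogate_id = "reference")
  expect_s3_class(rep, "msk_report")
  expect_equal(rep$rmse_length, 0)
  expect_equal(rep$rmse_moment_arm, 0)
  expect_equal(nrow(rep$ma_summary), 3)
  d <- withr::local_tempdir()
  write_report(rep, d)
  js <- jsonlite::fromJSON(file.path(d, "report.json"))
  expect_equal(js$rmse_length, 0)
  expect_true(file.exists(file.path(d, "moment_arm_errors.csv")))
})
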