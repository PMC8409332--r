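test_that("default generator reproduces the reference structure", {
  m <- build_default_model(seed = 1)
  expect_equal(nrow(m$joints), 18L)
  expect_equal(length(m$muscles), 33L)
  expect_equal(nrow(channel_table(m)), 99L)
  spans <- vapply(m$muscles, function(x) length(x$dofs), 0L)
  expect_true(all(spans <= 6L))
  expect_equal(mean(spans), 3)
  # channel conservation: channels = sum of spanned DOFs
  expect_equal(sum(spans), nrow(channel_table(m)))
})

test_that("model generation is seed-deterministic and configurable", {
  expect_identical(build_default_model(seed = 1), build_default_model(seed = 1))
  expect_false(identical(build_default_model(1), build_default_model(2)))
  cfg <- default_model_config(n_joints = 1L, coupling = c(`1` = 1L),
                              extra_terms_per_dof = 0L)
  m <- build_default_model(seed = 1, config = cfg)
  expect_equal(nrow(channel_table(m)), 1L)
})

test_that("infeasible coupling configurations are rejected", {
  expect_error(build_default_model(1, default_model_config(
    coupling = c(`7` = 33L))), "at most 6")
  expect_error(build_default_model(1, default_model_config(
    n_joints = 3L, coupling = c(`5` = 33L))), "exceeds joint count")
})

test_that("lengths stay positive and finite over the workspace", {
  m <- build_default_model(seed = 3)
  L <- evaluate_length(m, sample_postures(m, 20000, seed = 4))
  expect_true(all(is.finite(L)))
  expect_true(all(L > 0))
})

test_that("length evaluation matches hand computation", {
  expect_equal(as.numeric(evaluate_length(quad_model(), 0.5)), 0.25)
  expect_equal(as.numeric(evaluate_length(const_model(6), 0.3)), 6)
  # 3-term polynomial: 2 + 3*t - 0.5*t^3 at t = 0.7, term-by-term oracle
  m <- one_muscle_model(c(2, 3, -0.5), matrix(c(0L, 1L, 3L), 3, 1))
  t <- 0.7
  expect_equal(as.numeric(evaluate_length(m, t)), 2 + 3 * t - 0.5 * t^3)
  expect_error(evaluate_length(m, c(0.1, 0.2)), "dimension")
})

test_that("out-of-range postures are evaluated but flagged", {
  expect_warning(evaluate_length(quad_model(), 2), "outside")
  expect_silent(evaluate_length(quad_model(), 0.9))
})

test_that("partial derivative follows the power rule", {
  # d/dx1 (2 x1^2 x2) = 4 x1 x2
  d <- polynomial_partial_derivative(poly_terms(2, matrix(c(2L, 1L), 1)), 1)
  expect_equal(d$coef, 4)
  expect_equal(unname(d$expon), matrix(c(1L, 1L), 1))
  # d/dx1 (3 x2) vanishes
  d0 <- polynomial_partial_derivative(poly_terms(3, matrix(c(0L, 1L), 1)), 1)
  expect_length(d0$coef, 0)
  expect_error(polynomial_partial_derivative(poly_terms(1, matrix(0L, 1, 1)), 2),
               "dof_index")
})

test_that("analytic derivatives match finite differences on random polynomials", {
  terms <- random_terms(k = 3, n_terms = 10, seed = 42)
  d1 <- polynomial_partial_derivative(terms, 2)
  pts <- withr::with_seed(43, matrix(runif(60, -1, 1), 20, 3))
  h <- 1e-6
  for (i in 1:20) {
    p <- pts[i, , drop = FALSE]
    pp <- p; pp[2] <- pp[2] + h
    pm <- p; pm[2] <- pm[2] - h
    num <- (mskSurrogate:::eval_poly(terms, pp) -
              mskSurrogate:::eval_poly(terms, pm)) / (2 * h)
    expect_equal(mskSurrogate:::eval_poly(d1, p), num, tolerance = 1e-6)
  }
})

test_that("moment arms follow the sign convention", {
  # L = theta^2: dL/dtheta = 2 theta, MA = -2 theta
  expect_equal(as.numeric(evaluate_moment_arms(quad_model(), 0.5)), -1)
  expect_equal(as.numeric(evaluate_moment_arms(const_model(), 0.2)), 0)
  m <- quad_model()
  m$ma_sign <- 1
  expect_equal(as.numeric(evaluate_moment_arms(m, 0.5)), 1)
})

test_that("channel ordering is muscles-then-spanned-DOFs and stable", {
  m <- build_default_model(seed = 1)
  ch <- channel_table(m)
  expect_equal(ch$channel, seq_len(99))
  expect_true(!is.unsorted(ch$muscle))
  for (i in seq_along(m$muscles))
    expect_equal(ch$dof[ch$muscle == i], m$muscles[[i]]$dofs)
})

test_that("normalization constants recover known extrema", {
  # linear ramp on [0, 1]: Lmin -> 0, Lmax -> 1
  ramp <- one_muscle_model(1, matrix(1L, 1, 1), lo = 0, hi = 1)
  no <- compute_normalization(ramp, n_probe = 1e4, seed = 1)
  expect_equal(no$Lmin, 0, tolerance = 1e-2)
  expect_equal(no$Lmax, 1, tolerance = 1e-2)
  expect_false(no$degenerate)
  # theta^2 on [-1, 1]: Mmax = max |-2 theta| = 2
  no2 <- compute_normalization(quad_model(), n_probe = 1e4, seed = 1)
  expect_equal(no2$Mmax, 2, tolerance = 1e-2)
  expect_warning(compute_normalization(const_model(), n_probe = 1e4),
                 "degenerate")
  expect_error(compute_normalization(quad_model(), n_probe = 100), "1e4")
})

test_that("model JSON serialization round-trips losslessly", {
  m <- build_default_model(seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m[c("joints", "muscles", "seed", "ma_sign")],
                   m2[c("joints", "muscles", "seed", "ma_sign")])
})
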