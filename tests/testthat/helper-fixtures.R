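# Hand-built miniature models used across the suite.

# one joint on [lo, hi], one muscle with the given term set
one_muscle_model <- function(coef, expon, lo = -1, hi = 1) {
  joints <- data.frame(name = "J01", theta_min = lo, theta_max = hi,
                       stringsAsFactors = FALSE)
  msk_model(joints, list(list(name = "MUS", dofs = 1L,
                              terms = poly_terms(coef, expon))))
}

# L(theta) = theta^2 on [-1, 1]
quad_model <- function() one_muscle_model(1, matrix(2L, 1, 1))

# constant-length muscle L = value
const_model <- function(value = 6) one_muscle_model(value, matrix(0L, 1, 1))

# small 2-joint, 2-muscle model with smooth low-order polynomials;
# used where a full default model would be needlessly slow
toy2_model <- function(seed = 11L) {
  cfg <- default_model_config(n_joints = 2L, coupling = c(`1` = 1L, `2` = 1L),
                              extra_terms_per_dof = 2L)
  build_default_model(seed, cfg)
}

# random multivariate term set over k variables (for derivative oracles)
random_terms <- function(k, n_terms, seed) {
  withr::with_seed(seed, {
    pool <- expand.grid(rep(list(0:3), k))
    pool <- as.matrix(pool[rowSums(pool) <= 5, , drop = FALSE])
    storage.mode(pool) <- "integer"
    pick <- sample(nrow(pool), n_terms)
    poly_terms(rnorm(n_terms), pool[pick, , drop = FALSE])
  })
}
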