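#' Polynomial musculoskeletal reference model
#'
#' An `msk_model` describes a limb as a set of rotational degrees of freedom
#' (DOFs) with bounded angle ranges and a set of muscles whose musculotendon
#' length is a multivariate polynomial of the joint angles the muscle spans.
#' The moment arm of a muscle about a spanned joint is the analytic partial
#' derivative of its length with respect to that joint angle, multiplied by a
#' sign convention (default `-1`: a positive moment arm means the muscle
#' shortens as the joint angle increases).
#'
#' Internally a muscle is a list with fields `name`, `dofs` (ordered joint
#' indices, 1 to 6 entries) and `terms`, a term set as returned by
#' [poly_terms()]: a list with a numeric `coef` vector (mm) and an integer
#' exponent matrix `expon` with one row per term and one column per spanned
#' DOF; the total power of every term is at most 5.
#'
#' Moment-arm channels are ordered by muscle declaration order and, within a
#' muscle, by the order of its `dofs` vector. This ordering is fixed and is
#' what every dataset, surrogate and report in the package uses.
#'
#' @param joints data.frame with columns `name`, `theta_min`, `theta_max`
#'   (radians); `theta_min < theta_max` for every joint.
#' @param muscles list of muscle definitions (see Details).
#' @param seed integer seed recorded for provenance (may be `NA` for
#'   hand-built models).
#' @param ma_sign sign convention relating moment arms to the length
#'   gradient; one of `-1` (default) or `1`.
#' @return an object of class `msk_model`.
#' @seealso [build_default_model()], [evaluate_length()],
#'   [evaluate_moment_arms()]
#' @export
msk_model <- function(joints, muscles, seed = NA_integer_, ma_sign = -1) {
  stopifnot(is.data.frame(joints),
            all(c("name", "theta_min", "theta_max") %in% names(joints)))
  if (any(joints$theta_min >= joints$theta_max))
    stop("every joint must satisfy theta_min < theta_max")
  ma_sign <- as.numeric(ma_sign)
  if (!ma_sign %in% c(-1, 1)) stop("ma_sign must be -1 or +1")
  n_joints <- nrow(joints)
  for (mus in muscles) {
    stopifnot(is.list(mus), !is.null(mus$name), !is.null(mus$dofs),
              !is.null(mus$terms))
    d <- mus$dofs
    if (anyDuplicated(d) || any(d < 1L) || any(d > n_joints))
      stop("muscle '", mus$name, "': spanned DOFs must be distinct valid joint indices")
    if (length(d) < 1L || length(d) > 6L)
      stop("muscle '", mus$name, "': must span between 1 and 6 DOFs")
    tt <- mus$terms
    if (length(tt$coef) < 1L)
      stop("muscle '", mus$name, "': needs at least one polynomial term")
    if (ncol(tt$expon) != length(d))
      stop("muscle '", mus$name, "': exponent columns must match spanned DOFs")
    if (any(tt$expon < 0L) || any(rowSums(tt$expon) > 5L))
      stop("muscle '", mus$name, "': term powers must be in 0..5 total")
  }
  structure(list(joints = joints, muscles = muscles,
                 seed = as.integer(seed), ma_sign = ma_sign,
                 version = "1.0"),
            class = "msk_model")
}

#' Construct a polynomial term set
#'
#' @param coef numeric coefficients (mm).
#' @param expon integer matrix of exponents, one row per term, one column per
#'   spanned DOF.
#' @return list with elements `coef` and `expon`.
#' @export
poly_terms <- function(coef, expon) {
  expon <- matrix(as.integer(expon), nrow = length(coef))
  stopifnot(length(coef) == nrow(expon), all(expon >= 0L))
  list(coef = as.numeric(coef), expon = expon)
}

#' Default configuration of the synthetic reference model
#'
#' The defaults emulate the structure of a full arm-and-hand model: 18 DOFs,
#' 33 muscles, and a muscle-to-DOF coupling distribution in which a muscle
#' spans 3 DOFs on average and at most 6 (thumb-like muscles), for a total of
#' 99 moment-arm channels. `coupling` is a named integer vector mapping a
#' spanned-DOF count to the number of muscles with that count; the defaults
#' (11 two-DOF, 15 three-DOF, 4 four-DOF, 2 five-DOF, 1 six-DOF) sum to 33
#' muscles and 99 channels.
#'
#' Coefficient sampling is controlled by `amplitude_range` (per-muscle length
#' excursion scale, mm, drawn log-uniformly), `power_decay` (geometric decay
#' of coefficient magnitude with total term power, keeping high-order terms
#' small and the length surface smooth) and `base_length_range` (constant
#' offset, mm, keeping lengths positive and physiological). Each muscle gets
#' a constant term, all first-order terms in its spanned DOFs (so every
#' channel has a non-vanishing moment arm), and `extra_terms_per_dof` times
#' its DOF count randomly chosen higher-order terms of total power 2 to
#' `max_power`.
#'
#' @param n_joints number of DOFs.
#' @param theta_min,theta_max default joint range (rad), recycled per joint.
#' @param coupling named integer vector, names = spanned-DOF counts.
#' @param max_power maximum total polynomial power.
#' @param extra_terms_per_dof higher-order terms added per spanned DOF.
#' @param amplitude_range,power_decay,base_length_range coefficient-sampling
#'   controls (see Details).
#' @return a configuration list for [build_default_model()].
#' @export
default_model_config <- function(n_joints = 18L,
                                 theta_min = -pi / 2, theta_max = pi / 2,
                                 coupling = c(`2` = 11L, `3` = 15L,
                                              `4` = 4L, `5` = 2L, `6` = 1L),
                                 max_power = 5L,
                                 extra_terms_per_dof = 3L,
                                 amplitude_range = c(2, 50),
                                 power_decay = 0.5,
                                 base_length_range = c(60, 300)) {
  list(n_joints = as.integer(n_joints),
       theta_min = rep_len(theta_min, n_joints),
       theta_max = rep_len(theta_max, n_joints),
       coupling = coupling,
       max_power = as.integer(max_power),
       extra_terms_per_dof = as.integer(extra_terms_per_dof),
       amplitude_range = amplitude_range,
       power_decay = power_decay,
       base_length_range = base_length_range)
}

# all exponent vectors over k variables with total power in 1..max_power
exponent_pool <- function(k, max_power) {
  g <- as.matrix(expand.grid(rep(list(0:max_power), k)))
  storage.mode(g) <- "integer"
  tot <- rowSums(g)
  g[tot >= 1L & tot <= max_power, , drop = FALSE]
}

#' Generate a synthetic polynomial reference model
#'
#' Builds a seeded random `msk_model` with the structure given by `config`
#' (by default 18 joints, 33 muscles, 99 moment-arm channels). Muscle length
#' polynomials are sampled as described in [default_model_config()]; after
#' sampling, the constant term is raised if needed so that the length stays
#' at or above 5 mm over the workspace (checked on a 1000-posture probe).
#'
#' @param seed integer seed; the same seed and configuration always produce a
#'   bitwise-identical model.
#' @param config configuration list, see [default_model_config()].
#' @return an [msk_model()] object.
#' @examples
#' m <- build_default_model(seed = 1)
#' nrow(m$joints)          # 18
#' length(m$muscles)       # 33
#' nrow(channel_table(m))  # 99
#' @export
build_default_model <- function(seed = 1L, config = default_model_config()) {
  cfg <- config
  k_counts <- cfg$coupling
  ks <- as.integer(names(k_counts))
  if (any(is.na(ks)) || any(ks < 1L))
    stop("coupling names must be positive DOF counts")
  if (any(ks > 6L))
    stop("infeasible coupling: muscles may span at most 6 DOFs")
  if (any(ks > cfg$n_joints))
    stop("infeasible coupling: spanned-DOF count exceeds joint count")
  n_muscles <- sum(k_counts)
  n_channels <- sum(ks * k_counts)
  joints <- data.frame(name = sprintf("J%02d", seq_len(cfg$n_joints)),
                       theta_min = cfg$theta_min, theta_max = cfg$theta_max,
                       stringsAsFactors = FALSE)

  spans <- rep(ks, k_counts)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  muscles <- vector("list", n_muscles)
  for (i in seq_len(n_muscles)) {
    k <- spans[i]
    dofs <- sort(sample.int(cfg$n_joints, k))
    pool <- exponent_pool(k, cfg$max_power)
    tot <- rowSums(pool)
    linear <- which(tot == 1L)
    higher <- which(tot >= 2L)
    n_extra <- min(length(higher), cfg$extra_terms_per_dof * k)
    pick <- if (n_extra > 0L) sample(higher, n_extra) else integer(0)
    expon <- rbind(matrix(0L, 1L, k), pool[linear, , drop = FALSE],
                   pool[pick, , drop = FALSE])
    amp <- exp(stats::runif(1, log(cfg$amplitude_range[1]),
                            log(cfg$amplitude_range[2])))
    base <- stats::runif(1, cfg$base_length_range[1], cfg$base_length_range[2])
    coef <- numeric(nrow(expon))
    coef[1] <- base
    # first-order terms: bounded away from zero so every moment-arm channel
    # keeps a physiologically non-vanishing lever
    coef[1 + seq_len(k)] <- sample(c(-1, 1), k, replace = TRUE) *
      amp * stats::runif(k, 0.15, 0.6)
    if (n_extra > 0L) {
      p <- rowSums(expon[-(1:(k + 1L)), , drop = FALSE])
      coef[-(1:(k + 1L))] <- stats::rnorm(n_extra, 0, amp * cfg$power_decay^p)
    }
    muscles[[i]] <- list(name = sprintf("M%02d_%dd", i, k), dofs = dofs,
                         terms = poly_terms(coef, expon))
  }

  # positivity: raise the constant term so a conservative lower bound on
  # the polynomial over the whole workspace (constant minus the summed
  # worst-case magnitude of every non-constant term) stays above 10 mm
  for (i in seq_len(n_muscles)) {
    mus <- muscles[[i]]
    amax <- pmax(abs(joints$theta_min[mus$dofs]),
                 abs(joints$theta_max[mus$dofs]))
    mono_max <- apply(mus$terms$expon, 1, function(e) prod(amax^e))
    bound <- mus$terms$coef[1] -
      sum(abs(mus$terms$coef[-1]) * mono_max[-1])
    if (bound < 10)
      muscles[[i]]$terms$coef[1] <- mus$terms$coef[1] + (10 - bound)
  }
  model <- msk_model(joints, muscles, seed = seed)
  stopifnot(nrow(channel_table(model)) == n_channels)
  model
}

#' Moment-arm channel table
#'
#' Canonical ordering of moment-arm channels: muscles in declaration order,
#' and within a muscle its spanned DOFs in the order stored in `dofs`.
#'
#' @param model an [msk_model()].
#' @return data.frame with columns `channel`, `muscle` (index), `muscle_name`,
#'   `dof` (joint index) and `name` (`"<muscle>@<joint>"`).
#' @export
channel_table <- function(model) {
  stopifnot(inherits(model, "msk_model"))
  rows <- lapply(seq_along(model$muscles), function(i) {
    mus <- model$muscles[[i]]
    data.frame(muscle = i, muscle_name = mus$name, dof = mus$dofs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$channel <- seq_len(nrow(out))
  out$name <- sprintf("%s@%s", out$muscle_name, model$joints$name[out$dof])
  out[, c("channel", "muscle", "muscle_name", "dof", "name")]
}

# evaluate a term set over an n x k matrix of spanned-DOF angles
eval_poly <- function(terms, theta) {
  n <- nrow(theta)
  k <- ncol(terms$expon)
  maxp <- if (length(terms$coef)) max(terms$expon) else 0L
  pw <- vector("list", k)
  for (j in seq_len(k)) {
    m <- matrix(1, n, maxp + 1L)
    if (maxp > 0L) for (p in seq_len(maxp)) m[, p + 1L] <- m[, p] * theta[, j]
    pw[[j]] <- m
  }
  res <- numeric(n)
  for (t in seq_along(terms$coef)) {
    v <- rep(terms$coef[t], n)
    for (j in seq_len(k)) {
      e <- terms$expon[t, j]
      if (e > 0L) v <- v * pw[[j]][, e + 1L]
    }
    res <- res + v
  }
  res
}

as_posture_matrix <- function(model, postures) {
  if (is.null(dim(postures))) postures <- matrix(postures, nrow = 1L)
  postures <- as.matrix(postures)
  if (ncol(postures) != nrow(model$joints))
    stop("posture dimension (", ncol(postures),
         ") does not match joint count (", nrow(model$joints), ")")
  postures
}

check_workspace <- function(model, postures) {
  lo <- model$joints$theta_min
  hi <- model$joints$theta_max
  out <- sweep(postures, 2, lo, `<`) | sweep(postures, 2, hi, `>`)
  if (any(out))
    warning(sum(out), " joint angle(s) outside the modelled workspace",
            call. = FALSE)
  invisible(NULL)
}

#' Evaluate musculotendon lengths at given postures
#'
#' @param model an [msk_model()].
#' @param postures numeric vector (single posture) or n x n_joints matrix of
#'   joint angles (rad). Angles outside a joint's range are evaluated but
#'   flagged with a warning.
#' @return n x n_muscles matrix of lengths (mm), columns named by muscle.
#' @export
evaluate_length <- function(model, postures) {
  stopifnot(inherits(model, "msk_model"))
  postures <- as_posture_matrix(model, postures)
  check_workspace(model, postures)
  out <- matrix(NA_real_, nrow(postures), length(model$muscles),
                dimnames = list(NULL, vapply(model$muscles, `[[`, "", "name")))
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    out[, i] <- eval_poly(mus$terms, postures[, mus$dofs, drop = FALSE])
  }
  out
}

#' Differentiate a polynomial term set
#'
#' Applies the power rule to every term with respect to one spanned DOF;
#' terms with a zero exponent in that DOF vanish from the result.
#'
#' @param terms a term set from [poly_terms()].
#' @param dof_index column index (within the term set) of the variable to
#'   differentiate by.
#' @return a term set (possibly with zero terms).
#' @examples
#' # d/dx1 of 2 * x1^2 * x2  ->  4 * x1 * x2
#' t <- poly_terms(2, matrix(c(2L, 1L), 1))
#' polynomial_partial_derivative(t, 1)
#' @export
polynomial_partial_derivative <- function(terms, dof_index) {
  k <- ncol(terms$expon)
  if (length(dof_index) != 1L || dof_index < 1L || dof_index > k)
    stop("dof_index must be a single index in 1..", k)
  e <- terms$expon[, dof_index]
  keep <- which(e > 0L)
  coef <- terms$coef[keep] * e[keep]
  expon <- terms$expon[keep, , drop = FALSE]
  expon[, dof_index] <- expon[, dof_index] - 1L
  poly_terms(coef, expon)
}

# derivative term sets for every channel, in canonical channel order
model_derivatives <- function(model) {
  out <- list()
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    for (j in seq_along(mus$dofs)) {
      out[[length(out) + 1L]] <-
        list(muscle = i, terms = polynomial_partial_derivative(mus$terms, j))
    }
  }
  out
}

#' Evaluate moment arms at given postures
#'
#' The moment arm of muscle l about spanned joint j is
#' `ma_sign * dL_l/dtheta_j`, evaluated analytically from the length
#' polynomial (default sign `-1`: a positive moment arm means the muscle
#' shortens as the joint angle increases). Channels are ordered as in
#' [channel_table()].
#'
#' @inheritParams evaluate_length
#' @return n x n_channels matrix of moment arms (mm/rad), columns named
#'   `"<muscle>@<joint>"`.
#' @export
evaluate_moment_arms <- function(model, postures) {
  stopifnot(inherits(model, "msk_model"))
  postures <- as_posture_matrix(model, postures)
  check_workspace(model, postures)
  der <- model_derivatives(model)
  ch <- channel_table(model)
  out <- matrix(NA_real_, nrow(postures), length(der),
                dimnames = list(NULL, ch$name))
  for (c in seq_along(der)) {
    mus <- model$muscles[[der[[c]]$muscle]]
    out[, c] <- model$ma_sign *
      eval_poly(der[[c]]$terms, postures[, mus$dofs, drop = FALSE])
  }
  out
}

#' Predict method for the reference model
#'
#' Makes the reference model itself satisfy the surrogate prediction
#' contract (useful as a perfect-surrogate control in evaluations).
#'
#' @param object an [msk_model()].
#' @param postures posture matrix.
#' @param ... ignored.
#' @return list with matrices `lengths` and `moment_arms`.
#' @export
predict.msk_model <- function(object, postures, ...) {
  list(lengths = evaluate_length(object, postures),
       moment_arms = evaluate_moment_arms(object, postures))
}

#' Estimate normalization constants by workspace sampling
#'
#' Estimates, by dense uniform sampling of the workspace, the per-muscle
#' length extrema `Lmin`/`Lmax` (whose difference is the length range used to
#' normalize length errors) and the per-channel maximum absolute moment arm
#' `Mmax` used to normalize moment-arm errors.
#'
#' @param model an [msk_model()].
#' @param n_probe number of probe postures (at least 1e4; default 1e5).
#' @param seed probe-sampling seed.
#' @return object of class `msk_norms`: list with `Lmin`, `Lmax`, `Mmax`,
#'   logical `degenerate` (muscles with numerically zero length range, for
#'   which the normalized length metric is undefined), `n_probe` and `seed`.
#' @export
compute_normalization <- function(model, n_probe = 1e5, seed = 1L) {
  stopifnot(inherits(model, "msk_model"))
  if (n_probe < 1e4) stop("n_probe must be at least 1e4")
  n_probe <- as.integer(n_probe)
  nm <- length(model$muscles)
  nc <- nrow(channel_table(model))
  Lmin <- rep(Inf, nm); Lmax <- rep(-Inf, nm); Mmax <- rep(0, nc)
  chunk <- 100000L
  done <- 0L
  while (done < n_probe) {
    nb <- min(chunk, n_probe - done)
    x <- sample_postures(model, nb, seed = seed + done)
    L <- evaluate_length(model, x)
    A <- evaluate_moment_arms(model, x)
    Lmin <- pmin(Lmin, apply(L, 2, min))
    Lmax <- pmax(Lmax, apply(L, 2, max))
    Mmax <- pmax(Mmax, apply(abs(A), 2, max))
    done <- done + nb
  }
  degenerate <- (Lmax - Lmin) <= 1e-9 * pmax(1, abs(Lmax))
  if (any(degenerate))
    warning("degenerate muscle(s) with Lmax == Lmin: ",
            paste(which(degenerate), collapse = ", "),
            "; normalized length metric undefined for them", call. = FALSE)
  structure(list(Lmin = Lmin, Lmax = Lmax, Mmax = Mmax,
                 degenerate = degenerate, n_probe = n_probe, seed = seed),
            class = "msk_norms")
}

#' Write / read a model as JSON
#'
#' Self-describing structured text serialization (joints, muscles, terms,
#' seed, sign convention, version); the round trip is lossless to full
#' floating-point precision.
#'
#' @param model an [msk_model()].
#' @param path file path.
#' @return `read_model` returns an [msk_model()]; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "msk_model"))
  obj <- list(
    format = "mskSurrogate-model", version = model$version,
    seed = model$seed, ma_sign = model$ma_sign,
    joints = model$joints,
    muscles = lapply(model$muscles, function(m)
      list(name = m$name, dofs = m$dofs,
           coef = m$terms$coef,
           expon = m$terms$expon)))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "mskSurrogate-model"))
    stop("not a mskSurrogate model file: ", path)
  muscles <- lapply(seq_along(obj$muscles$name), function(i) {
    expon <- obj$muscles$expon[[i]]
    if (is.null(dim(expon))) expon <- matrix(expon, nrow = length(obj$muscles$coef[[i]]))
    list(name = obj$muscles$name[i],
         dofs = as.integer(obj$muscles$dofs[[i]]),
         terms = poly_terms(obj$muscles$coef[[i]], expon))
  })
  joints <- data.frame(name = as.character(obj$joints$name),
                       theta_min = as.numeric(obj$joints$theta_min),
                       theta_max = as.numeric(obj$joints$theta_max),
                       stringsAsFactors = FALSE)
  msk_model(joints, muscles, seed = obj$seed, ma_sign = obj$ma_sign)
}

#' @export
print.msk_model <- function(x, ...) {
  ch <- channel_table(x)
  cat("<msk_model> ", nrow(x$joints), " DOFs, ", length(x$muscles),
      " muscles, ", nrow(ch), " moment-arm channels (seed ",
      x$seed, ", MA sign ", x$ma_sign, ")\n", sep = "")
  invisible(x)
}
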