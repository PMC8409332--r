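#' Per-channel normalized errors
#'
#' Elementwise normalized absolute errors in percent:
#' `100 * |reference - predicted| / denom`, one denominator per channel
#' (the length range `Lmax - Lmin` for lengths, the maximum absolute moment
#' arm `Mmax` for moment arms).
#'
#' @param reference,predicted n x m matrices.
#' @param denom length-m vector of per-channel denominators.
#' @return n x m matrix of errors (%).
#' @export
normalized_errors <- function(reference, predicted, denom) {
  reference <- as.matrix(reference); predicted <- as.matrix(predicted)
  if (!all(dim(reference) == dim(predicted)))
    stop("reference and predicted shapes differ")
  if (length(denom) != ncol(reference))
    stop("need one denominator per channel")
  100 * sweep(abs(reference - predicted), 2, denom, `/`)
}

metric_block <- function(reference, predicted, denom, exclude, kind, what) {
  err <- normalized_errors(reference, predicted, denom) / 100
  if (any(exclude)) {
    warning("excluding ", sum(exclude), " degenerate ", what,
            " channel(s) from the metric", call. = FALSE)
    err <- err[, !exclude, drop = FALSE]
  }
  if (ncol(err) == 0L) stop("no non-degenerate channels left")
  per_channel <- if (kind == "printed") colMeans(err)
  else sqrt(colMeans(err^2))
  100 * per_channel
}

#' Normalized length error metric
#'
#' Range-normalized length error in percent: the mean over muscles of the
#' mean over test samples of `|x_r - x_p| / (Lmax - Lmin)` (the square root
#' of a single squared term, i.e. a normalized mean absolute error; this is
#' the form the metric takes when the root is applied per sample). A
#' conventional per-muscle root-mean-square variant is available with
#' `kind = "rms"`. Muscles flagged degenerate in `norms` (zero length
#' range) are excluded with a warning.
#'
#' @param reference,predicted n x m length matrices (mm).
#' @param norms [compute_normalization()] constants covering the m muscles.
#' @param kind `"printed"` (normalized mean absolute error, default) or
#'   `"rms"`.
#' @param per_muscle return the per-muscle values instead of their mean.
#' @return scalar percent error (or a length-m vector).
#' @export
rmse_length <- function(reference, predicted, norms,
                        kind = c("printed", "rms"), per_muscle = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(norms, "msk_norms"))
  v <- metric_block(reference, predicted, norms$Lmax - norms$Lmin,
                    norms$degenerate, kind, "length")
  if (per_muscle) v else mean(v)
}

#' Normalized moment-arm error metric
#'
#' As [rmse_length()], with each channel normalized by its maximum absolute
#' moment arm `Mmax`.
#'
#' @param reference,predicted n x m moment-arm matrices (mm/rad).
#' @param norms [compute_normalization()] constants covering the m channels.
#' @param kind `"printed"` or `"rms"`.
#' @param per_channel return the per-channel values instead of their mean.
#' @return scalar percent error (or a length-m vector).
#' @export
rmse_moment_arm <- function(reference, predicted, norms,
                            kind = c("printed", "rms"),
                            per_channel = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(norms, "msk_norms"))
  degenerate <- norms$Mmax <= 0
  v <- metric_block(reference, predicted, norms$Mmax, degenerate, kind,
                    "moment-arm")
  if (per_channel) v else mean(v)
}

#' Per-channel error-distribution summaries
#'
#' Summarizes the normalized absolute errors of each channel: median, first
#' and third quartile (linear interpolation between order statistics),
#' interquartile range, and the span up to the worst error. Channels can be
#' ordered by the number of DOFs their muscle spans (the convention used
#' when plotting simple muscles left, thumb-like muscles right).
#'
#' @param reference,predicted n x m matrices.
#' @param denom per-channel denominators (length range or `Mmax`).
#' @param order_by_dofs optional integer vector of spanned-DOF counts per
#'   channel used to order the summary rows.
#' @return data.frame with one row per channel: `channel`, `median`, `q1`,
#'   `q3`, `iqr`, `max`, `span` (all %), plus attribute `errors` holding
#'   the raw n x m error matrix.
#' @export
error_distribution <- function(reference, predicted, denom,
                               order_by_dofs = NULL) {
  err <- normalized_errors(reference, predicted, denom)
  qs <- apply(err, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              type = 7, names = FALSE)
  out <- data.frame(channel = colnames(err) %||% seq_len(ncol(err)),
                    median = qs[2, ], q1 = qs[1, ], q3 = qs[3, ],
                    iqr = qs[3, ] - qs[1, ],
                    max = apply(err, 2, max),
                    span = apply(err, 2, max) - apply(err, 2, min),
                    stringsAsFactors = FALSE)
  if (!is.null(order_by_dofs)) out <- out[order(order_by_dofs), ]
  attr(out, "errors") <- err
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample postures from the workspace edges
#'
#' Draws each joint angle uniformly from the outer quartiles of its range,
#' `[theta_min, theta_min + R/4]` or `[theta_max - R/4, theta_max]`
#' (`R` = range width), independently per joint with equal probability for
#' the two intervals.
#'
#' @inheritParams sample_postures
#' @return n x n_joints matrix of extreme postures (rad).
#' @export
extreme_postures <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "msk_model"))
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  d <- nrow(model$joints)
  out <- matrix(NA_real_, n, d, dimnames = list(NULL, model$joints$name))
  for (j in seq_len(d)) {
    lo <- model$joints$theta_min[j]; hi <- model$joints$theta_max[j]
    R <- hi - lo
    u <- stats::runif(n, 0, R / 4)
    upper <- stats::runif(n) < 0.5
    out[, j] <- ifelse(upper, hi - u, lo + u)
  }
  out
}

# resolve a surrogate argument into length/moment-arm predictions; accepts
# a single object whose predict() returns a list (msk_gbm, msk_model), a
# single msk_ann, or a list(lengths = ..., moment_arms = ...)
surrogate_predict <- function(surrogate, postures) {
  if (inherits(surrogate, "msk_ann")) {
    p <- predict(surrogate, postures)
    out <- list(lengths = NULL, moment_arms = NULL)
    out[[surrogate$block]] <- p
    return(out)
  }
  if (is.list(surrogate) && !is.object(surrogate)) {
    lp <- if (!is.null(surrogate$lengths))
      surrogate_predict(surrogate$lengths, postures)$lengths
    mp <- if (!is.null(surrogate$moment_arms))
      surrogate_predict(surrogate$moment_arms, postures)$moment_arms
    return(list(lengths = lp, moment_arms = mp))
  }
  predict(surrogate, postures)
}

#' Accuracy on workspace-edge postures
#'
#' Re-evaluates a surrogate on postures drawn from the outer quartiles of
#' every joint range ([extreme_postures()]), where accuracy is expected to
#' degrade, and reports the normalized block metrics there.
#'
#' @param model the reference [msk_model()].
#' @param surrogate a surrogate (`msk_gbm`, `msk_ann`, the model itself, or
#'   `list(lengths = , moment_arms = )` of block surrogates).
#' @param norms [compute_normalization()] constants.
#' @param n number of edge postures (>= 1000).
#' @param seed sampling seed.
#' @return list with `rmse_length` and `rmse_moment_arm` (%), `NA` for
#'   blocks the surrogate does not predict.
#' @export
extreme_posture_test <- function(model, surrogate, norms, n = 10000L,
                                 seed = 1L) {
  if (n < 1000) stop("n must be >= 1000")
  x <- extreme_postures(model, n, seed = seed)
  ref <- predict(model, x)
  pred <- surrogate_predict(surrogate, x)
  list(rmse_length = if (!is.null(pred$lengths))
    rmse_length(ref$lengths, pred$lengths, norms) else NA_real_,
    rmse_moment_arm = if (!is.null(pred$moment_arms))
      rmse_moment_arm(ref$moment_arms, pred$moment_arms, norms) else NA_real_)
}

#' Accuracy versus training-set size
#'
#' Trains an independent surrogate per dataset size on freshly drawn data
#' and evaluates each on one fixed held-out test set, tracing the
#' error-versus-size curve (sizes are typically log-spaced, e.g. 1e3 to
#' 1e6).
#'
#' @param model the reference [msk_model()].
#' @param family surrogate family to sweep.
#' @param sizes ascending vector of training-set sizes.
#' @param norms [compute_normalization()] constants.
#' @param seed base seed; each size uses an offset sub-seed.
#' @param n_test size of the fixed test set.
#' @param control family options: for `"gbm"` a [gbm_hyperparams()] in
#'   `$params` and optionally `$muscles`; for `"ann"` hidden widths in
#'   `$hidden` and `$max_epochs`, `$blocks`.
#' @param verbose print progress lines.
#' @return data.frame with columns `size`, `rmse_length`,
#'   `rmse_moment_arm`.
#' @export
dataset_size_sweep <- function(model, family = c("gbm", "ann"), sizes,
                               norms, seed = 1L, n_test = 5000L,
                               control = list(), verbose = FALSE) {
  family <- match.arg(family)
  stopifnot(all(diff(sizes) > 0))
  x_test <- sample_postures(model, n_test, seed = seed + 900100L)
  ref <- predict(model, x_test)
  rows <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    if (verbose) msg_stage("sweep", family, " n=", n)
    ds <- generate_dataset(model, n, seed = seed + i)
    sp <- split_dataset(n, seed = seed + 500L + i)
    if (family == "gbm") {
      params <- control$params %||% gbm_hyperparams()
      sur <- train_gbm(ds, sp, muscles = control$muscles, params = params,
                       seed = seed + i)
      pred <- predict(sur, x_test)
    } else {
      hidden <- control$hidden %||% c(64L, 32L)
      blocks <- control$blocks %||% c("lengths", "moment_arms")
      pred <- list(lengths = NULL, moment_arms = NULL)
      for (blk in blocks) {
        cfg <- ann_config(c(ncol(ds$postures), hidden, ncol(ds[[blk]])),
                          max_epochs = control$max_epochs %||% 30L,
                          seed = seed + i)
        net <- train_ann(cfg, ds, sp, block = blk)
        pred[[blk]] <- predict(net, x_test)
      }
    }
    data.frame(
      size = n,
      rmse_length = if (!is.null(pred$lengths))
        rmse_length(ref$lengths, pred$lengths, norms) else NA_real_,
      rmse_moment_arm = if (!is.null(pred$moment_arms))
        rmse_moment_arm(ref$moment_arms, pred$moment_arms, norms)
      else NA_real_)
  })
  do.call(rbind, rows)
}

#' Evaluation latency of a surrogate
#'
#' Times repeated single-posture evaluations (lengths and moment arms
#' combined when the surrogate provides both) and reports their mean and
#' standard deviation. Latency depends on hardware and is reported for
#' comparison only.
#'
#' @param surrogate a surrogate accepted by [extreme_posture_test()].
#' @param postures posture matrix to cycle through (one row per
#'   evaluation, recycled).
#' @param n_evals number of evaluations (>= 100; default 1000).
#' @return list with `mean_ms`, `sd_ms`, `n_evals` and the raw
#'   `durations_ms`.
#' @export
latency_benchmark <- function(surrogate, postures, n_evals = 1000L) {
  if (n_evals < 100) stop("n_evals must be >= 100")
  n_evals <- as.integer(n_evals)
  postures <- as.matrix(postures)
  durations <- numeric(n_evals)
  for (i in seq_len(n_evals)) {
    row <- postures[((i - 1L) %% nrow(postures)) + 1L, , drop = FALSE]
    t0 <- Sys.time()
    surrogate_predict(surrogate, row)
    durations[i] <- as.numeric(Sys.time() - t0, units = "secs") * 1000
  }
  list(mean_ms = mean(durations), sd_ms = stats::sd(durations),
       n_evals = n_evals, durations_ms = durations)
}

#' Full evaluation report for a surrogate
#'
#' Evaluates a surrogate on test postures against the reference model:
#' block-level normalized metrics, per-channel error summaries, and
#' metadata.
#'
#' @param model the reference [msk_model()].
#' @param surrogate a surrogate accepted by [extreme_posture_test()].
#' @param postures test posture matrix.
#' @param norms [compute_normalization()] constants.
#' @param surrogate_id label stored in the report.
#' @return object of class `msk_report`: list with `rmse_length`,
#'   `rmse_moment_arm`, `length_summary`, `ma_summary`, `n`,
#'   `surrogate_id`, `model_id`.
#' @export
evaluate_surrogate <- function(model, surrogate, postures, norms,
                               surrogate_id = "surrogate") {
  ref <- predict(model, postures)
  pred <- surrogate_predict(surrogate, postures)
  ch <- channel_table(model)
  dof_count <- vapply(model$muscles, function(m) length(m$dofs), 0L)
  out <- list(n = nrow(as.matrix(postures)), surrogate_id = surrogate_id,
              model_id = model_id(model),
              rmse_length = NA_real_, rmse_moment_arm = NA_real_,
              length_summary = NULL, ma_summary = NULL)
  if (!is.null(pred$lengths)) {
    out$rmse_length <- rmse_length(ref$lengths, pred$lengths, norms)
    out$length_summary <- error_distribution(
      ref$lengths, pred$lengths, norms$Lmax - norms$Lmin,
      order_by_dofs = dof_count)
  }
  if (!is.null(pred$moment_arms)) {
    out$rmse_moment_arm <- rmse_moment_arm(ref$moment_arms,
                                           pred$moment_arms, norms)
    out$ma_summary <- error_distribution(
      ref$moment_arms, pred$moment_arms, norms$Mmax,
      order_by_dofs = dof_count[ch$muscle])
  }
  structure(out, class = "msk_report")
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (scalars and metadata) and per-channel CSV tables.
#'
#' @param report an `msk_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "msk_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalars <- report[c("surrogate_id", "model_id", "n", "rmse_length",
                      "rmse_moment_arm")]
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, digits = NA),
             file.path(dir, "report.json"))
  if (!is.null(report$length_summary))
    utils::write.csv(report$length_summary,
                     file.path(dir, "length_errors.csv"), row.names = FALSE)
  if (!is.null(report$ma_summary))
    utils::write.csv(report$ma_summary,
                     file.path(dir, "moment_arm_errors.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.msk_report <- function(x, ...) {
  cat("<msk_report> ", x$surrogate_id, " on ", x$model_id, " (n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  normalized length error:     %s%%\n",
              format(x$rmse_length, digits = 4)))
  cat(sprintf("  normalized moment-arm error: %s%%\n",
              format(x$rmse_moment_arm, digits = 4)))
  invisible(x)
}
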