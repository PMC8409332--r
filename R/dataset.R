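#' Sample postures uniformly over the workspace
#'
#' Each joint angle is drawn independently and uniformly over that joint's
#' `[theta_min, theta_max]` range.
#'
#' @param model an [msk_model()].
#' @param n number of postures (>= 1).
#' @param seed sampling seed.
#' @return n x n_joints matrix of joint angles (rad).
#' @export
sample_postures <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "msk_model"))
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  d <- nrow(model$joints)
  out <- matrix(NA_real_, n, d, dimnames = list(NULL, model$joints$name))
  for (j in seq_len(d))
    out[, j] <- stats::runif(n, model$joints$theta_min[j],
                             model$joints$theta_max[j])
  out
}

#' Generate a posture/length/moment-arm dataset
#'
#' Samples `n` uniform postures and evaluates the reference model, producing
#' the paired input-output matrices used to train and test surrogates.
#' Evaluation is chunked so that large datasets do not hold intermediate
#' power tables in memory.
#'
#' @param model an [msk_model()].
#' @param n number of samples.
#' @param seed posture-sampling seed (recorded in provenance).
#' @param chunk rows evaluated per chunk.
#' @return object of class `msk_dataset`: list with matrices `postures`
#'   (n x n_joints), `lengths` (n x n_muscles), `moment_arms`
#'   (n x n_channels) and a `provenance` list (`model_seed`, `sample_seed`,
#'   `model_id`).
#' @export
generate_dataset <- function(model, n, seed = 1L, chunk = 200000L) {
  stopifnot(inherits(model, "msk_model"))
  postures <- sample_postures(model, n, seed = seed)
  n <- nrow(postures)
  nm <- length(model$muscles)
  nc <- nrow(channel_table(model))
  lengths <- matrix(NA_real_, n, nm)
  moment_arms <- matrix(NA_real_, n, nc)
  done <- 0L
  while (done < n) {
    idx <- (done + 1L):min(done + chunk, n)
    x <- postures[idx, , drop = FALSE]
    lengths[idx, ] <- evaluate_length(model, x)
    moment_arms[idx, ] <- evaluate_moment_arms(model, x)
    done <- idx[length(idx)]
  }
  colnames(lengths) <- vapply(model$muscles, `[[`, "", "name")
  colnames(moment_arms) <- channel_table(model)$name
  if (!all(is.finite(lengths)) || !all(is.finite(moment_arms)))
    stop("non-finite values in generated dataset")
  structure(list(postures = postures, lengths = lengths,
                 moment_arms = moment_arms,
                 provenance = list(model_seed = model$seed,
                                   sample_seed = as.integer(seed),
                                   model_id = model_id(model))),
            class = "msk_dataset")
}

model_id <- function(model) {
  sprintf("msk-%dj-%dm-%dch-seed%s", nrow(model$joints),
          length(model$muscles), nrow(channel_table(model)),
          model$seed)
}

#' Train/validation/test split protocol
#'
#' Carves out the test set first, then splits the remainder into training
#' (80%) and validation (20%). The three sets stand in the ratio
#' 5 : 80 : 20 (test : train : validation): the test set holds 5% as many
#' rows as the data that remains for training and validation, and sizes
#' use round-half-up arithmetic: `|test| = round(n * 5/105)`,
#' `|train| = round(0.8 (n - |test|))`, validation takes the rest. For
#' n = 1,050,000 this gives exactly 50,000 / 800,000 / 200,000
#' test/train/validation rows, the canonical full-scale protocol.
#'
#' @param n total number of rows (>= 10).
#' @param seed permutation seed.
#' @return object of class `msk_split`: list of integer index vectors
#'   `test`, `train`, `validation` (a disjoint cover of `1:n`).
#' @export
split_dataset <- function(n, seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  n <- as.integer(n)
  n_test <- as.integer(round_half_up(n * 5 / 105))
  n_train <- as.integer(round_half_up(0.80 * (n - n_test)))
  n_val <- n - n_test - n_train
  if (n_test < 1L || n_train < 1L || n_val < 1L)
    stop("n too small to populate test, train and validation sets")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  perm <- sample.int(n)
  structure(list(test = perm[seq_len(n_test)],
                 train = perm[n_test + seq_len(n_train)],
                 validation = perm[(n_test + n_train + 1L):n]),
            class = "msk_split")
}

#' 70/30 split used for hyperparameter tuning
#'
#' @param n total number of rows.
#' @param seed permutation seed.
#' @return list of integer index vectors `train` (70%) and `validation`
#'   (30%).
#' @export
tuning_split <- function(n, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  n <- as.integer(n)
  n_train <- as.integer(round_half_up(0.7 * n))
  if (n_train < 1L || n - n_train < 1L)
    stop("n too small for a 70/30 split")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  perm <- sample.int(n)
  list(train = perm[seq_len(n_train)], validation = perm[(n_train + 1L):n])
}

#' Save / load a dataset container
#'
#' Datasets are stored as a single native R serialization file holding the
#' three named arrays and provenance attributes; the round trip is lossless
#' to full floating precision. For small datasets [export_dataset_csv()]
#' writes a delimited-text copy.
#'
#' @param dataset an `msk_dataset`.
#' @param path file path (`.rds`).
#' @return `load_dataset` returns the `msk_dataset`; `save_dataset` returns
#'   `path` invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "msk_dataset"))
  saveRDS(dataset, path, version = 2)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "msk_dataset"))
  ds
}

#' @rdname save_dataset
#' @param dir output directory for the CSV export (`postures.csv`,
#'   `lengths.csv`, `moment_arms.csv`).
#' @export
export_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "msk_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$postures, file.path(dir, "postures.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$lengths, file.path(dir, "lengths.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$moment_arms, file.path(dir, "moment_arms.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.msk_dataset <- function(x, ...) {
  cat("<msk_dataset> ", nrow(x$postures), " samples: postures ",
      ncol(x$postures), "d, lengths ", ncol(x$lengths), ", moment arms ",
      ncol(x$moment_arms), " (", x$provenance$model_id, ")\n", sep = "")
  invisible(x)
}
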