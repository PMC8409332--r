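#' Default end-to-end pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param model_seed,data_seed,split_seed stage seeds (all recorded in the
#'   artifacts).
#' @param n dataset size.
#' @param family surrogate family: `"gbm"`, `"ann"` or `"both"`.
#' @param model_config reference-model configuration
#'   ([default_model_config()]).
#' @param gbm list of [train_gbm()] options.
#' @param ann list with per-block [ann_config()] options: `hidden`,
#'   `max_epochs`.
#' @param norm_probe probe size for [compute_normalization()].
#' @return a `run_config` list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, model_seed = 1L, data_seed = 2L,
                            split_seed = 3L, n = 10000L, family = "gbm",
                            model_config = default_model_config(),
                            gbm = list(), ann = list(hidden = c(64L, 32L),
                                                     max_epochs = 30L),
                            norm_probe = 1e5) {
  stopifnot(family %in% c("gbm", "ann", "both"))
  list(out_dir = out_dir, model_seed = as.integer(model_seed),
       data_seed = as.integer(data_seed), split_seed = as.integer(split_seed),
       n = as.integer(n), family = family, model_config = model_config,
       gbm = gbm, ann = ann, norm_probe = norm_probe)
}

#' Run the full surrogate pipeline
#'
#' Executes model generation, dataset generation, splitting, surrogate
#' training and evaluation as one seeded, idempotent run. Every artifact is
#' written under `config$out_dir` and carries its seeds; rerunning with the
#' same configuration reproduces the artifacts and metrics exactly.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage logs.
#' @return invisible list with the model, dataset, split, norms, trained
#'   surrogates and the evaluation report(s).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) msg_stage(...)

  say("gen-model", "seed=", config$model_seed)
  model <- build_default_model(config$model_seed, config$model_config)
  write_model(model, file.path(config$out_dir, "model.json"))

  say("gen-data", "n=", config$n, " seed=", config$data_seed)
  dataset <- generate_dataset(model, config$n, seed = config$data_seed)
  save_dataset(dataset, file.path(config$out_dir, "dataset.rds"))

  say("split", "seed=", config$split_seed)
  split <- split_dataset(config$n, seed = config$split_seed)
  saveRDS(split, file.path(config$out_dir, "split.rds"), version = 2)

  say("normalize", "probe=", config$norm_probe)
  norms <- compute_normalization(model, n_probe = config$norm_probe,
                                 seed = config$model_seed + 17L)

  x_test <- dataset$postures[split$test, , drop = FALSE]
  surrogates <- list(); reports <- list()

  if (config$family %in% c("gbm", "both")) {
    say("train-gbm", "channels=",
        length(model$muscles) + nrow(channel_table(model)))
    args <- c(list(dataset = dataset, split = split), config$gbm)
    sur <- do.call(train_gbm, args)
    save_gbm(sur, file.path(config$out_dir, "gbm_bundle"))
    surrogates$gbm <- sur
    reports$gbm <- evaluate_surrogate(model, sur, x_test, norms,
                                      surrogate_id = "gbm")
    write_report(reports$gbm, file.path(config$out_dir, "report_gbm"))
  }
  if (config$family %in% c("ann", "both")) {
    nets <- list()
    for (blk in c("lengths", "moment_arms")) {
      say("train-ann", blk)
      cfg <- ann_config(c(ncol(dataset$postures), config$ann$hidden,
                          ncol(dataset[[blk]])),
                        max_epochs = config$ann$max_epochs %||% 30L,
                        seed = config$model_seed)
      nets[[blk]] <- train_ann(cfg, dataset, split, block = blk,
                               norms = norms)
      save_ann(nets[[blk]],
               file.path(config$out_dir, paste0("ann_", blk, ".rds")))
    }
    surrogates$ann <- nets
    reports$ann <- evaluate_surrogate(model, nets, x_test, norms,
                                      surrogate_id = "ann")
    write_report(reports$ann, file.path(config$out_dir, "report_ann"))
  }
  say("done", "artifacts in ", config$out_dir)
  invisible(list(model = model, dataset = dataset, split = split,
                 norms = norms, surrogates = surrogates, reports = reports))
}

#' Miniature fixtures for tests and examples
#'
#' Seed-deterministic toy artifacts: `"toy-model"` is a 1-joint, 1-muscle,
#' 1-channel model; `"toy-dataset"` is a 100-row dataset generated from it.
#'
#' @param kind fixture kind.
#' @param seed seed.
#' @return an [msk_model()] or `msk_dataset`.
#' @export
make_fixture <- function(kind = c("toy-model", "toy-dataset"), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- default_model_config(n_joints = 1L, coupling = c(`1` = 1L),
                              extra_terms_per_dof = 2L)
  model <- build_default_model(seed, cfg)
  if (kind == "toy-model") return(model)
  generate_dataset(model, 100L, seed = seed + 1L)
}
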