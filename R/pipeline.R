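# Config-driven pipeline commands. Each run_*() function takes a validated
# config (YAML file or list), derives its stage seed from the single top-level
# seed, writes its outputs plus a provenance JSON under out_dir, and returns
# its result invisibly. The inst/cli/nifstack script exposes these as shell
# subcommands.

CONFIG_KEYS <- c("task", "paths", "seed", "cv", "groups", "learners",
                 "threshold", "embedding", "simulate", "log_level")
PATH_KEYS <- c("manifest", "embeddings", "reference_usage", "out_dir",
               "model")

#' Load and validate a run configuration
#'
#' Configs are YAML (or an equivalent named list) with keys `task`
#' (classification/regression), `paths` (manifest, embeddings,
#' reference_usage, out_dir, model), `seed`, `cv` (folds, repeats), `groups`
#' (feature-group roster), `learners` (base/meta overrides), `threshold`,
#' `embedding` (width, seed, source), `simulate` (generator parameters) and
#' `log_level`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file or a named list.
#' @param seed Optional seed override (e.g. from the command line).
#' @return Validated config list with defaults filled in.
#' @export
load_config <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$paths)) {
    unknown_paths <- setdiff(names(cfg$paths), PATH_KEYS)
    if (length(unknown_paths)) {
      stop("unknown paths key(s): ", paste(unknown_paths, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg$task <- match.arg(cfg$task %||% "classification",
                        c("classification", "regression"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$cv <- utils::modifyList(list(folds = 5L, repeats = 1L), cfg$cv %||%
                                list())
  cfg$groups <- cfg$groups %||% c("CT", "DPC", "PAAC", "RSCU",
                                  "Euclidean_distance", "Expression",
                                  "Gene_distance", "Copy_number", "Embedding")
  cfg$threshold <- cfg$threshold %||% 0.55
  cfg$embedding <- utils::modifyList(list(width = 32L, seed = NULL,
                                          source = "unknown"),
                                     cfg$embedding %||% list())
  cfg$log_level <- cfg$log_level %||% "info"
  cfg
}

stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 1009 + offset) %% 2147483647)
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

write_provenance <- function(cfg, out_dir, stage) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(stage = stage, seed = cfg$seed,
               config_hash = rlang::hash(cfg),
               package_version = as.character(utils::packageVersion(
                 "nifstack")))
  jsonlite::write_json(prov, file.path(out_dir,
                                       paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

pipeline_inputs <- function(cfg) {
  stopifnot(!is.null(cfg$paths$manifest))
  data <- read_manifest(cfg$paths$manifest)
  ref <- if (!is.null(cfg$paths$reference_usage)) {
    read_reference_usage(cfg$paths$reference_usage)
  } else default_reference_usage()
  emb <- if (!is.null(cfg$paths$embeddings)) {
    load_embedding_table(cfg$paths$embeddings, source = cfg$embedding$source)
  } else NULL
  blocks <- build_feature_groups(
    data, ref = ref, embedding = emb,
    embedding_width = cfg$embedding$width,
    embedding_seed = cfg$embedding$seed %||% stage_seed(cfg, 11L),
    groups = cfg$groups)
  list(data = data, blocks = blocks, ref = ref)
}

#' Pipeline commands
#'
#' `run_simulate()` generates a synthetic dataset and writes the fixture
#' bundle; `run_featurize()` writes one TSV per feature group;
#' `run_select_features()` runs the incremental feature-group search;
#' `run_select_models()` runs the incremental mutual-information learner
#' search; `run_train()` fits and saves the stacking ensemble;
#' `run_predict()` writes per-sample predictions; `run_evaluate()` writes the
#' metric report for a labelled manifest.
#'
#' @param config Config path or list, see [load_config()].
#' @param seed Optional seed override.
#' @return The stage result, invisibly (dataset, block list, trace, model,
#'   prediction tibble, or `nif_eval`).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  sim <- cfg$simulate %||% list()
  sim$seed <- sim$seed %||% stage_seed(cfg, 1L)
  gcfg <- do.call(generator_config, sim)
  data <- generate_dataset(gcfg)
  write_fixture_bundle(data, out_dir, embedding_width = cfg$embedding$width,
                       embedding_seed = cfg$embedding$seed %||%
                         stage_seed(cfg, 11L))
  write_provenance(cfg, out_dir, "simulate")
  log_msg(cfg, "simulated ", nrow(data), " samples into ", out_dir)
  invisible(data)
}

#' @rdname pipeline
#' @export
run_featurize <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- pipeline_inputs(cfg)
  for (g in names(inputs$blocks)) {
    write_feature_block(inputs$blocks[[g]],
                        file.path(out_dir, paste0("features_", g, ".tsv")))
    log_msg(cfg, "group ", g, ": ", ncol(inputs$blocks[[g]]) - 1L,
            " features x ", nrow(inputs$blocks[[g]]), " samples")
  }
  write_provenance(cfg, out_dir, "featurize")
  invisible(inputs$blocks)
}

#' @rdname pipeline
#' @export
run_select_features <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  inputs <- pipeline_inputs(cfg)
  data <- label_dataset(inputs$data)
  y <- if (cfg$task == "classification") data$label else data$target
  evaluator <- learner_spec(
    if (cfg$task == "classification") "xgb" else "xgbr",
    cfg$learners$evaluator_params %||% list(),
    seed = stage_seed(cfg, 2L))
  trace <- ifs_search(inputs$blocks, y, evaluator,
                      folds = cfg$cv$folds, seed = stage_seed(cfg, 3L),
                      repeats = cfg$cv$repeats)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_selection_trace(trace, file.path(out_dir, "feature_selection.json"))
  writeLines(format_selection_table(trace),
             file.path(out_dir, "feature_selection.txt"))
  write_provenance(cfg, out_dir, "select_features")
  log_msg(cfg, "selected groups: ", paste(trace$final_set, collapse = ", "))
  invisible(trace)
}

default_candidate_roster <- function(task, seed) {
  if (task == "classification") {
    list(KNN = learner_spec("knn", seed = seed),
         RF = learner_spec("rf", list(n_estimators = 100L), seed = seed),
         SVM = learner_spec("svm", seed = seed),
         XGB = learner_spec("xgb", list(n_estimators = 50L), seed = seed),
         DTC = learner_spec("dtc", seed = seed))
  } else {
    list(DTR = learner_spec("dtr", list(max_depth = 5L), seed = seed),
         XGBR = learner_spec("xgbr", list(n_estimators = 50L), seed = seed),
         SVR = learner_spec("svr", seed = seed),
         RFR = learner_spec("rfr", list(n_estimators = 100L), seed = seed),
         KNNR = learner_spec("knnr", seed = seed))
  }
}

#' @rdname pipeline
#' @export
run_select_models <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  inputs <- pipeline_inputs(cfg)
  data <- label_dataset(inputs$data)
  y <- if (cfg$task == "classification") data$label else data$target
  candidates <- default_candidate_roster(cfg$task, stage_seed(cfg, 4L))
  trace <- imi_search(candidates, inputs$blocks, y,
                      seed = stage_seed(cfg, 5L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_selection_trace(trace, file.path(out_dir, "model_selection.json"))
  writeLines(format_selection_table(trace),
             file.path(out_dir, "model_selection.txt"))
  write_provenance(cfg, out_dir, "select_models")
  log_msg(cfg, "selected learners: ", paste(trace$final_set, collapse = ", "))
  invisible(trace)
}

#' @rdname pipeline
#' @export
run_train <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  inputs <- pipeline_inputs(cfg)
  data <- label_dataset(inputs$data)
  y <- if (cfg$task == "classification") data$label else data$target
  model <- fit_stacking(inputs$blocks, y, task = cfg$task,
                        threshold = cfg$threshold,
                        seed = stage_seed(cfg, 6L))
  save_model(model, file.path(out_dir, "model"))
  write_provenance(cfg, out_dir, "train")
  log_msg(cfg, "trained ", cfg$task, " stacking model on ", nrow(data),
          " samples")
  invisible(model)
}

#' @rdname pipeline
#' @export
run_predict <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  model_path <- cfg$paths$model %||% file.path(out_dir, "model")
  model <- load_model(model_path)
  inputs <- pipeline_inputs(cfg)
  pred <- predict(model, inputs$blocks)
  pred <- dplyr::bind_cols(
    tibble::tibble(sample_id = inputs$data$sample_id), pred)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(pred, file.path(out_dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(cfg, out_dir, "predict")
  invisible(pred)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(config, seed = NULL) {
  cfg <- load_config(config, seed)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir required")
  model_path <- cfg$paths$model %||% file.path(out_dir, "model")
  model <- load_model(model_path)
  inputs <- pipeline_inputs(cfg)
  data <- label_dataset(inputs$data)
  ev <- if (model$task == "classification") {
    p <- predict_proba(model, inputs$blocks)
    evaluate_predictions(data$label, as.integer(p >= model$threshold),
                         scores = p, task = "classification")
  } else {
    pred <- predict_activity(model, inputs$blocks)
    evaluate_predictions(data$target, pred$pred_log, task = "regression")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_report(ev, file.path(out_dir, "metrics.json"))
  write_metrics_report(ev, file.path(out_dir, "metrics.tsv"))
  write_provenance(cfg, out_dir, "evaluate")
  log_msg(cfg, "metrics: ",
          paste(names(ev$metrics), signif(unlist(ev$metrics), 4L),
                sep = "=", collapse = ", "))
  invisible(ev)
}
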