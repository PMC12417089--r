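# Two-layer stacking ensembles. Base learners are fitted on 60% of the
# training data (Training-60); their held-out outputs on the remaining 40%
# (the base-learner probability vector, BLP) augment the feature matrix on
# which the meta learner is fitted (Training-40). Classification predicts the
# positive class when the meta probability reaches the decision threshold
# (default 0.55).

#' Default tuned learner configurations
#'
#' The tuned stacking configurations: classification uses k-nearest
#' neighbours (5 neighbours, uniform weights) as base learner and a random
#' forest (200 trees, unlimited depth, min split 5, log2 feature subsampling,
#' bootstrap) as meta learner with decision threshold 0.55; regression uses a
#' depth-5 decision tree (min split 10, sqrt feature subsampling) and
#' gradient-boosted trees (depth 5, learning rate 0.01, 200 rounds, gamma 0)
#' as base learners with a radial-basis support-vector regressor (C = 1,
#' epsilon = 0.01, scale kernel width) as meta learner.
#'
#' @param task `"classification"` or `"regression"`.
#' @param seed Seed stored in each spec.
#' @return List with elements `base` (named list of [learner_spec()]) and
#'   `meta` (a [learner_spec()]), plus `threshold` for classification.
#' @export
default_stacking_config <- function(task = c("classification", "regression"),
                                    seed = 1L) {
  task <- match.arg(task)
  if (task == "classification") {
    list(
      base = list(KNN = learner_spec("knn",
                                     list(n_neighbors = 5L,
                                          weights = "uniform"),
                                     seed = seed)),
      meta = learner_spec("rf",
                          list(n_estimators = 200L, max_depth = "None",
                               min_samples_split = 5L, min_samples_leaf = 1L,
                               max_features = "log2", bootstrap = TRUE),
                          seed = seed),
      threshold = 0.55
    )
  } else {
    list(
      base = list(
        DTR = learner_spec("dtr",
                           list(max_depth = 5L, splitter = "random",
                                min_samples_split = 10L,
                                min_samples_leaf = 1L,
                                max_features = "sqrt"),
                           seed = seed),
        XGBR = learner_spec("xgbr",
                            list(max_depth = 5L, learning_rate = 0.01,
                                 n_estimators = 200L, gamma = 0),
                            seed = seed)
      ),
      meta = learner_spec("svr",
                          list(kernel = "rbf", C = 1, epsilon = 0.01,
                               gamma = "scale"),
                          seed = seed)
    )
  }
}

#' Fit a two-layer stacking ensemble
#'
#' Splits the training samples 60/40 (stratified on the label for
#' classification), fits the base learners on Training-60, computes their
#' held-out outputs (BLP) on Training-40, and fits the meta learner on the
#' Training-40 features augmented with the BLP columns. The meta input width
#' is therefore the selected-feature width plus one column per base learner.
#'
#' @param blocks Named list of feature-block tibbles (the selected groups) or
#'   a design matrix.
#' @param y Labels (0/1) or numeric targets.
#' @param task `"classification"` or `"regression"`.
#' @param base Named list of base [learner_spec()]s; defaults to the tuned
#'   configuration.
#' @param meta Meta [learner_spec()]; defaults likewise.
#' @param split A [split_spec()] for the 60/40 protocol.
#' @param threshold Classification decision threshold in (0, 1).
#' @param seed Seed used for default specs and the split when not supplied.
#' @return A fitted `nif_stack` model.
#' @export
fit_stacking <- function(blocks, y,
                         task = c("classification", "regression"),
                         base = NULL, meta = NULL, split = NULL,
                         threshold = 0.55, seed = 1L) {
  task <- match.arg(task)
  cfg <- default_stacking_config(task, seed = seed)
  base <- base %||% cfg$base
  meta <- meta %||% cfg$meta
  if (is.null(names(base))) names(base) <- paste0("base", seq_along(base))
  split <- split %||% split_spec(0.6, stratified = task == "classification",
                                 seed = seed)
  if (task == "classification") {
    stopifnot(threshold > 0, threshold < 1)
    y <- as.integer(y)
  }
  x <- if (is.matrix(blocks)) blocks else design_matrix(blocks)
  if (nrow(x) < 20L) stop("need at least 20 samples", call. = FALSE)
  stopifnot(nrow(x) == length(y))

  df <- tibble::tibble(.row = seq_len(nrow(x)))
  if (split$stratified) df$label <- y
  parts <- stratified_split(df, split)
  i60 <- parts$a$.row
  i40 <- parts$b$.row
  if (task == "classification" &&
      (length(unique(y[i60])) < 2L || length(unique(y[i40])) < 2L)) {
    stop("degenerate partition: both classes required in both partitions",
         call. = FALSE)
  }

  base_fits <- lapply(base, function(spec) {
    stopifnot(identical(spec$task, task))
    fit_learner(spec, x[i60, , drop = FALSE], y[i60])
  })
  blp40 <- blp_matrix(base_fits, x[i40, , drop = FALSE])
  meta_x <- cbind(x[i40, , drop = FALSE], blp40)
  stopifnot(identical(meta$task, task))
  meta_fit <- fit_learner(meta, meta_x, y[i40])

  structure(list(
    task = task,
    groups = if (is.matrix(blocks)) NULL else names(blocks),
    feature_names = colnames(x),
    base_fits = base_fits,
    meta_fit = meta_fit,
    threshold = if (task == "classification") threshold else NULL,
    split = split,
    seed = seed,
    n_train = nrow(x),
    n60 = length(i60), n40 = length(i40)
  ), class = "nif_stack")
}

blp_matrix <- function(base_fits, x) {
  cols <- lapply(base_fits, function(f) {
    predict_learner(f, x,
                    type = if (f$spec$task == "classification") "prob"
                           else "response")
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("BLP_", names(base_fits))
  out
}

#' @export
print.nif_stack <- function(x, ...) {
  cat("<nif_stack> ", x$task, " stacking ensemble\n", sep = "")
  cat("  base: ", paste(names(x$base_fits), collapse = ", "),
      " | meta: ", x$meta_fit$spec$family, "\n", sep = "")
  cat("  features: ", length(x$feature_names),
      if (!is.null(x$groups)) paste0(" (groups: ",
                                     paste(x$groups, collapse = ", "), ")"),
      "\n", sep = "")
  if (!is.null(x$threshold)) cat("  threshold: ", x$threshold, "\n", sep = "")
  invisible(x)
}

stack_design <- function(model, blocks) {
  x <- if (is.matrix(blocks)) blocks else {
    if (!is.null(model$groups)) {
      missing_groups <- setdiff(model$groups, names(blocks))
      if (length(missing_groups)) {
        stop("missing feature group(s): ",
             paste(missing_groups, collapse = ", "), call. = FALSE)
      }
      design_matrix(blocks, model$groups)
    } else design_matrix(blocks)
  }
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  x
}

#' Meta-learner probabilities from a stacking model
#'
#' Computes base-learner outputs on the new samples, augments the features
#' with them, and returns the meta learner's positive-class probability.
#'
#' @param model A fitted `nif_stack` (classification).
#' @param blocks Feature blocks (named list) or design matrix for the new
#'   samples.
#' @return Numeric probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, blocks) {
  stopifnot(inherits(model, "nif_stack"))
  if (model$task != "classification") {
    stop("predict_proba applies to classification models", call. = FALSE)
  }
  x <- stack_design(model, blocks)
  meta_x <- cbind(x, blp_matrix(model$base_fits, x))
  predict_learner(model$meta_fit, meta_x, type = "prob")
}

#' Predicted labels at the decision threshold
#'
#' Positive (1) when the meta probability is greater than or equal to the
#' threshold — the stored model threshold (default 0.55) unless overridden.
#'
#' @inheritParams predict_proba
#' @param threshold Optional override in (0, 1).
#' @return Integer 0/1 labels.
#' @export
predict_label <- function(model, blocks, threshold = NULL) {
  thr <- threshold %||% model$threshold
  if (is.null(thr) || thr <= 0 || thr >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  as.integer(predict_proba(model, blocks) >= thr)
}

#' Predicted activity from a regression stacking model
#'
#' Returns predictions on the log scale (`log10(activity + 2)`) and, via the
#' inverse transform, on the original activity scale.
#'
#' @param model A fitted `nif_stack` (regression).
#' @param blocks Feature blocks or design matrix.
#' @return Tibble with columns `pred_log` and `pred_activity`.
#' @export
predict_activity <- function(model, blocks) {
  stopifnot(inherits(model, "nif_stack"))
  if (model$task != "regression") {
    stop("predict_activity applies to regression models", call. = FALSE)
  }
  x <- stack_design(model, blocks)
  meta_x <- cbind(x, blp_matrix(model$base_fits, x))
  pred <- predict_learner(model$meta_fit, meta_x, type = "response")
  tibble::tibble(pred_log = pred,
                 pred_activity = pmax(inverse_transform_activity(pred), 0))
}

#' @export
predict.nif_stack <- function(object, blocks, ...) {
  if (object$task == "classification") {
    p <- predict_proba(object, blocks)
    tibble::tibble(prob = p,
                   label = as.integer(p >= object$threshold))
  } else {
    predict_activity(object, blocks)
  }
}

# ---- grid search --------------------------------------------------------

#' Hyperparameter grids searched for each tuned learner
#'
#' The grids over which the base and meta learners were tuned: KNN
#' (n_neighbors 3/5/7, weights uniform/distance, algorithm auto/ball_tree/
#' kd_tree/brute, leaf_size 30/50/100), RF (n_estimators, max_depth,
#' min_samples_split, min_samples_leaf, max_features, bootstrap, plus the
#' decision threshold 0.4-0.7), DTR, XGBR and SVR. `algorithm` and
#' `leaf_size` only affect neighbour-search internals in other
#' implementations; the in-package exact KNN accepts and records them.
#'
#' @param family One of `"knn"`, `"rf"`, `"dtr"`, `"xgbr"`, `"svr"`.
#' @return Named list of searched values.
#' @export
tuning_grid <- function(family = c("knn", "rf", "dtr", "xgbr", "svr")) {
  family <- match.arg(family)
  switch(family,
    knn = list(n_neighbors = c(3L, 5L, 7L),
               weights = c("uniform", "distance"),
               algorithm = c("auto", "ball_tree", "kd_tree", "brute"),
               leaf_size = c(30L, 50L, 100L)),
    rf = list(n_estimators = c(100L, 200L),
              max_depth = list("None", 10L),
              min_samples_split = c(2L, 5L),
              min_samples_leaf = c(1L, 2L),
              max_features = list("sqrt", "log2", "None"),
              bootstrap = c(TRUE, FALSE)),
    dtr = list(max_depth = list("None", 5L, 10L, 20L),
               splitter = c("best", "random"),
               min_samples_split = c(2L, 5L, 10L),
               min_samples_leaf = c(1L, 2L, 4L),
               max_features = list("sqrt", "log2", "None")),
    xgbr = list(max_depth = c(3L, 5L, 10L),
                learning_rate = c(0.01, 0.1, 0.2),
                n_estimators = c(100L, 200L),
                gamma = c(0, 1, 5)),
    svr = list(kernel = c("rbf", "linear"),
               C = c(0.1, 1, 10),
               epsilon = c(0.01, 0.1, 1),
               gamma = c("scale", "auto"))
  )
}

#' Exhaustive grid search over a hyperparameter grid
#'
#' Evaluates every cell of the grid by cross-validation and returns the tuned
#' [learner_spec()]. Cells are enumerated in grid order (first parameter
#' varies fastest); ties keep the first cell. A cell that fails to fit scores
#' `-Inf` and is logged with a warning.
#'
#' @param family Learner family.
#' @param grid Named list of candidate values; defaults to [tuning_grid()]
#'   for tuned families.
#' @param x Design matrix or named list of feature blocks.
#' @param y Labels or targets.
#' @param folds CV folds (default 5).
#' @param metric Passed to [cv_score()].
#' @param seed Fold seed (also stored in the specs).
#' @return List: `spec` (tuned [learner_spec()]), `results` (tibble of every
#'   cell with its score), `n_cells`.
#' @export
grid_search <- function(family, grid = NULL, x, y, folds = 5L,
                        metric = NULL, seed = 1L) {
  grid <- grid %||% tuning_grid(family)
  stopifnot(is.list(grid), length(grid) >= 1L)
  x <- if (is.matrix(x)) x else design_matrix(x)
  cells <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  scores <- numeric(n_cells)
  specs <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    params <- lapply(names(grid), function(p) grid[[p]][[cells[i, p]]])
    names(params) <- names(grid)
    spec <- learner_spec(family, params, seed = seed)
    specs[[i]] <- spec
    scores[i] <- tryCatch(
      cv_score(x, y, spec, folds = folds, metric = metric, seed = seed),
      error = function(e) {
        warning("grid cell ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        -Inf
      })
  }
  best <- which.max(scores) # first max = first in grid order on ties
  results <- tibble::tibble(
    cell = seq_len(n_cells),
    params = lapply(specs, function(s) s$params),
    score = scores
  )
  list(spec = specs[[best]], results = results, n_cells = n_cells)
}

# ---- persistence --------------------------------------------------------

MODEL_FORMAT_VERSION <- "1"

#' Save / load a stacking model
#'
#' The archive is a directory holding `meta.json` (format version, task,
#' learner families, feature groups, threshold, seeds) and `model.rds` (the
#' fitted learner states). Loading verifies the format version and produces a
#' model giving identical predictions.
#'
#' @param model A `nif_stack`.
#' @param path Archive directory.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nif_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format_version = MODEL_FORMAT_VERSION,
    task = model$task,
    base = lapply(model$base_fits, function(f) f$spec$family),
    meta_learner = model$meta_fit$spec$family,
    groups = model$groups,
    threshold = model$threshold,
    seed = model$seed,
    n_train = model$n_train
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(path, "model.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  rds_path <- file.path(path, "model.rds")
  if (!file.exists(meta_path) || !file.exists(rds_path)) {
    stop("not a model archive (missing meta.json/model.rds): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path)
  if (!identical(as.character(meta$format_version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", meta$format_version,
         call. = FALSE)
  }
  model <- readRDS(rds_path)
  if (!inherits(model, "nif_stack")) stop("corrupt model archive",
                                          call. = FALSE)
  model
}
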