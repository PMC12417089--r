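# Learner registry: a thin uniform fit/predict layer over the model families
# used as base learners, meta learners and selection evaluators. Hyperparameter
# names follow the grids the models were tuned over (n_neighbors,
# n_estimators, max_depth, learning_rate, ...) and are translated to each
# backend's arguments; unlisted parameters keep the backend defaults.

CLASSIFICATION_FAMILIES <- c("knn", "rf", "svm", "xgb", "logistic", "dtc",
                             "constant")
REGRESSION_FAMILIES <- c("knnr", "rfr", "svr", "xgbr", "dtr", "ridge",
                         "lasso", "lm", "mean")

#' Learner specification
#'
#' @param family Model family. Classification: `knn`, `rf`, `svm`, `xgb`,
#'   `logistic`, `dtc`, `constant`. Regression: `knnr`, `rfr`, `svr`, `xgbr`,
#'   `dtr`, `ridge`, `lasso`, `lm`, `mean`.
#' @param params Named list of hyperparameters (sklearn-style names such as
#'   `n_neighbors`, `n_estimators`, `max_depth`, `learning_rate`, `C`,
#'   `epsilon`, `gamma`).
#' @param seed Integer seed; every stochastic fit is wrapped in it.
#' @param task `"classification"` or `"regression"`; inferred from the family
#'   when omitted.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(family, params = list(), seed = 1L, task = NULL) {
  if (is.null(task)) {
    task <- if (family %in% CLASSIFICATION_FAMILIES) "classification"
            else if (family %in% REGRESSION_FAMILIES) "regression"
            else stop("unknown learner family: ", family, call. = FALSE)
  }
  task <- match.arg(task, c("classification", "regression"))
  ok <- if (task == "classification") CLASSIFICATION_FAMILIES
        else REGRESSION_FAMILIES
  if (!family %in% ok) {
    stop("family '", family, "' is not registered for ", task, call. = FALSE)
  }
  structure(list(family = family, params = params, seed = as.integer(seed),
                 task = task),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), vapply(x$params, function(p) paste(p, collapse = "/"),
                                  character(1L)), sep = "=", collapse = ", ")
  } else "defaults"
  cat("<learner_spec> ", x$family, " (", x$task, "; ", ps, "; seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

param <- function(spec, name, default) spec$params[[name]] %||% default

#' Fit a learner on a design matrix
#'
#' @param spec A [learner_spec()].
#' @param x Numeric design matrix (samples x features).
#' @param y Integer 0/1 labels (classification) or numeric targets
#'   (regression).
#' @return A `fitted_learner` object usable with [predict_learner()].
#' @export
fit_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"), is.matrix(x),
            nrow(x) == length(y))
  if (spec$task == "classification") {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  }
  local_rng(spec$seed)
  fit <- switch(
    spec$family,
    knn = , knnr = list(x = x, y = y,
                        k = param(spec, "n_neighbors", 5L),
                        weights = param(spec, "weights", "uniform")),
    rf = fit_rf(spec, x, factor(y, levels = c(0L, 1L))),
    rfr = fit_rf(spec, x, as.numeric(y)),
    svm = e1071::svm(x, factor(y, levels = c(0L, 1L)), probability = TRUE,
                     kernel = svm_kernel(param(spec, "kernel", "rbf")),
                     cost = param(spec, "C", 1),
                     gamma = svm_gamma(param(spec, "gamma", "scale"), x)),
    svr = e1071::svm(x, as.numeric(y), type = "eps-regression",
                     kernel = svm_kernel(param(spec, "kernel", "rbf")),
                     cost = param(spec, "C", 1),
                     epsilon = param(spec, "epsilon", 0.1),
                     gamma = svm_gamma(param(spec, "gamma", "scale"), x)),
    xgb = fit_xgb(spec, x, y, "binary:logistic"),
    xgbr = fit_xgb(spec, x, y, "reg:squarederror"),
    logistic = fit_logistic(x, y),
    dtc = fit_rpart(spec, x, factor(y, levels = c(0L, 1L)), "class"),
    dtr = fit_rpart(spec, x, as.numeric(y), "anova"),
    ridge = fit_glmnet(spec, x, y, alpha = 0),
    lasso = fit_glmnet(spec, x, y, alpha = 1),
    lm = fit_logistic(x, y, gaussian = TRUE),
    constant = list(p = mean(y)),
    mean = list(p = mean(y)),
    stop("unknown family: ", spec$family, call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, p = ncol(x),
                 feat = colnames(x)),
            class = "fitted_learner")
}

fit_rf <- function(spec, x, y) {
  p <- ncol(x)
  mf <- param(spec, "max_features", "sqrt")
  mtry <- if (is.null(mf) || identical(mf, "None")) p
          else if (identical(mf, "sqrt")) max(1L, floor(sqrt(p)))
          else if (identical(mf, "log2")) max(1L, floor(log2(p)))
          else max(1L, as.integer(mf))
  md <- param(spec, "max_depth", NULL)
  randomForest::randomForest(
    x, y,
    ntree = param(spec, "n_estimators", 100L),
    mtry = mtry,
    nodesize = max(param(spec, "min_samples_leaf", 1L),
                   ceiling(param(spec, "min_samples_split", 2L) / 2)),
    maxnodes = if (is.null(md) || identical(md, "None")) NULL else 2L^md,
    replace = param(spec, "bootstrap", TRUE)
  )
}

fit_xgb <- function(spec, x, y, objective) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(
    params = list(objective = objective,
                  max_depth = param(spec, "max_depth", 6L),
                  eta = param(spec, "learning_rate", 0.3),
                  gamma = param(spec, "gamma", 0),
                  nthread = 1, seed = spec$seed),
    data = dtrain,
    nrounds = param(spec, "n_estimators", 100L),
    verbose = 0
  )
}

fit_rpart <- function(spec, x, y, method) {
  md <- param(spec, "max_depth", NULL)
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, method = method,
               control = rpart::rpart.control(
                 maxdepth = if (is.null(md) || identical(md, "None")) 30L
                            else as.integer(md),
                 minsplit = param(spec, "min_samples_split", 2L),
                 minbucket = param(spec, "min_samples_leaf", 1L),
                 cp = param(spec, "cp", 0.001), xval = 0L))
}

fit_logistic <- function(x, y, gaussian = FALSE) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  fam <- if (gaussian) stats::gaussian() else stats::binomial()
  suppressWarnings(stats::glm(.y ~ ., data = df, family = fam))
}

fit_glmnet <- function(spec, x, y, alpha) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("glmnet not available", call. = FALSE)
  }
  list(model = glmnet::glmnet(x, y, alpha = alpha,
                              lambda = param(spec, "lambda", 0.01)),
       lambda = param(spec, "lambda", 0.01))
}

svm_kernel <- function(k) {
  switch(tolower(as.character(k)), rbf = , radial = "radial",
         linear = "linear", poly = "polynomial", sigmoid = "sigmoid",
         stop("unknown SVM kernel: ", k, call. = FALSE))
}

svm_gamma <- function(g, x) {
  if (is.numeric(g)) return(g)
  p <- ncol(x)
  switch(as.character(g),
         scale = 1 / (p * max(stats::var(as.vector(x)), 1e-12)),
         auto = 1 / p,
         stop("unknown gamma spec: ", g, call. = FALSE))
}

#' Predict from a fitted learner
#'
#' @param object A `fitted_learner`.
#' @param x Numeric matrix of new samples.
#' @param type `"prob"` (positive-class probability, classification),
#'   `"label"` (0/1 at probability 0.5), or `"response"` (regression value).
#' @return Numeric (prob/response) or integer (label) vector.
#' @export
predict_learner <- function(object, x,
                            type = c("prob", "label", "response")) {
  stopifnot(inherits(object, "fitted_learner"), is.matrix(x))
  type <- match.arg(type)
  spec <- object$spec
  if (spec$task == "regression" && type != "response") {
    stop("regression learners predict type = 'response'", call. = FALSE)
  }
  if (spec$task == "classification" && type == "response") {
    stop("classification learners predict 'prob' or 'label'", call. = FALSE)
  }
  out <- switch(
    spec$family,
    knn = knn_predict(object$fit, x, classify = TRUE),
    knnr = knn_predict(object$fit, x, classify = FALSE),
    rf = predict(object$fit, x, type = "prob")[, "1"],
    rfr = as.numeric(predict(object$fit, x)),
    svm = attr(predict(object$fit, x, probability = TRUE),
               "probabilities")[, "1"],
    svr = as.numeric(predict(object$fit, x)),
    xgb = , xgbr = as.numeric(predict(object$fit,
                                      xgboost::xgb.DMatrix(x, nthread = 1))),
    logistic = , lm = {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(suppressWarnings(predict(object$fit, df,
                                          type = "response")))
    },
    dtc = predict(object$fit, rpart_frame(x), type = "prob")[, "1"],
    dtr = as.numeric(predict(object$fit, rpart_frame(x))),
    ridge = , lasso = as.numeric(predict(object$fit$model, x,
                                         s = object$fit$lambda)),
    constant = , mean = rep(object$fit$p, nrow(x))
  )
  if (spec$task == "classification") {
    out <- pmin(pmax(out, 0), 1)
    if (type == "label") out <- as.integer(out >= 0.5)
  }
  unname(out)
}

rpart_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df
}

# Brute-force k-nearest-neighbour prediction with uniform or inverse-distance
# weights (classification: weighted positive fraction; regression: weighted
# mean). Exact-match neighbours (distance 0) take the whole vote.
knn_predict <- function(fit, x, classify) {
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(x^2), rowSums(fit$x^2), `+`) -
    2 * tcrossprod(x, fit$x)
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(x)), function(i) {
    ord <- order(d2[i, ], decreasing = FALSE)[seq_len(k)]
    dd <- sqrt(d2[i, ord])
    yk <- as.numeric(fit$y[ord])
    if (identical(fit$weights, "distance")) {
      if (any(dd == 0)) return(mean(yk[dd == 0]))
      w <- 1 / dd
      sum(w * yk) / sum(w)
    } else {
      mean(yk)
    }
  }, numeric(1L))
}
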