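# Stacking ensembles, grid search, persistence.

separable_classification <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2L)[sample.int(n)]
  x <- cbind(f1 = y * 2 - 1 + rnorm(n, 0, 0.05), f2 = rnorm(n))
  list(blocks = list(main = as_block(x, sprintf("S%03d", 1:n))), y = y)
}

test_that("stacking achieves perfect accuracy on separable data", {
  d <- separable_classification(200L, seed = 2L)
  model <- fit_stacking(d$blocks, d$y, task = "classification", seed = 2L)
  expect_identical(predict_label(model, d$blocks), d$y)
})

test_that("noiseless linear regression reaches held-out R2 >= 0.9", {
  set.seed(3)
  n <- 260L
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 2 * x[, "a"] - x[, "b"]
  blocks <- list(main = as_block(x, sprintf("S%03d", 1:n)))
  train <- 1:200
  test <- 201:n
  tr_blocks <- list(main = blocks$main[train, ])
  te_blocks <- list(main = blocks$main[test, ])
  model <- fit_stacking(tr_blocks, y[train], task = "regression", seed = 3L)
  pred <- predict_activity(model, te_blocks)
  expect_gte(regression_metrics(y[test], pred$pred_log)$r2, 0.9)
})

test_that("stacking is deterministic under fixed seeds", {
  d <- separable_classification(120L, seed = 7L)
  m1 <- fit_stacking(d$blocks, d$y, seed = 7L)
  m2 <- fit_stacking(d$blocks, d$y, seed = 7L)
  expect_identical(predict_proba(m1, d$blocks), predict_proba(m2, d$blocks))
})

test_that("meta input width = feature width + one column per base learner", {
  d <- separable_classification(100L, seed = 4L)
  model <- fit_stacking(d$blocks, d$y, seed = 4L)
  gl <- glance(model)
  expect_identical(gl$meta_input_width, gl$n_features + gl$n_base_learners)
  expect_identical(model$meta_fit$p,
                   length(model$feature_names) + length(model$base_fits))
  td <- tidy(model)
  expect_identical(td$layer, c("base", "meta"))
})

test_that("probabilities are bounded and consistent with labels", {
  d <- separable_classification(100L, seed = 5L)
  model <- fit_stacking(d$blocks, d$y, seed = 5L)
  p <- predict_proba(model, d$blocks)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict_label(model, d$blocks),
                   as.integer(p >= model$threshold))
  # threshold comparison is inclusive (>=) and overrides are validated
  expect_identical(as.integer(p >= 0.4),
                   predict_label(model, d$blocks, threshold = 0.4))
  expect_error(predict_label(model, d$blocks, threshold = 1.5), "threshold")
  pr <- predict(model, d$blocks)
  expect_identical(names(pr), c("prob", "label"))
})

test_that("degenerate partitions and small samples are rejected", {
  set.seed(6)
  x <- matrix(rnorm(30L), 15L, 2L)
  blocks <- list(m = as_block(x))
  expect_error(fit_stacking(blocks, rep(c(0L, 1L), c(7L, 8L)), seed = 1L),
               "at least 20")
  d <- separable_classification(40L, seed = 6L)
  expect_error(fit_stacking(d$blocks, rep(0L, 40L), seed = 1L), "class")
})

test_that("stacked model beats the meta-only model on planted-BLP signal", {
  # base-learnable nonlinear signal: the base KNN's held-out probabilities
  # carry information the linear meta learner cannot extract from the raw
  # features, mirroring the with/without-BLP ablation
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 240L
    x <- matrix(rnorm(n * 2L), n, 2L, dimnames = list(NULL, c("a", "b")))
    y <- as.integer(xor(x[, 1] > 0, x[, 2] > 0))
    train <- 1:160
    test <- 161:n
    blocks_tr <- list(m = as_block(x[train, ], sprintf("S%03d", train)))
    blocks_te <- list(m = as_block(x[test, ], sprintf("S%03d", test)))
    meta_spec <- learner_spec("logistic", seed = seed)
    stacked <- fit_stacking(blocks_tr, y[train],
                            base = list(KNN = learner_spec(
                              "knn", list(n_neighbors = 5L), seed = seed)),
                            meta = meta_spec, seed = seed)
    acc_stacked <- mean(predict_label(stacked, blocks_te) == y[test])
    meta_only <- fit_learner(meta_spec, x[train, ], y[train])
    acc_meta <- mean(predict_learner(meta_only, x[test, ], "label") ==
                       y[test])
    if (acc_stacked > acc_meta) wins <- wins + 1L
  }
  expect_gte(wins, 16L) # >= 80% of 20 seeds
})

test_that("grid search enumerates every cell once and finds the planted optimum", {
  d <- separable_classification(80L, seed = 8L)
  x <- design_matrix(d$blocks)
  # single-cell grid returns that cell
  g1 <- grid_search("knn", list(n_neighbors = 3L), x, d$y, folds = 3L)
  expect_identical(g1$n_cells, 1L)
  expect_identical(g1$spec$params$n_neighbors, 3L)
  # full KNN grid: 3 x 2 x 4 x 3 = 72 cells, enumerated exactly once each
  grid <- tuning_grid("knn")
  cells <- expand.grid(lapply(grid, seq_along))
  expect_identical(nrow(cells), 72L)
  g <- grid_search("knn", grid, x[1:40, ], d$y[1:40], folds = 2L)
  expect_identical(g$n_cells, 72L)
  expect_identical(nrow(g$results), 72L)
  expect_identical(anyDuplicated(g$results$params), 0L)
  # planted optimum: only k=1 separates a memorisable XOR-like pattern
  set.seed(9)
  n <- 60L
  xs <- matrix(rnorm(n * 2L), n, 2L)
  ys <- as.integer(xor(xs[, 1] > 0, xs[, 2] > 0))
  gknn <- grid_search("knn", list(n_neighbors = c(1L, 35L)), xs, ys,
                      folds = 3L)
  expect_identical(gknn$spec$params$n_neighbors, 1L)
})

test_that("grid layouts match the tuned search spaces", {
  expect_identical(vapply(tuning_grid("rf"), length, integer(1L)),
                   c(n_estimators = 2L, max_depth = 2L,
                     min_samples_split = 2L, min_samples_leaf = 2L,
                     max_features = 3L, bootstrap = 2L))
  expect_identical(prod(lengths(tuning_grid("dtr"))), 216)
  expect_identical(prod(lengths(tuning_grid("xgbr"))), 54)
  expect_identical(prod(lengths(tuning_grid("svr"))), 36)
})

test_that("models round-trip through the versioned archive", {
  d <- separable_classification(80L, seed = 10L)
  model <- fit_stacking(d$blocks, d$y, seed = 10L)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_identical(predict_proba(back, d$blocks),
                   predict_proba(model, d$blocks))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_identical(meta$task, "classification")
  # version mismatch is rejected
  meta$format_version <- "999"
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "format version")
  expect_error(load_model(withr::local_tempdir()), "archive")
})

test_that("default configurations carry the tuned hyperparameters", {
  cls <- default_stacking_config("classification")
  expect_identical(cls$base$KNN$params$n_neighbors, 5L)
  expect_identical(cls$meta$family, "rf")
  expect_identical(cls$meta$params$max_features, "log2")
  expect_identical(cls$threshold, 0.55)
  reg <- default_stacking_config("regression")
  expect_setequal(names(reg$base), c("DTR", "XGBR"))
  expect_identical(reg$base$XGBR$params$learning_rate, 0.01)
  expect_identical(reg$meta$family, "svr")
  expect_identical(reg$meta$params$kernel, "rbf")
})
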