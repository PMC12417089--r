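# Cross-validation scoring, incremental feature-group selection, incremental
# mutual-information learner selection.

test_that("cv_score is perfect on a label-copy feature and deterministic", {
  set.seed(1)
  y <- rep(c(0L, 1L), 30L)[sample.int(60L)]
  blocks <- list(copy = as_block(cbind(lab = y),
                                 sprintf("S%03d", 1:60)))
  s <- cv_score(blocks, y, cheap_classifier(), seed = 2L)
  expect_equal(s, 1.0)
  expect_identical(cv_score(blocks, y, cheap_classifier(), seed = 2L), s)
})

test_that("cv_score on pure noise vs balanced labels stays near chance", {
  scores <- vapply(1:5, function(seed) {
    set.seed(seed)
    y <- rep(c(0L, 1L), 100L)[sample.int(200L)]
    blocks <- list(noise = as_block(matrix(rnorm(200 * 4), 200L, 4L)))
    cv_score(blocks, y, cheap_classifier(seed), seed = seed)
  }, numeric(1L))
  expect_true(all(abs(scores - 0.5) < 0.15))
})

test_that("fold construction is stratified and errors when impossible", {
  y <- rep(c(0L, 1L), c(10L, 10L))
  folds <- nifstack:::make_folds(y, 5L, TRUE, 1L)
  for (f in 1:5) {
    expect_identical(sum(y[folds == f] == 1L), 2L)
  }
  expect_error(nifstack:::make_folds(y, 25L, TRUE, 1L), "impossible")
  expect_error(nifstack:::make_folds(c(0L, rep(1L, 9L)), 2L, TRUE, 1L),
               "fewer than 2")
})

test_that("IFS selects a planted informative group first and keeps it", {
  hits_first <- 0L
  for (seed in 1:20) {
    pl <- planted_classification(n = 120L, n_noise_groups = 3L, seed = seed)
    trace <- ifs_search(pl$groups, pl$y, cheap_classifier(seed), seed = seed)
    round1 <- trace$rounds[trace$rounds$round == 1L, ]
    winner <- round1$set[[which.max(round1$score)]]
    if (identical(winner, "signal")) hits_first <- hits_first + 1L
    expect_true("signal" %in% trace$final_set)
  }
  expect_gte(hits_first, 18L) # >= 90% of 20 seeds
})

test_that("IFS finds both groups of an additive split signal", {
  ok <- 0L
  for (seed in 1:10) {
    pl <- planted_regression(n = 150L, seed = seed)
    trace <- ifs_search(pl$groups, pl$y, cheap_regressor(seed), seed = seed)
    if (all(c("partA", "partB") %in% trace$final_set)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("IFS trace structure: exhaustion, extension-by-one, trace size", {
  pl <- planted_classification(n = 60L, n_noise_groups = 4L, seed = 3L)
  G <- length(pl$groups) # 5
  trace <- ifs_search(pl$groups, pl$y, cheap_classifier(), seed = 3L)
  expect_identical(nrow(trace$rounds), sum(seq_len(G)))
  expect_identical(max(trace$rounds$round), G)
  # each round's retained set extends the previous by exactly one group
  retained <- trace$rounds[trace$rounds$retained, ]
  retained <- retained[order(retained$round), ]
  for (r in seq_len(G)) {
    expect_identical(lengths(retained$set)[r], r)
    if (r > 1L) {
      expect_true(all(retained$set[[r - 1L]] %in% retained$set[[r]]))
    }
  }
  # final score equals the maximum over every evaluated set, exactly
  expect_identical(trace$final_score, max(trace$rounds$score))
  # ties break toward fewer groups
  best <- trace$rounds$score == trace$final_score
  expect_identical(length(trace$final_set), min(lengths(trace$rounds$set[best])))
})

test_that("selection traces serialise to JSON and render as tables", {
  pl <- planted_classification(n = 60L, n_noise_groups = 2L, seed = 5L)
  trace <- ifs_search(pl$groups, pl$y, cheap_classifier(), seed = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_trace(trace, path)
  back <- jsonlite::read_json(path)
  expect_identical(unlist(back$final_set), trace$final_set)
  expect_equal(back$final_score, trace$final_score, tolerance = 1e-12)
  expect_identical(length(back$rounds), nrow(trace$rounds))
  tbl <- format_selection_table(trace)
  expect_identical(length(tbl), nrow(trace$rounds) + 2L)
  td <- tidy(trace)
  expect_identical(nrow(td), nrow(trace$rounds))
  gl <- glance(trace)
  expect_identical(gl$n_evaluated, nrow(trace$rounds))
  p <- autoplot(trace)
  expect_s3_class(p, "ggplot")
})

test_that("IMI selects a memorising learner first among weak candidates", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 160L
    x <- matrix(rnorm(n * 2L), n, 2L, dimnames = list(NULL, c("a", "b")))
    y <- as.integer(xor(x[, 1] > 0, x[, 2] > 0)) # non-linear mapping
    cands <- list(
      KNN = learner_spec("knn", list(n_neighbors = 3L), seed = seed),
      LOGIT = learner_spec("logistic", seed = seed),
      CONST = learner_spec("constant", seed = seed)
    )
    trace <- imi_search(cands, x, y, seed = seed)
    round1 <- trace$rounds[trace$rounds$round == 1L, ]
    if (identical(round1$set[[which.max(round1$score)]], "KNN")) {
      hits <- hits + 1L
    }
    expect_true("KNN" %in% trace$final_set)
  }
  expect_gte(hits, 18L)
})

test_that("all-constant candidates give zero MI and the tie rule holds", {
  set.seed(2)
  x <- matrix(rnorm(100L), 50L, 2L)
  y <- rep(c(0L, 1L), 25L)
  cands <- list(C1 = learner_spec("constant"),
                C2 = learner_spec("constant"))
  trace <- imi_search(cands, x, y, seed = 1L)
  expect_true(all(trace$rounds$score == 0))
  expect_identical(trace$final_set, "C1") # first evaluated singleton
})

test_that("a failing candidate is skipped with a warning", {
  set.seed(3)
  x <- matrix(rnorm(80L), 40L, 2L)
  y <- rep(c(0L, 1L), 20L)
  boom <- learner_spec("logistic")
  boom$family <- "does_not_exist"
  cands <- list(OK = learner_spec("knn"), BAD = boom)
  expect_warning(trace <- imi_search(cands, x, y, seed = 1L), "skipped")
  expect_false(any(vapply(trace$rounds$set, function(s) "BAD" %in% s,
                          logical(1L))))
})

test_that("IMI works for regression with the k-NN MI objective", {
  set.seed(4)
  n <- 120L
  x <- matrix(rnorm(n * 3L), n, 3L)
  y <- x[, 1]^2 + rnorm(n, 0, 0.05) # tree-learnable, not linear
  cands <- list(
    DTR = learner_spec("dtr", list(max_depth = 5L), seed = 4L),
    MEAN = learner_spec("mean", seed = 4L)
  )
  trace <- imi_search(cands, x, y, seed = 4L)
  expect_identical(trace$rounds$set[[which.max(
    trace$rounds$score[trace$rounds$round == 1L])]], "DTR")
  expect_gte(trace$final_score, 0)
})
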