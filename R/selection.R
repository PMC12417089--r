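# Cross-validation scoring, greedy incremental feature-group selection (IFS)
# and incremental mutual-information base-learner selection (IMI).

#' Cross-validated score of a feature-group subset
#'
#' Concatenates the given blocks into a design matrix and scores an evaluator
#' learner by k-fold cross-validation: stratified folds for classification
#' (metric `"f1"` on predicted labels), shuffled folds for regression (metric
#' `"r2"`). An F1 undefined on a fold (no positive predictions or truths)
#' counts as 0. With `repeats > 1` the full CV is repeated under seeds
#' `seed, seed + 1, ...` and the scores averaged.
#'
#' @param blocks Named list of feature-block tibbles, or a numeric design
#'   matrix.
#' @param y Labels (0/1) or numeric targets.
#' @param evaluator A [learner_spec()].
#' @param folds Number of CV folds (default 5).
#' @param metric `"f1"` or `"r2"`; defaults to the evaluator's task.
#' @param seed Fold-construction seed.
#' @param repeats Number of repeated CV rounds to average.
#' @return Mean score across folds (and repeats).
#' @export
cv_score <- function(blocks, y, evaluator, folds = 5L, metric = NULL,
                     seed = 1L, repeats = 1L) {
  stopifnot(inherits(evaluator, "learner_spec"))
  metric <- metric %||% switch(evaluator$task, classification = "f1",
                               regression = "r2")
  metric <- match.arg(metric, c("f1", "r2"))
  x <- if (is.matrix(blocks)) blocks else design_matrix(blocks)
  stopifnot(nrow(x) == length(y))
  scores <- vapply(seq_len(repeats), function(r) {
    fold_id <- make_folds(y, folds, evaluator$task == "classification",
                          seed + r - 1L)
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_learner(evaluator, x[tr, , drop = FALSE], y[tr])
      if (metric == "f1") {
        pred <- predict_learner(fit, x[!tr, , drop = FALSE], type = "label")
        classification_metrics(confusion_counts(as.integer(y[!tr]), pred))$f1
      } else {
        pred <- predict_learner(fit, x[!tr, , drop = FALSE],
                                type = "response")
        regression_metrics(y[!tr], pred)$r2
      }
    }, numeric(1L))
    mean(per_fold)
  }, numeric(1L))
  mean(scores)
}

make_folds <- function(y, folds, stratified, seed) {
  n <- length(y)
  if (folds < 2L || folds > n) stop("impossible fold count", call. = FALSE)
  local_rng(seed)
  fold_id <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      if (length(rows) < 2L) {
        stop("class ", cl, " has fewer than 2 members; cannot stratify",
             call. = FALSE)
      }
      fold_id[sample(rows)] <- rep_len(seq_len(folds), length(rows))
    }
  } else {
    fold_id[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  fold_id
}

# ---- selection traces ---------------------------------------------------

new_selection_trace <- function(rounds, objective, seed, kind) {
  stopifnot(is.data.frame(rounds))
  scores <- rounds$score
  best <- order(-scores, lengths(rounds$set), seq_along(scores))[1L]
  structure(list(rounds = tibble::as_tibble(rounds),
                 final_set = rounds$set[[best]],
                 final_score = unname(scores[best]),
                 objective = objective, seed = seed, kind = kind),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", x$kind, " (", x$objective, "), ",
      nrow(x$rounds), " sets evaluated\n", sep = "")
  cat("final: {", paste(x$final_set, collapse = ", "), "} score ",
      signif(x$final_score, 4L), "\n", sep = "")
  invisible(x)
}

#' Greedy incremental feature-group selection
#'
#' Round 1 scores every single feature group by cross-validation; each later
#' round scores the retained set extended by each unused group and keeps the
#' best extension. The search runs until all groups are included; the final
#' selection is the global maximum over every evaluated set, ties broken by
#' fewer groups, then by evaluation order. Over G groups, G + (G-1) + ... + 1
#' candidate sets are evaluated.
#'
#' @param groups Named list of feature-block tibbles.
#' @param y Labels or targets.
#' @param evaluator A [learner_spec()]; gradient-boosted trees by default
#'   (classification `xgb`, regression `xgbr`).
#' @param folds,metric,seed,repeats Passed to [cv_score()].
#' @return A `selection_trace`.
#' @export
ifs_search <- function(groups, y, evaluator = NULL, folds = 5L,
                       metric = NULL, seed = 1L, repeats = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)), !anyDuplicated(names(groups)))
  if (is.null(evaluator)) {
    task <- if (all(y %in% c(0L, 1L))) "classification" else "regression"
    evaluator <- learner_spec(if (task == "classification") "xgb" else "xgbr",
                              seed = seed)
  }
  retained <- character(0)
  rows <- list()
  round_i <- 0L
  while (length(retained) < length(groups)) {
    round_i <- round_i + 1L
    candidates <- setdiff(names(groups), retained)
    round_scores <- vapply(candidates, function(g) {
      cv_score(groups[c(retained, g)], y, evaluator, folds = folds,
               metric = metric, seed = seed, repeats = repeats)
    }, numeric(1L))
    for (i in seq_along(candidates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        round = round_i,
        set = list(c(retained, candidates[i])),
        score = unname(round_scores[i])
      )
    }
    retained <- c(retained, candidates[which.max(round_scores)])
  }
  rounds <- dplyr::bind_rows(rows)
  rounds$retained <- vapply(seq_len(nrow(rounds)), function(i) {
    setequal(rounds$set[[i]], retained[seq_len(rounds$round[i])])
  }, logical(1L))
  new_selection_trace(rounds,
                      objective = metric %||%
                        switch(evaluator$task, classification = "f1",
                               regression = "r2"),
                      seed = seed, kind = "feature_groups")
}

#' Greedy incremental mutual-information learner selection
#'
#' Fits each candidate base learner on the first partition of a 60/40 split
#' of the training data and produces its outputs on the held-out 40%
#' (predicted labels for classification, predictions for regression). The
#' objective is the mutual information between the joint outputs of the
#' current learner set and the truth (plug-in estimate for labels; k-NN
#' estimate for continuous outputs). Greedy growth and tie-breaking follow
#' the same scheme as [ifs_search()]. A candidate that fails to fit is
#' skipped with a warning.
#'
#' @param candidates Named list of [learner_spec()]s (all same task).
#' @param x Design matrix or named list of feature blocks.
#' @param y Labels (0/1) or numeric targets.
#' @param split_fraction Fraction of samples used to fit the candidates
#'   (default 0.6, matching the stacking protocol).
#' @param seed Split seed.
#' @param k Neighbour count for the continuous MI estimator.
#' @return A `selection_trace` over learner names.
#' @export
imi_search <- function(candidates, x, y, split_fraction = 0.6, seed = 1L,
                       k = 3L) {
  stopifnot(is.list(candidates), length(candidates) >= 1L,
            !is.null(names(candidates)))
  task <- candidates[[1L]]$task
  stopifnot(all(vapply(candidates, function(s) s$task, character(1L)) ==
                  task))
  x <- if (is.matrix(x)) x else design_matrix(x)
  classify <- task == "classification"
  df <- tibble::tibble(.row = seq_len(nrow(x)))
  if (classify) df$label <- as.integer(y)
  parts <- stratified_split(df, split_spec(split_fraction,
                                           stratified = classify,
                                           seed = seed))
  i60 <- parts$a$.row
  i40 <- parts$b$.row

  outputs <- list()
  for (nm in names(candidates)) {
    out <- tryCatch({
      fit <- fit_learner(candidates[[nm]], x[i60, , drop = FALSE], y[i60])
      predict_learner(fit, x[i40, , drop = FALSE],
                      type = if (classify) "label" else "response")
    }, error = function(e) {
      warning("candidate '", nm, "' failed to fit and was skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(out)) outputs[[nm]] <- out
  }
  if (length(outputs) == 0L) stop("no candidate fitted successfully",
                                  call. = FALSE)
  truth <- y[i40]
  objective <- function(set) {
    joint <- do.call(cbind, outputs[set])
    if (classify) discrete_mutual_information(joint, truth)
    else continuous_mutual_information(joint, truth, k = k,
                                       jitter_seed = seed)
  }

  retained <- character(0)
  rows <- list()
  round_i <- 0L
  while (length(retained) < length(outputs)) {
    round_i <- round_i + 1L
    cands <- setdiff(names(outputs), retained)
    sc <- vapply(cands, function(nm) objective(c(retained, nm)), numeric(1L))
    for (i in seq_along(cands)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        round = round_i, set = list(c(retained, cands[i])), score = unname(sc[i]))
    }
    retained <- c(retained, cands[which.max(sc)])
  }
  rounds <- dplyr::bind_rows(rows)
  rounds$retained <- vapply(seq_len(nrow(rounds)), function(i) {
    setequal(rounds$set[[i]], retained[seq_len(rounds$round[i])])
  }, logical(1L))
  new_selection_trace(rounds, objective = "mutual_information",
                      seed = seed, kind = "learners")
}

# ---- trace serialisation ------------------------------------------------

#' Serialise a selection trace as JSON
#'
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  payload <- list(
    kind = trace$kind, objective = trace$objective, seed = trace$seed,
    final_set = trace$final_set, final_score = trace$final_score,
    rounds = lapply(seq_len(nrow(trace$rounds)), function(i) {
      list(round = trace$rounds$round[i],
           set = trace$rounds$set[[i]],
           score = trace$rounds$score[i],
           retained = trace$rounds$retained[i])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Human-readable selection table
#'
#' Renders the trace in the layout used to report incremental selection
#' results: one row per evaluated set, the winner flagged.
#'
#' @param trace A `selection_trace`.
#' @return Character vector of table lines.
#' @export
format_selection_table <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  sets <- vapply(trace$rounds$set, paste, character(1L), collapse = ", ")
  best <- vapply(trace$rounds$set, setequal, logical(1L), trace$final_set)
  header <- sprintf("%-70s  %10s", "Set", trace$objective)
  body <- sprintf("%-70s  %10.4f%s", sets, trace$rounds$score,
                  ifelse(best, "  *", ""))
  c(header, strrep("-", nchar(header)), body)
}
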