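# Evaluation metrics: the classification suite (F1, SN, SP, ACC, BACC, PREC,
# MCC) from confusion counts, rank-based AUC, and the regression suite
# (R2, MSE, RMSE, MAE).

#' Confusion counts from labels
#'
#' @param truth Integer 0/1 truth vector.
#' @param pred Integer 0/1 prediction vector.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  c(tp = sum(truth == 1L & pred == 1L),
    fp = sum(truth == 0L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fn = sum(truth == 1L & pred == 0L))
}

#' Classification metric suite
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' balanced accuracy `(SN+SP)/2`, precision `TP/(TP+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. Zero-denominator
#' conventions: SN/SP/PREC/F1 are 0 when undefined; MCC is 0 when any marginal
#' is zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (or pass a named vector
#'   from [confusion_counts()] as `tp`).
#' @return One-row tibble with columns `sn`, `sp`, `bacc`, `acc`, `prec`,
#'   `f1`, `mcc`.
#' @export
classification_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    cc <- tp
    tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  }
  counts <- c(tp, fp, tn, fn)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- as.numeric(tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  }
  tibble::tibble(
    sn = sn, sp = sp, bacc = (sn + sp) / 2,
    acc = (tp + tn) / sum(counts), prec = prec, f1 = f1, mcc = mcc
  )
}

#' Rank-based AUC
#'
#' The probability that a uniformly random positive sample outranks a
#' uniformly random negative sample, with ties counted 1/2 (the normalised
#' Mann-Whitney U statistic) — exact for finite samples, equivalent to the
#' area under the empirical ROC curve.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Integer 0/1 truth vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Regression metric suite
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `MSE = mean((y - yhat)^2)`, `RMSE = sqrt(MSE)`,
#' `MAE = mean(|y - yhat|)`.
#'
#' @param truth Numeric vector of true targets.
#' @param pred Numeric vector of predictions.
#' @return One-row tibble with columns `r2`, `mse`, `rmse`, `mae`.
#' @export
regression_metrics <- function(truth, pred) {
  stopifnot(is.numeric(truth), is.numeric(pred),
            length(truth) == length(pred), length(truth) >= 1L)
  mse <- mean((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (length(truth) < 2L || ss_tot == 0) {
    stop("R2 undefined: truth has zero variance", call. = FALSE)
  } else {
    1 - sum((truth - pred)^2) / ss_tot
  }
  tibble::tibble(r2 = r2, mse = mse, rmse = sqrt(mse),
                 mae = mean(abs(truth - pred)))
}

#' Evaluate predictions against truth
#'
#' Bundles truth, predictions and the applicable metric suite into an
#' evaluation object with `tidy()`, `glance()` and `autoplot()` methods.
#'
#' @param truth 0/1 labels (classification) or numeric targets (regression).
#' @param pred Predicted 0/1 labels or numeric values.
#' @param scores Optional probability scores (classification; enables AUC).
#' @param task `"classification"` or `"regression"`.
#' @return A `nif_eval` object.
#' @export
evaluate_predictions <- function(truth, pred, scores = NULL,
                                 task = c("classification", "regression")) {
  task <- match.arg(task)
  metrics <- if (task == "classification") {
    m <- classification_metrics(confusion_counts(as.integer(truth),
                                                 as.integer(pred)))
    if (!is.null(scores)) m$auc <- auc(scores, as.integer(truth))
    m
  } else {
    regression_metrics(truth, pred)
  }
  structure(list(task = task, truth = truth, pred = pred, scores = scores,
                 metrics = metrics),
            class = "nif_eval")
}

#' @export
print.nif_eval <- function(x, ...) {
  cat("<nif_eval> ", x$task, ", n = ", length(x$truth), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Write a metrics report
#'
#' Serialises an evaluation as JSON or as a one-row TSV whose column order
#' mirrors the standard reporting layout (SN, SP, BACC, ACC, PREC, F1, MCC,
#' AUC for classification; R2, MSE, RMSE, MAE for regression).
#'
#' @param eval A `nif_eval` object.
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @export
write_metrics_report <- function(eval, path) {
  stopifnot(inherits(eval, "nif_eval"))
  m <- eval$metrics
  if (eval$task == "classification") {
    ord <- intersect(c("sn", "sp", "bacc", "acc", "prec", "f1", "mcc", "auc"),
                     names(m))
    m <- m[, ord]
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(m), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
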