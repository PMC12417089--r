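# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection trace
#'
#' One row per evaluated candidate set: round, the set (comma-collapsed),
#' its size, score and whether it was retained as that round's extension.
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  tibble::tibble(
    round = x$rounds$round,
    set = vapply(x$rounds$set, paste, character(1L), collapse = ", "),
    size = lengths(x$rounds$set),
    score = x$rounds$score,
    retained = x$rounds$retained
  )
}

#' @rdname tidy.selection_trace
#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    objective = x$objective,
    n_evaluated = nrow(x$rounds),
    final_set = paste(x$final_set, collapse = ", "),
    final_size = length(x$final_set),
    final_score = x$final_score,
    seed = x$seed
  )
}

#' Tidy a fitted stacking model
#'
#' One row per learner (base layer rows, then the meta learner) with its
#' family and hyperparameters.
#'
#' @param x A `nif_stack`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nif_stack
#' @export
tidy.nif_stack <- function(x, ...) {
  specs <- c(lapply(x$base_fits, function(f) f$spec),
             list(meta = x$meta_fit$spec))
  tibble::tibble(
    layer = c(rep("base", length(x$base_fits)), "meta"),
    learner = names(specs),
    family = vapply(specs, function(s) s$family, character(1L)),
    params = vapply(specs, function(s) {
      if (!length(s$params)) return("defaults")
      paste(names(s$params),
            vapply(s$params, function(p) paste(p, collapse = "/"),
                   character(1L)),
            sep = "=", collapse = ", ")
    }, character(1L)),
    seed = vapply(specs, function(s) s$seed, integer(1L))
  )
}

#' @rdname tidy.nif_stack
#' @method glance nif_stack
#' @export
glance.nif_stack <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_train = x$n_train, n60 = x$n60, n40 = x$n40,
    n_features = length(x$feature_names),
    n_base_learners = length(x$base_fits),
    meta_input_width = length(x$feature_names) + length(x$base_fits),
    threshold = x$threshold %||% NA_real_,
    groups = paste(x$groups %||% NA_character_, collapse = ", ")
  )
}

#' Tidy an evaluation
#'
#' Long format: one row per metric.
#'
#' @param x A `nif_eval`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value` columns.
#' @method tidy nif_eval
#' @export
tidy.nif_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.nif_eval
#' @method glance nif_eval
#' @export
glance.nif_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(task = x$task, n = length(x$truth)),
                   x$metrics)
}

# ---- autoplot methods ---------------------------------------------------

#' Plot a selection trace
#'
#' Scores of every evaluated candidate set by round, with the per-round
#' retained extension connected and the final selection highlighted.
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  df <- tidy(object)
  df$final <- vapply(object$rounds$set, setequal, logical(1L),
                     object$final_set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_line(data = df[df$retained, ], colour = "steelblue") +
    ggplot2::geom_point(data = df[df$retained, ], colour = "steelblue",
                        size = 2) +
    ggplot2::geom_point(data = df[df$final, ], colour = "firebrick",
                        size = 3, shape = 18) +
    ggplot2::scale_x_continuous(breaks = unique(df$round)) +
    ggplot2::labs(x = "Selection round", y = object$objective,
                  title = paste("Incremental", gsub("_", " ", object$kind),
                                "selection")) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation
#'
#' Classification: the empirical ROC curve (when scores are available,
#' otherwise a metric bar chart). Regression: predicted vs true targets with
#' the identity line.
#'
#' @param object A `nif_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nif_eval
#' @export
autoplot.nif_eval <- function(object, ...) {
  if (object$task == "regression") {
    df <- tibble::tibble(truth = object$truth, pred = object$pred)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                             colour = "grey50") +
        ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
        ggplot2::labs(x = "True target (log10 activity + 2)",
                      y = "Predicted target",
                      title = sprintf("R² = %.3f, RMSE = %.3f",
                                      object$metrics$r2,
                                      object$metrics$rmse)) +
        ggplot2::theme_minimal()
    )
  }
  if (!is.null(object$scores)) {
    ord <- order(object$scores, decreasing = TRUE)
    truth <- as.integer(object$truth)[ord]
    df <- tibble::tibble(
      fpr = c(0, cumsum(truth == 0L) / sum(truth == 0L)),
      tpr = c(0, cumsum(truth == 1L) / sum(truth == 1L))
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_step(colour = "steelblue") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.3f)",
                                    object$metrics$auc %||% NA)) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = NULL, y = "Value", title = "Classification metrics") +
      ggplot2::theme_minimal()
  }
}
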