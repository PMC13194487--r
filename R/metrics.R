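#' Quadratic weighted kappa
#'
#' Chance-corrected ordinal agreement between true and predicted stages,
#' with disagreement penalized by the squared ordinal distance:
#' `kappa = 1 - sum(W * O) / sum(W * E)` where `W[i, j] = (i - j)^2 /
#' (K - 1)^2`, `O` is the observed confusion matrix and `E` the outer
#' product of its marginals scaled to `N`. Values lie in \[-1, 1\]; above
#' about 0.8 is conventionally read as strong ordinal agreement.
#'
#' If both marginals concentrate on a single identical class the expected
#' disagreement is zero; perfect agreement then returns 1 by convention,
#' anything else is an error.
#'
#' @param truth,pred Integer stage vectors of equal length, values in
#'   `1..K`.
#' @param K Number of ordered classes (default 4).
#' @return The kappa statistic, a single number in \[-1, 1\].
#' @examples
#' quadratic_weighted_kappa(c(1, 2, 3, 4), c(1, 2, 3, 4)) # 1
#' quadratic_weighted_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
quadratic_weighted_kappa <- function(truth, pred, K = 4L) {
  check_scalar_number(K, "K", lower = 2)
  if (length(truth) != length(pred) || length(truth) < 1L) {
    abort("`truth` and `pred` must be equal-length, non-empty vectors.")
  }
  lv <- seq_len(K)
  if (!all(truth %in% lv) || !all(pred %in% lv)) {
    abort(sprintf("Stages must lie in 1..%d.", K))
  }
  O <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  O <- matrix(as.numeric(O), K, K)
  n <- length(truth)
  W <- outer(lv, lv, function(i, j) (i - j)^2 / (K - 1)^2)
  E <- outer(rowSums(O), colSums(O)) / n
  den <- sum(W * E)
  num <- sum(W * O)
  if (den == 0) {
    if (num == 0) return(1.0)
    abort("Degenerate marginals with observed disagreement: kappa undefined.")
  }
  1 - num / den
}

#' Evaluate stage predictions
#'
#' Computes the full ordinal evaluation report: exact-agreement accuracy,
#' stage mean absolute error, quadratic weighted kappa, the 4x4 confusion
#' matrix (rows = true stage, columns = predicted), and the within-one
#' rate - the fraction *of misclassifications* that lie within one stage
#' of the truth (1 by convention when there are no errors).
#'
#' @param truth,pred Integer GOLD stage vectors (1-4) of equal length.
#' @return An object of class `eval_report` with elements `accuracy`,
#'   `mae`, `qwk`, `confusion`, `within_1_rate` and `n`.
#' @examples
#' r <- evaluate_predictions(c(1, 2, 3, 4), c(2, 2, 3, 4))
#' glance(r)
#' @export
evaluate_predictions <- function(truth, pred) {
  truth <- check_stages(truth, "truth")
  pred <- check_stages(pred, "pred")
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length.")
  }
  n <- length(truth)
  confusion <- table(
    true = factor(truth, levels = 1:4),
    predicted = factor(pred, levels = 1:4)
  )
  confusion <- matrix(as.integer(confusion), 4L, 4L,
                      dimnames = list(true = 1:4, predicted = 1:4))
  err <- abs(truth - pred)
  misses <- err[err > 0]
  structure(
    list(
      accuracy = mean(truth == pred),
      mae = mean(err),
      qwk = quadratic_weighted_kappa(truth, pred, K = 4L),
      confusion = confusion,
      within_1_rate = if (length(misses) == 0L) 1.0 else mean(misses <= 1L),
      n = n
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Ordinal evaluation (n = %d): accuracy %.3f | MAE %.3f stages | QWK %.3f | %.0f%% of errors within +/-1\n",
    x$n, x$accuracy, x$mae, x$qwk, 100 * x$within_1_rate
  ))
  cat("Confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' @describeIn evaluate_predictions Confusion matrix in long (tidy) form.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::expand_grid(true = 1:4, predicted = 1:4) |>
    dplyr::mutate(count = as.integer(t(x$confusion))[
      (.data$true - 1L) * 4L + .data$predicted
    ])
}

#' @describeIn evaluate_predictions One-row tibble of summary metrics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, mae = x$mae, qwk = x$qwk,
    within_1_rate = x$within_1_rate, n = x$n
  )
}

#' @describeIn evaluate_predictions Confusion-matrix heatmap.
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_reverse(breaks = 1:4) +
    ggplot2::scale_x_continuous(breaks = 1:4, position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted GOLD stage", y = "True GOLD stage",
                  title = "Stage confusion matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write an evaluation report to disk
#'
#' Serializes the scalar metrics as JSON and, optionally, the confusion
#' matrix as CSV alongside.
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @param confusion_csv Optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, confusion_csv = NULL) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(
      accuracy = report$accuracy, mae = report$mae, qwk = report$qwk,
      within_1_rate = report$within_1_rate, n = report$n,
      confusion = report$confusion
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(confusion_csv)) {
    utils::write.csv(report$confusion, confusion_csv)
  }
  invisible(path)
}
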