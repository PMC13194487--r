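#' Multinomial logistic-regression baseline
#'
#' Fits a multinomial logistic model over the same value-mask design the
#' networks see, with modest L2 weight decay. Feature rows from either
#' cohort use the unified layout `[shared | source-private |
#' target-private]` blocks, a cohort's foreign private columns sitting at
#' zero with mask zero. Predictions are integer GOLD stages.
#'
#' @param features Numeric design matrix (rows = patients).
#' @param labels Integer GOLD stages 1-4 (at least two distinct values).
#' @param seed Integer seed (the optimizer start is randomized).
#' @param decay L2 penalty passed to the fitter (default 1e-3).
#' @return An object of class `gold_logistic` with a `predict()` method
#'   returning stages in 1-4.
#' @examples
#' x <- matrix(rnorm(80), 40, 2)
#' y <- 1L + (x[, 1] > 0) + 2L * (x[, 2] > 0)
#' fit <- fit_logistic_baseline(x, y, seed = 1)
#' table(predict(fit, x), y)
#' @export
fit_logistic_baseline <- function(features, labels, seed = 1L, decay = 1e-3) {
  features <- as.matrix(features)
  labels <- check_stages(labels, "labels")
  if (nrow(features) != length(labels)) {
    abort("`features` rows and `labels` length differ.")
  }
  lev <- sort(unique(labels))
  if (length(lev) < 2L) abort("Need at least two distinct classes to fit.")

  df <- as.data.frame(features)
  names(df) <- paste0("x", seq_len(ncol(features)))
  df$.stage <- factor(labels, levels = lev)
  model <- with_seed(seed, {
    nnet::multinom(.stage ~ ., data = df, decay = decay, maxit = 500,
                   trace = FALSE)
  })
  structure(
    list(model = model, levels = lev, p = ncol(features)),
    class = "gold_logistic"
  )
}

#' @export
predict.gold_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    abort(sprintf("Expected %d feature columns, got %d.", object$p, ncol(newdata)))
  }
  df <- as.data.frame(newdata)
  names(df) <- paste0("x", seq_len(ncol(newdata)))
  as.integer(as.character(predict(object$model, newdata = df)))
}

#' @export
print.gold_logistic <- function(x, ...) {
  cat(sprintf("<gold_logistic> multinomial baseline over %d features, classes %s\n",
              x$p, paste(x$levels, collapse = "/")))
  invisible(x)
}

# Unified value-mask design across both cohorts: shared block, then source-
# private, then target-private columns; foreign private columns are zero
# (value 0, mask 0), which value-mask semantics read as "not measured".
unified_design <- function(blocks, specs) {
  specs <- validate_feature_specs(specs)
  src_feats <- specs$name[specs$role == "source_private"]
  tgt_feats <- specs$name[specs$role == "target_private"]
  n <- length(blocks$gold)
  zeros <- function(feats) {
    matrix(0, n, 2L * length(feats),
           dimnames = list(NULL, c(feats, paste0(feats, "_mask"))))
  }
  if (blocks$domain == "source") {
    cbind(blocks$shared, blocks$private, zeros(tgt_feats))
  } else {
    cbind(blocks$shared, zeros(src_feats), blocks$private)
  }
}
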