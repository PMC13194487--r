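#' Training control parameters
#'
#' Full-batch training defaults: Adam with learning rate 3e-4, at most
#' 3,000 epochs, validation metrics every 10 epochs, global gradient-norm
#' clipping at 1.0. The checkpoint returned after training is the one with
#' minimum validation MAE (earliest epoch on ties); there is no other
#' early stopping and no mini-batching.
#'
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs Maximum number of full-batch epochs.
#' @param eval_every Validation cadence in epochs.
#' @param clip_norm Global gradient-norm ceiling (> 0).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `train_control`.
#' @export
train_control <- function(learning_rate = 3e-4, max_epochs = 3000L,
                          eval_every = 10L, clip_norm = 1.0, seed = 1L) {
  check_scalar_number(learning_rate, "learning_rate", lower = 0, open_lower = TRUE)
  check_scalar_number(max_epochs, "max_epochs", lower = 1)
  check_scalar_number(eval_every, "eval_every", lower = 1)
  check_scalar_number(clip_norm, "clip_norm", lower = 0, open_lower = TRUE)
  check_scalar_number(seed, "seed")
  structure(
    list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         eval_every = as.integer(eval_every), clip_norm = clip_norm,
         seed = as.integer(seed)),
    class = "train_control"
  )
}

.prob_eps <- 1e-7

#' Ordinal binary cross-entropy loss
#'
#' Mean over all `N x 3` entries of the per-threshold binary cross-entropy
#' `-(t log p + (1 - t) log(1 - p))`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` so the loss stays finite at saturated outputs.
#'
#' @param probs Numeric `N x 3` matrix of threshold probabilities.
#' @param targets Numeric `N x 3` binary matrix from [encode_stage()].
#' @return A single non-negative number.
#' @examples
#' ordinal_bce_loss(matrix(0.5, 2, 3), encode_stage(c(1, 4))) # log(2)
#' @export
ordinal_bce_loss <- function(probs, targets) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3L)
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3L)
  if (!all(dim(probs) == dim(targets))) {
    abort("`probs` and `targets` must have identical dimensions.")
  }
  p <- clamp(probs, .prob_eps, 1 - .prob_eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

multiclass_ce_loss <- function(probs, stages) {
  p <- clamp(probs[cbind(seq_along(stages), stages)], .prob_eps, 1)
  -mean(log(p))
}

# ---- gradient machinery ----------------------------------------------------

zero_like <- function(params) {
  lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))
}

# Backpropagate dL/dZ through a cached forward pass, accumulating into `grads`.
accumulate_grads <- function(grads, params, config, cache, dZ) {
  grads$head$W <- grads$head$W + crossprod(cache$J, dZ)
  grads$head$b <- grads$head$b + colSums(dZ)
  dJ <- tcrossprod(dZ, params$head$W)
  offset <- 0L
  if (config$uses_shared) {
    w <- config$shared_widths[2L]
    dH2 <- dJ[, seq_len(w), drop = FALSE] * (cache$H2 > 0)
    grads$shared2$W <- grads$shared2$W + crossprod(cache$H1, dH2)
    grads$shared2$b <- grads$shared2$b + colSums(dH2)
    dH1 <- tcrossprod(dH2, params$shared2$W) * (cache$H1 > 0)
    grads$shared1$W <- grads$shared1$W + crossprod(cache$Xs, dH1)
    grads$shared1$b <- grads$shared1$b + colSums(dH1)
    offset <- w
  }
  if (config$uses_private) {
    cols <- offset + seq_len(config$private_width)
    dP <- dJ[, cols, drop = FALSE] * (cache$P > 0)
    nm <- if (cache$domain == "source") "source_private" else "target_private"
    grads[[nm]]$W <- grads[[nm]]$W + crossprod(cache$Xp, dP)
    grads[[nm]]$b <- grads[[nm]]$b + colSums(dP)
  }
  grads
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(l) sum(l$W^2) + sum(l$b^2), numeric(1))))
}

clip_grads <- function(grads, clip_norm) {
  gn <- global_grad_norm(grads)
  if (is.finite(gn) && gn > clip_norm) {
    scale <- clip_norm / gn
    grads <- lapply(grads, function(l) list(W = l$W * scale, b = l$b * scale))
  }
  grads
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * g
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[part]] / bc1
      vhat <- state$v[[nm]][[part]] / bc2
      params[[nm]][[part]] <- params[[nm]][[part]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Decode network outputs to stages: counting rule for ordinal heads,
# argmax (first on ties) for the softmax head.
probs_to_stages <- function(probs, config) {
  if (config$variant == "multiclass") {
    as.integer(max.col(probs, ties.method = "first"))
  } else {
    decode_thresholds(probs)
  }
}

validation_metrics <- function(params, config, val_blocks) {
  probs <- onn_forward(params, config, val_blocks$shared, val_blocks$private,
                       val_blocks$domain)
  pred <- probs_to_stages(probs, config)
  rep <- evaluate_predictions(val_blocks$gold, pred)
  list(accuracy = rep$accuracy, mae = rep$mae, qwk = rep$qwk, pred = pred)
}

#' Train a shared-private network on design blocks
#'
#' Full-batch training: every epoch performs one Adam update on the pooled
#' loss over all training rows from both cohorts, each row routed through
#' its own cohort's private encoder. For ordinal variants the loss is the
#' mean per-threshold binary cross-entropy against cumulative-threshold
#' targets; the multiclass variant uses softmax cross-entropy. The global
#' gradient norm is clipped before the Adam update. Every `eval_every`
#' epochs the target-validation metrics are logged; the returned parameters
#' are those of the evaluation with minimum validation MAE (earliest epoch
#' on ties). Deterministic for a fixed `control$seed`.
#'
#' @param config An `onn_config`.
#' @param train_blocks List of `design_blocks` training batches (typically
#'   the full source cohort and the target training subset).
#' @param val_blocks A `design_blocks` object for the validation rows.
#' @param control A [train_control()] object.
#' @param params Optional initial `onn_params`; defaults to
#'   `init_params(config, control$seed)`.
#' @return An object of class `onn_fit`: the best parameters (`params`),
#'   the final-epoch parameters, the evaluation log (a tibble with epoch,
#'   train loss and validation metrics), `best_epoch`, `best_val_mae`, and
#'   the epoch-0 validation metrics (`initial`).
#' @export
train_onn <- function(config, train_blocks, val_blocks, control = train_control(),
                      params = NULL) {
  stopifnot(inherits(config, "onn_config"), inherits(control, "train_control"))
  if (length(train_blocks) == 0L || sum(vapply(train_blocks, function(b) length(b$gold), 0)) == 0L) {
    abort("Training set is empty.")
  }
  if (length(val_blocks$gold) == 0L) abort("Validation set is empty.")
  params <- params %||% init_params(config, control$seed)

  batches <- lapply(train_blocks, function(b) {
    list(
      shared = b$shared, private = b$private, domain = b$domain,
      gold = b$gold,
      targets = if (config$variant == "multiclass") NULL else encode_stage(b$gold)
    )
  })
  n_rows <- sum(vapply(batches, function(b) length(b$gold), 0))
  n_entries <- n_rows * 3L  # BCE averages over rows x thresholds

  state <- list(m = zero_like(params), v = zero_like(params))
  initial <- validation_metrics(params, config, val_blocks)

  log <- vector("list", control$max_epochs %/% control$eval_every + 1L)
  n_logged <- 0L
  best <- list(mae = Inf, epoch = NA_integer_, params = params)

  for (epoch in seq_len(control$max_epochs)) {
    grads <- zero_like(params)
    loss_sum <- 0
    for (b in batches) {
      cache <- onn_forward_cache(params, config, b$shared, b$private, b$domain)
      if (config$variant == "multiclass") {
        loss_sum <- loss_sum + multiclass_ce_loss(cache$probs, b$gold) * length(b$gold)
        onehot <- matrix(0, length(b$gold), 4L)
        onehot[cbind(seq_along(b$gold), b$gold)] <- 1
        dZ <- (cache$probs - onehot) / n_rows
      } else {
        loss_sum <- loss_sum + ordinal_bce_loss(cache$probs, b$targets) *
          length(b$gold) * 3L
        dZ <- (cache$probs - b$targets) / n_entries
      }
      grads <- accumulate_grads(grads, params, config, cache, dZ)
    }
    loss <- loss_sum / (if (config$variant == "multiclass") n_rows else n_entries)
    if (!is.finite(loss)) {
      abort(sprintf("Non-finite training loss at epoch %d (loss = %s).",
                    epoch, format(loss)))
    }
    grads <- clip_grads(grads, control$clip_norm)
    upd <- adam_step(params, grads, state, control$learning_rate, epoch)
    params <- upd$params
    state <- upd$state

    if (epoch %% control$eval_every == 0L) {
      vm <- validation_metrics(params, config, val_blocks)
      n_logged <- n_logged + 1L
      log[[n_logged]] <- tibble(
        epoch = epoch, loss = loss, val_accuracy = vm$accuracy,
        val_mae = vm$mae, val_qwk = vm$qwk
      )
      if (vm$mae < best$mae) {
        best <- list(mae = vm$mae, epoch = epoch, params = params)
      }
    }
  }

  log <- dplyr::bind_rows(log[seq_len(n_logged)])
  structure(
    list(
      config = config, params = best$params, final_params = params,
      log = log, best_epoch = best$epoch, best_val_mae = best$mae,
      initial = initial[c("accuracy", "mae", "qwk")], control = control
    ),
    class = "onn_fit"
  )
}

#' @export
print.onn_fit <- function(x, ...) {
  cat(sprintf(
    "<onn_fit> %s: best epoch %d (validation MAE %.3f) over %d epochs\n",
    x$config$variant, x$best_epoch, x$best_val_mae, x$control$max_epochs
  ))
  invisible(x)
}

#' @describeIn train_onn Per-evaluation training log as a tibble.
#' @param x An `onn_fit`.
#' @param ... Unused.
#' @export
tidy.onn_fit <- function(x, ...) x$log

#' @describeIn train_onn One-row summary of the selected checkpoint.
#' @export
glance.onn_fit <- function(x, ...) {
  at_best <- x$log[x$log$epoch == x$best_epoch, ]
  tibble(
    variant = x$config$variant, best_epoch = x$best_epoch,
    best_val_mae = x$best_val_mae,
    val_accuracy = at_best$val_accuracy, val_qwk = at_best$val_qwk,
    n_params = n_params(x$params), epochs = x$control$max_epochs
  )
}

#' @describeIn train_onn Training curves (loss and validation metrics).
#' @param object An `onn_fit`.
#' @export
autoplot.onn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        color = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL,
                  title = sprintf("Training dynamics (%s)", object$config$variant),
                  subtitle = sprintf("Dashed line: selected checkpoint (epoch %d)",
                                     object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Export a training log as CSV
#' @param fit An `onn_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(fit, path) {
  stopifnot(inherits(fit, "onn_fit"))
  readr::write_csv(fit$log, path)
  invisible(path)
}
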