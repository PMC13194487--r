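#' Shared-private network configuration
#'
#' Describes one of the four network variants:
#' \describe{
#'   \item{`full_ordinal`}{shared encoder (input -> 32 -> 16, ReLU) plus a
#'     one-layer private encoder per cohort (input -> 8, ReLU); the 16-d
#'     shared embedding and 8-d private embedding concatenate into a 24-d
#'     joint representation feeding a linear head with 3 sigmoid outputs,
#'     one per cumulative threshold.}
#'   \item{`shared_only_ordinal`}{private pathways removed; head input 16.}
#'   \item{`private_only_ordinal`}{shared pathway removed; head input 8.}
#'   \item{`multiclass`}{the shared encoder with a 4-way softmax head
#'     instead of ordinal thresholds (no private pathways), the standard
#'     nominal-classification baseline.}
#' }
#' Encoder input widths are twice the raw feature counts because value-mask
#' encoding doubles every block.
#'
#' @param variant One of `"full_ordinal"`, `"shared_only_ordinal"`,
#'   `"private_only_ordinal"`, `"multiclass"`.
#' @param d_shared,d_source_private,d_target_private Raw (pre-doubling)
#'   feature counts per block.
#' @param shared_widths Hidden widths of the shared encoder (default
#'   `c(32, 16)`).
#' @param private_width Width of each private encoder (default 8).
#' @return An object of class `onn_config`.
#' @examples
#' model_config("full_ordinal", d_shared = 7, d_source_private = 2,
#'              d_target_private = 2)
#' @export
model_config <- function(variant = c("full_ordinal", "shared_only_ordinal",
                                     "private_only_ordinal", "multiclass"),
                         d_shared, d_source_private, d_target_private,
                         shared_widths = c(32L, 16L), private_width = 8L) {
  variant <- match.arg(variant)
  for (nm in c("d_shared", "d_source_private", "d_target_private")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  if (length(shared_widths) != 2L || any(shared_widths < 1)) {
    abort("`shared_widths` must be two positive layer widths.")
  }
  check_scalar_number(private_width, "private_width", lower = 1)

  uses_shared <- variant != "private_only_ordinal"
  uses_private <- !variant %in% c("shared_only_ordinal", "multiclass")
  if (uses_shared && d_shared < 1) abort("Variant needs d_shared >= 1.")
  if (uses_private && (d_source_private < 1 || d_target_private < 1)) {
    abort("Variant needs private feature counts >= 1.")
  }

  head_inputs <- (if (uses_shared) shared_widths[2L] else 0L) +
    (if (uses_private) private_width else 0L)
  structure(
    list(
      variant = variant,
      d_shared = as.integer(d_shared),
      d_source_private = as.integer(d_source_private),
      d_target_private = as.integer(d_target_private),
      shared_widths = as.integer(shared_widths),
      private_width = as.integer(private_width),
      uses_shared = uses_shared,
      uses_private = uses_private,
      head_inputs = as.integer(head_inputs),
      head_outputs = if (variant == "multiclass") 4L else 3L
    ),
    class = "onn_config"
  )
}

#' @export
print.onn_config <- function(x, ...) {
  cat(sprintf(
    "<onn_config> %s: shared %s, private width %d, head %d -> %d (%s)\n",
    x$variant,
    if (x$uses_shared) paste(c(2L * x$d_shared, x$shared_widths), collapse = " -> ") else "none",
    if (x$uses_private) x$private_width else 0L,
    x$head_inputs, x$head_outputs,
    if (x$variant == "multiclass") "softmax" else "sigmoid"
  ))
  invisible(x)
}

# Fan-in scaled uniform init for one layer; biases start at zero.
init_layer <- function(n_in, n_out) {
  s <- 1 / sqrt(n_in)
  list(
    W = matrix(runif(n_in * n_out, -s, s), nrow = n_in, ncol = n_out),
    b = numeric(n_out)
  )
}

#' Initialize model parameters
#'
#' Draws all weights from a fan-in-scaled uniform distribution
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`) and sets biases to zero.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param config An `onn_config`.
#' @param seed Integer seed.
#' @return An object of class `onn_params`: a named list of layers, each a
#'   list with weight matrix `W` and bias vector `b`.
#' @export
init_params <- function(config, seed) {
  stopifnot(inherits(config, "onn_config"))
  check_scalar_number(seed, "seed")
  with_seed(seed, {
    params <- list()
    if (config$uses_shared) {
      params$shared1 <- init_layer(2L * config$d_shared, config$shared_widths[1L])
      params$shared2 <- init_layer(config$shared_widths[1L], config$shared_widths[2L])
    }
    if (config$uses_private) {
      params$source_private <- init_layer(2L * config$d_source_private, config$private_width)
      params$target_private <- init_layer(2L * config$d_target_private, config$private_width)
    }
    params$head <- init_layer(config$head_inputs, config$head_outputs)
    structure(params, class = "onn_params")
  })
}

# Total trainable parameter count.
n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(z) pmax(z, 0)

affine <- function(x, layer) sweep(x %*% layer$W, 2L, layer$b, "+")

# Forward pass keeping intermediate activations for backprop.
onn_forward_cache <- function(params, config, shared_block, private_block, domain) {
  n <- if (config$uses_shared) nrow(shared_block) else nrow(private_block)
  cache <- list(domain = domain)
  parts <- list()
  if (config$uses_shared) {
    if (ncol(shared_block) != 2L * config$d_shared) {
      abort(sprintf("shared block width %d != expected %d.",
                    ncol(shared_block), 2L * config$d_shared))
    }
    cache$Xs <- shared_block
    cache$H1 <- relu(affine(shared_block, params$shared1))
    cache$H2 <- relu(affine(cache$H1, params$shared2))
    parts$shared <- cache$H2
  }
  if (config$uses_private) {
    d_priv <- switch(domain,
      source = config$d_source_private,
      target = config$d_target_private,
      abort(sprintf("Unknown domain `%s`.", domain))
    )
    if (ncol(private_block) != 2L * d_priv) {
      abort(sprintf("private block width %d != expected %d for %s domain.",
                    ncol(private_block), 2L * d_priv, domain))
    }
    layer <- if (domain == "source") params$source_private else params$target_private
    cache$Xp <- private_block
    cache$P <- relu(affine(private_block, layer))
    parts$private <- cache$P
  } else {
    if (!domain %in% c("source", "target")) abort(sprintf("Unknown domain `%s`.", domain))
  }
  cache$J <- do.call(cbind, unname(parts))
  cache$Z <- affine(cache$J, params$head)
  cache$probs <- if (config$variant == "multiclass") {
    softmax_rows(cache$Z)
  } else {
    sigmoid(cache$Z)
  }
  cache
}

#' Forward pass of the shared-private network
#'
#' Runs one cohort's design blocks through the network. The domain tag
#' selects which private encoder processes the private block; ordinal
#' variants emit one sigmoid probability per cumulative threshold, the
#' multiclass variant a softmax distribution over the four stages.
#'
#' @param params An `onn_params` object.
#' @param config The matching `onn_config`.
#' @param shared_block,private_block Numeric matrices from
#'   [build_design_blocks()] (ignored blocks may be `NULL` for ablation
#'   variants).
#' @param domain `"source"` or `"target"`.
#' @return An `N x head_outputs` matrix of probabilities.
#' @export
onn_forward <- function(params, config, shared_block, private_block, domain) {
  stopifnot(inherits(config, "onn_config"))
  onn_forward_cache(params, config, shared_block, private_block, domain)$probs
}
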