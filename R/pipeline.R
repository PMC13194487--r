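#' Fit a shared-private ordinal model on a cohort pair
#'
#' End-to-end pipeline: stratify the target cohort into train/validation
#' (the source cohort is wholly training data), build value-mask design
#' blocks for every partition, construct cumulative-threshold targets, and
#' train the requested network variant with full-batch Adam. The returned
#' fit carries the validation evaluation report alongside the training log
#' and best-MAE checkpoint.
#'
#' @param source,target `cohort_tbl` objects (see [cohort_table()] /
#'   [read_cohort_csv()]).
#' @param specs Feature specification; defaults to [gold_feature_specs()].
#' @param variant Network variant, see [model_config()].
#' @param split Optional precomputed [stratified_split()] of the target
#'   rows; by default one is drawn with `fraction` and `split_seed`.
#' @param fraction,split_seed Validation fraction and seed used when
#'   `split` is `NULL`.
#' @param control A [train_control()]; `control$seed` drives parameter
#'   initialization.
#' @return An object of class `gold_onn` (also `onn_fit`), additionally
#'   holding `specs`, `split`, the validation predictions and an
#'   `eval_report` in `$validation`.
#' @examples
#' \donttest{
#' pair <- generate_pair(sim_spec(seed = 7))
#' fit <- fit_gold_onn(pair$source, pair$target,
#'                     control = train_control(max_epochs = 200))
#' glance(fit)
#' }
#' @export
fit_gold_onn <- function(source, target, specs = gold_feature_specs(),
                         variant = "full_ordinal", split = NULL,
                         fraction = 0.2, split_seed = 42L,
                         control = train_control()) {
  specs <- validate_feature_specs(specs)
  if (cohort_domain(source) != "source" || cohort_domain(target) != "target") {
    abort("`source` and `target` must be cohort tables with matching domains.")
  }
  split <- split %||% stratified_split(target$gold, fraction = fraction,
                                       seed = split_seed)

  src_blocks <- build_design_blocks(source, specs)
  tgt_blocks <- build_design_blocks(target, specs)
  config <- model_config(
    variant,
    d_shared = src_blocks$d_shared,
    d_source_private = src_blocks$d_private,
    d_target_private = tgt_blocks$d_private
  )

  fit <- train_onn(
    config,
    train_blocks = list(src_blocks, blocks_rows(tgt_blocks, split$train)),
    val_blocks = blocks_rows(tgt_blocks, split$validation),
    control = control
  )

  val_blocks <- blocks_rows(tgt_blocks, split$validation)
  probs <- onn_forward(fit$params, config, val_blocks$shared,
                       val_blocks$private, "target")
  pred <- probs_to_stages(probs, config)

  fit$specs <- specs
  fit$split <- split
  fit$validation <- list(
    index = split$validation,
    truth = val_blocks$gold,
    pred = pred,
    probs = probs,
    report = evaluate_predictions(val_blocks$gold, pred)
  )
  class(fit) <- c("gold_onn", class(fit))
  fit
}

#' @export
print.gold_onn <- function(x, ...) {
  NextMethod()
  print(x$validation$report)
  invisible(x)
}

#' Predict GOLD stages for new patients
#'
#' @param object A `gold_onn` fit.
#' @param newdata A `cohort_tbl` whose domain tag selects the private
#'   encoder.
#' @param ... Unused.
#' @return A tibble with the decoded `.pred_stage` and one probability
#'   column per network output.
#' @export
predict.gold_onn <- function(object, newdata, ...) {
  blocks <- build_design_blocks(newdata, object$specs)
  probs <- onn_forward(object$params, object$config, blocks$shared,
                       blocks$private, blocks$domain)
  out <- as_tibble(as.data.frame(probs, optional = TRUE),
                   .name_repair = "minimal")
  names(out) <- if (object$config$variant == "multiclass") {
    paste0(".pred_stage", 1:4)
  } else {
    c(".pred_ge2", ".pred_ge3", ".pred_ge4")
  }
  dplyr::bind_cols(tibble(.pred_stage = probs_to_stages(probs, object$config)), out)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are a flat key-to-array JSON container: each entry
#' `<layer>.W` / `<layer>.b` stores `dim` and the column-major `values`,
#' so a checkpoint round-trips bit-exactly through text. The network
#' configuration is written alongside as YAML (same path with extension
#' `.yaml`).
#'
#' @param fit A `gold_onn` / `onn_fit` object (or bare `onn_params` with a
#'   `config` argument).
#' @param path Checkpoint path (`.json`).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a list with `params` and `config`.
#' @export
write_checkpoint <- function(fit, path) {
  params <- if (inherits(fit, "onn_fit")) fit$params else fit
  config <- fit$config
  flat <- list()
  for (nm in names(params)) {
    flat[[paste0(nm, ".W")]] <- list(dim = dim(params[[nm]]$W),
                                     values = as.numeric(params[[nm]]$W))
    flat[[paste0(nm, ".b")]] <- list(dim = length(params[[nm]]$b),
                                     values = as.numeric(params[[nm]]$b))
  }
  jsonlite::write_json(flat, path, digits = NA)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, sub("\\.json$", ".yaml", path))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  layer_names <- unique(sub("\\.(W|b)$", "", names(flat)))
  params <- lapply(setNames(layer_names, layer_names), function(nm) {
    w <- flat[[paste0(nm, ".W")]]
    list(
      W = matrix(w$values, nrow = w$dim[1], ncol = w$dim[2]),
      b = as.numeric(flat[[paste0(nm, ".b")]]$values)
    )
  })
  cfg_path <- sub("\\.json$", ".yaml", path)
  config <- NULL
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    config <- model_config(
      cfg$variant, cfg$d_shared, cfg$d_source_private, cfg$d_target_private,
      shared_widths = unlist(cfg$shared_widths), private_width = cfg$private_width
    )
  }
  list(params = structure(params, class = "onn_params"), config = config)
}
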