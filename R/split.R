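#' Stratified train/validation split
#'
#' Splits row indices into training and validation sets while preserving the
#' GOLD stage distribution. The total validation size is
#' `round(fraction * N)` (ties rounded away from zero). Validation seats are
#' allocated per stage by largest-remainder rounding of
#' `fraction * class count`, which keeps every class within one seat of its
#' exact share while hitting the global total; remainder ties go to the
#' larger class. Rows within each stage are shuffled by `seed`, so the split
#' is fully reproducible.
#'
#' The source cohort is never split - it is wholly training data. This
#' function is intended for the target cohort, whose validation subset is
#' the evaluation set for every model variant.
#'
#' @param labels Integer GOLD stages (1-4), one per row.
#' @param fraction Validation fraction in (0, 1); default 0.2.
#' @param seed Integer seed driving the within-stage shuffle.
#' @return An object of class `split_indices`: a list with integer vectors
#'   `train` and `validation`, plus `seed` and `fraction`.
#' @examples
#' labs <- rep(1:4, times = c(23, 43, 27, 8))
#' sp <- stratified_split(labs, fraction = 0.2, seed = 42)
#' lengths(sp[c("train", "validation")]) # 81 and 20
#' @export
stratified_split <- function(labels, fraction = 0.2, seed = 42L) {
  labels <- check_stages(labels, "labels")
  check_scalar_number(fraction, "fraction", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(seed, "seed")
  n <- length(labels)

  counts <- table(factor(labels, levels = sort(unique(labels))))
  if (any(counts == 0L)) abort("Every class present must have at least one member.")

  total_val <- as.integer(round_half_away(fraction * n))
  if (total_val < 1L) {
    abort(sprintf("fraction %.3f of %d rows gives an empty validation set.", fraction, n))
  }

  # Largest-remainder allocation of validation seats across stages.
  quota <- fraction * as.numeric(counts)
  alloc <- floor(quota)
  remainder <- quota - alloc
  need <- total_val - sum(alloc)
  if (need > 0) {
    ord <- order(-remainder, -as.numeric(counts), seq_along(counts))
    alloc[ord[seq_len(need)]] <- alloc[ord[seq_len(need)]] + 1L
  } else if (need < 0) {
    ord <- order(remainder, as.numeric(counts), seq_along(counts))
    take <- ord[alloc[ord] > 0][seq_len(-need)]
    alloc[take] <- alloc[take] - 1L
  }
  alloc <- as.integer(pmin(alloc, as.numeric(counts)))

  validation <- integer(0)
  with_seed(seed, {
    for (k in seq_along(counts)) {
      stage <- as.integer(names(counts)[k])
      idx <- which(labels == stage)
      shuffled <- if (length(idx) == 1L) idx else sample(idx)
      validation <- c(validation, shuffled[seq_len(alloc[k])])
    }
  })
  validation <- sort(validation)
  train <- setdiff(seq_len(n), validation)

  structure(
    list(train = train, validation = validation,
         seed = as.integer(seed), fraction = fraction),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf(
    "Stratified split: %d train / %d validation (fraction %.2f, seed %d)\n",
    length(x$train), length(x$validation), x$fraction, x$seed
  ))
  invisible(x)
}

#' @export
tidy.split_indices <- function(x, ...) {
  tibble(
    index = c(x$train, x$validation),
    set = rep(c("train", "validation"), c(length(x$train), length(x$validation)))
  ) |> dplyr::arrange(.data$index)
}
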