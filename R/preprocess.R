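#' Fixed-range min-max normalization
#'
#' Maps a clinical value onto \[0, 1\] via `(v - lo) / (hi - lo)` using a
#' fixed clinical range, then clamps out-of-range values to the unit
#' interval. The range is part of the feature specification, never
#' estimated from data, so the same mapping applies to every cohort.
#'
#' @param v Numeric vector of values in clinical units (`NA` passes through).
#' @param lo,hi Range bounds with `hi > lo`.
#' @return Numeric vector in \[0, 1\] (or `NA` where `v` is `NA`).
#' @examples
#' minmax_normalize(c(40, 70, 120), lo = 40, hi = 100) # 0, 0.5, 1 (clamped)
#' @export
minmax_normalize <- function(v, lo, hi) {
  check_scalar_number(lo, "lo")
  check_scalar_number(hi, "hi")
  if (hi <= lo) abort(sprintf("`hi` (%g) must exceed `lo` (%g).", hi, lo))
  clamp((v - lo) / (hi - lo), 0, 1)
}

#' Value-mask encoding of a patient row
#'
#' Encodes a partially observed feature row as a pair of equal-length
#' vectors: the values, with missing entries set to 0.0, and a binary mask
#' that is 1.0 where the measurement is present and 0.0 where it is
#' missing. A genuinely measured zero keeps mask 1.0, so it stays
#' distinguishable from an absent value. This is the package's only
#' missing-data mechanism; nothing is imputed.
#'
#' @param row Named list or named numeric vector, `NA` meaning missing.
#' @param order Character vector giving the feature order of the encoding.
#' @return A list with numeric `values` and `masks`, both of length
#'   `length(order)` and named by `order`.
#' @examples
#' value_mask_encode(c(FEV1 = 0.7, FVC = NA), order = c("FEV1", "FVC"))
#' @export
value_mask_encode <- function(row, order) {
  if (length(order) == 0L) abort("`order` must name at least one feature.")
  row <- unlist(row, use.names = TRUE)
  v <- as.numeric(row[order])
  masks <- as.numeric(!is.na(v))
  values <- ifelse(is.na(v), 0, v)
  list(values = setNames(values, order), masks = setNames(masks, order))
}

#' Build the design blocks for one cohort
#'
#' Converts a cohort table into the two numeric matrices the encoders
#' consume. Shared features are min-max normalized on their fixed clinical
#' ranges and then value-mask encoded; the cohort's private features are
#' value-mask encoded without any scaling. Each block is the column-wise
#' concatenation `[values | masks]`, so its width is twice the number of
#' role-matching features. A feature the specs assign to this cohort but
#' absent from its columns is encoded as missing everywhere (mask 0).
#'
#' @param cohort A `cohort_tbl`.
#' @param specs A `feature_spec_tbl`.
#' @return An object of class `design_blocks`: list with matrices `shared`
#'   (`N x 2 d_shared`) and `private` (`N x 2 d_private`), the feature name
#'   vectors, counts `d_shared` / `d_private`, `domain` and integer `gold`.
#' @examples
#' coh <- cohort_table(
#'   data.frame(age = c(52, NA), FEV1 = c(2.2, 1.1), GOLD = c(1, 3)),
#'   domain = "target"
#' )
#' sp <- gold_feature_specs()
#' build_design_blocks(coh, sp)$shared[, 1:4]
#' @export
build_design_blocks <- function(cohort, specs) {
  if (!inherits(cohort, "cohort_tbl")) abort("`cohort` must be a cohort_tbl.")
  specs <- validate_feature_specs(specs)
  domain <- cohort_domain(cohort)

  present <- setdiff(names(cohort), "gold")
  unknown <- setdiff(present, specs$name)
  if (length(unknown)) {
    abort(sprintf("Schema error: cohort feature(s) not in specs: %s.",
                  paste(unknown, collapse = ", ")))
  }
  foreign <- specs$name[specs$role == paste0(setdiff(c("source", "target"), domain), "_private")]
  if (any(present %in% foreign)) {
    abort(sprintf("Schema error: %s cohort carries foreign private feature(s): %s.",
                  domain, paste(intersect(present, foreign), collapse = ", ")))
  }

  n <- nrow(cohort)
  encode_block <- function(block_specs, normalized) {
    feats <- block_specs$name
    d <- length(feats)
    if (d == 0L) {
      return(list(mat = matrix(numeric(0), nrow = n, ncol = 0), features = feats))
    }
    vals <- matrix(NA_real_, nrow = n, ncol = d, dimnames = list(NULL, feats))
    for (j in seq_len(d)) {
      f <- feats[j]
      col <- if (f %in% present) as.numeric(cohort[[f]]) else rep(NA_real_, n)
      if (normalized && block_specs$normalize[j]) {
        col <- minmax_normalize(col, block_specs$lo[j], block_specs$hi[j])
      }
      vals[, j] <- col
    }
    masks <- 1 - is.na(vals) * 1
    vals[is.na(vals)] <- 0
    colnames(masks) <- paste0(feats, "_mask")
    list(mat = cbind(vals, masks), features = feats)
  }

  shared <- encode_block(specs[specs$role == "shared", , drop = FALSE], normalized = TRUE)
  private <- encode_block(
    specs[specs$role == paste0(domain, "_private"), , drop = FALSE],
    normalized = FALSE
  )

  structure(
    list(
      shared = shared$mat,
      private = private$mat,
      shared_features = shared$features,
      private_features = private$features,
      d_shared = length(shared$features),
      d_private = length(private$features),
      domain = domain,
      gold = cohort$gold
    ),
    class = "design_blocks"
  )
}

#' @export
print.design_blocks <- function(x, ...) {
  cat(sprintf(
    "Design blocks (%s): %d rows; shared %d features -> width %d; private %d -> width %d\n",
    x$domain, length(x$gold), x$d_shared, ncol(x$shared), x$d_private, ncol(x$private)
  ))
  invisible(x)
}

# Subset the rows of a design-blocks object.
blocks_rows <- function(blocks, idx) {
  out <- blocks
  out$shared <- blocks$shared[idx, , drop = FALSE]
  out$private <- blocks$private[idx, , drop = FALSE]
  out$gold <- blocks$gold[idx]
  out
}
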