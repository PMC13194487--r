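#' Cumulative-threshold encoding of GOLD stages
#'
#' An ordinal stage `g` in 1-4 is represented by the three binary
#' indicators `(g >= 2, g >= 3, g >= 4)`. Stage 1 encodes to `(0, 0, 0)`,
#' stage 2 to `(1, 0, 0)`, stage 3 to `(1, 1, 0)` and stage 4 to
#' `(1, 1, 1)`; the encoding is a bijection onto the monotone binary
#' 3-vectors and preserves the severity ordering.
#'
#' @param gold Integer vector of GOLD stages in 1-4.
#' @return A numeric `length(gold) x 3` matrix with columns
#'   `ge2`, `ge3`, `ge4`.
#' @examples
#' encode_stage(1:4)
#' @export
encode_stage <- function(gold) {
  gold <- check_stages(gold, "gold")
  out <- cbind(ge2 = as.numeric(gold >= 2),
               ge3 = as.numeric(gold >= 3),
               ge4 = as.numeric(gold >= 4))
  out
}

#' Decode threshold probabilities to GOLD stages
#'
#' Applies the counting rule: the predicted stage is one plus the number of
#' threshold probabilities strictly above 0.5. The rule coincides with
#' inverting [encode_stage()] on monotone vectors but stays well defined on
#' non-monotone ones, which independently trained sigmoid outputs can
#' produce. A probability of exactly 0.5 does not count as exceeded, so
#' ties resolve toward the milder stage.
#'
#' @param probs Numeric `N x 3` matrix (or length-3 vector) of threshold
#'   probabilities in \[0, 1\], columns ordered `(>=2, >=3, >=4)`.
#' @return Integer vector of stages in 1-4.
#' @examples
#' decode_thresholds(c(0.9, 0.8, 0.2)) # 3
#' decode_thresholds(encode_stage(1:4)) # 1 2 3 4
#' @export
decode_thresholds <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (ncol(probs) != 3L) abort("`probs` must have three threshold columns.")
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    abort("Threshold probabilities must lie in [0, 1].")
  }
  as.integer(1L + rowSums(probs > 0.5))
}
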