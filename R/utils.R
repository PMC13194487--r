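# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round to nearest with ties away from zero (base round() ties to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s; got %g.",
      name, if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_stages <- function(x, name = "stages") {
  if (length(x) == 0L) abort(sprintf("`%s` must be non-empty.", name))
  if (anyNA(x) || !is.numeric(x) || any(x != as.integer(x)) || any(x < 1 | x > 4)) {
    bad <- which(is.na(x) | !(x %in% 1:4))
    abort(sprintf(
      "`%s` must be integer GOLD stages in 1-4; invalid at position(s) %s.",
      name, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  as.integer(x)
}
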