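#' Feature specification tables
#'
#' A feature specification describes each clinical variable the pipeline may
#' encounter: its name, whether it is shared across cohorts or private to one
#' of them, and the fixed clinical range used for min-max normalization.
#' Specifications are plain tibbles with columns `name`, `role`, `lo`, `hi`
#' and `normalize`, so they can be filtered and joined like any other data
#' frame.
#'
#' Roles partition the feature universe: a feature is exactly one of
#' `"shared"` (present in both cohorts), `"source_private"` or
#' `"target_private"`. Normalization ranges are fixed clinical ranges, not
#' data-driven statistics, so the same mapping applies to every cohort.
#'
#' @param name Character vector of feature names.
#' @param role Character vector of roles, each one of `"shared"`,
#'   `"source_private"`, `"target_private"`.
#' @param lo,hi Numeric normalization bounds in clinical units. Required
#'   (with `hi > lo`) whenever `normalize` is `TRUE`.
#' @param normalize Logical; should the feature be min-max normalized?
#'
#' @return A tibble with class `feature_spec_tbl`.
#' @examples
#' feature_spec("age", "shared", lo = 40, hi = 100, normalize = TRUE)
#' @export
feature_spec <- function(name, role, lo = NA_real_, hi = NA_real_, normalize = FALSE) {
  spec <- tibble(
    name = as.character(name),
    role = as.character(role),
    lo = as.numeric(lo),
    hi = as.numeric(hi),
    normalize = as.logical(normalize)
  )
  validate_feature_specs(spec)
}

feature_roles <- c("shared", "source_private", "target_private")

validate_feature_specs <- function(spec) {
  spec <- as_tibble(spec)
  needed <- c("name", "role", "lo", "hi", "normalize")
  if (!all(needed %in% names(spec))) {
    abort(paste0(
      "A feature specification needs columns ",
      paste(needed, collapse = ", "), "."
    ))
  }
  bad_role <- setdiff(unique(spec$role), feature_roles)
  if (length(bad_role)) {
    abort(sprintf(
      "Unknown feature role(s): %s. Roles must be one of %s.",
      paste(bad_role, collapse = ", "), paste(feature_roles, collapse = ", ")
    ))
  }
  if (anyDuplicated(spec$name)) {
    dup <- spec$name[duplicated(spec$name)]
    abort(sprintf(
      "Each feature must appear under exactly one role; duplicated: %s.",
      paste(unique(dup), collapse = ", ")
    ))
  }
  norm <- spec$normalize
  if (any(norm & (!is.finite(spec$lo) | !is.finite(spec$hi)))) {
    abort("Normalized features need finite `lo` and `hi` bounds.")
  }
  if (any(norm & spec$hi <= spec$lo)) {
    bad <- spec$name[norm & spec$hi <= spec$lo]
    abort(sprintf("`hi` must exceed `lo` for normalized feature(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  class(spec) <- unique(c("feature_spec_tbl", class(spec)))
  spec
}

#' Default GOLD-staging feature specification
#'
#' The default clinical schema for paired COPD cohorts: seven shared
#' variables (demographics, smoking exposure and spirometry), two
#' source-private symptom variables (CAT score and annual exacerbation
#' count) and two target-private functional-capacity variables (six-minute
#' walk tests). Shared features carry fixed clinical normalization ranges:
#' age 40-100 years, sex coded 0/1, smoking status coded 0-2, pack-years
#' 0-110, FEV1 0.4-4.0 L, FVC 0.5-6.0 L and FEV1/FVC 0-1. Private features
#' are never scaled.
#'
#' @return A `feature_spec_tbl` tibble with eleven rows.
#' @examples
#' gold_feature_specs()
#' @export
gold_feature_specs <- function() {
  validate_feature_specs(tibble(
    name = c(
      "age", "sex", "smoking_status", "pack_years", "FEV1", "FVC",
      "FEV1_FVC", "CAT", "exacerbations", "MWT1", "MWT2"
    ),
    role = c(
      rep("shared", 7L),
      rep("source_private", 2L),
      rep("target_private", 2L)
    ),
    lo = c(40, 0, 0, 0, 0.4, 0.5, 0, NA, NA, NA, NA),
    hi = c(100, 1, 2, 110, 4.0, 6.0, 1, NA, NA, NA, NA),
    normalize = c(rep(TRUE, 7L), rep(FALSE, 4L))
  ))
}

#' Read or write a feature specification as YAML
#'
#' The YAML layout is a top-level `features` list, one entry per feature
#' with fields `name`, `role`, `lo`, `hi`, `normalize` (bounds may be
#' omitted for unnormalized features).
#'
#' @param path Path to a YAML file.
#' @param spec A `feature_spec_tbl`, e.g. from [gold_feature_specs()].
#' @return `read_feature_specs()` returns a `feature_spec_tbl`;
#'   `write_feature_specs()` returns `path` invisibly.
#' @export
read_feature_specs <- function(path) {
  if (!file.exists(path)) abort(sprintf("Feature spec file not found: %s", path))
  raw <- yaml::read_yaml(path)
  entries <- raw$features %||% raw
  spec <- purrr::map_dfr(entries, function(e) {
    tibble(
      name = e$name,
      role = e$role,
      lo = as.numeric(e$lo %||% NA_real_),
      hi = as.numeric(e$hi %||% NA_real_),
      normalize = isTRUE(e$normalize)
    )
  })
  validate_feature_specs(spec)
}

#' @rdname read_feature_specs
#' @export
write_feature_specs <- function(spec, path) {
  spec <- validate_feature_specs(spec)
  entries <- purrr::pmap(spec, function(name, role, lo, hi, normalize) {
    e <- list(name = name, role = role, normalize = normalize)
    if (is.finite(lo)) e$lo <- lo
    if (is.finite(hi)) e$hi <- hi
    e
  })
  yaml::write_yaml(list(features = entries), path)
  invisible(path)
}

# Features belonging to one cohort: shared plus that cohort's private ones.
specs_for_domain <- function(spec, domain) {
  private_role <- paste0(domain, "_private")
  spec[spec$role %in% c("shared", private_role), , drop = FALSE]
}
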