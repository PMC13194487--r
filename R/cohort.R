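#' Cohort tables
#'
#' A cohort table holds one patient per row: clinical feature columns
#' (missing measurements as `NA`), an integer `gold` column with the GOLD
#' stage 1-4, and a `domain` attribute naming which cohort
#' (`"source"` or `"target"`) the rows come from. It is an ordinary tibble
#' and works with dplyr verbs; the class only carries validation and the
#' domain tag.
#'
#' @param data A data frame of feature columns plus a GOLD label column.
#' @param domain `"source"` or `"target"`.
#' @param gold_col Name of the label column in `data` (default `"GOLD"`);
#'   it is renamed to `gold` internally.
#' @return A tibble with class `cohort_tbl` and attribute `domain`.
#' @examples
#' cohort_table(
#'   data.frame(age = c(52, 61), FEV1 = c(2.1, NA), GOLD = c(1, 3)),
#'   domain = "target"
#' )
#' @export
cohort_table <- function(data, domain, gold_col = "GOLD") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  domain <- match.arg(domain, c("source", "target"))
  data <- as_tibble(data)
  if (!gold_col %in% names(data) && !"gold" %in% names(data)) {
    abort(sprintf("No GOLD label column: expected `%s` (or `gold`).", gold_col))
  }
  if (gold_col %in% names(data)) {
    names(data)[names(data) == gold_col] <- "gold"
  }
  labels <- data$gold
  bad <- which(is.na(labels) | !(labels %in% 1:4))
  if (length(bad)) {
    abort(sprintf(
      "GOLD labels must be integers 1-4; invalid label in row(s) %s.",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  data$gold <- as.integer(labels)
  feat <- setdiff(names(data), "gold")
  for (f in feat) data[[f]] <- as.numeric(data[[f]])
  data <- data[c(feat, "gold")]
  attr(data, "domain") <- domain
  class(data) <- unique(c("cohort_tbl", class(data)))
  data
}

#' @export
print.cohort_tbl <- function(x, ...) {
  cat(sprintf("# A %s cohort: %d patients, %d feature columns\n",
              cohort_domain(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Domain tag of a cohort table
#' @param cohort A `cohort_tbl`.
#' @return `"source"` or `"target"`.
#' @export
cohort_domain <- function(cohort) {
  attr(cohort, "domain") %||% abort("Not a cohort table: no domain attribute.")
}

# Missing-value spellings accepted in CSV cells (case-insensitive).
.na_spellings <- c("", "na", "nan")

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered CSV into a [cohort_table()].
#' Empty cells and the spellings `NA` / `NaN` (any case) are recorded as
#' missing, never as zero. Columns named in `specs` (for the given domain)
#' are kept; a feature column the specs do not mention is dropped with a
#' warning, and any column whose name mentions "predicted" lung-capacity
#' estimates is dropped because such derived columns are too noisy to use.
#'
#' @param path CSV file path.
#' @param specs A `feature_spec_tbl` describing the feature universe.
#' @param domain `"source"` or `"target"`.
#' @param gold_col Label column name (default `"GOLD"`).
#' @return A `cohort_tbl`.
#' @export
read_cohort_csv <- function(path, specs, domain, gold_col = "GOLD") {
  if (!file.exists(path)) abort(sprintf("Cannot read cohort file: %s", path))
  specs <- validate_feature_specs(specs)
  domain <- match.arg(domain, c("source", "target"))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!gold_col %in% names(raw)) {
    abort(sprintf("Schema error: label column `%s` not found in %s.", gold_col, path))
  }

  pred_cols <- grep("predicted", names(raw), ignore.case = TRUE, value = TRUE)
  if (length(pred_cols)) {
    inform(sprintf("Dropping predicted lung-capacity column(s): %s.",
                   paste(pred_cols, collapse = ", ")))
    raw <- raw[setdiff(names(raw), pred_cols)]
  }

  wanted <- specs_for_domain(specs, domain)$name
  extra <- setdiff(names(raw), c(wanted, gold_col))
  if (length(extra)) {
    warn(sprintf("Ignoring unknown column(s) in %s: %s.",
                 path, paste(extra, collapse = ", ")))
    raw <- raw[setdiff(names(raw), extra)]
  }

  parse_cell <- function(x) {
    x <- trimws(x)
    x[is.na(x) | tolower(x) %in% .na_spellings] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    unparsed <- !is.na(x) & is.na(out)
    if (any(unparsed)) {
      abort(sprintf("Non-numeric cell value(s): %s.",
                    paste(unique(x[unparsed])[1:min(3, sum(unparsed))], collapse = ", ")))
    }
    out
  }
  for (nm in setdiff(names(raw), gold_col)) raw[[nm]] <- parse_cell(raw[[nm]])

  lab <- parse_cell(raw[[gold_col]])
  bad <- which(is.na(lab) | !(lab %in% 1:4))
  if (length(bad)) {
    abort(sprintf(
      "Label outside GOLD 1-4 (or missing) in row(s) %s of %s.",
      paste(head(bad, 5L), collapse = ", "), path
    ))
  }
  raw[[gold_col]] <- as.integer(lab)
  cohort_table(raw, domain = domain, gold_col = gold_col)
}

#' Write a cohort to CSV
#'
#' Writes the exact dialect [read_cohort_csv()] consumes: header row,
#' comma-separated, missing cells empty, label column named `GOLD`.
#'
#' @param cohort A `cohort_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (!inherits(cohort, "cohort_tbl")) abort("`cohort` must be a cohort_tbl.")
  out <- as.data.frame(cohort)
  names(out)[names(out) == "gold"] <- "GOLD"
  readr::write_csv(out, path, na = "")
  invisible(path)
}
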