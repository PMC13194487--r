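test_that("feature specs validate roles, ranges and uniqueness", {
  spec <- gold_feature_specs()
  expect_s3_class(spec, "feature_spec_tbl")
  expect_equal(sum(spec$role == "shared"), 7L)
  expect_equal(sum(spec$role == "source_private"), 2L)
  expect_equal(sum(spec$role == "target_private"), 2L)
  expect_true(all(spec$hi[spec$normalize] > spec$lo[spec$normalize]))

  expect_error(feature_spec("age", "common"), "role")
  expect_error(
    feature_spec(c("age", "age"), c("shared", "source_private")),
    "exactly one role"
  )
  expect_error(feature_spec("age", "shared", lo = 100, hi = 40, normalize = TRUE),
               "exceed")
})

test_that("feature specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_specs(gold_feature_specs(), path)
  back <- read_feature_specs(path)
  expect_equal(as.data.frame(back), as.data.frame(gold_feature_specs()))
})

test_that("CSV reading records empty cells as missing, preserves labels in order", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(path, labels = c(1, 3, 2))
  coh <- read_cohort_csv(path, tiny_specs(), "target")
  expect_true(is.na(coh$FEV1[2]))
  expect_false(any(is.na(coh$FEV1[c(1, 3)])))
  expect_equal(coh$gold, c(1L, 3L, 2L))
  expect_identical(cohort_domain(coh), "target")
})

test_that("CSV reading enforces the label schema and names offending rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex,FEV1,GOLD", "52,1,2.1,5", "63,0,1.5,2"), path)
  expect_error(read_cohort_csv(path, tiny_specs(), "target"), "row\\(s\\) 1")

  writeLines(c("age,sex,FEV1", "52,1,2.1"), path)
  expect_error(read_cohort_csv(path, tiny_specs(), "target"), "label column")

  expect_error(read_cohort_csv(tempfile(), tiny_specs(), "target"), "Cannot read")
})

test_that("unknown columns are dropped with a warning, predicted columns removed", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "age,sex,FEV1,mystery,predicted_FVC,GOLD",
    "52,1,2.1,9,3.3,1",
    "63,0,1.5,8,2.2,2"
  ), path)
  expect_warning(
    coh <- suppressMessages(read_cohort_csv(path, tiny_specs(), "target")),
    "mystery"
  )
  expect_setdiff <- setdiff(c("mystery", "predicted_FVC"), names(coh))
  expect_equal(sort(expect_setdiff), c("mystery", "predicted_FVC"))
})

test_that("NA spellings parse as missing regardless of case", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex,FEV1,GOLD", "NA,nan,,1", "52,1,2.0,2"), path)
  coh <- read_cohort_csv(path, tiny_specs(), "target")
  expect_true(all(is.na(coh[1, c("age", "sex", "FEV1")])))
})

test_that("cohorts round-trip through CSV with identical values and missingness", {
  pair <- small_pair(seed = 11)
  for (domain in c("source", "target")) {
    coh <- pair[[domain]]
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort_csv(coh, path)
    back <- read_cohort_csv(path, gold_feature_specs(), domain)
    expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
    expect_identical(is.na(back), is.na(tibble::as_tibble(coh)),
                     ignore_attr = TRUE)
  }
})

test_that("stratified split reproduces the 81/20 partition for the 23/43/27/8 cohort", {
  labels <- rep(1:4, times = c(23, 43, 27, 8))
  sp <- stratified_split(labels, fraction = 0.2, seed = 42)
  expect_length(sp$train, 81L)
  expect_length(sp$validation, 20L)
  expect_setequal(c(sp$train, sp$validation), seq_along(labels))
})

test_that("stratified split is deterministic and respects per-class shares", {
  labels <- rep(1:4, times = c(23, 43, 27, 8))
  a <- stratified_split(labels, 0.2, seed = 7)
  b <- stratified_split(labels, 0.2, seed = 7)
  expect_identical(a$validation, b$validation)
  expect_identical(a$train, b$train)

  val_counts <- table(factor(labels[a$validation], levels = 1:4))
  expect_true(all(abs(as.numeric(val_counts) - 0.2 * c(23, 43, 27, 8)) <= 1))

  one_class <- stratified_split(rep(2L, 10), 0.2, seed = 1)
  expect_length(one_class$train, 8L)
  expect_length(one_class$validation, 2L)

  expect_error(stratified_split(rep(1L, 3), fraction = 0.01), "empty validation")
})

test_that("stratified split partitions indices exactly over many random label vectors", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(8:60, 1)
    labels <- sample(1:4, n, replace = TRUE, prob = runif(4) + 0.1)
    labels[1:4] <- 1:4  # every class inhabited
    sp <- stratified_split(labels, fraction = runif(1, 0.1, 0.5), seed = i)
    expect_identical(sort(c(sp$train, sp$validation)), seq_len(n))
    expect_length(intersect(sp$train, sp$validation), 0L)
  }
})

test_that("per-class validation proportions converge to the fraction at large n", {
  labels <- sample(1:4, 10000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  sp <- stratified_split(labels, fraction = 0.2, seed = 3)
  prop <- table(factor(labels[sp$validation], levels = 1:4)) /
    table(factor(labels, levels = 1:4))
  expect_true(all(abs(as.numeric(prop) - 0.2) < 0.005))
})
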