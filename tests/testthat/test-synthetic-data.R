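test_that("spirometric staging bands are left-closed as specified", {
  expect_equal(assign_stage_from_fev1pct(c(85, 50, 25)), c(1L, 2L, 4L))
  expect_equal(assign_stage_from_fev1pct(c(80, 79.9, 30, 29.9)), c(1L, 2L, 3L, 4L))
  expect_error(assign_stage_from_fev1pct(-3), "positive")
})

test_that("sim_spec validates its probability vectors and rates", {
  expect_error(sim_spec(stage_probs_target = c(0.5, 0.5, 0.1, 0.1)), "summing to 1")
  expect_error(sim_spec(missing_rate = 1), "missing_rate")
  expect_error(sim_spec(noise_sd = -1), "noise_sd")
})

test_that("generation is fully reproducible from the seed", {
  a <- generate_pair(sim_spec(n_source = 40, n_target = 30, seed = 21))
  b <- generate_pair(sim_spec(n_source = 40, n_target = 30, seed = 21))
  expect_identical(as.data.frame(a$source), as.data.frame(b$source))
  expect_identical(as.data.frame(a$target), as.data.frame(b$target))
})

test_that("cohorts carry the schema's feature availability split", {
  pair <- small_pair(seed = 8)
  expect_true(all(c("CAT", "exacerbations") %in% names(pair$source)))
  expect_false(any(c("MWT1", "MWT2") %in% names(pair$source)))
  expect_true(all(c("MWT1", "MWT2") %in% names(pair$target)))
  expect_false(any(c("CAT", "exacerbations") %in% names(pair$target)))
})

test_that("target stage counts at the default mix stay within multinomial sampling error", {
  pair <- generate_pair(sim_spec(seed = 1))
  counts <- table(factor(pair$target$gold, levels = 1:4))
  gof <- stats::chisq.test(counts, p = c(23, 43, 27, 8) / 101)
  expect_gt(gof$p.value, 0.001)
  expect_equal(sum(counts), 101)
})

test_that("label distribution matches stage_probs at n = 10,000 (chi-square alpha 0.01)", {
  p <- c(23, 43, 27, 8) / 101
  big <- generate_pair(sim_spec(n_source = 10, n_target = 10000,
                                stage_probs_target = p, seed = 8))
  gof <- stats::chisq.test(table(factor(big$target$gold, levels = 1:4)), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("zero missing rate yields fully observed cohorts and all-one masks", {
  pair <- small_pair(seed = 5, missing_rate = 0)
  expect_false(anyNA(pair$target))
  blocks <- build_design_blocks(pair$target, gold_feature_specs())
  expect_true(all(blocks$shared[, 8:14] == 1))
  expect_true(all(blocks$private[, 3:4] == 1))
})

test_that("in the noiseless fully observed limit a spirometric rule recovers every label", {
  nl <- generate_pair(sim_spec(noise_sd = 0, missing_rate = 0, seed = 6))
  for (coh in nl) {
    pp <- 100 * coh$FEV1 / predicted_fev1(coh$age, coh$sex)
    expect_equal(assign_stage_from_fev1pct(pp), coh$gold)
  }
})

test_that("generated shared values honor the clinical ranges at default noise", {
  pair <- generate_pair(sim_spec(n_source = 2000, n_target = 2000,
                                 seed = 4, missing_rate = 0))
  in_range <- function(coh) {
    c(coh$age >= 40 & coh$age <= 100,
      coh$sex %in% 0:1,
      coh$smoking_status %in% 0:2,
      coh$pack_years >= 0 & coh$pack_years <= 110,
      coh$FEV1 >= 0.4 & coh$FEV1 <= 4.0)
  }
  expect_gte(mean(c(in_range(pair$source), in_range(pair$target))), 0.99)
})

test_that("stage-conditional trends run the right way", {
  pair <- generate_pair(sim_spec(n_source = 3000, n_target = 3000,
                                 seed = 13, missing_rate = 0))
  src <- pair$source
  cat_means <- tapply(src$CAT, src$gold, mean)
  expect_true(all(diff(cat_means) > 0))
  tgt <- pair$target
  mwt_means <- tapply(tgt$MWT1, tgt$gold, mean)
  expect_true(all(diff(mwt_means) < 0))
  fev_means <- tapply(src$FEV1, src$gold, mean)
  expect_true(all(diff(fev_means) < 0))
})

test_that("stronger severity signal raises the logistic baseline's held-out QWK", {
  qwk_at <- function(sig) {
    mean(vapply(1:10, function(s) {
      suite <- run_suite(
        sim_spec(n_source = 120, n_target = 80, signal_strength = sig, seed = s),
        repeats = 1, base_seed = s, variants = "logistic"
      )
      suite$summary$qwk_mean
    }, numeric(1)))
  }
  q <- vapply(c(0, 0.5, 1), qwk_at, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("written pairs land in the dialect the reader consumes", {
  dir <- withr::local_tempdir()
  pair <- small_pair(seed = 2)
  paths <- write_pair(pair, dir)
  back <- read_cohort_csv(file.path(dir, "source.csv"), gold_feature_specs(), "source")
  expect_equal(as.data.frame(back), as.data.frame(pair$source), tolerance = 1e-12)
})
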