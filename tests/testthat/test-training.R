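test_that("ordinal BCE matches analytic values", {
  expect_equal(ordinal_bce_loss(matrix(0.5, 4, 3), encode_stage(c(1, 2, 3, 4))),
               log(2))
  expect_equal(ordinal_bce_loss(matrix(0.8, 1, 3)[, 1, drop = FALSE],
                                matrix(0, 1, 1)),
               -log(0.2), tolerance = 1e-9)
  # near-perfect predictions drive the loss toward zero
  t <- encode_stage(c(1, 4))
  eps <- 1e-6
  p <- t * (1 - eps) + (1 - t) * eps
  expect_lt(ordinal_bce_loss(p, t), 1e-5)
  expect_error(ordinal_bce_loss(matrix(0.5, 2, 3), matrix(0, 3, 3)), "identical")
})

test_that("training is deterministic for a fixed seed", {
  pair <- small_pair(seed = 4)
  f1 <- fit_gold_onn(pair$source, pair$target, control = fast_control(seed = 2, epochs = 60))
  f2 <- fit_gold_onn(pair$source, pair$target, control = fast_control(seed = 2, epochs = 60))
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$validation$pred, f2$validation$pred)
})

test_that("checkpoint selection tracks the minimum validation MAE at the evaluation cadence", {
  pair <- small_pair(seed = 4)
  fit <- fit_gold_onn(pair$source, pair$target, control = fast_control(epochs = 200))
  expect_equal(fit$best_val_mae, min(fit$log$val_mae))
  expect_equal(fit$best_epoch, fit$log$epoch[which.min(fit$log$val_mae)])
  expect_equal(fit$best_epoch %% fit$control$eval_every, 0L)
  # earliest epoch wins ties
  ties <- fit$log$epoch[fit$log$val_mae == fit$best_val_mae]
  expect_equal(fit$best_epoch, min(ties))
})

test_that("re-evaluating the stored checkpoint reproduces the best validation MAE exactly", {
  pair <- small_pair(seed = 7)
  specs <- gold_feature_specs()
  fit <- fit_gold_onn(pair$source, pair$target, specs,
                      control = fast_control(epochs = 150))
  blocks <- build_design_blocks(pair$target, specs)
  val <- goldstage:::blocks_rows(blocks, fit$split$validation)
  probs <- onn_forward(fit$params, fit$config, val$shared, val$private, "target")
  expect_equal(mean(abs(decode_thresholds(probs) - val$gold)), fit$best_val_mae)
})

test_that("one tiny unclipped gradient step decreases the training loss", {
  pair <- small_pair(seed = 6)
  ctrl <- train_control(learning_rate = 1e-6, max_epochs = 2, eval_every = 1,
                        clip_norm = 1e9, seed = 3)
  fit <- fit_gold_onn(pair$source, pair$target, control = ctrl)
  expect_lt(fit$log$loss[2], fit$log$loss[1])
})

test_that("training improves on the epoch-0 validation error under strong signal", {
  pair <- small_pair(seed = 1)
  fit <- fit_gold_onn(pair$source, pair$target, control = fast_control(epochs = 800))
  expect_lt(fit$best_val_mae, fit$initial$mae)
})

test_that("losses stay finite over several seeds at short horizons", {
  pair <- small_pair(seed = 10)
  for (s in 1:5) {
    fit <- fit_gold_onn(pair$source, pair$target, control = fast_control(seed = s, epochs = 80))
    expect_true(all(is.finite(fit$log$loss)))
  }
})

test_that("multiclass variant trains with softmax cross-entropy and argmax decoding", {
  pair <- small_pair(seed = 12)
  fit <- fit_gold_onn(pair$source, pair$target, variant = "multiclass",
                      control = fast_control(epochs = 150))
  expect_true(all(fit$validation$pred %in% 1:4))
  expect_equal(ncol(fit$validation$probs), 4L)
  expect_equal(rowSums(fit$validation$probs), rep(1, length(fit$validation$pred)),
               tolerance = 1e-9)
})

test_that("train log exports and empty training inputs error", {
  pair <- small_pair(seed = 3)
  fit <- fit_gold_onn(pair$source, pair$target, control = fast_control(epochs = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_train_log(fit, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(fit$log))
  expect_named(back, c("epoch", "loss", "val_accuracy", "val_mae", "val_qwk"))
})
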