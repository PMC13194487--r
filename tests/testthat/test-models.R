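default_config <- function(variant = "full_ordinal") {
  model_config(variant, d_shared = 7, d_source_private = 2, d_target_private = 2)
}

zero_params <- function(config) {
  p <- init_params(config, seed = 1)
  for (nm in names(p)) {
    p[[nm]]$W[] <- 0
    p[[nm]]$b[] <- 0
  }
  p
}

rand_blocks <- function(n, d_shared = 7, d_private = 2, seed = 1) {
  set.seed(seed)
  list(
    shared = matrix(runif(n * 2 * d_shared), n),
    private = matrix(runif(n * 2 * d_private), n)
  )
}

test_that("default full model wires 2x7 -> 32 -> 16 shared, 8-d private, 24 -> 3 head", {
  cfg <- default_config()
  p <- init_params(cfg, seed = 3)
  expect_equal(dim(p$shared1$W), c(14L, 32L))
  expect_equal(dim(p$shared2$W), c(32L, 16L))
  expect_equal(dim(p$source_private$W), c(4L, 8L))
  expect_equal(dim(p$target_private$W), c(4L, 8L))
  expect_equal(dim(p$head$W), c(24L, 3L))
  expect_equal(cfg$head_inputs, 24L)
  expect_equal(cfg$head_outputs, 3L)
})

test_that("initialization is deterministic, fan-in bounded, with zero biases", {
  cfg <- default_config()
  a <- init_params(cfg, seed = 11)
  b <- init_params(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, init_params(cfg, seed = 12)))
  expect_true(all(abs(a$shared1$W) <= 1 / sqrt(14)))
  expect_true(all(a$head$b == 0))
})

test_that("parameter count matches the closed-form hand count", {
  # shared: 14*32+32 + 32*16+16; privates: 2*(4*8+8); head: 24*3+3
  expected <- (14 * 32 + 32) + (32 * 16 + 16) + 2 * (4 * 8 + 8) + (24 * 3 + 3)
  expect_equal(goldstage:::n_params(init_params(default_config(), 1)), expected)
  expect_equal(expected, 1163)
})

test_that("zero parameters give neutral outputs: 0.5 sigmoids, uniform softmax", {
  blk <- rand_blocks(5)
  cfg <- default_config()
  probs <- onn_forward(zero_params(cfg), cfg, blk$shared, blk$private, "target")
  expect_equal(dim(probs), c(5L, 3L))
  expect_true(all(probs == 0.5))

  mc <- default_config("multiclass")
  probs <- onn_forward(zero_params(mc), mc, blk$shared, blk$private, "source")
  expect_equal(dim(probs), c(5L, 4L))
  expect_true(all(abs(probs - 0.25) < 1e-12))
  expect_equal(rowSums(probs), rep(1, 5))
})

test_that("forward validates widths and domains", {
  cfg <- default_config()
  p <- init_params(cfg, 1)
  blk <- rand_blocks(3)
  expect_error(onn_forward(p, cfg, blk$shared[, 1:10], blk$private, "target"),
               "width")
  expect_error(onn_forward(p, cfg, blk$shared, blk$private, "elsewhere"),
               "domain")
})

test_that("forward is row-equivariant", {
  cfg <- default_config()
  p <- init_params(cfg, 5)
  blk <- rand_blocks(12, seed = 4)
  out <- onn_forward(p, cfg, blk$shared, blk$private, "source")
  perm <- sample(12)
  out_p <- onn_forward(p, cfg, blk$shared[perm, ], blk$private[perm, ], "source")
  expect_equal(out_p, out[perm, ])
})

test_that("ablation variants ignore the removed pathway entirely", {
  blk <- rand_blocks(6, seed = 2)
  so <- model_config("shared_only_ordinal", 7, 2, 2)
  p <- init_params(so, 1)
  a <- onn_forward(p, so, blk$shared, blk$private, "target")
  b <- onn_forward(p, so, blk$shared, blk$private * 100 - 3, "target")
  expect_identical(a, b)
  expect_equal(dim(p$head$W), c(16L, 3L))

  po <- model_config("private_only_ordinal", 7, 2, 2)
  q <- init_params(po, 1)
  a <- onn_forward(q, po, blk$shared, blk$private, "target")
  b <- onn_forward(q, po, blk$shared * -5 + 1, blk$private, "target")
  expect_identical(a, b)
  expect_equal(dim(q$head$W), c(8L, 3L))

  # multiclass baseline is shared-encoder only
  mc <- model_config("multiclass", 7, 2, 2)
  m <- init_params(mc, 1)
  expect_equal(dim(m$head$W), c(16L, 4L))
  expect_identical(
    onn_forward(m, mc, blk$shared, blk$private, "target"),
    onn_forward(m, mc, blk$shared, blk$private * 9, "target")
  )
})

test_that("checkpoints round-trip parameters and config exactly through JSON/YAML", {
  pair <- small_pair(seed = 3)
  fit <- fit_gold_onn(pair$source, pair$target, control = fast_control(epochs = 30))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ck.json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$params, fit$params, ignore_attr = TRUE)
  expect_equal(back$config, fit$config)
})

test_that("logistic baseline separates a linearly separable 4-class set perfectly", {
  set.seed(8)
  n <- 120
  y <- sample(1:4, n, replace = TRUE)
  x <- cbind(y * 10 + runif(n, -2, 2), rnorm(n))
  # brute-force separability check: class intervals on x1 must not overlap
  rng <- vapply(1:4, function(k) range(x[y == k, 1]), numeric(2))
  expect_true(all(rng[2, 1:3] < rng[1, 2:4]))

  fit <- fit_logistic_baseline(x, y, seed = 1)
  expect_equal(predict(fit, x), y)
})

test_that("logistic baseline is deterministic and stays in the stage codomain", {
  set.seed(3)
  x <- matrix(rnorm(200), 50)
  y <- sample(1:4, 50, replace = TRUE)
  f1 <- fit_logistic_baseline(x, y, seed = 9)
  f2 <- fit_logistic_baseline(x, y, seed = 9)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_true(all(predict(f1, x) %in% 1:4))
  expect_error(fit_logistic_baseline(x, rep(2L, 50), seed = 1), "two distinct")
})
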