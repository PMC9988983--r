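test_that("architecture downsampling and determinism contracts hold", {
  expect_equal(downsampling_factor(model_config()), 4096)
  expect_equal(downsampling_factor(model_config(depth = 4)), 16)
  m1 <- tiny_model(seed = 3)
  m2 <- tiny_model(seed = 3)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, tiny_model(seed = 4)$params))
})

test_that("parameter count grows with depth and base filters", {
  n <- vapply(2:4, function(d) count_params(tiny_model(depth = d)), 0)
  expect_true(all(diff(n) > 0))
  n2 <- vapply(c(3, 5, 8), function(b)
    count_params(tiny_model(base_filters = b)), 0)
  expect_true(all(diff(n2) > 0))
})

test_that("forward is length-agnostic and emits probability rows", {
  m <- tiny_model()
  i <- 30 * FIX_FS
  for (L in c(2, 7)) {
    X <- matrix(rnorm(L * i * 2), L * i, 2)
    pr <- forward(m, X)
    expect_equal(dim(pr), c(L, 5))
    expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  }
  # untrained model (zero output conv) predicts the uniform law
  X <- matrix(rnorm(2 * i * 2), 2 * i, 2)
  expect_equal(forward(m, X), matrix(0.2, 2, 5,
               dimnames = list(NULL, stage_levels())), tolerance = 1e-12)
  expect_error(forward(m, X[1:100, ]), "whole number")
  X[1] <- NA
  expect_error(forward(m, X), "non-finite")
})

test_that("conditional models require a valid condition index", {
  m <- tiny_model(norm_mode = "sabn", G = 3)
  i <- 30 * FIX_FS
  X <- matrix(rnorm(2 * i * 2), 2 * i, 2)
  expect_error(forward(m, X), "condition index")
  expect_error(forward(m, X, g = 5), "out of")
  expect_equal(dim(forward(m, X, g = 2)), c(2, 5))
})

test_that("normalization reduces along sabn -> ccbn -> vanilla", {
  set.seed(11)
  B <- 4; C <- 3; T <- 50
  f <- array(rnorm(B * C * T, 2, 3), c(B, C, T))
  params <- psgres:::new_norm(C, 2)
  params$gamma <- runif(C, 0.5, 2); params$beta <- rnorm(C)
  params$gamma_g <- matrix(runif(2 * C, 0.5, 2), 2, C)
  params$beta_g <- matrix(rnorm(2 * C), 2, C)
  g <- c(1L, 2L, 1L, 2L)

  # sabn with identity sandwich == ccbn with the same group affines
  expect_identical(
    conditional_normalize(f, g, params, "sabn", training = TRUE),
    conditional_normalize(f, g, params, "ccbn", training = TRUE))

  # ccbn with G = 1 and gamma_1 = gamma == vanilla
  p1 <- psgres:::new_norm(C, 1)
  p1$gamma <- params$gamma; p1$beta <- params$beta
  p1$gamma_g <- matrix(params$gamma, 1, C)
  p1$beta_g <- matrix(params$beta, 1, C)
  expect_identical(
    conditional_normalize(f, rep(1L, B), p1, "ccbn", training = TRUE),
    conditional_normalize(f, NULL, p1, "vanilla", training = TRUE))
})

test_that("batch normalization standardizes to zero mean, unit variance", {
  set.seed(2)
  f <- array(rnorm(8 * 2 * 100, mean = 5, sd = 4), c(8, 2, 100))
  params <- psgres:::new_norm(2, 1)
  h <- conditional_normalize(f, NULL, params, "vanilla", training = TRUE)
  for (c in 1:2) {
    expect_lt(abs(mean(h[, c, ])), 1e-5)
    expect_lt(abs(stats::var(as.vector(h[, c, ])) - 1), 1e-2)
  }
})

test_that("changing one sample's condition only changes that sample", {
  m <- tiny_model(norm_mode = "sabn", G = 2, seed = 5)
  # give the group affines distinct values so g matters
  m$params$seg$norm_h$gamma_g[2, ] <- 2
  m$params$seg$conv_o$W[] <- rnorm(length(m$params$seg$conv_o$W), 0, 0.3)
  i <- 30 * FIX_FS
  X <- array(rnorm(3 * 2 * i * 2), c(3, 2 * i, 2))
  p1 <- psgres:::net_forward(m, X, g = c(1L, 1L, 1L))$probs
  p2 <- psgres:::net_forward(m, X, g = c(1L, 2L, 1L))$probs
  expect_identical(p1[1, , ], p2[1, , ])
  expect_identical(p1[3, , ], p2[3, , ])
  expect_false(identical(p1[2, , ], p2[2, , ]))
})

test_that("norm-mode conversion preserves predictions for every group", {
  m <- tiny_model(seed = 9)
  m$params$seg$conv_o$W[] <- rnorm(length(m$params$seg$conv_o$W), 0, 0.3)
  i <- 30 * FIX_FS
  X <- matrix(rnorm(2 * i * 2), 2 * i, 2)
  base <- forward(m, X)
  ms <- convert_norm_mode(m, "sabn", G = 3)
  for (g in 1:3) expect_equal(forward(ms, X, g = g), base, tolerance = 1e-12)

  # parameter accounting: one affine set has n_affine parameters in total;
  # ccbn replaces it by G copies (surplus (G-1) sets), sabn keeps the
  # shared sandwich affine and adds G group sets (surplus G sets)
  n_affine <- 0
  walk <- function(x) {
    if (is.list(x) && !is.null(x$run_mean))
      n_affine <<- n_affine + 2 * length(x$gamma)
    else if (is.list(x) && is.null(x$W)) for (e in x) walk(e)
  }
  walk(m$params)
  mc <- convert_norm_mode(m, "ccbn", G = 3)
  expect_equal(count_params(mc) - count_params(m), 2 * n_affine)
  expect_equal(count_params(ms) - count_params(m), 3 * n_affine)
})
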