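test_that("forward differences match the hand oracle and its conventions", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)  # [[0,1],[2,3]] row-wise
  f <- forward_gradient(m)
  expect_equal(f$dx_down, rbind(c(2, 2), c(0, 0)))
  expect_equal(f$dx_right, rbind(c(1, 0), c(1, 0)))
  expect_true(all(f$dx_down[nrow(m), ] == 0))
  expect_true(all(f$dx_right[, ncol(m)] == 0))

  const <- forward_gradient(matrix(5, 4, 4))
  expect_true(all(const$dx_down == 0) && all(const$dx_right == 0))

  set.seed(1)
  a <- matrix(runif(30), 5, 6)
  fa <- forward_gradient(a)
  fb <- forward_gradient(a + 17.3)
  expect_equal(fa, fb)
  o <- oracle_forward_diff(a)
  expect_equal(fa$dx_down, o$dd)
  expect_equal(fa$dx_right, o$dr)

  expect_error(forward_gradient(matrix(1, 1, 5)), "degenerate")
})

test_that("gradient normalization yields bounded near-unit vectors", {
  f <- structure(list(dx_down = matrix(3, 2, 2), dx_right = matrix(4, 2, 2)),
                 class = "gradient_field")
  n <- normalized_gradient(f, eps = 1e-12)
  expect_equal(n$dx_down[1, 1], 0.6, tolerance = 1e-10)
  expect_equal(n$dx_right[1, 1], 0.8, tolerance = 1e-10)

  z <- structure(list(dx_down = matrix(0, 2, 2), dx_right = matrix(0, 2, 2)),
                 class = "gradient_field")
  nz <- normalized_gradient(z, eps = 1e-8)
  expect_true(all(nz$dx_down == 0) && all(nz$dx_right == 0))

  set.seed(2)
  f8 <- forward_gradient(matrix(rnorm(64), 8, 8))
  n8 <- normalized_gradient(f8, eps = 1e-8)
  mag <- sqrt(n8$dx_down^2 + n8$dx_right^2)
  expect_true(all(mag >= 0 & mag <= 1))
  expect_error(normalized_gradient(f8, eps = 0), "positive")
})

test_that("pixelwise gradient loss reproduces the worked cases", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)
  expect_equal(pixelwise_gradient_loss(m, 2 * m, eps = 1e-12), -3 / 4,
               tolerance = 1e-9)
  set.seed(3)
  a <- matrix(runif(64, 0, 100), 8, 8)
  # identical non-constant images: -(count of nonzero-gradient pixels)/N
  f <- forward_gradient(a)
  k <- sum(f$dx_down^2 + f$dx_right^2 > 0)
  expect_equal(pixelwise_gradient_loss(a, a, eps = 1e-14), -k / 64,
               tolerance = 1e-9)
  # intensity inversion of the target changes nothing (squared dot product)
  expect_equal(pixelwise_gradient_loss(a, 100 - a),
               pixelwise_gradient_loss(a, a), tolerance = 1e-10)
  expect_error(pixelwise_gradient_loss(a, matrix(0, 4, 4)), "mismatch")
})

test_that("pixelwise gradient loss matches the brute-force oracle on random pairs", {
  set.seed(4)
  for (r in 1:50) {
    a <- matrix(runif(64, 0, 4095), 8, 8)
    b <- matrix(runif(64, 0, 4095), 8, 8)
    expect_equal(pixelwise_gradient_loss(a, b, eps = 1e-12),
                 oracle_pg_loss(a, b, eps = 1e-12), tolerance = 1e-10)
  }
})

test_that("pixelwise gradient loss is bounded and affine-invariant", {
  set.seed(5)
  for (r in 1:20) {
    a <- matrix(runif(64, 0, 100), 8, 8)
    b <- matrix(runif(64, 0, 100), 8, 8)
    v <- pixelwise_gradient_loss(a, b)
    expect_gte(v, -1)
    expect_lte(v, 0)
    for (k in c(0.5, 2)) {
      expect_lt(abs(pixelwise_gradient_loss(k * a + 7, b) - v), 1e-6)
      expect_lt(abs(pixelwise_gradient_loss(a, k * b + 3) - v), 1e-6)
    }
  }
})

test_that("self-alignment minimizes the gradient loss over random perturbations", {
  set.seed(6)
  x <- matrix(runif(64, 0, 10), 8, 8)
  self <- pixelwise_gradient_loss(x, x)
  worse <- vapply(1:1000, function(i) {
    y <- x + matrix(rnorm(64, sd = runif(1, 0.01, 5)), 8, 8)
    pixelwise_gradient_loss(x, y)
  }, numeric(1))
  expect_true(all(self <= worse + 1e-12))
})

test_that("LSGAN losses match their scalar definitions and a loop oracle", {
  expect_equal(lsgan_d_loss(matrix(1, 4, 4), matrix(0, 4, 4)), 0)
  expect_equal(lsgan_d_loss(matrix(0, 4, 4), matrix(1, 4, 4)), 1)
  expect_equal(lsgan_d_loss(matrix(0.5, 4, 4), matrix(0.5, 4, 4)), 0.25)
  expect_equal(lsgan_g_loss(matrix(1, 4, 4)), 0)
  expect_equal(lsgan_g_loss(matrix(0, 4, 4)), 0.5)
  expect_equal(lsgan_g_loss(matrix(-1, 4, 4)), 2)

  set.seed(7)
  for (r in 1:10) {
    dr <- matrix(rnorm(16), 4, 4)
    df <- matrix(rnorm(16), 4, 4)
    accr <- 0; accf <- 0
    for (i in 1:4) for (j in 1:4) {
      accr <- accr + (dr[i, j] - 1)^2
      accf <- accf + df[i, j]^2
    }
    expect_equal(lsgan_d_loss(dr, df), 0.5 * accr / 16 + 0.5 * accf / 16,
                 tolerance = 1e-12)
    accg <- 0
    for (i in 1:4) for (j in 1:4) accg <- accg + (df[i, j] - 1)^2
    expect_equal(lsgan_g_loss(df), 0.5 * accg / 16, tolerance = 1e-12)
  }
})

test_that("gradient penalty matches analytic cases and is non-negative", {
  set.seed(8)
  batch <- list(matrix(runif(36), 6, 6), matrix(runif(36), 6, 6))
  expect_equal(gradient_penalty(function(x) 3.7, batch, gamma = 10), 0)
  # linear D with unit weights: penalty = gamma/2 * H * W
  expect_equal(gradient_penalty(function(x) sum(x), batch, gamma = 10),
               10 / 2 * 36, tolerance = 1e-6)
  expect_gte(gradient_penalty(function(x) sum(sin(x)) + mean(x^2), batch), 0)
  expect_error(gradient_penalty("not a model", batch), "discriminator")
})

test_that("the generator objective decouples into its weighted terms", {
  set.seed(9)
  a <- matrix(runif(64, 0, 100), 8, 8)
  b <- matrix(runif(64, 0, 100), 8, 8)
  df <- matrix(rnorm(16), 4, 4)
  pg <- pixelwise_gradient_loss(a, b)
  gl <- lsgan_g_loss(df)
  expect_equal(generator_objective(a, b, df, loss_weights(1, 0)), pg)
  expect_equal(generator_objective(a, a, matrix(1, 2, 2), loss_weights(0, 1)), 0)
  # 1:1 objective is the appropriately rescaled mean of the 10:1 and 1:10 ones
  o10 <- generator_objective(a, b, df, loss_weights(10, 1))
  o01 <- generator_objective(a, b, df, loss_weights(1, 10))
  o11 <- generator_objective(a, b, df, loss_weights(1, 1))
  expect_equal((o10 + o01) / 11, o11, tolerance = 1e-12)
  expect_error(loss_weights(0, 0), "both")
})
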