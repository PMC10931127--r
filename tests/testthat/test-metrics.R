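test_that("MAE and MSE match constant-shift cases and the loop oracle", {
  s <- rand_raw_slice(8, seed = 1)
  g <- slice_image(pmin(s$pixels + 3, 4095), "raw")
  expect_equal(img_mae(s, s), 0)
  expect_equal(img_mse(s, s), 0)
  s2 <- slice_image(matrix(100, 8, 8), "raw")
  g2 <- slice_image(matrix(103, 8, 8), "raw")
  expect_equal(img_mae(s2, g2), 3)
  expect_equal(img_mse(s2, g2), 9)
  set.seed(2)
  for (r in 1:10) {
    a <- matrix(runif(64, 0, 4095), 8, 8)
    b <- matrix(runif(64, 0, 4095), 8, 8)
    expect_equal(img_mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
    expect_equal(img_mse(a, b), oracle_mse(a, b), tolerance = 1e-12)
  }
  expect_error(img_mae(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
  # Cauchy-Schwarz: mse >= mae^2 per image pair
  set.seed(3)
  for (r in 1:20) {
    a <- matrix(runif(64, 0, 4095), 8, 8)
    b <- matrix(runif(64, 0, 4095), 8, 8)
    expect_gte(img_mse(a, b), img_mae(a, b)^2)
  }
})

test_that("global SSIM hits identity, symmetry and the constant closed form", {
  s <- rand_raw_slice(16, seed = 4)
  expect_equal(img_ssim(s, s), 1, tolerance = 1e-12)
  g <- rand_raw_slice(16, seed = 5)
  expect_equal(img_ssim(s, g), img_ssim(g, s), tolerance = 1e-12)
  # constants a != b: covariance term degenerates to c2/c2 = 1
  c1 <- (0.01 * 4095)^2
  a <- 1000; b <- 1500
  got <- img_ssim(matrix(a, 8, 8), matrix(b, 8, 8))
  expect_equal(got, (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-12)
  expect_equal(c1, 40.95^2)  # 1676.9025
  expect_true(got < 1 && got > 0)
})

test_that("texture metrics reproduce the hand-worked 2x2 examples", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)  # [[0,1],[2,3]]
  expect_equal(img_tmsvpmi(m), (sqrt(5) + 2 + 1 + 0) / 4 / 1.5, tolerance = 1e-10)
  expect_equal(img_tmsvpmi(m), 0.87268, tolerance = 1e-5)
  expect_equal(img_tavpmi(m), 1.0, tolerance = 1e-12)
  expect_equal(img_vfpmi(m), sqrt(1.25) / 1.5, tolerance = 1e-12)
  expect_equal(img_vfpmi(m), 0.74536, tolerance = 1e-5)
})

test_that("texture metrics vanish on constants and reject degenerate means", {
  const <- matrix(42, 8, 8)
  expect_equal(img_tmsvpmi(const), 0)
  expect_equal(img_tavpmi(const), 0)
  expect_equal(img_tfpmi(const), 0)
  expect_equal(img_vfpmi(const), 0)
  expect_error(img_tmsvpmi(matrix(0, 4, 4)), "positive")
  expect_error(img_tfpmi(matrix(1, 2, 2)), "3x3")
})

test_that("all four texture metrics are invariant under positive scaling", {
  set.seed(6)
  m <- matrix(runif(144, 1, 4095), 12, 12)
  for (metric in list(img_tmsvpmi, img_tavpmi, img_tfpmi, img_vfpmi)) {
    base <- metric(m)
    for (k in c(0.5, 2, 10))
      expect_lt(abs(metric(k * m / max(k, 1)) - base) / base, 1e-9)
  }
})

test_that("tavpmi dominates tmsvpmi and Tenengrad matches a convolution oracle", {
  set.seed(7)
  for (r in 1:20) {
    m <- matrix(runif(64, 1, 100), 8, 8)
    expect_gte(img_tavpmi(m), img_tmsvpmi(m))
    expect_equal(img_tfpmi(m), oracle_tfpmi(m), tolerance = 1e-10)
    expect_equal(img_tmsvpmi(m), oracle_tmsvpmi(m), tolerance = 1e-10)
    expect_equal(img_tavpmi(m), oracle_tavpmi(m), tolerance = 1e-10)
    expect_equal(img_vfpmi(m), oracle_vfpmi(m), tolerance = 1e-10)
  }
  # vertical step edge: Tenengrad per mean intensity independent of step height
  step <- function(c) cbind(matrix(0, 8, 4), matrix(c, 8, 4))
  expect_equal(img_tfpmi(step(100)), img_tfpmi(step(3000)), tolerance = 1e-12)
})

test_that("3x3 mean filtering strictly decreases the gradient-based metrics", {
  set.seed(8)
  for (r in 1:25) {
    m <- matrix(runif(100, 1, 100), 10, 10)
    sm <- mean_filter3(m)
    expect_lt(img_tmsvpmi(sm), img_tmsvpmi(m))
    expect_lt(img_tavpmi(sm), img_tavpmi(m))
    expect_lt(img_tfpmi(sm), img_tfpmi(m))
  }
})

test_that("modality-ablation ratios follow their definition", {
  dual <- list(mae = 2, mse = 8, ssim = 0.8)
  expect_equal(metric_ratios(dual, dual), list(maer = 0, mser = 0, ssimr = 0))
  single <- list(mae = 3, mse = 8, ssim = 0.8)
  expect_equal(metric_ratios(single, dual)$maer, 0.5)
  expect_error(metric_ratios(single, list(mae = 0, mse = 1, ssim = 1)), "MAE")
})

test_that("aggregation reports sample mean and SD per metric", {
  df <- data.frame(mae = c(1, 3), ssim = c(0.5, 0.5))
  agg <- aggregate_metrics(df)
  expect_equal(agg$mean[agg$metric == "mae"], 2)
  expect_equal(agg$sd[agg$metric == "mae"], sqrt(2))
  expect_equal(agg$sd[agg$metric == "ssim"], 0)
  expect_error(aggregate_metrics(df[1, , drop = FALSE]), "at least 2")
  set.seed(9)
  v <- runif(100)
  df2 <- data.frame(x = v)
  agg2 <- aggregate_metrics(df2)
  mu <- sum(v) / 100
  expect_equal(agg2$mean, mu, tolerance = 1e-12)
  expect_equal(agg2$sd, sqrt(sum((v - mu)^2) / 99), tolerance = 1e-12)
})

test_that("evaluate_pairs emits the seven-metric slice table", {
  preds <- lapply(1:3, function(k) rand_raw_slice(8, seed = 10 + k))
  truths <- lapply(1:3, function(k) rand_raw_slice(8, seed = 20 + k))
  df <- evaluate_pairs(preds, truths)
  expect_equal(names(df), c("mae", "mse", "ssim", "tmsvpmi", "tavpmi",
                            "tfpmi", "vfpmi"))
  expect_equal(nrow(df), 3)
  expect_true(all(is.finite(as.matrix(df))))
})
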