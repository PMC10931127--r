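test_that("generator honours shape contracts and deterministic init", {
  spec <- generator_spec("dual", base_width = 4, depth = 2)
  g1 <- suppressMessages(build_generator(spec, seed = 7))
  g2 <- suppressMessages(build_generator(spec, seed = 7))
  expect_identical(g1$params, g2$params)
  x1 <- array(runif(192 * 192), c(192, 192, 1, 1))
  x2 <- array(runif(192 * 192), c(192, 192, 1, 1))
  out <- pgvce:::gen_predict(g1, x1, x2)
  expect_equal(dim(out), c(192L, 192L, 1L, 1L))
  bad <- array(runif(30 * 30), c(30, 30, 1, 1))
  expect_error(pgvce:::gen_predict(g1, bad, bad), "divisible")
})

test_that("single-modality generators ignore the absent modality entirely", {
  spec <- generator_spec("t1_only", base_width = 4, depth = 2)
  g <- suppressMessages(build_generator(spec, seed = 3))
  x1 <- array(runif(32 * 32), c(32, 32, 1, 2))
  o1 <- pgvce:::gen_predict(g, x1, NULL)
  o2 <- pgvce:::gen_predict(g, x1, array(runif(32 * 32 * 2), c(32, 32, 1, 2)))
  expect_identical(o1, o2)
  expect_error(pgvce:::gen_predict(g, NULL, x1), "missing")
})

test_that("dual generators carry strictly more parameters than single-mode", {
  nd <- suppressMessages(build_generator(generator_spec("dual", 4, 2), 1))$n_params
  n1 <- suppressMessages(build_generator(generator_spec("t1_only", 4, 2), 1))$n_params
  n2 <- suppressMessages(build_generator(generator_spec("t2_only", 4, 2), 1))$n_params
  expect_gt(nd, n1)
  expect_gt(nd, n2)
})

test_that("generator output stays finite and matches the head activation range", {
  spec <- generator_spec("dual", base_width = 4, depth = 2, out_activation = "sigmoid")
  g <- suppressMessages(build_generator(spec, seed = 9))
  set.seed(10)
  for (r in 1:100) {
    x1 <- array(runif(16 * 16, 0, 1), c(16, 16, 1, 1))
    x2 <- array(runif(16 * 16, 0, 1), c(16, 16, 1, 1))
    out <- pgvce:::gen_predict(g, x1, x2)
    expect_true(all(is.finite(out)))
    expect_true(all(out > 0 & out < 1))
  }
  lin <- suppressMessages(build_generator(
    generator_spec("dual", 4, 2, out_activation = "linear"), seed = 9))
  o <- pgvce:::gen_predict(lin, array(rnorm(256), c(16, 16, 1, 1)),
                           array(rnorm(256), c(16, 16, 1, 1)))
  expect_true(all(is.finite(o)))
})

test_that("discriminator produces a deterministic patch-score grid", {
  spec <- discriminator_spec(base_width = 4, depth = 3, modality_mode = "dual")
  expect_equal(spec$patch_receptive_field, 70)
  d1 <- suppressMessages(build_discriminator(spec, seed = 5))
  d2 <- suppressMessages(build_discriminator(spec, seed = 5))
  cand <- matrix(runif(192 * 192), 192, 192)
  t1 <- matrix(runif(192 * 192), 192, 192)
  t2 <- matrix(runif(192 * 192), 192, 192)
  s1 <- disc_score(d1, cand, t1, t2)
  s2 <- disc_score(d2, cand, t1, t2)
  expect_identical(s1, s2)
  expect_true(all(dim(s1) > 1))  # a grid of local scores, not a scalar
})

test_that("patch scores are shift-equivariant in the interior", {
  d <- suppressMessages(build_discriminator(
    discriminator_spec(base_width = 4, depth = 2, modality_mode = "t1_only"), seed = 6))
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  cond <- matrix(runif(64 * 64), 64, 64)
  stride <- 4  # two stride-2 stages
  sh <- function(m) rbind(m[(stride + 1):nrow(m), ], m[1:stride, ])
  s0 <- disc_score(d, img, t1 = cond)
  s1 <- disc_score(d, sh(img), t1 = sh(cond))
  # interior rows of the shifted score grid equal the unshifted grid moved by
  # one patch (crop generously to stay clear of the wrapped border)
  n <- nrow(s0); m <- ncol(s0)
  a <- s0[6:(n - 5), 3:(m - 3)]
  b <- s1[5:(n - 6), 3:(m - 3)]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("tape gradients agree with finite differences through both networks", {
  set.seed(12)
  g <- suppressMessages(build_generator(generator_spec("dual", 3, 1), seed = 2))
  x1 <- array(runif(8 * 8), c(8, 8, 1, 1))
  x2 <- array(runif(8 * 8), c(8, 8, 1, 1))
  R <- array(rnorm(64), c(8, 8, 1, 1))
  tp <- pgvce:::tape_new()
  pe <- pgvce:::param_env(tp, g$params, TRUE)
  fg <- pgvce:::gen_forward(g, x1, x2, tp, pe = pe)
  pgvce:::tape_backward(tp, list(list(node = fg$out, grad = R)))
  h <- 1e-6
  for (nm in c("m1_stem_w", "gate_m2_s0", "up1_w", "head_b")) {
    idx <- 1L
    gp <- g; gp$params[[nm]][idx] <- gp$params[[nm]][idx] + h
    gm <- g; gm$params[[nm]][idx] <- gm$params[[nm]][idx] - h
    fd <- (sum(pgvce:::gen_predict(gp, x1, x2) * R) -
           sum(pgvce:::gen_predict(gm, x1, x2) * R)) / (2 * h)
    expect_equal(pe$leaves[[nm]]$grad[idx], fd, tolerance = 1e-5)
  }
})
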