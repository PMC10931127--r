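test_that("training configuration echoes the published recipe by default", {
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(cfg$beta1, 0.5)
  expect_equal(cfg$beta2, 0.999)
  expect_equal(cfg$iterations, 14000L)
  expect_equal(cfg$batch_size, 4L)
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(beta1 = 1), "beta1")
  expect_error(training_config(iterations = 0), "iterations")
})

make_prepped <- function(n_patients = 2L, size = c(32L, 32L), seed = 42L,
                         method = "sigmoid") {
  cfg <- tiny_phantom_cfg(n_patients = n_patients, size = size, seed = seed)
  ds <- generate_dataset(cfg)
  prepare_paired_data(ds$samples, method)
}

test_that("a short training run produces finite logs and a usable checkpoint", {
  prep <- make_prepped()
  cfg <- tiny_training_cfg(iterations = 25L)
  fit <- train(prep$samples, cfg)
  expect_equal(nrow(fit$log), 25)
  expect_true(all(is.finite(as.matrix(fit$log))))
  expect_equal(fit$log$iteration, 1:25)
  expect_s3_class(fit$checkpoint, "vce_checkpoint")

  # checkpoint round-trips through disk and synthesizes deterministically
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, f)
  ck <- load_checkpoint(f)
  cfg_ph <- tiny_phantom_cfg(n_patients = 3L)
  s <- generate_patient(cfg_ph, 3)[[1]]
  params <- list(t1 = fit_norm_params(list(s$t1), "sigmoid"),
                 t2 = fit_norm_params(list(s$t2), "sigmoid"),
                 t1c = fit_norm_params(list(s$t1c), "sigmoid"))
  out1 <- synthesize(ck, s$t1, s$t2, params)
  out2 <- synthesize(ck, s$t1, s$t2, params)
  expect_identical(out1$pixels, out2$pixels)
  expect_equal(out1$intensity_space, "raw")
  expect_true(all(out1$pixels >= 0 & out1$pixels <= 4095))
  expect_equal(dim(out1$pixels), dim(s$t1$pixels))
})

test_that("training is reproducible for a fixed seed", {
  prep <- make_prepped(size = c(16L, 16L))
  cfg <- tiny_training_cfg(iterations = 10L)
  f1 <- train(prep$samples, cfg)
  f2 <- train(prep$samples, cfg)
  expect_equal(tail(f1$log$g_loss, 1), tail(f2$log$g_loss, 1), tolerance = 1e-12)
  expect_identical(f1$generator$params, f2$generator$params)
})

test_that("training rejects unnormalized input and missing ground truth", {
  cfg_ph <- tiny_phantom_cfg()
  raw <- generate_patient(cfg_ph, 1)
  expect_error(train(raw, tiny_training_cfg()), "normalize")
  prep <- make_prepped()
  nogt <- lapply(prep$samples, function(s)
    paired_sample(s$t1, s$t2, NULL, patient_id = s$patient_id,
                  slice_index = s$slice_index))
  expect_error(train(nogt, tiny_training_cfg()), "ground-truth")
})

test_that("single-modality checkpoints ignore the unused modality at inference", {
  prep <- make_prepped(size = c(16L, 16L))
  cfg <- tiny_training_cfg(iterations = 8L, modality_mode = "t1_only")
  fit <- train(prep$samples, cfg)
  cfg_ph <- tiny_phantom_cfg(n_patients = 3L, size = c(16L, 16L))
  s <- generate_patient(cfg_ph, 3)[[1]]
  params <- list(t1 = fit_norm_params(list(s$t1), "sigmoid"),
                 t2 = fit_norm_params(list(s$t2), "sigmoid"),
                 t1c = fit_norm_params(list(s$t1c), "sigmoid"))
  with_t2 <- synthesize(fit$checkpoint, s$t1, s$t2, params)
  without_t2 <- synthesize(fit$checkpoint, s$t1, NULL, params)
  expect_identical(with_t2$pixels, without_t2$pixels)
  expect_error(synthesize(fit$checkpoint, NULL, s$t2, params), "t1")
})

test_that("gradient-only training runs without a discriminator", {
  prep <- make_prepped(size = c(16L, 16L))
  cfg <- tiny_training_cfg(iterations = 12L, weights = loss_weights(1, 0))
  fit <- train(prep$samples, cfg)
  expect_null(fit$discriminator)
  expect_true(all(fit$log$gan_loss_term == 0))
  expect_true(all(is.finite(fit$log$gradient_loss_term)))
})

test_that("the ablation driver produces one labelled row per configuration", {
  cfg_ph <- tiny_phantom_cfg(n_patients = 3L, size = c(16L, 16L))
  ds <- generate_dataset(cfg_ph)
  split <- split_by_patient(ds$samples, 2, 1, seed = 1)
  tr <- split_samples(ds$samples, split, "train")
  te <- split_samples(ds$samples, split, "test")
  grid <- list(tiny_training_cfg(iterations = 6L, modality_mode = "dual"),
               tiny_training_cfg(iterations = 6L, modality_mode = "t1_only"))
  tab <- run_ablation(grid, tr, te)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$modality_mode, c("dual", "t1_only"))
  # the dual row's ratios against itself are exactly zero
  expect_equal(tab$maer[1], 0)
  expect_equal(tab$mser[1], 0)
  expect_equal(tab$ssimr[1], 0)
  expect_true(all(is.finite(as.matrix(tab[, c("mae", "mse", "ssim", "tmsvpmi",
                                              "tavpmi", "tfpmi", "vfpmi")]))))
})
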