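test_that("slice_image enforces range and finiteness invariants", {
  expect_error(slice_image(matrix(c(0, NA, 1, 2), 2, 2), "raw"), "non-finite")
  expect_error(slice_image(matrix(-1, 2, 2), "raw"), "raw intensities")
  expect_error(slice_image(matrix(5000, 2, 2), "raw"), "raw intensities")
  expect_error(slice_image(matrix(1, 2, 2), "sigmoid"), "strictly inside")
  expect_silent(slice_image(matrix(0.5, 2, 2), "tanh"))
  expect_equal(dim(slice_image(matrix(0, 3, 5))), c(3L, 5L))
})

test_that("paired_sample requires consistent geometry and spaces", {
  a <- rand_raw_slice(4)
  b <- rand_raw_slice(4)
  expect_silent(paired_sample(a, b, patient_id = "P1", slice_index = 0))
  expect_error(paired_sample(a, rand_raw_slice(5), patient_id = "P1", slice_index = 0),
               "dims")
  n <- slice_image(matrix(0.5, 4, 4), "sigmoid")
  expect_error(paired_sample(a, n, patient_id = "P1", slice_index = 0), "space")
  expect_error(paired_sample(a, b, patient_id = "P1", slice_index = -1),
               "non-negative")
})

test_that("NIfTI volumes load slice-by-slice along the third axis", {
  arr <- array(round(runif(16 * 12 * 5, 0, 4095)), c(16, 12, 5))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  slices <- load_volume(f, "nifti")
  expect_length(slices, 5)
  expect_equal(dim(slices[[3]]$pixels), c(16L, 12L))
  expect_equal(slices[[4]]$pixels, arr[, , 4], tolerance = 1e-6)
  expect_equal(slices[[1]]$intensity_space, "raw")
})

test_that("load_volume rejects missing paths, 4-D input and bad intensities", {
  expect_error(load_volume(tempfile(), "nifti"), "not found")
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2, 2))), f4)
  expect_error(load_volume(f4, "nifti"), "3-D")
  fneg <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(-3, c(4, 4, 2))), fneg)
  expect_error(load_volume(fneg, "nifti"), "negative.*range", ignore.case = TRUE)
})

test_that("PNG stacks round-trip integer intensities exactly and keep order", {
  set.seed(7)
  slices <- lapply(1:12, function(k)
    slice_image(matrix(round(runif(64, 0, 4095)), 8, 8), "raw"))
  d <- tempfile()
  save_volume(slices, d, "png_stack", patient_id = "P007")
  expect_length(list.files(d, pattern = "^P007_[0-9]{4}\\.png$"), 12)
  back <- load_volume(d, "png_stack")
  expect_length(back, 12)
  for (k in seq_along(slices))
    expect_identical(back[[k]]$pixels, slices[[k]]$pixels)
})

test_that("NIfTI save/load round-trips a phantom volume within float tolerance", {
  cfg <- tiny_phantom_cfg()
  ps <- generate_patient(cfg, 1)
  f <- tempfile(fileext = ".nii.gz")
  save_volume(lapply(ps, `[[`, "t1c"), f, "nifti")
  back <- load_volume(f, "nifti")
  for (k in seq_along(ps))
    expect_equal(back[[k]]$pixels, ps[[k]]$t1c$pixels, tolerance = 1e-6)
})

test_that("resize_slice honours target dims, identity and constants", {
  s <- rand_raw_slice(256, 256, seed = 1)
  r <- resize_slice(s, c(192, 192))
  expect_equal(dim(r$pixels), c(192L, 192L))
  expect_equal(r$intensity_space, "raw")
  expect_true(all(r$pixels >= 0 & r$pixels <= 4095))
  s192 <- rand_raw_slice(192, 192, seed = 2)
  expect_equal(resize_slice(s192, c(192, 192))$pixels, s192$pixels)
  const <- slice_image(matrix(1234, 64, 64), "raw")
  up <- resize_slice(const, c(192, 192))
  expect_equal(unique(as.vector(up$pixels)), 1234)
  expect_error(resize_slice(s, c(0, 10)), "positive")
})

test_that("patient split is deterministic, disjoint and exhaustive", {
  samples <- unlist(lapply(1:8, function(p) {
    lapply(0:1, function(k) {
      a <- rand_raw_slice(4)
      paired_sample(a, rand_raw_slice(4), patient_id = sprintf("P%02d", p),
                    slice_index = k)
    })
  }), recursive = FALSE)
  sp1 <- split_by_patient(samples, 6, 2, seed = 11)
  sp2 <- split_by_patient(samples, 6, 2, seed = 11)
  expect_identical(sp1, sp2)
  expect_length(sp1$train_patients, 6)
  expect_length(sp1$test_patients, 2)
  expect_length(intersect(sp1$train_patients, sp1$test_patients), 0)
  expect_error(split_by_patient(samples, 7, 2, seed = 1), "only 8")

  # membership property over many seeds: every slice's patient is in exactly
  # one partition, and no patient straddles both
  for (seed in 1:100) {
    sp <- split_by_patient(samples, 5, 3, seed = seed)
    for (s in samples) {
      in_train <- s$patient_id %in% sp$train_patients
      in_test <- s$patient_id %in% sp$test_patients
      expect_true(xor(in_train, in_test))
    }
  }
})

test_that("split manifests round-trip through the two-column text format", {
  samples <- lapply(1:5, function(p) {
    a <- rand_raw_slice(4)
    paired_sample(a, rand_raw_slice(4), patient_id = paste0("Q", p), slice_index = 0)
  })
  sp <- split_by_patient(samples, 4, 1, seed = 3)
  f <- tempfile()
  write_split(sp, f)
  expect_identical(read_split(f), sp)
})
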