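#' Load a volume as an ordered list of slices
#'
#' Reads either a 3-D NIfTI volume (axial slices taken along the third axis)
#' or a directory of 16-bit grayscale PNG slices in lexicographic filename
#' order. All slices are returned in raw intensity space on the
#' \eqn{[0, 4095]} dynamic range.
#'
#' @param path path to a `.nii`/`.nii.gz` file or a directory of PNGs.
#' @param format `"nifti"` or `"png_stack"`.
#' @return List of [slice_image] objects, one per axial slice, order
#'   preserved.
#' @seealso [save_volume()] for the inverse operation.
#' @export
load_volume <- function(path, format = c("nifti", "png_stack")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("path not found: '%s'", path), call. = FALSE)
  if (format == "nifti") {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop(sprintf("unsupported format: expected a 3-D volume, got %d dimensions",
                   length(dim(arr))), call. = FALSE)
    check_raw_range(arr, path)
    lapply(seq_len(dim(arr)[3]), function(k) slice_image(arr[, , k], "raw"))
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("no PNG files found under '%s'", path), call. = FALSE)
    lapply(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) != 2L)
        stop(sprintf("unsupported format: '%s' is not single-channel grayscale", f),
             call. = FALSE)
      raw <- round(px * 65535)
      check_raw_range(raw, f)
      slice_image(raw, "raw")
    })
  }
}

check_raw_range <- function(x, origin) {
  if (any(!is.finite(x)))
    stop(sprintf("non-finite intensities in '%s'", origin), call. = FALSE)
  rng <- range(x)
  if (rng[1] < 0)
    stop(sprintf("negative intensities in '%s' (range [%g, %g])",
                 origin, rng[1], rng[2]), call. = FALSE)
  if (rng[2] > RAW_MAX)
    stop(sprintf("intensities in '%s' exceed the %d dynamic range (range [%g, %g])",
                 origin, RAW_MAX, rng[1], rng[2]), call. = FALSE)
  invisible(TRUE)
}

#' Save a slice stack as a volume
#'
#' Writes slices either as one 3-D NIfTI volume or as a directory of 16-bit
#' grayscale PNGs named `<patient>_<slice>.png` (slice index zero-padded to
#' four digits). PNG output stores rounded raw intensities losslessly;
#' NIfTI output stores floating-point values.
#'
#' @param slices list of [slice_image] objects in raw space.
#' @param path output file (NIfTI) or directory (PNG stack).
#' @param format `"nifti"` or `"png_stack"`.
#' @param patient_id filename prefix used for the PNG stack.
#' @return `path`, invisibly.
#' @export
save_volume <- function(slices, path, format = c("nifti", "png_stack"),
                        patient_id = "patient") {
  format <- match.arg(format)
  stopifnot(length(slices) > 0)
  for (s in slices) stopifnot(is_slice_image(s))
  if (format == "nifti") {
    arr <- array(0, c(dim(slices[[1]]$pixels), length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(slices)) {
      px <- round(slices[[k]]$pixels)
      storage.mode(px) <- "integer"
      write_png16(file.path(path, sprintf("%s_%04d.png", patient_id, k - 1L)), px)
    }
  }
  invisible(path)
}

#' Resize a slice with bilinear interpolation
#'
#' Resamples to the network resolution (the training pipeline uses 192×192).
#' Interpolated values are clipped back to the valid range of the slice's
#' intensity space; a constant slice resizes to the same constant.
#'
#' @param img a [slice_image].
#' @param target integer vector `c(rows, cols)`.
#' @return A [slice_image] of size `target` in the same intensity space.
#' @export
resize_slice <- function(img, target = c(192L, 192L)) {
  img <- as_slice_image(img)
  target <- as.integer(target)
  if (length(target) != 2 || any(is.na(target)) || any(target <= 0))
    stop("`target` must be two positive integers (rows, cols)", call. = FALSE)
  if (identical(dim(img$pixels), target)) return(img)
  # EBImage stores images x-by-y, so transpose in and out
  res <- EBImage::resize(EBImage::Image(t(img$pixels)),
                         w = target[2], h = target[1], filter = "bilinear")
  px <- t(EBImage::imageData(res))
  px <- switch(img$intensity_space,
               raw = pmin(pmax(px, 0), RAW_MAX),
               zscore = px,
               pmin(pmax(px, 1e-12), 1 - 1e-12))
  slice_image(px, img$intensity_space)
}

#' Patient-wise train/test split
#'
#' Randomly partitions patients (never slices) into disjoint train and test
#' sets, mirroring a patient-level 70/10 split. Deterministic for a given
#' seed.
#'
#' @param samples list of [paired_sample] objects.
#' @param n_train,n_test number of patients per partition.
#' @param seed integer RNG seed.
#' @return An object of class `dataset_split` with character vectors
#'   `train_patients` and `test_patients`.
#' @export
split_by_patient <- function(samples, n_train, n_test, seed) {
  ids <- sort(unique(vapply(samples, function(s) s$patient_id, character(1))))
  if (n_train + n_test > length(ids))
    stop(sprintf("requested %d + %d patients but only %d are present",
                 n_train, n_test, length(ids)), call. = FALSE)
  perm <- with_seed(seed, sample(ids))
  structure(list(train_patients = sort(perm[seq_len(n_train)]),
                 test_patients = sort(perm[n_train + seq_len(n_test)])),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d test patients>\n",
              length(x$train_patients), length(x$test_patients)))
  invisible(x)
}

#' Select the samples belonging to one partition
#'
#' @param samples list of [paired_sample] objects.
#' @param split a `dataset_split` from [split_by_patient()].
#' @param partition `"train"` or `"test"`.
#' @return The subset of `samples` whose patient is in the partition.
#' @export
split_samples <- function(samples, split, partition = c("train", "test")) {
  partition <- match.arg(partition)
  keep <- if (partition == "train") split$train_patients else split$test_patients
  Filter(function(s) s$patient_id %in% keep, samples)
}

#' Write / read a split manifest
#'
#' The manifest is a two-column whitespace-delimited text file
#' (`patient_id partition`).
#'
#' @param split a `dataset_split`.
#' @param path manifest file path.
#' @return `path` (write) or a `dataset_split` (read).
#' @export
write_split <- function(split, path) {
  df <- rbind(data.frame(patient_id = split$train_patients, partition = "train"),
              data.frame(patient_id = split$test_patients, partition = "test"))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, col.names = c("patient_id", "partition"),
                          colClasses = "character")
  structure(list(train_patients = sort(df$patient_id[df$partition == "train"]),
                 test_patients = sort(df$patient_id[df$partition == "test"])),
            class = "dataset_split")
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
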