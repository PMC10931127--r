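#' Single-channel 2-D MRI slice
#'
#' A `slice_image` wraps a numeric matrix of pixel intensities together with
#' an intensity-space tag. Raw slices carry scanner intensities on the
#' \eqn{[0, 4095]} dynamic range; `"sigmoid"` and `"tanh"` slices hold
#' per-patient normalized values in \eqn{(0, 1)}; `"zscore"` slices are
#' unbounded standardized intensities. Pixels are indexed `(row i, column j)`,
#' with `i` increasing downward.
#'
#' @param pixels numeric matrix of intensities.
#' @param intensity_space one of `"raw"`, `"zscore"`, `"sigmoid"`, `"tanh"`.
#' @return An object of class `slice_image` with fields `pixels` and
#'   `intensity_space`.
#' @examples
#' img <- slice_image(matrix(0:3, 2, 2), "raw")
#' dim(img$pixels)
#' @export
slice_image <- function(pixels, intensity_space = c("raw", "zscore", "sigmoid", "tanh")) {
  intensity_space <- match.arg(intensity_space)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)))
    stop("slice contains non-finite pixel values", call. = FALSE)
  if (intensity_space == "raw") {
    rng <- range(pixels)
    if (rng[1] < 0 || rng[2] > RAW_MAX)
      stop(sprintf("raw intensities must lie in [0, %d]; observed range [%g, %g]",
                   RAW_MAX, rng[1], rng[2]), call. = FALSE)
  } else if (intensity_space %in% c("sigmoid", "tanh")) {
    rng <- range(pixels)
    if (rng[1] <= 0 || rng[2] >= 1)
      stop(sprintf("%s-normalized intensities must lie strictly inside (0, 1); observed range [%g, %g]",
                   intensity_space, rng[1], rng[2]), call. = FALSE)
  }
  structure(list(pixels = pixels, intensity_space = intensity_space),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image %dx%d, %s space, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$intensity_space,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.slice_image <- function(x) dim(x$pixels)

is_slice_image <- function(x) inherits(x, "slice_image")

#' Coerce a matrix to a slice image
#'
#' @param x a `slice_image` (returned unchanged) or numeric matrix.
#' @param intensity_space intensity space assumed when `x` is a bare matrix.
#' @return A `slice_image`.
#' @export
as_slice_image <- function(x, intensity_space = "raw") {
  if (is_slice_image(x)) return(x)
  slice_image(x, intensity_space)
}

#' Aligned (T1-w, T2-w, T1C) slice triplet
#'
#' Bundles co-registered slices of one patient at one slice position. The
#' ground-truth contrast-enhanced slice `t1c` may be absent at inference
#' time. All present slices must agree in size and intensity space.
#'
#' @param t1,t2 `slice_image` objects (pre-contrast modalities).
#' @param t1c `slice_image` or `NULL` (contrast-enhanced ground truth).
#' @param patient_id character scalar identifying the patient.
#' @param slice_index integer slice position within the volume (0-based).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(t1, t2, t1c = NULL, patient_id, slice_index) {
  stopifnot(is_slice_image(t1), is_slice_image(t2))
  slices <- list(t1 = t1, t2 = t2)
  if (!is.null(t1c)) {
    stopifnot(is_slice_image(t1c))
    slices$t1c <- t1c
  }
  d <- dim(t1$pixels)
  for (nm in names(slices)) {
    s <- slices[[nm]]
    if (!identical(dim(s$pixels), d))
      stop(sprintf("slice '%s' has dims %dx%d; expected %dx%d",
                   nm, nrow(s$pixels), ncol(s$pixels), d[1], d[2]), call. = FALSE)
    if (!identical(s$intensity_space, t1$intensity_space))
      stop(sprintf("slice '%s' is in %s space; expected %s",
                   nm, s$intensity_space, t1$intensity_space), call. = FALSE)
  }
  if (!(is.character(patient_id) && length(patient_id) == 1))
    stop("`patient_id` must be a single string", call. = FALSE)
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0)
    stop("`slice_index` must be a non-negative integer", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, t1c = if (!is.null(t1c)) t1c,
                 patient_id = patient_id, slice_index = slice_index),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample %s #%d, %dx%d, %s space%s>\n",
              x$patient_id, x$slice_index, nrow(x$t1$pixels), ncol(x$t1$pixels),
              x$t1$intensity_space,
              if (is.null(x$t1c)) ", no ground truth" else ""))
  invisible(x)
}
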