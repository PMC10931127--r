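#' Per-patient intensity normalization parameters
#'
#' Mean and standard deviation of one patient volume (one modality), plus the
#' normalization method they parameterize. Fitted over all voxels of the
#' volume jointly, never per slice, so that every slice of a patient is
#' transformed consistently and the transform can be inverted exactly.
#'
#' @param mean volume mean, raw intensity units.
#' @param std volume standard deviation, raw intensity units; must be > 0.
#' @param method `"zscore"`, `"sigmoid"`, or `"tanh"`.
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(mean, std, method = c("zscore", "sigmoid", "tanh")) {
  method <- match.arg(method)
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean),
            is.numeric(std), length(std) == 1, is.finite(std))
  if (std <= 0) stop("`std` must be strictly positive", call. = FALSE)
  structure(list(mean = as.numeric(mean), std = as.numeric(std), method = method),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf("<norm_params %s: mean=%.4g sd=%.4g>\n", x$method, x$mean, x$std))
  invisible(x)
}

#' Fit normalization parameters on a patient volume
#'
#' Computes the volume mean and standard deviation (population form,
#' divide-by-N) over all voxels of all slices jointly. Parameters are
#' fitted per patient and per modality.
#'
#' @param volume non-empty list of raw-space [slice_image] objects.
#' @param method normalization method the parameters will drive.
#' @return A [norm_params] object.
#' @export
fit_norm_params <- function(volume, method = c("zscore", "sigmoid", "tanh")) {
  method <- match.arg(method)
  if (length(volume) == 0) stop("`volume` must be non-empty", call. = FALSE)
  vox <- unlist(lapply(volume, function(s) {
    s <- as_slice_image(s)
    if (s$intensity_space != "raw")
      stop("normalization parameters are fitted on raw-space volumes", call. = FALSE)
    as.vector(s$pixels)
  }))
  mu <- mean(vox)
  sdv <- sqrt(mean((vox - mu)^2))
  if (!is.finite(sdv) || sdv <= 0)
    stop("degenerate volume: zero intensity variance, cannot normalize", call. = FALSE)
  norm_params(mu, sdv, method)
}

#' Normalize a raw slice
#'
#' Applies the per-patient transform selected by `p$method` to raw
#' intensities `x` with volume statistics \eqn{\mu_x, \delta_x}:
#' z-score \eqn{z = (x-\mu_x)/\delta_x}; sigmoid \eqn{1/(1+e^{-z})};
#' tanh \eqn{\tfrac12(\tanh(0.01\,z)+1)}. The sigmoid and tanh maps land
#' strictly inside \eqn{(0,1)}; all three are strictly increasing in `x`.
#'
#' @param img raw-space [slice_image].
#' @param p [norm_params].
#' @return A [slice_image] whose `intensity_space` equals `p$method`.
#' @export
normalize_slice <- function(img, p) {
  img <- as_slice_image(img)
  stopifnot(inherits(p, "norm_params"))
  if (img$intensity_space != "raw")
    stop(sprintf("expected a raw-space slice, got '%s'", img$intensity_space),
         call. = FALSE)
  z <- (img$pixels - p$mean) / p$std
  px <- switch(p$method,
               zscore = z,
               sigmoid = 1 / (1 + exp(-z)),
               tanh = 0.5 * (tanh(0.01 * z) + 1))
  slice_image(px, p$method)
}

#' Invert normalization back to raw intensities
#'
#' Exact algebraic inverse of [normalize_slice()]. For the bounded maps,
#' values are clamped to \eqn{[\delta, 1-\delta]} with \eqn{\delta=10^{-6}}
#' before inversion (with a warning) so saturated pixels do not produce
#' infinite logits.
#'
#' The result is clamped to the raw \eqn{[0, 4095]} dynamic range (network
#' output can overshoot slightly).
#'
#' @param img normalized [slice_image] whose space matches `p$method`.
#' @param p [norm_params].
#' @return A raw-space [slice_image].
#' @export
denormalize_slice <- function(img, p) {
  img <- as_slice_image(img, intensity_space = p$method)
  stopifnot(inherits(p, "norm_params"))
  if (img$intensity_space != p$method)
    stop(sprintf("slice is in '%s' space but params are for '%s'",
                 img$intensity_space, p$method), call. = FALSE)
  delta <- 1e-6
  v <- img$pixels
  if (p$method %in% c("sigmoid", "tanh")) {
    n_sat <- sum(v < delta | v > 1 - delta)
    if (n_sat > 0) {
      warning(sprintf("%d saturated pixel(s) clamped to (%g, %g) before inversion",
                      n_sat, delta, 1 - delta), call. = FALSE)
      v <- pmin(pmax(v, delta), 1 - delta)
    }
  }
  z <- switch(p$method,
              zscore = v,
              sigmoid = log(v / (1 - v)),
              tanh = atanh(2 * v - 1) / 0.01)
  raw <- pmin(pmax(p$mean + p$std * z, 0), RAW_MAX)
  slice_image(raw, "raw")
}

#' Serialize / restore normalization parameters
#'
#' Sidecar JSON files let inference invert a patient's normalization exactly.
#'
#' @param p [norm_params] (write) / `path` file path.
#' @param path file path for the JSON sidecar.
#' @return `path` (write) or a [norm_params] (read).
#' @export
write_norm_params <- function(p, path) {
  stopifnot(inherits(p, "norm_params"))
  jsonlite::write_json(list(mean = p$mean, std = p$std, method = p$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm_params(x$mean, x$std, x$method)
}
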