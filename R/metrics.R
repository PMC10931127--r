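#' Similarity metrics between a synthetic and a ground-truth slice
#'
#' Mean absolute error \eqn{\frac1N\sum|y-g|}, mean square error
#' \eqn{\frac1N\sum(y-g)^2}, and the global structural similarity index
#' computed from whole-slice means, variances and covariance with
#' stabilizers \eqn{c_1=(k_1 L)^2}, \eqn{c_2=(k_2 L)^2}. Defaults
#' \eqn{L=4095}, \eqn{k_1=0.01}, \eqn{k_2=0.03} match the raw MRI dynamic
#' range; population (divide-by-N) moments are used.
#'
#' @param y,g equally sized slices in the same intensity space.
#' @param L dynamic range (for [img_ssim()]).
#' @param k1,k2 SSIM stabilizer constants.
#' @return Scalar metric value.
#' @export
img_mae <- function(y, g) {
  check_pair(y, g)
  mean(abs(as_pixels(y) - as_pixels(g)))
}

#' @rdname img_mae
#' @export
img_mse <- function(y, g) {
  check_pair(y, g)
  mean((as_pixels(y) - as_pixels(g))^2)
}

#' @rdname img_mae
#' @export
img_ssim <- function(y, g, L = RAW_MAX, k1 = 0.01, k2 = 0.03) {
  check_pair(y, g)
  yv <- as.vector(as_pixels(y)); gv <- as.vector(as_pixels(g))
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  my <- mean(yv); mg <- mean(gv)
  vy <- mean((yv - my)^2); vg <- mean((gv - mg)^2)
  cov <- mean((yv - my) * (gv - mg))
  ((2 * my * mg + c1) * (2 * cov + c2)) / ((my^2 + mg^2 + c1) * (vy + vg + c2))
}

check_pair <- function(y, g) {
  yp <- as_pixels(y); gp <- as_pixels(g)
  if (!identical(dim(yp), dim(gp)))
    stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                 nrow(yp), ncol(yp), nrow(gp), ncol(gp)), call. = FALSE)
  if (is_slice_image(y) && is_slice_image(g) &&
      !identical(y$intensity_space, g$intensity_space))
    stop(sprintf("intensity-space mismatch: %s vs %s",
                 y$intensity_space, g$intensity_space), call. = FALSE)
  invisible(TRUE)
}

img_mean_checked <- function(m) {
  mu <- mean(m)
  if (!is.finite(mu) || mu <= 0)
    stop("degenerate image: mean intensity must be positive", call. = FALSE)
  mu
}

#' Texture metrics per mean intensity
#'
#' Four scale-invariant roughness/sharpness measures. Each divides by the
#' mean intensity \eqn{\mu} so that multiplying the image by a positive
#' constant leaves the value unchanged — texture is intrinsic to the image,
#' not to its brightness. Smaller values mean a smoother image.
#'
#' * `img_tmsvpmi()`: mean per-pixel Euclidean magnitude of the forward-
#'   difference gradient, \eqn{\frac1\mu\frac1N\sum_p\sqrt{(\nabla_x)^2 +
#'   (\nabla_y)^2}} (total mean square variation per mean intensity).
#' * `img_tavpmi()`: mean L1 gradient magnitude
#'   \eqn{\frac1\mu\frac1N\sum_p(|\nabla_x| + |\nabla_y|)} (total absolute
#'   variation per mean intensity); always \eqn{\ge} `img_tmsvpmi`.
#' * `img_tfpmi()`: Tenengrad — mean Sobel gradient magnitude over the
#'   valid interior (one-pixel border excluded), per mean intensity.
#' * `img_vfpmi()`: root-mean-square deviation from the mean, per mean
#'   intensity (the coefficient of variation).
#'
#' Forward-difference gradients use the same boundary convention as
#' [forward_gradient()] (zero at the last row/column).
#'
#' @param img a [slice_image] or numeric matrix with positive mean.
#' @return Scalar metric value (\eqn{\ge 0}; 0 for a constant image).
#' @export
img_tmsvpmi <- function(img) {
  m <- as_pixels(img)
  mu <- img_mean_checked(m)
  f <- forward_gradient(m)
  mean(sqrt(f$dx_down^2 + f$dx_right^2)) / mu
}

#' @rdname img_tmsvpmi
#' @export
img_tavpmi <- function(img) {
  m <- as_pixels(img)
  mu <- img_mean_checked(m)
  f <- forward_gradient(m)
  mean(abs(f$dx_down) + abs(f$dx_right)) / mu
}

#' @rdname img_tmsvpmi
#' @export
img_tfpmi <- function(img) {
  m <- as_pixels(img)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3)
    stop(sprintf("image must be at least 3x3 for the Sobel operator, got %dx%d",
                 nr, nc), call. = FALSE)
  mu <- img_mean_checked(m)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  gx <- (m[i - 1, j + 1] + 2 * m[i, j + 1] + m[i + 1, j + 1]) -
        (m[i - 1, j - 1] + 2 * m[i, j - 1] + m[i + 1, j - 1])
  gy <- (m[i - 1, j - 1] + 2 * m[i - 1, j] + m[i - 1, j + 1]) -
        (m[i + 1, j - 1] + 2 * m[i + 1, j] + m[i + 1, j + 1])
  mean(sqrt(gx^2 + gy^2)) / mu
}

#' @rdname img_tmsvpmi
#' @export
img_vfpmi <- function(img) {
  m <- as_pixels(img)
  mu <- img_mean_checked(m)
  sqrt(mean((m - mu)^2)) / mu
}

#' All four texture metrics of one slice
#'
#' @param img a [slice_image] or matrix.
#' @return Named list with `tmsvpmi`, `tavpmi`, `tfpmi`, `vfpmi`.
#' @export
texture_report <- function(img) {
  list(tmsvpmi = img_tmsvpmi(img), tavpmi = img_tavpmi(img),
       tfpmi = img_tfpmi(img), vfpmi = img_vfpmi(img))
}

#' Modality-ablation ratios
#'
#' Relative degradation of a single-modality model against the dual-modality
#' reference: `(single - dual) / dual`, componentwise for MAE, MSE, and
#' SSIM. Zero means the single-modality model matched the dual one.
#'
#' @param single,dual named lists or one-row data frames holding `mae`,
#'   `mse`, `ssim`.
#' @return Named list with `maer`, `mser`, `ssimr`.
#' @export
metric_ratios <- function(single, dual) {
  out <- list()
  for (nm in c("mae", "mse", "ssim")) {
    dv <- as.numeric(dual[[nm]]); sv <- as.numeric(single[[nm]])
    if (!is.finite(dv) || dv == 0)
      stop(sprintf("dual-modality %s is zero; ratio undefined", toupper(nm)),
           call. = FALSE)
    out[[paste0(nm, "r")]] <- (sv - dv) / dv
  }
  out
}

#' Slice-level evaluation table
#'
#' One row per slice pair: similarity of prediction vs truth (MAE, MSE,
#' SSIM) plus the four texture metrics of the prediction. Mirrors the
#' layout the `evaluate` CLI command writes as CSV.
#'
#' @param pred,truth equally long lists of raw-space slices.
#' @return A data frame with columns `mae`, `mse`, `ssim`, `tmsvpmi`,
#'   `tavpmi`, `tfpmi`, `vfpmi`.
#' @export
evaluate_pairs <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  rows <- lapply(seq_along(pred), function(k) {
    tx <- texture_report(pred[[k]])
    data.frame(mae = img_mae(pred[[k]], truth[[k]]),
               mse = img_mse(pred[[k]], truth[[k]]),
               ssim = img_ssim(pred[[k]], truth[[k]]),
               tmsvpmi = tx$tmsvpmi, tavpmi = tx$tavpmi,
               tfpmi = tx$tfpmi, vfpmi = tx$vfpmi)
  })
  do.call(rbind, rows)
}

#' Aggregate per-slice metrics to mean and SD
#'
#' Sample mean and sample standard deviation of every metric column,
#' matching the `value ± value` reporting convention.
#'
#' @param df data frame of per-slice metric values (at least 2 rows).
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(df) {
  if (nrow(df) < 2)
    stop("need at least 2 slices to report a standard deviation", call. = FALSE)
  data.frame(metric = names(df),
             mean = vapply(df, mean, numeric(1)),
             sd = vapply(df, stats::sd, numeric(1)),
             row.names = NULL)
}
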