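#' Loss weights for the generator objective
#'
#' Relative weight of the pixelwise normalized-gradient shape term and the
#' LSGAN contrast term. The study grid uses ratios 10:1, 1:1 and 1:10.
#'
#' @param lambda_gradient,lambda_gan non-negative weights, not both zero.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_gradient = 1, lambda_gan = 1) {
  stopifnot(is.numeric(lambda_gradient), is.numeric(lambda_gan),
            lambda_gradient >= 0, lambda_gan >= 0)
  if (lambda_gradient == 0 && lambda_gan == 0)
    stop("loss_weights: lambda_gradient and lambda_gan must not both be zero",
         call. = FALSE)
  structure(list(lambda_gradient = lambda_gradient, lambda_gan = lambda_gan),
            class = "loss_weights")
}

as_pixels <- function(x) {
  if (is_slice_image(x)) x$pixels else if (is.matrix(x)) x else
    stop("expected a slice_image or matrix", call. = FALSE)
}

#' Forward-difference gradient field
#'
#' Per-pixel forward differences
#' \eqn{\nabla x_{i,j} = (x_{i+1,j}-x_{i,j},\; x_{i,j+1}-x_{i,j})}.
#' Differences that would reach outside the image are zero, so the last row
#' of the down component and the last column of the right component vanish.
#'
#' @param img [slice_image] or matrix, at least 2×2.
#' @return A `gradient_field` with matrices `dx_down` and `dx_right`.
#' @export
forward_gradient <- function(img) {
  m <- as_pixels(img)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2)
    stop(sprintf("degenerate input: need at least 2x2 pixels, got %dx%d", nr, nc),
         call. = FALSE)
  dd <- rbind(m[-1, , drop = FALSE] - m[-nr, , drop = FALSE], rep(0, nc))
  dr <- cbind(m[, -1, drop = FALSE] - m[, -nc, drop = FALSE], rep(0, nr))
  structure(list(dx_down = dd, dx_right = dr), class = "gradient_field")
}

#' Normalize a gradient field to (near-)unit vectors
#'
#' Divides each pixel's gradient vector by its Euclidean magnitude plus a
#' small stabilizer `eps`, so flat regions map to the zero vector instead of
#' dividing by zero and all magnitudes stay in \eqn{[0, 1)}.
#'
#' @param field a `gradient_field` from [forward_gradient()].
#' @param eps positive stabilizing constant (default `1e-8`).
#' @return A normalized `gradient_field`.
#' @export
normalized_gradient <- function(field, eps = 1e-8) {
  stopifnot(inherits(field, "gradient_field"))
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0)
    stop("`eps` must be a positive scalar", call. = FALSE)
  s <- sqrt(field$dx_down^2 + field$dx_right^2)
  structure(list(dx_down = field$dx_down / (s + eps),
                 dx_right = field$dx_right / (s + eps)),
            class = "gradient_field")
}

#' Pixelwise normalized-gradient shape loss
#'
#' Measures how well the output's edge geometry aligns with the target's:
#' the negative mean over pixels of the squared dot product of the two
#' normalized gradients,
#' \eqn{-\frac1N\sum_p (n_{\mathrm{out}}\cdot n_{\mathrm{target}})^2}.
#' Squaring makes gradients pointing in the same or opposite direction
#' equally good, so the loss is blind to contrast polarity; the value always
#' lies in \eqn{[-1, 0]}. The mean (rather than sum) reduction keeps the
#' loss-weight ratios resolution independent.
#'
#' @param output,target equally sized slices (any intensity space, compared
#'   as-is).
#' @param eps gradient-normalization stabilizer.
#' @return Scalar loss in \eqn{[-1, 0]}.
#' @export
pixelwise_gradient_loss <- function(output, target, eps = 1e-8) {
  yo <- as_pixels(output); yt <- as_pixels(target)
  if (!identical(dim(yo), dim(yt)))
    stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                 nrow(yo), ncol(yo), nrow(yt), ncol(yt)), call. = FALSE)
  no <- normalized_gradient(forward_gradient(yo), eps)
  nt <- normalized_gradient(forward_gradient(yt), eps)
  dot <- no$dx_down * nt$dx_down + no$dx_right * nt$dx_right
  -mean(dot^2)
}

# Analytic d(loss)/d(output pixels) for the training loop.
pg_loss_input_grad <- function(output, target, eps = 1e-8) {
  yo <- as_pixels(output); yt <- as_pixels(target)
  N <- length(yo)
  go <- forward_gradient(yo)
  nt <- normalized_gradient(forward_gradient(yt), eps)
  s <- sqrt(go$dx_down^2 + go$dx_right^2)
  se <- s + eps
  no_d <- go$dx_down / se
  no_r <- go$dx_right / se
  dot <- no_d * nt$dx_down + no_r * nt$dx_right
  # dL/dn = -(2/N) * dot * n_target
  dn_d <- -(2 / N) * dot * nt$dx_down
  dn_r <- -(2 / N) * dot * nt$dx_right
  # through n = g/(s+eps): J^T v = v/(s+eps) - g * (g.v)/(s*(s+eps)^2)
  s_safe <- pmax(s, 1e-300)
  gv <- go$dx_down * dn_d + go$dx_right * dn_r
  dg_d <- dn_d / se - go$dx_down * gv / (s_safe * se^2)
  dg_r <- dn_r / se - go$dx_right * gv / (s_safe * se^2)
  # adjoint of the forward differences
  nr <- nrow(yo); nc <- ncol(yo)
  dy <- -dg_d
  dy[-1, ] <- dy[-1, , drop = FALSE] + dg_d[-nr, , drop = FALSE]
  dy <- dy - dg_r
  dy[, -1] <- dy[, -1, drop = FALSE] + dg_r[, -nc, drop = FALSE]
  dy
}

#' Least-squares GAN losses
#'
#' LSGAN objectives with target labels 1 (real) and 0 (fake):
#' discriminator \eqn{\tfrac12\mathrm{mean}((D_{real}-1)^2) +
#' \tfrac12\mathrm{mean}(D_{fake}^2)}; generator
#' \eqn{\tfrac12\mathrm{mean}((D_{fake}-1)^2)}. Scores are patch-score
#' grids (any numeric array).
#'
#' @param d_real,d_fake numeric arrays of patch scores.
#' @return Scalar loss.
#' @export
lsgan_d_loss <- function(d_real, d_fake) {
  stopifnot(all(is.finite(d_real)), all(is.finite(d_fake)))
  0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2)
}

#' @rdname lsgan_d_loss
#' @export
lsgan_g_loss <- function(d_fake) {
  stopifnot(all(is.finite(d_fake)))
  0.5 * mean((d_fake - 1)^2)
}

#' R1 gradient penalty of a discriminator at real samples
#'
#' \eqn{\frac{\gamma}{2}\,\mathbb{E}_{x\sim real}\,\lVert\nabla_x
#' \bar D(x)\rVert^2}, where \eqn{\bar D} is the mean patch score of a
#' sample. Penalizing the input gradient at real data keeps the adversarial
#' signal smooth and stabilizes training.
#'
#' `disc` may be a discriminator built by [build_discriminator()] (the
#' gradient is obtained by backpropagation) or any plain R function mapping
#' an input array to a score grid (the gradient is then measured by central
#' finite differences; intended for analysis and testing).
#'
#' @param disc discriminator model or score function.
#' @param real_batch list of input arrays (or of [paired_sample] objects in
#'   normalized space when `disc` is a built discriminator).
#' @param gamma penalty coefficient (default 10).
#' @param fd_step step for the finite-difference route.
#' @return Scalar penalty \eqn{\ge 0}.
#' @export
gradient_penalty <- function(disc, real_batch, gamma = 10, fd_step = 1e-4) {
  stopifnot(length(real_batch) >= 1, gamma >= 0)
  if (inherits(disc, "vce_network")) {
    grads <- disc_input_grads(disc, real_batch)
    pen <- vapply(grads, function(g) sum(g^2), numeric(1))
    return(gamma / 2 * mean(pen))
  }
  if (!is.function(disc))
    stop("`disc` must be a built discriminator or a score function", call. = FALSE)
  pen <- vapply(real_batch, function(x) {
    x <- if (is_slice_image(x)) x$pixels else x
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + fd_step
      xm[i] <- xm[i] - fd_step
      g[i] <- (mean(disc(xp)) - mean(disc(xm))) / (2 * fd_step)
    }
    sum(g^2)
  }, numeric(1))
  gamma / 2 * mean(pen)
}

#' Weighted generator objective
#'
#' `lambda_gradient * pixelwise_gradient_loss + lambda_gan * lsgan_g_loss`.
#'
#' @param output,target slices passed to [pixelwise_gradient_loss()].
#' @param d_fake discriminator scores of the output.
#' @param weights a [loss_weights] object.
#' @param eps gradient-normalization stabilizer.
#' @return Scalar objective value.
#' @export
generator_objective <- function(output, target, d_fake, weights = loss_weights(),
                                eps = 1e-8) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$lambda_gradient * pixelwise_gradient_loss(output, target, eps) +
    weights$lambda_gan * lsgan_g_loss(d_fake)
}
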