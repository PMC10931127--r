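# Small fixtures built in code.

rand_raw_slice <- function(n = 8, m = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slice_image(matrix(runif(n * m, 0, 4095), n, m), "raw")
}

tiny_phantom_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 2L, slices_per_patient = 3L, size = c(32L, 32L), seed = 42L),
    list(...))
  do.call(phantom_config, args)
}

tiny_training_cfg <- function(...) {
  args <- utils::modifyList(
    list(iterations = 20L, batch_size = 2L, gen_base_width = 4L, gen_depth = 2L,
         disc_base_width = 4L, disc_depth = 2L, seed = 1L),
    list(...))
  do.call(training_config, args)
}

# brute-force scalar-loop oracles, deliberately independent of the package
# implementations
oracle_mae <- function(y, g) {
  acc <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y)))
    acc <- acc + abs(y[i, j] - g[i, j])
  acc / length(y)
}

oracle_mse <- function(y, g) {
  acc <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y)))
    acc <- acc + (y[i, j] - g[i, j])^2
  acc / length(y)
}

oracle_forward_diff <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dd <- matrix(0, nr, nc); dr <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) dd[i, j] <- m[i + 1, j] - m[i, j]
    if (j < nc) dr[i, j] <- m[i, j + 1] - m[i, j]
  }
  list(dd = dd, dr = dr)
}

oracle_tmsvpmi <- function(m) {
  f <- oracle_forward_diff(m)
  acc <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    acc <- acc + sqrt(f$dd[i, j]^2 + f$dr[i, j]^2)
  acc / length(m) / mean(m)
}

oracle_tavpmi <- function(m) {
  f <- oracle_forward_diff(m)
  sum(abs(f$dd) + abs(f$dr)) / length(m) / mean(m)
}

oracle_tfpmi <- function(m) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- rbind(c(1, 2, 1), c(0, 0, 0), c(-1, -2, -1))
  nr <- nrow(m); nc <- ncol(m)
  acc <- 0; n <- 0
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      gx <- gx + kx[a + 2, b + 2] * m[i + a, j + b]
      gy <- gy + ky[a + 2, b + 2] * m[i + a, j + b]
    }
    acc <- acc + sqrt(gx^2 + gy^2)
    n <- n + 1
  }
  acc / n / mean(m)
}

oracle_vfpmi <- function(m) {
  mu <- mean(m)
  sqrt(mean((m - mu)^2)) / mu
}

oracle_pg_loss <- function(a, b, eps = 1e-12) {
  fa <- oracle_forward_diff(a); fb <- oracle_forward_diff(b)
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    sa <- sqrt(fa$dd[i, j]^2 + fa$dr[i, j]^2)
    sb <- sqrt(fb$dd[i, j]^2 + fb$dr[i, j]^2)
    na <- c(fa$dd[i, j], fa$dr[i, j]) / (sa + eps)
    nb <- c(fb$dd[i, j], fb$dr[i, j]) / (sb + eps)
    acc <- acc + sum(na * nb)^2
  }
  -acc / length(a)
}

mean_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) out <- out + p[di + 1:nr, dj + 1:nc]
  out / 9
}
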