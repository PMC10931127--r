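#' Synthetic head-phantom configuration
#'
#' Generates co-registered (T1-w, T2-w, T1C) slice triplets with the
#' statistical structure the synthesis method assumes: a head-like ellipse
#' partitioned into smooth tissue regions with per-class T1/T2 intensity
#' signatures; a focal "enhancing" lesion visible mainly in T1C; a
#' fine-scale multiplicative texture field shared by all three channels;
#' and independent additive Gaussian noise per channel. The ground-truth
#' T1C is a fixed deterministic mix of BOTH modalities (see
#' [phantom_mix()]), so a single-modality model is information-limited by
#' construction.
#'
#' The default tissue classes are loosely modelled on head tissue contrast
#' (white-matter-, gray-matter-, CSF-, and muscle-like signatures). Two
#' classes deliberately share the same T1 signature while differing in T2,
#' so the ground-truth T1C is provably not a function of T1 alone.
#'
#' @param n_patients,slices_per_patient dataset size.
#' @param size slice dims `c(rows, cols)`, default `c(192, 192)`.
#' @param tissue_classes numeric matrix with columns `t1_mean`, `t2_mean`
#'   (raw units, within \eqn{[0, 4095]}); at least 2 rows.
#' @param enhancement_gain additive T1C intensity of the lesion (raw units).
#' @param noise_sigma SD of the additive Gaussian noise (raw units).
#' @param texture_amplitude relative amplitude of the multiplicative
#'   fine-scale texture field.
#' @param seed integer master seed; each patient derives its own stream
#'   from `(seed, patient_index)`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 10L, slices_per_patient = 10L,
                           size = c(192L, 192L),
                           tissue_classes = default_tissue_classes(),
                           enhancement_gain = 800, noise_sigma = 30,
                           texture_amplitude = 0.05, seed = 1L) {
  size <- as.integer(size)
  tissue_classes <- as.matrix(tissue_classes)
  if (ncol(tissue_classes) != 2)
    stop("`tissue_classes` must have two columns (t1_mean, t2_mean)", call. = FALSE)
  if (nrow(tissue_classes) < 2)
    stop("at least 2 tissue classes are required", call. = FALSE)
  if (any(tissue_classes < 0) || any(tissue_classes > RAW_MAX))
    stop(sprintf("tissue signatures must lie in [0, %d]", RAW_MAX), call. = FALSE)
  stopifnot(n_patients >= 1, slices_per_patient >= 1, all(size >= 16),
            enhancement_gain > 0, noise_sigma >= 0, texture_amplitude >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 size = size, tissue_classes = tissue_classes,
                 enhancement_gain = enhancement_gain,
                 noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_tissue_classes <- function() {
  m <- rbind(white_matter = c(2600, 1400),
             gray_matter  = c(2000, 2200),
             csf          = c(900, 3400),
             lesion_bed   = c(2600, 3000),  # same T1 as white matter, brighter T2
             muscle       = c(1600, 1100))
  colnames(m) <- c("t1_mean", "t2_mean")
  m
}

#' Deterministic dual-modality mixing function of the phantom
#'
#' Ground-truth contrast enhancement of the phantom:
#' `T1C = (a*T1 + b*(4095 - T2)) * head + gain * lesion`, clamped to
#' \eqn{[0, 4095]}. Monotone in T1 and anti-monotone in T2 (fluid is bright
#' on T2 but dark on T1C), so faithful synthesis requires both modalities.
#' The mix is restricted to the head mask so that background air stays
#' dark.
#'
#' @param t1,t2 noise-free T1-w / T2-w signature matrices (raw units).
#' @param head,lesion 0/1 masks.
#' @param gain lesion enhancement gain.
#' @param a,b mixing coefficients.
#' @return Raw-space T1C matrix.
#' @export
phantom_mix <- function(t1, t2, head, lesion, gain, a = 0.5, b = 0.5) {
  pmin(pmax((a * t1 + b * (RAW_MAX - t2)) * head + gain * lesion, 0), RAW_MAX)
}

# Bilinear upsample of a coarse field to H x W (used for smooth tissue maps).
upsample_field <- function(coarse, H, W) {
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(coarse)),
                                       w = W, h = H, filter = "bilinear")))
}

smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]  # replicate borders
  acc <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + 1:nr, dj + 1:nc]
  acc / 9
}

#' Generate all slices of one phantom patient
#'
#' Fully deterministic given `(cfg$seed, patient_index)`: patient anatomy
#' (head geometry, tissue partition, lesion position) is drawn from a
#' per-patient stream, then per-slice fields are derived from it. Every
#' patient has the lesion in at least one slice. Returned samples carry the
#' binary `head_mask` and `lesion_mask` used during construction as
#' attributes, so the deterministic mix can be recomputed and verified.
#'
#' @param cfg a [phantom_config].
#' @param patient_index positive integer.
#' @return List of [paired_sample] objects in raw space.
#' @export
generate_patient <- function(cfg, patient_index) {
  stopifnot(inherits(cfg, "phantom_config"), patient_index >= 1)
  H <- cfg$size[1]; W <- cfg$size[2]
  K <- nrow(cfg$tissue_classes)
  nsl <- cfg$slices_per_patient
  pid <- sprintf("P%03d", patient_index)
  seed_p <- (cfg$seed %% 100003L) * 10007L + patient_index * 7919L

  with_seed(seed_p, {
    cy <- H / 2 + stats::runif(1, -0.03, 0.03) * H
    cx <- W / 2 + stats::runif(1, -0.03, 0.03) * W
    ry0 <- 0.40 * H * stats::runif(1, 0.95, 1.05)
    rx0 <- 0.34 * W * stats::runif(1, 0.95, 1.05)
    base_field <- matrix(stats::rnorm(36), 6, 6)
    # lesion geometry: ellipse inside the head, 1-5% of the head area
    les_ang <- stats::runif(1, 0, 2 * pi)
    les_rad <- stats::runif(1, 0.1, 0.55)
    les_frac <- stats::runif(1, 0.01, 0.05)
    les_aspect <- stats::runif(1, 0.6, 1.6)
    les_slices <- which(stats::runif(nsl) < 0.6)
    if (length(les_slices) == 0) les_slices <- max(1L, nsl %/% 2L)

    ii <- matrix(seq_len(H), H, W)
    jj <- matrix(seq_len(W), H, W, byrow = TRUE)
    samples <- vector("list", nsl)
    for (k in seq_len(nsl)) {
      z <- if (nsl == 1) 0 else (k - (nsl + 1) / 2) / ((nsl + 1) / 2)
      sc <- sqrt(max(0.25, 1 - 0.7 * z^2))
      ry <- ry0 * sc; rx <- rx0 * sc
      head <- ((ii - cy) / ry)^2 + ((jj - cx) / rx)^2 <= 1
      field <- upsample_field(base_field + 0.15 * matrix(stats::rnorm(36), 6, 6),
                              H, W)
      inside <- field[head]
      qs <- stats::quantile(inside, probs = seq_len(K - 1) / K)
      cls <- matrix(0L, H, W)
      cls[head] <- findInterval(inside, qs) + 1L
      t1 <- matrix(0, H, W); t2 <- matrix(0, H, W)
      for (c in seq_len(K)) {
        sel <- cls == c
        t1[sel] <- cfg$tissue_classes[c, 1]
        t2[sel] <- cfg$tissue_classes[c, 2]
      }
      # lesion mask for this slice
      lesion <- matrix(0, H, W)
      if (k %in% les_slices) {
        lcy <- cy + les_rad * ry * sin(les_ang)
        lcx <- cx + les_rad * rx * cos(les_ang)
        head_area <- sum(head)
        lr <- sqrt(les_frac * head_area / pi)
        lry <- lr * sqrt(les_aspect); lrx <- lr / sqrt(les_aspect)
        lesion[((ii - lcy) / lry)^2 + ((jj - lcx) / lrx)^2 <= 1 & head] <- 1
      }
      t2 <- pmin(t2 + 0.2 * cfg$enhancement_gain * lesion, RAW_MAX)
      t1c <- phantom_mix(t1, t2, head, lesion, cfg$enhancement_gain)
      if (cfg$texture_amplitude > 0) {
        zf <- smooth3(matrix(stats::rnorm(H * W), H, W))
        zf <- (zf - mean(zf)) / stats::sd(zf)
        tex <- pmax(1 + cfg$texture_amplitude * zf, 0.05)
        t1 <- t1 * tex; t2 <- t2 * tex; t1c <- t1c * tex
      }
      if (cfg$noise_sigma > 0) {
        t1 <- t1 + stats::rnorm(H * W, sd = cfg$noise_sigma)
        t2 <- t2 + stats::rnorm(H * W, sd = cfg$noise_sigma)
        t1c <- t1c + stats::rnorm(H * W, sd = cfg$noise_sigma)
      }
      clamp <- function(m) pmin(pmax(m, 0), RAW_MAX)
      s <- paired_sample(slice_image(clamp(t1), "raw"),
                         slice_image(clamp(t2), "raw"),
                         slice_image(clamp(t1c), "raw"),
                         patient_id = pid, slice_index = k - 1L)
      attr(s, "head_mask") <- head * 1
      attr(s, "lesion_mask") <- lesion
      samples[[k]] <- s
    }
    samples
  })
}

#' Generate a phantom dataset
#'
#' Concatenates [generate_patient()] over all patients; optionally writes
#' the dataset as 16-bit PNG slice stacks (subdirectories `t1/`, `t2/`,
#' `t1c/`) plus a tab-separated manifest, the same layout the CLI consumes
#' for real data.
#'
#' @param cfg a [phantom_config].
#' @param out_dir optional output directory.
#' @return List with `samples` (list of [paired_sample]) and `manifest`
#'   (data frame: `patient_id`, `slice_index`, `has_lesion`).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  samples <- list()
  rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    ps <- generate_patient(cfg, p)
    for (s in ps) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = s$patient_id, slice_index = s$slice_index,
        has_lesion = sum(attr(s, "lesion_mask")) > 0)
    }
    samples <- c(samples, ps)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    for (mod in c("t1", "t2", "t1c"))
      dir.create(file.path(out_dir, mod), recursive = TRUE, showWarnings = FALSE)
    for (p in unique(manifest$patient_id)) {
      psel <- Filter(function(s) s$patient_id == p, samples)
      for (mod in c("t1", "t2", "t1c"))
        save_volume(lapply(psel, `[[`, mod), file.path(out_dir, mod),
                    format = "png_stack", patient_id = p)
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Load a slice-stack dataset directory
#'
#' Reads the `t1/`, `t2/`, `t1c/` PNG-stack layout written by
#' [generate_dataset()] (or prepared from real data), pairing slices by
#' `<patient>_<slice>.png` filename.
#'
#' @param dir dataset directory.
#' @param require_t1c error if ground-truth T1C slices are missing.
#' @return List of [paired_sample] objects.
#' @export
load_dataset_dir <- function(dir, require_t1c = TRUE) {
  parse_stack <- function(sub) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) return(NULL)
    files <- sort(list.files(d, pattern = "\\.png$"))
    info <- regmatches(files, regexec("^(.+)_([0-9]{4})\\.png$", files))
    bad <- vapply(info, length, integer(1)) != 3
    if (any(bad))
      stop(sprintf("unrecognized slice filename(s) under %s: %s", d,
                   paste(files[bad], collapse = ", ")), call. = FALSE)
    data.frame(file = file.path(d, files),
               patient_id = vapply(info, `[`, character(1), 2),
               slice_index = as.integer(vapply(info, `[`, character(1), 3)))
  }
  t1 <- parse_stack("t1"); t2 <- parse_stack("t2"); t1c <- parse_stack("t1c")
  if (is.null(t1) || is.null(t2))
    stop(sprintf("dataset directory '%s' must contain t1/ and t2/ stacks", dir),
         call. = FALSE)
  if (require_t1c && is.null(t1c))
    stop(sprintf("dataset directory '%s' has no t1c/ ground-truth stack", dir),
         call. = FALSE)
  key <- paste(t1$patient_id, t1$slice_index)
  stopifnot(identical(key, paste(t2$patient_id, t2$slice_index)))
  read_slice <- function(f) {
    px <- png::readPNG(f)
    slice_image(round(px * 65535), "raw")
  }
  lapply(seq_len(nrow(t1)), function(r) {
    paired_sample(read_slice(t1$file[r]), read_slice(t2$file[r]),
                  if (!is.null(t1c)) read_slice(t1c$file[r]),
                  patient_id = t1$patient_id[r],
                  slice_index = t1$slice_index[r])
  })
}
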