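#' Generator architecture specification
#'
#' The generator is a dual-encoder U-Net: one convolutional encoder per
#' input modality (T1-w, T2-w), gated additive feature fusion at every
#' scale, and a decoder with skip connections that upsamples back to the
#' input resolution and emits a single-channel slice. In single-modality
#' mode only one encoder exists and fusion is the identity. The fusion
#' gates are per-channel trainable weights squashed through a logistic, so
#' the contribution of each modality is adjusted dynamically during
#' training.
#'
#' @param modality_mode `"dual"`, `"t1_only"`, or `"t2_only"`.
#' @param base_width feature maps in the first encoder stage (default 64).
#' @param depth number of 2x downsampling stages (default 4); input dims
#'   must be divisible by `2^depth`.
#' @param out_activation `"sigmoid"` squashes the output into (0,1) for
#'   sigmoid/tanh-normalized training; `"linear"` leaves it unbounded for
#'   z-score training.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(modality_mode = c("dual", "t1_only", "t2_only"),
                           base_width = 64L, depth = 4L,
                           out_activation = c("sigmoid", "linear")) {
  modality_mode <- match.arg(modality_mode)
  out_activation <- match.arg(out_activation)
  base_width <- as.integer(base_width); depth <- as.integer(depth)
  stopifnot(base_width >= 1, depth >= 1)
  structure(list(modality_mode = modality_mode, base_width = base_width,
                 depth = depth, out_activation = out_activation,
                 input_channels = if (modality_mode == "dual") 2L else 1L),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A conditional patch discriminator: the candidate T1C slice is stacked
#' with the conditioning input modalities and scored patch-by-patch through
#' a stack of stride-2 4x4 convolutions, producing a grid of local realism
#' scores rather than a single scalar. With the default depth of 3 the
#' effective receptive field of each patch score is 70x70 pixels.
#'
#' @param base_width feature maps in the first stage (default 64).
#' @param depth number of stride-2 stages (default 3).
#' @param modality_mode conditioning modalities, as in [generator_spec()].
#' @return An object of class `discriminator_spec` (the computed
#'   `patch_receptive_field` is included).
#' @export
discriminator_spec <- function(base_width = 64L, depth = 3L,
                               modality_mode = c("dual", "t1_only", "t2_only")) {
  modality_mode <- match.arg(modality_mode)
  base_width <- as.integer(base_width); depth <- as.integer(depth)
  stopifnot(base_width >= 1, depth >= 1)
  # receptive field of k4/s2 stages followed by two k4/s1 layers
  rf <- 4L
  rf <- rf + 3L                       # second s1 conv
  for (i in seq_len(depth)) rf <- 2L * rf + 2L
  structure(list(base_width = base_width, depth = depth,
                 modality_mode = modality_mode,
                 input_channels = 1L + (if (modality_mode == "dual") 2L else 1L),
                 patch_receptive_field = rf),
            class = "discriminator_spec")
}

stage_width <- function(base, s) as.integer(min(base * 2^s, base * 8L))

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build a generator with deterministic initialization
#'
#' Allocates and initializes all parameters (He-normal weights, zero biases,
#' fusion gates at logit 0, i.e. weight 1/2 per modality). The same seed
#' always yields bit-identical parameters. The total parameter count is
#' reported via `message()`.
#'
#' @param spec a [generator_spec].
#' @param seed integer RNG seed for initialization.
#' @return An object of class `c("vce_generator", "vce_network")`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  mods <- if (spec$modality_mode == "dual") c("m1", "m2")
          else if (spec$modality_mode == "t1_only") "m1" else "m2"
  params <- with_seed(seed, {
    p <- list()
    for (m in mods) {
      p[[paste0(m, "_stem_w")]] <- he_init(3, 1, stage_width(spec$base_width, 0))
      p[[paste0(m, "_stem_b")]] <- numeric(stage_width(spec$base_width, 0))
      for (s in seq_len(spec$depth)) {
        cin <- stage_width(spec$base_width, s - 1)
        cout <- stage_width(spec$base_width, s)
        p[[paste0(m, "_down", s, "_w")]] <- he_init(3, cin, cout)
        p[[paste0(m, "_down", s, "_b")]] <- numeric(cout)
      }
    }
    if (spec$modality_mode == "dual") {
      for (s in 0:spec$depth) {
        cw <- stage_width(spec$base_width, s)
        p[[paste0("gate_m1_s", s)]] <- numeric(cw)
        p[[paste0("gate_m2_s", s)]] <- numeric(cw)
      }
    }
    for (s in rev(seq_len(spec$depth))) {
      cin_up <- stage_width(spec$base_width, s)
      cout <- stage_width(spec$base_width, s - 1)
      p[[paste0("up", s, "_w")]] <- he_init(3, cin_up + cout, cout)
      p[[paste0("up", s, "_b")]] <- numeric(cout)
    }
    p[["head_w"]] <- he_init(3, stage_width(spec$base_width, 0), 1)
    p[["head_b"]] <- numeric(1)
    p
  })
  n_par <- sum(vapply(params, length, numeric(1)))
  message(sprintf("generator (%s): %d parameters", spec$modality_mode, n_par))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 role = "generator", n_params = n_par),
            class = c("vce_generator", "vce_network"))
}

#' Build a patch discriminator with deterministic initialization
#'
#' @param spec a [discriminator_spec].
#' @param seed integer RNG seed for initialization.
#' @return An object of class `c("vce_discriminator", "vce_network")`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  params <- with_seed(seed, {
    p <- list()
    cin <- spec$input_channels
    for (s in seq_len(spec$depth)) {
      cout <- stage_width(spec$base_width, s - 1)
      p[[paste0("d", s, "_w")]] <- he_init(4, cin, cout)
      p[[paste0("d", s, "_b")]] <- numeric(cout)
      cin <- cout
    }
    cout <- stage_width(spec$base_width, spec$depth)
    p[["pen_w"]] <- he_init(4, cin, cout)
    p[["pen_b"]] <- numeric(cout)
    p[["out_w"]] <- he_init(4, cout, 1)
    p[["out_b"]] <- numeric(1)
    p
  })
  n_par <- sum(vapply(params, length, numeric(1)))
  message(sprintf("discriminator (%s): %d parameters", spec$modality_mode, n_par))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 role = "discriminator", n_params = n_par),
            class = c("vce_discriminator", "vce_network"))
}

#' @export
print.vce_network <- function(x, ...) {
  cat(sprintf("<%s: %s, %d parameters>\n", x$role, x$spec$modality_mode, x$n_params))
  invisible(x)
}

check_divisible <- function(d, depth) {
  div <- 2^depth
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input dims %dx%d must be divisible by 2^depth = %d",
                 d[1], d[2], div), call. = FALSE)
}

# Wrap current parameter arrays in leaf nodes (or pass through as constants
# when train=FALSE), returning list(p = lookup fn, leaves = named list).
# An optional cache environment reuses the leaf environments across
# iterations (values refreshed, gradients cleared) to avoid re-allocation in
# the training loop.
param_env <- function(tape, params, train, cache = NULL) {
  leaves <- list()
  if (train) {
    if (!is.null(cache)) {
      if (is.null(cache$leaves))
        cache$leaves <- lapply(params, function(p) ad_leaf(tape, p))
      leaves <- cache$leaves
      for (nm in names(params)) {
        leaves[[nm]]$value <- params[[nm]]
        leaves[[nm]]$grad <- NULL
      }
    } else {
      for (nm in names(params)) leaves[[nm]] <- ad_leaf(tape, params[[nm]])
    }
  }
  p <- function(nm) if (train) leaves[[nm]] else params[[nm]]
  list(p = p, leaves = leaves)
}

# Generator forward pass. x1/x2: [H,W,1,N] arrays (the one matching the
# modality mode may be NULL in single modes). Returns the output node/array
# and parameter leaves. A precomputed param_env `pe` can be supplied so
# several passes share the same leaves.
gen_forward <- function(model, x1, x2, tape = NULL, train = !is.null(tape),
                        pe = NULL) {
  spec <- model$spec
  xin <- switch(spec$modality_mode,
                dual = list(m1 = x1, m2 = x2),
                t1_only = list(m1 = x1),
                t2_only = list(m2 = x2))
  for (x in xin) {
    if (is.null(x)) stop(sprintf("modality input missing for mode '%s'",
                                 spec$modality_mode), call. = FALSE)
  }
  d <- dim(xin[[1]])
  check_divisible(d, spec$depth)
  if (is.null(pe)) pe <- param_env(tape, model$params, train)
  p <- pe$p

  feats <- list()  # per modality, list over scales 0..depth
  for (m in names(xin)) {
    h <- op_lrelu(tape, op_conv(tape, xin[[m]], p(paste0(m, "_stem_w")),
                                p(paste0(m, "_stem_b")), 1L, 1L))
    sc <- list(h)
    for (s in seq_len(spec$depth)) {
      h <- op_lrelu(tape, op_conv(tape, h, p(paste0(m, "_down", s, "_w")),
                                  p(paste0(m, "_down", s, "_b")), 2L, 1L))
      sc[[s + 1]] <- h
    }
    feats[[m]] <- sc
  }
  fused <- vector("list", spec$depth + 1)
  for (s in 0:spec$depth) {
    if (spec$modality_mode == "dual") {
      fused[[s + 1]] <- op_add(tape,
        op_gate(tape, feats$m1[[s + 1]], p(paste0("gate_m1_s", s))),
        op_gate(tape, feats$m2[[s + 1]], p(paste0("gate_m2_s", s))))
    } else {
      fused[[s + 1]] <- feats[[1]][[s + 1]]
    }
  }
  h <- fused[[spec$depth + 1]]
  for (s in rev(seq_len(spec$depth))) {
    h <- op_upsample2(tape, h)
    h <- op_concat(tape, h, fused[[s]])
    h <- op_lrelu(tape, op_conv(tape, h, p(paste0("up", s, "_w")),
                                p(paste0("up", s, "_b")), 1L, 1L))
  }
  out <- op_conv(tape, h, p("head_w"), p("head_b"), 1L, 1L)
  if (spec$out_activation == "sigmoid") out <- op_sigmoid(tape, out)
  list(out = out, leaves = pe$leaves)
}

# Plain inference: [H,W,1,N] in, [H,W,1,N] out.
gen_predict <- function(model, x1, x2 = NULL) {
  gen_forward(model, x1, x2, tape = NULL)$out
}

# Discriminator forward. x: [H,W,C,N] stacked (candidate, conditioning).
disc_forward <- function(model, x, tape = NULL, train = !is.null(tape),
                         pe = NULL) {
  spec <- model$spec
  d <- dim(ad_val(x))
  if (d[3] != spec$input_channels)
    stop(sprintf("discriminator expects %d channels, got %d",
                 spec$input_channels, d[3]), call. = FALSE)
  if (is.null(pe)) pe <- param_env(tape, model$params, train)
  p <- pe$p
  h <- x
  for (s in seq_len(spec$depth))
    h <- op_lrelu(tape, op_conv(tape, h, p(paste0("d", s, "_w")),
                                p(paste0("d", s, "_b")), 2L, 1L))
  h <- op_lrelu(tape, op_conv(tape, h, p("pen_w"), p("pen_b"), 1L, 1L))
  scores <- op_conv(tape, h, p("out_w"), p("out_b"), 1L, 1L)
  list(scores = scores, leaves = pe$leaves)
}

# Stack a candidate slice with the conditioning modalities into the
# discriminator input channel order (candidate, then T1, then T2 as present).
disc_stack <- function(mode, cand, t1, t2) {
  chans <- switch(mode,
                  dual = list(cand, t1, t2),
                  t1_only = list(cand, t1),
                  t2_only = list(cand, t2))
  d <- dim(cand)
  out <- array(0, c(d[1], d[2], length(chans), d[4]))
  for (i in seq_along(chans)) out[, , i, ] <- chans[[i]]
  out
}

# Per-sample input gradients of the mean patch score at the given inputs.
# `batch` is a list of [H,W,C] arrays or paired_samples in normalized space.
disc_input_grads <- function(disc, batch) {
  arrs <- lapply(batch, function(b) {
    if (inherits(b, "paired_sample")) {
      if (is.null(b$t1c)) stop("paired_sample without ground-truth T1C", call. = FALSE)
      cand <- b$t1c$pixels
      d <- dim(cand)
      x <- disc_stack(disc$spec$modality_mode,
                      array(cand, c(d, 1, 1)),
                      array(b$t1$pixels, c(d, 1, 1)),
                      array(b$t2$pixels, c(d, 1, 1)))
      x[, , , 1, drop = FALSE]
    } else {
      a <- b
      if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
      array(a, c(dim(a)[1:3], 1L))
    }
  })
  d <- dim(arrs[[1]])
  X <- array(0, c(d[1], d[2], d[3], length(arrs)))
  for (i in seq_along(arrs)) X[, , , i] <- arrs[[i]]
  tape <- tape_new()
  xn <- ad_leaf(tape, X)
  fw <- disc_forward(disc, xn, tape, train = FALSE)
  sc <- ad_val(fw$scores)
  npatch <- prod(dim(sc)[1:3])
  seed <- array(1 / npatch, dim(sc))
  tape_backward(tape, list(list(node = fw$scores, grad = seed)))
  lapply(seq_along(arrs), function(i) xn$grad[, , , i, drop = TRUE])
}

#' Score slices with a discriminator
#'
#' Convenience wrapper returning the patch-score grid for a candidate slice
#' with its conditioning modalities.
#'
#' @param disc a built discriminator.
#' @param candidate,t1,t2 matrices/[slice_image]s in the training intensity
#'   space (`t1`/`t2` as required by the conditioning mode).
#' @return Numeric matrix of patch scores.
#' @export
disc_score <- function(disc, candidate, t1 = NULL, t2 = NULL) {
  cand <- as_matrix4(candidate)
  x <- disc_stack(disc$spec$modality_mode, cand,
                  if (!is.null(t1)) as_matrix4(t1),
                  if (!is.null(t2)) as_matrix4(t2))
  sc <- ad_val(disc_forward(disc, x, tape = NULL)$scores)
  sc[, , 1, 1]
}

as_matrix4 <- function(x) {
  m <- if (is_slice_image(x)) x$pixels else x
  array(m, c(dim(m), 1L, 1L))
}
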