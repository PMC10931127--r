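#' Training configuration
#'
#' Bundles everything a training run depends on: Adam settings (defaults
#' lr = 0.0002, beta1 = 0.5, beta2 = 0.999), the iteration budget (default
#' 14,000), batch size (default 4), the loss weights, the normalization
#' method applied per patient volume, the modality mode, architecture
#' widths/depths, gradient-penalty settings, and the RNG seed that makes
#' the run deterministic.
#'
#' `shape_loss` selects the shape term of the generator objective:
#' `"pgrad"` is the pixelwise normalized-gradient loss (the full model);
#' `"l1"` swaps in a plain L1 term, giving the L1+GAN ablation baseline
#' used for texture comparisons.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param beta1,beta2 Adam moment decays (`0 <= beta1 < 1`).
#' @param iterations number of generator/discriminator update pairs.
#' @param batch_size minibatch size.
#' @param weights a [loss_weights] object.
#' @param eps gradient-normalization stabilizer of the shape loss.
#' @param gp_gamma R1 gradient-penalty coefficient (0 disables).
#' @param gp_interval apply the penalty every `gp_interval` iterations
#'   (lazy regularization; 1 = every iteration).
#' @param gp_fd_step step of the directional finite difference used for the
#'   penalty's parameter gradient.
#' @param normalization_method `"zscore"`, `"sigmoid"`, or `"tanh"`.
#' @param modality_mode `"dual"`, `"t1_only"`, or `"t2_only"`.
#' @param shape_loss `"pgrad"` or `"l1"`.
#' @param gen_base_width,gen_depth,disc_base_width,disc_depth architecture
#'   hyperparameters (see [generator_spec()] / [discriminator_spec()]).
#' @param checkpoint_interval iterations between periodic checkpoints
#'   (written only when `checkpoint_dir` is set).
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param log_interval iterations between stderr progress lines when
#'   `verbose`.
#' @param verbose emit progress to stderr.
#' @param seed integer seed controlling initialization and batch order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                            iterations = 14000L, batch_size = 4L,
                            weights = loss_weights(1, 1), eps = 1e-8,
                            gp_gamma = 10, gp_interval = 4L, gp_fd_step = 1e-3,
                            normalization_method = c("sigmoid", "zscore", "tanh"),
                            modality_mode = c("dual", "t1_only", "t2_only"),
                            shape_loss = c("pgrad", "l1"),
                            gen_base_width = 64L, gen_depth = 4L,
                            disc_base_width = 64L, disc_depth = 3L,
                            checkpoint_interval = 1000L, checkpoint_dir = NULL,
                            log_interval = 100L, verbose = FALSE, seed = 1L) {
  normalization_method <- match.arg(normalization_method)
  modality_mode <- match.arg(modality_mode)
  shape_loss <- match.arg(shape_loss)
  stopifnot(inherits(weights, "loss_weights"))
  if (!(learning_rate > 0)) stop("learning_rate must be > 0", call. = FALSE)
  if (!(beta1 >= 0 && beta1 < 1)) stop("beta1 must be in [0, 1)", call. = FALSE)
  iterations <- as.integer(iterations)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 iterations = iterations, batch_size = as.integer(batch_size),
                 weights = weights, eps = eps, gp_gamma = gp_gamma,
                 gp_interval = as.integer(gp_interval), gp_fd_step = gp_fd_step,
                 normalization_method = normalization_method,
                 modality_mode = modality_mode, shape_loss = shape_loss,
                 gen_base_width = as.integer(gen_base_width),
                 gen_depth = as.integer(gen_depth),
                 disc_base_width = as.integer(disc_base_width),
                 disc_depth = as.integer(disc_depth),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 checkpoint_dir = checkpoint_dir,
                 log_interval = as.integer(log_interval),
                 verbose = isTRUE(verbose), seed = as.integer(seed)),
            class = "training_config")
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, b1, b2, adam_eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + adam_eps)
  }
  list(params = params, state = st)
}

leaf_grads <- function(leaves) lapply(leaves, function(l) l$grad)

stack_samples <- function(samples, field) {
  d <- dim(samples[[1]][[field]]$pixels)
  X <- array(0, c(d[1], d[2], 1L, length(samples)))
  for (i in seq_along(samples)) X[, , 1, i] <- samples[[i]][[field]]$pixels
  X
}

#' Train the synthesis model
#'
#' Alternating optimization: one discriminator step and one generator step
#' per iteration, Adam for both, deterministic batch order given
#' `cfg$seed`. The discriminator minimizes the LSGAN loss plus the R1
#' gradient penalty at real samples; the generator minimizes
#' `lambda_gradient * shape_loss + lambda_gan * lsgan_g_loss`.
#'
#' Training operates in the normalized intensity space: every sample's
#' `intensity_space` must equal `cfg$normalization_method` (see
#' [prepare_paired_data()]). Any non-finite loss aborts with a diagnostic
#' naming the offending term and iteration.
#'
#' @param train_set non-empty list of normalized [paired_sample] objects
#'   with ground-truth T1C.
#' @param cfg a [training_config].
#' @return List with `checkpoint` (a `vce_checkpoint`), `log` (data frame
#'   of per-iteration loss records), `generator`, `discriminator`.
#' @export
train <- function(train_set, cfg) {
  stopifnot(inherits(cfg, "training_config"), length(train_set) >= 1)
  for (s in train_set) {
    if (!inherits(s, "paired_sample")) stop("train_set must hold paired_samples", call. = FALSE)
    if (is.null(s$t1c)) stop("training requires ground-truth T1C slices", call. = FALSE)
    if (s$t1$intensity_space != cfg$normalization_method)
      stop(sprintf("sample in '%s' space; expected '%s' (normalize first)",
                   s$t1$intensity_space, cfg$normalization_method), call. = FALSE)
  }
  out_act <- if (cfg$normalization_method == "zscore") "linear" else "sigmoid"
  gspec <- generator_spec(cfg$modality_mode, cfg$gen_base_width, cfg$gen_depth, out_act)
  gen <- suppressMessages(build_generator(gspec, seed = cfg$seed))
  use_disc <- cfg$weights$lambda_gan > 0
  disc <- if (use_disc) {
    dspec <- discriminator_spec(cfg$disc_base_width, cfg$disc_depth, cfg$modality_mode)
    suppressMessages(build_discriminator(dspec, seed = cfg$seed + 1L))
  }

  X1 <- stack_samples(train_set, "t1")
  X2 <- stack_samples(train_set, "t2")
  Y <- stack_samples(train_set, "t1c")
  M <- length(train_set)
  B <- cfg$batch_size
  lam_g <- cfg$weights$lambda_gradient
  lam_a <- cfg$weights$lambda_gan

  ad_g <- adam_new(gen$params)
  ad_d <- if (use_disc) adam_new(disc$params)
  cache_g <- new.env(parent = emptyenv())
  cache_d <- new.env(parent = emptyenv())
  cache_fd <- new.env(parent = emptyenv())
  log_mat <- matrix(NA_real_, cfg$iterations, 6,
                    dimnames = list(NULL, c("iteration", "g_loss", "d_loss",
                                            "gradient_loss_term", "gan_loss_term",
                                            "penalty")))
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      idx <- sample.int(M, B, replace = TRUE)
      x1 <- X1[, , , idx, drop = FALSE]
      x2 <- X2[, , , idx, drop = FALSE]
      y <- Y[, , , idx, drop = FALSE]

      # Generator forward once; its output serves the discriminator step as
      # a constant and the generator step through the same tape.
      tp_g <- tape_new()
      pe_g <- param_env(tp_g, gen$params, TRUE, cache = cache_g)
      fg <- gen_forward(gen, x1, x2, tp_g, pe = pe_g)
      out_node <- fg$out
      fake <- ad_val(out_node)

      # ---- discriminator step ----
      d_loss <- 0
      penalty <- 0
      if (use_disc) {
      # Real and fake samples share one batched pass (samples are
      # independent, so scores and gradients are identical to two passes).
      inp_real <- disc_stack(cfg$modality_mode, y, x1, x2)
      inp_fake <- disc_stack(cfg$modality_mode, fake, x1, x2)
      di <- dim(inp_real)
      inp_all <- array(c(inp_real, inp_fake), c(di[1:3], 2L * B))
      tp <- tape_new()
      xr <- ad_leaf(tp, inp_all)
      pe_d <- param_env(tp, disc$params, TRUE, cache = cache_d)
      fr <- disc_forward(disc, xr, tp, pe = pe_d)
      sc <- ad_val(fr$scores)
      dr <- sc[, , , seq_len(B), drop = FALSE]
      df <- sc[, , , B + seq_len(B), drop = FALSE]
      d_loss <- lsgan_d_loss(dr, df)
      npatch <- prod(dim(dr)[1:3])
      vnorm <- NULL
      gp_now <- cfg$gp_gamma > 0 && (it %% cfg$gp_interval == 0L)
      if (gp_now) {
        seed <- array(0, dim(sc))
        seed[, , , seq_len(B)] <- 1 / npatch
        tape_backward(tp, list(list(node = fr$scores, grad = seed)))
        v <- xr$grad[, , , seq_len(B), drop = FALSE]
        vnorm <- sqrt(colSums(matrix(v^2, ncol = B)))
        penalty <- cfg$gp_gamma / 2 * mean(vnorm^2)
        tape_zero_grads(tp, c(pe_d$leaves, list(xr)))
      }
      seed <- array(0, dim(sc))
      seed[, , , seq_len(B)] <- (dr - 1) / length(dr)
      seed[, , , B + seq_len(B)] <- df / length(df)
      tape_backward(tp, list(list(node = fr$scores, grad = seed)))
      gd <- leaf_grads(pe_d$leaves)
      if (gp_now && any(vnorm > 0)) {
        e <- v
        for (b in seq_len(B)) if (vnorm[b] > 0) e[, , , b] <- v[, , , b] / vnorm[b]
        h <- cfg$gp_fd_step
        wts <- cfg$gp_gamma * vnorm / (B * 2 * h * npatch)
        # the +eps and -eps probes run as one batched pass
        probe <- array(c(inp_real + h * e, inp_real - h * e), c(di[1:3], 2L * B))
        tp2 <- tape_new()
        pe2 <- param_env(tp2, disc$params, TRUE, cache = cache_fd)
        f2 <- disc_forward(disc, probe, tp2, pe = pe2)
        seed <- array(0, dim(sc))
        for (b in seq_len(B)) {
          seed[, , , b] <- wts[b]
          seed[, , , B + b] <- -wts[b]
        }
        tape_backward(tp2, list(list(node = f2$scores, grad = seed)))
        g2 <- leaf_grads(pe2$leaves)
        for (nm in names(gd))
          if (!is.null(g2[[nm]])) gd[[nm]] <- gd[[nm]] + g2[[nm]]
      }
      upd <- adam_step(disc$params, gd, ad_d, cfg$learning_rate, cfg$beta1, cfg$beta2)
      disc$params <- upd$params
      ad_d <- upd$state
      }

      # ---- generator step (against the updated discriminator) ----
      tp <- tp_g
      gan_term <- 0
      if (use_disc) {
        cond <- if (cfg$modality_mode == "dual") {
          dd <- dim(x1)
          cc <- array(0, c(dd[1], dd[2], 2L, dd[4]))
          cc[, , 1, ] <- x1; cc[, , 2, ] <- x2
          cc
        } else if (cfg$modality_mode == "t1_only") x1 else x2
        xin <- op_concat(tp, out_node, cond)
        fd <- disc_forward(disc, xin, tp, train = FALSE)
        dfk <- ad_val(fd$scores)
        gan_term <- lsgan_g_loss(dfk)
      }

      shape_seed <- array(0, dim(fake))
      if (cfg$shape_loss == "pgrad") {
        shape_vals <- numeric(B)
        for (b in seq_len(B)) {
          shape_vals[b] <- pixelwise_gradient_loss(fake[, , 1, b], y[, , 1, b], cfg$eps)
          shape_seed[, , 1, b] <-
            pg_loss_input_grad(fake[, , 1, b], y[, , 1, b], cfg$eps) / B
        }
        shape_term <- mean(shape_vals)
      } else {
        diffs <- fake - y
        shape_term <- mean(abs(diffs))
        shape_seed <- sign(diffs) / length(diffs)
      }
      seeds <- list(list(node = out_node, grad = lam_g * shape_seed))
      if (use_disc)
        seeds[[2]] <- list(node = fd$scores, grad = lam_a * (dfk - 1) / length(dfk))
      tape_backward(tp, seeds)
      upd <- adam_step(gen$params, leaf_grads(pe_g$leaves), ad_g,
                       cfg$learning_rate, cfg$beta1, cfg$beta2)
      gen$params <- upd$params
      ad_g <- upd$state

      g_loss <- lam_g * shape_term + lam_a * gan_term
      vals <- c(g_loss = g_loss, d_loss = d_loss,
                gradient_loss_term = shape_term, gan_loss_term = gan_term,
                penalty = penalty)
      bad <- !is.finite(vals)
      if (any(bad))
        stop(sprintf("non-finite %s at iteration %d; training aborted",
                     paste(names(vals)[bad], collapse = ", "), it), call. = FALSE)
      log_mat[it, ] <- c(it, vals)
      if (cfg$verbose && it %% cfg$log_interval == 0)
        message(sprintf("[%s] iter %6d  g_loss %.5f  d_loss %.5f  penalty %.5f",
                        format(Sys.time(), "%H:%M:%S"), it, g_loss, d_loss, penalty))
      if (!is.null(cfg$checkpoint_dir) && it %% cfg$checkpoint_interval == 0)
        save_checkpoint(new_checkpoint(gen, disc, cfg, it),
                        file.path(cfg$checkpoint_dir, sprintf("ckpt_%06d.rds", it)))
    }
  })
  ck <- new_checkpoint(gen, disc, cfg, cfg$iterations)
  if (!is.null(cfg$checkpoint_dir))
    save_checkpoint(ck, file.path(cfg$checkpoint_dir, "ckpt_final.rds"))
  list(checkpoint = ck, log = as.data.frame(log_mat),
       generator = gen, discriminator = disc)
}

new_checkpoint <- function(gen, disc, cfg, iteration) {
  structure(list(generator = gen, discriminator = disc, cfg = cfg,
                 iteration = as.integer(iteration)),
            class = "vce_checkpoint")
}

#' Save / load a training checkpoint
#'
#' A checkpoint embeds the generator and discriminator (spec, parameters,
#' initialization seed), the full training configuration, and the
#' iteration, so a model reloads exactly.
#'
#' @param ck a `vce_checkpoint` / `path` file path.
#' @param path file path (`.rds`).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ck, path) {
  stopifnot(inherits(ck, "vce_checkpoint"))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "vce_checkpoint"))
  ck
}

#' @export
print.vce_checkpoint <- function(x, ...) {
  cat(sprintf("<vce_checkpoint: %s, %s shape loss, iteration %d>\n",
              x$cfg$modality_mode, x$cfg$shape_loss, x$iteration))
  invisible(x)
}

#' Fit per-patient normalization and normalize a sample set
#'
#' Fits [norm_params] per patient and per modality over all of that
#' patient's slices in `samples`, then returns the normalized samples
#' alongside the parameters (needed later to invert the transform).
#'
#' @param samples list of raw-space [paired_sample] objects.
#' @param method normalization method.
#' @return List with `samples` (normalized) and `params`
#'   (`params[[patient_id]][[modality]]`).
#' @export
prepare_paired_data <- function(samples, method = "sigmoid") {
  pids <- unique(vapply(samples, function(s) s$patient_id, character(1)))
  params <- list()
  for (pid in pids) {
    sel <- Filter(function(s) s$patient_id == pid, samples)
    params[[pid]] <- list(
      t1 = fit_norm_params(lapply(sel, `[[`, "t1"), method),
      t2 = fit_norm_params(lapply(sel, `[[`, "t2"), method))
    if (!is.null(sel[[1]]$t1c))
      params[[pid]]$t1c <- fit_norm_params(lapply(sel, `[[`, "t1c"), method)
  }
  norm <- lapply(samples, function(s) {
    p <- params[[s$patient_id]]
    paired_sample(normalize_slice(s$t1, p$t1), normalize_slice(s$t2, p$t2),
                  if (!is.null(s$t1c)) normalize_slice(s$t1c, p$t1c),
                  patient_id = s$patient_id, slice_index = s$slice_index)
  })
  list(samples = norm, params = params)
}

#' Synthesize a virtual-contrast-enhanced slice
#'
#' Normalizes the raw input modalities with the stored method, runs the
#' generator, and inverts the normalization so the output is a raw-space
#' T1C slice in \eqn{[0, 4095]}. Inputs not consumed by the checkpoint's
#' modality mode are ignored. Deterministic: no randomness is involved.
#'
#' @param ck a `vce_checkpoint`.
#' @param t1,t2 raw-space [slice_image] inputs (as required by the mode).
#' @param params named list of [norm_params] with entries `t1`, `t2`, and
#'   `t1c` (the T1C entry drives the inverse transform of the output).
#' @return Raw-space [slice_image].
#' @export
synthesize <- function(ck, t1 = NULL, t2 = NULL, params) {
  stopifnot(inherits(ck, "vce_checkpoint"))
  mode <- ck$cfg$modality_mode
  need <- switch(mode, dual = c("t1", "t2"), t1_only = "t1", t2_only = "t2")
  inputs <- list(t1 = t1, t2 = t2)
  for (nm in need)
    if (is.null(inputs[[nm]]))
      stop(sprintf("modality '%s' is required by mode '%s'", nm, mode), call. = FALSE)
  if (is.null(params$t1c))
    stop("params$t1c is required to invert the output normalization", call. = FALSE)
  to_arr <- function(nm) {
    if (!(nm %in% need)) return(NULL)
    sl <- normalize_slice(as_slice_image(inputs[[nm]]), params[[nm]])
    array(sl$pixels, c(dim(sl$pixels), 1L, 1L))
  }
  out <- gen_predict(ck$generator, to_arr("t1"), to_arr("t2"))
  m <- out[, , 1, 1]
  if (ck$generator$spec$out_activation == "sigmoid")
    m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  denormalize_slice(slice_image(m, ck$cfg$normalization_method), params$t1c)
}

#' MAE of the copy-T1 baseline
#'
#' The no-model reference that simply presents the pre-contrast T1-w slice
#' as the prediction; a trained model must beat this for synthesis to have
#' learned anything.
#'
#' @param samples raw-space [paired_sample] objects with ground truth.
#' @return Mean MAE over slices.
#' @export
copy_t1_baseline_mae <- function(samples) {
  mean(vapply(samples, function(s) img_mae(s$t1, s$t1c), numeric(1)))
}

#' End-to-end experiment: normalize, train, synthesize, evaluate
#'
#' Runs the full pipeline on raw-space phantom or patient samples:
#' per-patient normalization, training on the train split, synthesis of
#' every test slice, and raw-space evaluation against ground truth.
#'
#' @param train_samples,test_samples raw-space [paired_sample] lists.
#' @param cfg a [training_config].
#' @return List with `checkpoint`, `log`, `per_slice` (metric data frame
#'   from [evaluate_pairs()]), `summary` (from [aggregate_metrics()]), and
#'   `similarity` (named means: mae, mse, ssim).
#' @export
run_experiment <- function(train_samples, test_samples, cfg) {
  prep_tr <- prepare_paired_data(train_samples, cfg$normalization_method)
  prep_te <- prepare_paired_data(test_samples, cfg$normalization_method)
  fit <- train(prep_tr$samples, cfg)
  preds <- lapply(seq_along(test_samples), function(k) {
    s <- test_samples[[k]]
    synthesize(fit$checkpoint, s$t1, s$t2, prep_te$params[[s$patient_id]])
  })
  truths <- lapply(test_samples, `[[`, "t1c")
  per_slice <- evaluate_pairs(preds, truths)
  list(checkpoint = fit$checkpoint, log = fit$log, per_slice = per_slice,
       predictions = preds,
       summary = if (nrow(per_slice) >= 2) aggregate_metrics(per_slice),
       similarity = list(mae = mean(per_slice$mae), mse = mean(per_slice$mse),
                         ssim = mean(per_slice$ssim)))
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per configuration (configs should differ
#' only along the declared ablation axes: loss ratio, normalization method,
#' modality mode, or shape loss). For single-modality rows the MAER, MSER
#' and SSIMR ratios are reported relative to the first dual-modality row.
#'
#' @param grid list of [training_config] objects.
#' @param train_samples,test_samples raw-space [paired_sample] lists.
#' @param labels optional row labels.
#' @return Data frame with one row per configuration.
#' @export
run_ablation <- function(grid, train_samples, test_samples, labels = NULL) {
  stopifnot(length(grid) >= 1)
  if (is.null(labels))
    labels <- vapply(grid, function(cfg)
      sprintf("%s/%s/%g:%g/%s", cfg$modality_mode, cfg$normalization_method,
              cfg$weights$lambda_gradient, cfg$weights$lambda_gan,
              cfg$shape_loss), character(1))
  res <- lapply(grid, function(cfg) run_experiment(train_samples, test_samples, cfg))
  rows <- lapply(seq_along(grid), function(i) {
    ps <- res[[i]]$per_slice
    data.frame(label = labels[i],
               modality_mode = grid[[i]]$modality_mode,
               normalization = grid[[i]]$normalization_method,
               lambda_gradient = grid[[i]]$weights$lambda_gradient,
               lambda_gan = grid[[i]]$weights$lambda_gan,
               shape_loss = grid[[i]]$shape_loss,
               mae = mean(ps$mae), mse = mean(ps$mse), ssim = mean(ps$ssim),
               tmsvpmi = mean(ps$tmsvpmi), tavpmi = mean(ps$tavpmi),
               tfpmi = mean(ps$tfpmi), vfpmi = mean(ps$vfpmi))
  })
  tab <- do.call(rbind, rows)
  dual_row <- which(tab$modality_mode == "dual")[1]
  tab$maer <- tab$mser <- tab$ssimr <- NA_real_
  if (!is.na(dual_row)) {
    for (i in seq_len(nrow(tab))) {
      r <- metric_ratios(tab[i, c("mae", "mse", "ssim")],
                         tab[dual_row, c("mae", "mse", "ssim")])
      tab$maer[i] <- r$maer; tab$mser[i] <- r$mser; tab$ssimr[i] <- r$ssimr
    }
  }
  tab
}
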