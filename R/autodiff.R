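# Minimal define-by-run reverse-mode tape over numeric arrays.
#
# Feature maps are [H, W, C, N] arrays. A node is an environment holding the
# forward value, an accumulated gradient, and a backward closure returning
# (parent node, gradient contribution) pairs. Creation order is a topological
# order, so the backward sweep just walks the tape in reverse. Ops accept
# plain arrays wherever a constant (no gradient) is wanted; with `tape =
# NULL` every op returns a bare array, giving a fast inference path through
# the same code.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

# Leaf with respect to which gradients are wanted (parameters, inputs).
# Leaves carry no backward step, so they are not registered on the tape;
# they receive gradients purely as parents of op nodes.
ad_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd
}

ad_val <- function(x) if (is.environment(x)) x$value else x
ad_is_node <- function(x) is.environment(x)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# seeds: list of list(node=, grad=). Multiple seeds supported (e.g. a loss
# gradient injected at the generator output while another flows from the
# discriminator scores).
tape_backward <- function(tape, seeds) {
  for (s in seeds) ad_accum(s$node, s$grad)
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    for (contrib in nd$backward(nd$grad)) ad_accum(contrib$node, contrib$grad)
  }
  invisible(NULL)
}

tape_zero_grads <- function(tape, leaves = list()) {
  for (k in seq_len(tape$n)) tape$nodes[[k]]$grad <- NULL
  for (l in leaves) l$grad <- NULL
  invisible(NULL)
}

# ---- ops -------------------------------------------------------------------

op_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b)
  y <- nn_conv_fw(xv, dim(xv), wv, dim(wv), bv, as.integer(stride), as.integer(pad))
  if (is.null(tape)) return(y)
  need_dx <- ad_is_node(x)
  need_dw <- ad_is_node(w) || ad_is_node(b)
  ad_node(tape, y, backward = function(dy) {
    bw <- nn_conv_bw(xv, dim(xv), wv, dim(wv), dy, as.integer(stride),
                     as.integer(pad), need_dx, need_dw)
    out <- list()
    if (ad_is_node(x)) out[[length(out) + 1L]] <- list(node = x, grad = bw$dx)
    if (ad_is_node(w)) out[[length(out) + 1L]] <- list(node = w, grad = bw$dw)
    if (ad_is_node(b)) out[[length(out) + 1L]] <- list(node = b, grad = bw$db)
    out
  })
}

op_lrelu <- function(tape, x, alpha = 0.2) {
  xv <- ad_val(x)
  y <- nn_lrelu_fw(xv, alpha)
  if (is.null(tape)) return(y)
  ad_node(tape, y, backward = function(dy) {
    if (!ad_is_node(x)) return(list())
    list(list(node = x, grad = nn_lrelu_bw(xv, dy, alpha)))
  })
}

op_sigmoid <- function(tape, x) {
  xv <- ad_val(x)
  y <- 1 / (1 + exp(-xv))
  if (is.null(tape)) return(y)
  ad_node(tape, y, backward = function(dy) {
    if (!ad_is_node(x)) return(list())
    list(list(node = x, grad = dy * y * (1 - y)))
  })
}

op_add <- function(tape, x, y) {
  v <- ad_val(x) + ad_val(y)
  if (is.null(tape)) return(v)
  ad_node(tape, v, backward = function(dy) {
    out <- list()
    if (ad_is_node(x)) out[[length(out) + 1L]] <- list(node = x, grad = dy)
    if (ad_is_node(y)) out[[length(out) + 1L]] <- list(node = y, grad = dy)
    out
  })
}

# Per-channel gate: y = x * sigmoid(theta)[channel]; theta has length C.
op_gate <- function(tape, x, theta) {
  xv <- ad_val(x); tv <- ad_val(theta)
  g <- 1 / (1 + exp(-tv))
  y <- nn_gate_fw(xv, dim(xv), g)
  if (is.null(tape)) return(y)
  ad_node(tape, y, backward = function(dy) {
    bw <- nn_gate_bw(xv, dim(xv), g, dy)
    out <- list()
    if (ad_is_node(x)) out[[length(out) + 1L]] <- list(node = x, grad = bw$dx)
    if (ad_is_node(theta))
      out[[length(out) + 1L]] <- list(node = theta,
                                      grad = bw$dg_raw * g * (1 - g))
    out
  })
}

op_concat <- function(tape, x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  dx <- dim(xv); dyv <- dim(yv)
  stopifnot(dx[1] == dyv[1], dx[2] == dyv[2], dx[4] == dyv[4])
  v <- array(0, c(dx[1], dx[2], dx[3] + dyv[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- xv
  v[, , dx[3] + seq_len(dyv[3]), ] <- yv
  if (is.null(tape)) return(v)
  ad_node(tape, v, backward = function(dz) {
    out <- list()
    if (ad_is_node(x))
      out[[length(out) + 1L]] <- list(node = x,
        grad = dz[, , seq_len(dx[3]), , drop = FALSE])
    if (ad_is_node(y))
      out[[length(out) + 1L]] <- list(node = y,
        grad = dz[, , dx[3] + seq_len(dyv[3]), , drop = FALSE])
    out
  })
}

# Nearest-neighbour 2x upsampling.
op_upsample2 <- function(tape, x) {
  xv <- ad_val(x)
  y <- nn_up2_fw(xv, dim(xv))
  if (is.null(tape)) return(y)
  ad_node(tape, y, backward = function(dy) {
    if (!ad_is_node(x)) return(list())
    list(list(node = x, grad = nn_up2_bw(dy, dim(dy))))
  })
}
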