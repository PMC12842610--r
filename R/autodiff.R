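# Reverse-mode automatic differentiation on a dynamic tape.
#
# Data tensors are plain R arrays in layout (H, W, N, C) -- spatial dims
# fastest, channels slowest -- or (D, N) matrices after flattening, or
# scalars for losses.  Trainable parameters are persistent environments
# (see layers.R); ops accumulate into `param$grad` directly during the
# backward sweep, so only data tensors live on the tape.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

new_node <- function(tape, value, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

# Gradient accumulation without per-step allocation, in two flavours that
# differ in who may later touch the increment `g`:
#
# * accum_grad(): `g` may be shared -- av_add / av_add_relu hand the *same*
#   array to both parents -- so an adopted gradient must never be mutated
#   (own = FALSE).  The second increment goes through R's `+`, which
#   allocates a private sum we exclusively own (own = TRUE); from then on
#   increments are added in place.
# * accum_grad_own(): the caller guarantees `g` was freshly computed for this
#   call and is referenced nowhere else, so the first increment is adopted
#   *and* owned outright; every later increment adds in place.
accum_grad <- function(nd, g) {
  if (is.null(nd$grad)) {
    nd$grad <- g
    nd$own <- FALSE
  } else if (isTRUE(nd$own)) {
    cpp_add_inplace(nd$grad, g)
  } else {
    nd$grad <- nd$grad + g
    nd$own <- TRUE
  }
  invisible(NULL)
}

accum_grad_own <- function(nd, g) {
  if (is.null(nd$grad)) {
    nd$grad <- g
    nd$own <- TRUE
  } else if (isTRUE(nd$own)) {
    cpp_add_inplace(nd$grad, g)
  } else {
    nd$grad <- nd$grad + g
    nd$own <- TRUE
  }
  invisible(NULL)
}

# Parameter-side accumulation.  Every call site computes its increment fresh
# (C++ kernel outputs, tcrossprod/rowSums results, scalar arithmetic), so the
# first increment can be adopted *and* owned outright; later increments add in
# place.  zero_grads() resets both $grad and the ownership flag.
accum_pgrad <- function(p, g) {
  if (isTRUE(p$gown)) {
    cpp_add_inplace(p$grad, g)
  } else {
    p$grad <- g
    p$gown <- TRUE
  }
  invisible(NULL)
}

#' @noRd
tape_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd, nd$grad)
  }
  invisible(NULL)
}

av_input <- function(tape, value) new_node(tape, value)

# ---- convolution / pooling (C++ kernels) -----------------------------------

av_conv2d <- function(tape, x, p, stride = 1L, pad = 0L) {
  y <- cpp_conv2d_forward(x$value, p$w$value, p$b$value, stride, pad)
  need_gx <- !isTRUE(x$no_grad)   # image inputs opt out of data gradients
  new_node(tape, y, list(x), function(nd, g) {
    r <- cpp_conv2d_backward(x$value, p$w$value, g, stride, pad, need_gx)
    if (need_gx) accum_grad_own(x, r$gx)
    accum_pgrad(p$w, r$gw)
    accum_pgrad(p$b, r$gb)
  })
}

av_convT2d <- function(tape, x, p, stride = 2L) {
  y <- cpp_convT2d_forward(x$value, p$w$value, p$b$value, stride)
  new_node(tape, y, list(x), function(nd, g) {
    r <- cpp_convT2d_backward(x$value, p$w$value, g, stride)
    accum_grad_own(x, r$gx)
    accum_pgrad(p$w, r$gw)
    accum_pgrad(p$b, r$gb)
  })
}

av_maxpool <- function(tape, x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_forward(x$value, k, stride, pad)
  xd <- dim(x$value)
  new_node(tape, r$y, list(x), function(nd, g) {
    accum_grad_own(x, cpp_maxpool_backward(r$idx, g, xd))
  })
}

# ---- batch normalisation ----------------------------------------------------

# st: persistent env with $mean, $var (running), $momentum, $eps.
# At batch size 1 the batch variance is degenerate, so running statistics
# are used even in training mode.  `relu = TRUE` fuses the following ReLU
# (forward clamp; backward masks on the stored output).
av_bn2d <- function(tape, x, p_gamma, p_beta, st, training, relu = FALSE) {
  d <- dim(x$value)
  use_batch <- training && d[3] > 1L
  r <- cpp_bn2d_forward(x$value, p_gamma$value, p_beta$value,
                        st$mean, st$var, use_batch, st$eps, relu)
  if (use_batch) {
    M <- prod(d[1:3])
    st$mean <- (1 - st$momentum) * st$mean + st$momentum * r$mu
    st$var <- (1 - st$momentum) * st$var + st$momentum * r$var * M / max(M - 1, 1)
  }
  y <- r$y
  new_node(tape, y, list(x), function(nd, g) {
    rb <- cpp_bn2d_backward(x$value, y, g, p_gamma$value, r$mu, r$invstd,
                            use_batch, relu)
    accum_pgrad(p_gamma, rb$ggamma)
    accum_pgrad(p_beta, rb$gbeta)
    accum_grad_own(x, rb$gx)
  })
}

# ---- pointwise --------------------------------------------------------------

av_relu <- function(tape, x) {
  y <- cpp_relu_forward(x$value)
  new_node(tape, y, list(x), function(nd, g) {
    accum_grad_own(x, cpp_relu_backward(y, g))
  })
}

# fused y = relu(x + z); the backward mask is shared by both parents
av_add_relu <- function(tape, x, z) {
  y <- cpp_add_relu_forward(x$value, z$value)
  new_node(tape, y, list(x, z), function(nd, g) {
    gm <- cpp_relu_backward(y, g)
    accum_grad(x, gm)
    accum_grad(z, gm)
  })
}

av_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(tape, s, list(x), function(nd, g) accum_grad_own(x, g * s * (1 - s)))
}

av_add <- function(tape, x, y) {
  new_node(tape, x$value + y$value, list(x, y), function(nd, g) {
    accum_grad(x, g)
    accum_grad(y, g)
  })
}

# ---- broadcast multiplies (attention) ---------------------------------------

# a: (N, C) matrix of per-sample per-channel gates; x: (H, W, N, C).
av_scale_channels <- function(tape, x, a) {
  new_node(tape, cpp_scale_channels_forward(x$value, a$value), list(x, a),
           function(nd, g) {
    r <- cpp_scale_channels_backward(x$value, a$value, g)
    accum_grad_own(x, r$gx)
    accum_grad_own(a, r$ga)
  })
}

# a: (H, W, N, 1) spatial map, broadcast over channels of x (H, W, N, C).
av_scale_spatial <- function(tape, x, a) {
  new_node(tape, cpp_scale_spatial_forward(x$value, a$value), list(x, a),
           function(nd, g) {
    r <- cpp_scale_spatial_backward(x$value, a$value, g)
    accum_grad_own(x, r$gx)
    accum_grad_own(a, r$ga)
  })
}

# ---- channel-wise statistics (CBAM) -----------------------------------------

# global average + max pool over H, W, computed in one pass; returns a list
# of two (N, C) nodes so CBAM's shared-MLP branches reuse the same sweep.
av_gap_gmp <- function(tape, x) {
  d <- dim(x$value)
  r <- cpp_gap_gmp_forward(x$value)
  avg <- new_node(tape, r$avg, list(x), function(nd, g) {
    accum_grad_own(x, cpp_gap_gmp_backward(g, numeric(0), integer(0), d))
  })
  mx <- new_node(tape, r$max, list(x), function(nd, g) {
    accum_grad_own(x, cpp_gap_gmp_backward(numeric(0), g, r$wm, d))
  })
  list(avg = avg, max = mx)
}

av_gap <- function(tape, x) av_gap_gmp(tape, x)$avg
av_gmp <- function(tape, x) av_gap_gmp(tape, x)$max

# per-pixel mean and max over channels -> (H, W, N, 2)
av_channel_pool <- function(tape, x) {
  d <- dim(x$value)
  r <- cpp_channel_pool_forward(x$value)
  new_node(tape, r$y, list(x), function(nd, g) {
    accum_grad_own(x, cpp_channel_pool_backward(g, r$wm, d))
  })
}

# ---- shape ops --------------------------------------------------------------

# (H, W, N, C) -> (H*W*C, N) per-sample feature columns
av_flatten <- function(tape, x) {
  d <- dim(x$value)
  y <- matrix(aperm(x$value, c(1L, 2L, 4L, 3L)), prod(d[c(1, 2, 4)]), d[3])
  new_node(tape, y, list(x), function(nd, g) {
    gx <- aperm(array(g, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    accum_grad_own(x, gx)
  })
}

av_concat_c <- function(tape, x, y) {
  dx <- dim(x$value)
  dy <- dim(y$value)
  stopifnot(all(dx[1:3] == dy[1:3]))
  v <- cpp_concat_c(x$value, y$value)
  new_node(tape, v, list(x, y), function(nd, g) {
    nx <- prod(dx)
    accum_grad_own(x, array(g[seq_len(nx)], dx))
    accum_grad_own(y, array(g[nx + seq_len(prod(dy))], dy))
  })
}

# keep samples `idx` along the batch dim of an (H, W, N, C) array
av_slice_n <- function(tape, x, idx) {
  d <- dim(x$value)
  v <- cpp_slice_n_forward(x$value, as.integer(idx))
  new_node(tape, v, list(x), function(nd, g) {
    accum_grad_own(x, cpp_slice_n_backward(g, as.integer(idx), d[3]))
  })
}

# keep columns `idx` of a (D, N) matrix
av_slice_cols <- function(tape, x, idx) {
  d <- dim(x$value)
  v <- x$value[, idx, drop = FALSE]
  new_node(tape, v, list(x), function(nd, g) {
    gx <- matrix(0, d[1], d[2])
    gx[, idx] <- g
    accum_grad_own(x, gx)
  })
}

# ---- dense / dropout --------------------------------------------------------

# x: (Din, N); p$w: (Dout, Din); y: (Dout, N)
av_linear <- function(tape, x, p) {
  y <- p$w$value %*% x$value + p$b$value
  new_node(tape, y, list(x), function(nd, g) {
    accum_grad_own(x, crossprod(p$w$value, g))
    accum_pgrad(p$w, tcrossprod(g, x$value))
    accum_pgrad(p$b, rowSums(g))
  })
}

av_dropout <- function(tape, x, prob, training) {
  if (!training || prob <= 0) return(x)
  keep <- 1 - prob
  m <- (array(stats::runif(length(x$value)), dim(x$value)) < keep) / keep
  new_node(tape, x$value * m, list(x), function(nd, g) accum_grad_own(x, g * m))
}

# ---- resizing ---------------------------------------------------------------

# 1-D bilinear interpolation matrix (half-pixel centres), out_n x in_n
interp_matrix <- function(in_n, out_n) {
  key <- paste0(in_n, "_", out_n)
  if (!is.null(.interp_cache[[key]])) return(.interp_cache[[key]])
  scale <- in_n / out_n
  pos <- (seq_len(out_n) - 0.5) * scale + 0.5
  l <- floor(pos)
  frac <- pos - l
  frac[l < 1] <- 0
  l <- pmin(pmax(l, 1), in_n)
  l1 <- pmin(l + 1, in_n)
  M <- matrix(0, out_n, in_n)
  M[cbind(seq_len(out_n), l)] <- M[cbind(seq_len(out_n), l)] + (1 - frac)
  M[cbind(seq_len(out_n), l1)] <- M[cbind(seq_len(out_n), l1)] + frac
  .interp_cache[[key]] <- M
  M
}

.interp_cache <- new.env(parent = emptyenv())

# the same grid as interp_matrix() in sparse form (1-based lo/hi indices and
# the fractional weight on hi), consumed by the C++ resize kernels
interp_grid <- function(in_n, out_n) {
  key <- paste0("g", in_n, "_", out_n)
  if (!is.null(.interp_cache[[key]])) return(.interp_cache[[key]])
  scale <- in_n / out_n
  pos <- (seq_len(out_n) - 0.5) * scale + 0.5
  l <- floor(pos)
  frac <- pos - l
  frac[l < 1] <- 0
  l <- pmin(pmax(l, 1), in_n)
  gr <- list(lo = as.integer(l), hi = as.integer(pmin(l + 1, in_n)),
             fr = frac)
  .interp_cache[[key]] <- gr
  gr
}

# plain-array bilinear resize of (H, W, N, C) to (oh, ow)
resize_bilinear_array <- function(x, oh, ow) {
  d <- dim(x)
  gh <- interp_grid(d[1], oh)
  gw <- interp_grid(d[2], ow)
  cpp_resize_bilinear_forward(x, gh$lo, gh$hi, gh$fr, gw$lo, gw$hi, gw$fr)
}

av_resize_bilinear <- function(tape, x, oh, ow) {
  d <- dim(x$value)
  gh <- interp_grid(d[1], oh)
  gw <- interp_grid(d[2], ow)
  y <- cpp_resize_bilinear_forward(x$value, gh$lo, gh$hi, gh$fr,
                                   gw$lo, gw$hi, gw$fr)
  new_node(tape, y, list(x), function(nd, g) {
    accum_grad_own(x, cpp_resize_bilinear_backward(g, d[1], d[2],
                                               gh$lo, gh$hi, gh$fr,
                                               gw$lo, gw$hi, gw$fr))
  })
}

# ---- gradient reversal ------------------------------------------------------

av_grl <- function(tape, x, lambda) {
  if (lambda < 0) stop("grl: lambda must be non-negative", call. = FALSE)
  new_node(tape, x$value, list(x), function(nd, g) accum_grad_own(x, -lambda * g))
}

# ---- losses (scalar nodes) --------------------------------------------------

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# logits (K, N); labels integer 0..K-1
av_softmax_ce <- function(tape, logits, labels) {
  p <- softmax_cols(logits$value)
  n <- ncol(p)
  ii <- cbind(labels + 1L, seq_len(n))
  val <- -mean(log(pmax(p[ii], 1e-12)))
  new_node(tape, val, list(logits), function(nd, g) {
    gz <- p
    gz[ii] <- gz[ii] - 1
    accum_grad_own(logits, gz * (g / n))
  })
}

# S: (H, W, N, K) segmentation logits; mask: (H, W, N) in {0,1};
# weighted pixel CE normalised by the summed true-class weights.
av_weighted_seg_ce <- function(tape, S, mask, w) {
  d <- dim(S$value)
  M <- prod(d[1:3])
  z <- matrix(S$value, M, d[4])
  zmax <- pmax(z[, 1], z[, 2])
  lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
  yi <- as.integer(as.vector(mask))            # 0 background, 1 gland
  zt <- z[cbind(seq_len(M), yi + 1L)]
  wi <- w[yi + 1L]
  wsum <- sum(wi)
  val <- sum(wi * (lse - zt)) / wsum
  new_node(tape, val, list(S), function(nd, g) {
    p <- exp(z - lse)                           # softmax rows
    p[cbind(seq_len(M), yi + 1L)] <- p[cbind(seq_len(M), yi + 1L)] - 1
    accum_grad_own(S, array(p * (wi * g / wsum), d))
  })
}

# mean squared deviation of an attention map from the constant delta
av_mse_const <- function(tape, A, delta) {
  n <- length(A$value)
  val <- mean((A$value - delta)^2)
  new_node(tape, val, list(A), function(nd, g) {
    accum_grad_own(A, (2 / n) * (A$value - delta) * g)
  })
}

# homoscedastic-uncertainty weighting of a scalar loss node:
# exp(-s) / 2 * L + s, with s = log(sigma^2) a trainable parameter
av_uncertainty_weight <- function(tape, L, s_param) {
  s <- s_param$value
  val <- exp(-s) / 2 * L$value + s
  new_node(tape, val, list(L), function(nd, g) {
    accum_grad_own(L, g * exp(-s) / 2)
    accum_pgrad(s_param, g * (1 - exp(-s) / 2 * L$value))
  })
}

# weighted sum of scalar nodes with fixed coefficients
av_weighted_sum <- function(tape, nodes, coefs) {
  val <- sum(vapply(nodes, function(n) n$value, 0) * coefs)
  new_node(tape, val, nodes, function(nd, g) {
    for (i in seq_along(nodes)) accum_grad_own(nodes[[i]], g * coefs[i])
  })
}
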