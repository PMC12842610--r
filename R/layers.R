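# Trainable parameters and reusable network modules.
#
# A parameter is an environment with $value, $grad (same shape), $name and
# $group (one of "f", "seg", "cls", "dom", "loss") plus Adam moments $m, $v.
# A module is a list carrying its parameter environments and a forward
# closure; composite modules nest.

new_param <- function(name, dim, group, init = c("he", "zeros", "ones"),
                      fan_in = NULL) {
  init <- match.arg(init)
  n <- prod(dim)
  value <- switch(init,
    he = {
      if (is.null(fan_in)) fan_in <- if (length(dim) > 1) prod(dim[-length(dim)]) else dim
      stats::rnorm(n, sd = sqrt(2 / fan_in))
    },
    zeros = rep(0, n),
    ones = rep(1, n)
  )
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$group <- group
  # set dims in place rather than through array(), which would copy; the
  # wide heads alone hold ~100M values at full scale
  if (length(dim) > 1) dim(value) <- dim
  p$value <- value
  p$grad <- 0
  # Adam state ($m, $v) is allocated lazily on the first optimizer step so
  # that models built only for inspection or evaluation stay lean
  p
}

collect_params <- function(mod) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x) && !is.null(x$value) && !is.null(x$grad)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(mod)
  out
}

zero_grads <- function(params) {
  # scalar placeholder: the first accumulation adopts its (freshly computed)
  # increment outright, so no full-size zero buffer is ever allocated or
  # written; gown = FALSE releases last step's buffer for adoption anew
  for (p in params) {
    p$grad <- 0
    p$gown <- FALSE
  }
  invisible(NULL)
}

# ---- primitive layers -------------------------------------------------------

layer_conv <- function(name, k, cin, cout, stride = 1L, pad = NULL, group) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  mod <- list(
    kind = "conv", k = k, cin = cin, cout = cout, stride = stride, pad = pad,
    w = new_param(paste0(name, ".w"), c(k, k, cin, cout), group,
                  fan_in = k * k * cin),
    b = new_param(paste0(name, ".b"), cout, group, init = "zeros")
  )
  mod$forward <- function(tape, x, training) av_conv2d(tape, x, mod, mod$stride, mod$pad)
  mod
}

layer_convT <- function(name, k, cin, cout, group) {
  mod <- list(
    kind = "convT", k = k, cin = cin, cout = cout,
    w = new_param(paste0(name, ".w"), c(k, k, cout, cin), group,
                  fan_in = k * k * cin),
    b = new_param(paste0(name, ".b"), cout, group, init = "zeros")
  )
  mod$forward <- function(tape, x, training) av_convT2d(tape, x, mod, mod$k)
  mod
}

layer_bn <- function(name, c, group, momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, c)
  st$var <- rep(1, c)
  st$momentum <- momentum
  st$eps <- eps
  mod <- list(
    kind = "bn", c = c, state = st,
    gamma = new_param(paste0(name, ".gamma"), c, group, init = "ones"),
    beta = new_param(paste0(name, ".beta"), c, group, init = "zeros")
  )
  mod$forward <- function(tape, x, training, relu = FALSE) {
    av_bn2d(tape, x, mod$gamma, mod$beta, mod$state, training, relu)
  }
  mod
}

layer_linear <- function(name, din, dout, group) {
  mod <- list(
    kind = "linear", din = din, dout = dout,
    w = new_param(paste0(name, ".w"), c(dout, din), group, fan_in = din),
    b = new_param(paste0(name, ".b"), dout, group, init = "zeros")
  )
  mod$forward <- function(tape, x, training) av_linear(tape, x, mod)
  mod
}

# conv -> BN -> ReLU
block_cbr <- function(name, k, cin, cout, stride, group) {
  mod <- list(
    kind = "cbr",
    conv = layer_conv(paste0(name, ".conv"), k, cin, cout, stride, group = group),
    bn = layer_bn(paste0(name, ".bn"), cout, group)
  )
  mod$forward <- function(tape, x, training) {
    mod$bn$forward(tape, mod$conv$forward(tape, x, training), training,
                   relu = TRUE)
  }
  mod
}

# residual basic block (two 3x3 convs, identity or 1x1-projected shortcut)
block_residual <- function(name, cin, cout, stride, group) {
  mod <- list(
    kind = "residual",
    conv1 = layer_conv(paste0(name, ".conv1"), 3L, cin, cout, stride, group = group),
    bn1 = layer_bn(paste0(name, ".bn1"), cout, group),
    conv2 = layer_conv(paste0(name, ".conv2"), 3L, cout, cout, 1L, group = group),
    bn2 = layer_bn(paste0(name, ".bn2"), cout, group),
    proj = if (stride != 1L || cin != cout) {
      list(
        conv = layer_conv(paste0(name, ".proj.conv"), 1L, cin, cout, stride,
                          pad = 0L, group = group),
        bn = layer_bn(paste0(name, ".proj.bn"), cout, group)
      )
    }
  )
  mod$forward <- function(tape, x, training) {
    h <- mod$bn1$forward(tape, mod$conv1$forward(tape, x, training), training,
                         relu = TRUE)
    h <- mod$bn2$forward(tape, mod$conv2$forward(tape, h, training), training)
    sc <- if (is.null(mod$proj)) x else {
      mod$proj$bn$forward(tape, mod$proj$conv$forward(tape, x, training), training)
    }
    av_add_relu(tape, h, sc)
  }
  mod
}

# ---- CBAM: sequential channel then spatial attention -------------------------

module_cbam <- function(name, c, group, reduction = 16L, spatial_k = 7L) {
  hidden <- max(c %/% reduction, 4L)
  mod <- list(
    kind = "cbam", c = c,
    fc1 = layer_linear(paste0(name, ".fc1"), c, hidden, group),
    fc2 = layer_linear(paste0(name, ".fc2"), hidden, c, group),
    sconv = layer_conv(paste0(name, ".sconv"), spatial_k, 2L, 1L, group = group)
  )
  mlp <- function(tape, s) {
    # s: (N, C) node; shared bottleneck operates on (C, N) columns
    tr <- new_node(tape, t(s$value), list(s),
                   function(nd, g) accum_grad_own(s, t(g)))
    h <- av_relu(tape, mod$fc1$forward(tape, tr, FALSE))
    o <- mod$fc2$forward(tape, h, FALSE)
    new_node(tape, t(o$value), list(o), function(nd, g) accum_grad_own(o, t(g)))
  }
  mod$forward <- function(tape, x, training) {
    pools <- av_gap_gmp(tape, x)
    gate_c <- av_sigmoid(tape, av_add(tape,
      mlp(tape, pools$avg),
      mlp(tape, pools$max)))
    xc <- av_scale_channels(tape, x, gate_c)
    gate_s <- av_sigmoid(tape, mod$sconv$forward(
      tape, av_channel_pool(tape, xc), training))
    av_scale_spatial(tape, xc, gate_s)
  }
  mod
}

# identity stand-in used when CBAM is ablated
module_identity <- function() {
  list(kind = "identity", forward = function(tape, x, training) x)
}

# ---- classification / discrimination heads ----------------------------------

# fully connected head on flattened features; dropout between the first two
# fully connected layers (the reconstructed wide-head design)
module_head <- function(name, din, hidden, kout, dropout_p, group) {
  mod <- list(kind = "head", din = din, hidden = hidden, kout = kout,
              dropout_p = dropout_p, fcs = list())
  dims <- c(din, hidden, kout)
  for (i in seq_len(length(dims) - 1L)) {
    mod$fcs[[i]] <- layer_linear(paste0(name, ".fc", i), dims[i], dims[i + 1L], group)
  }
  mod$forward <- function(tape, x, training) {
    h <- x
    nfc <- length(mod$fcs)
    for (i in seq_len(nfc)) {
      h <- mod$fcs[[i]]$forward(tape, h, training)
      if (i < nfc) {
        h <- av_relu(tape, h)
        if (i == 1L && mod$dropout_p > 0) {
          h <- av_dropout(tape, h, mod$dropout_p, training)
        }
      }
    }
    h
  }
  mod
}

# ---- SGSA: attention map from segmentation logits ----------------------------

# A = sigmoid(conv1x1(relu(bn(conv3x3(S)))))
module_sgsa <- function(name, kseg, hidden = 8L, group = "f") {
  mod <- list(
    kind = "sgsa",
    conv3 = layer_conv(paste0(name, ".conv3"), 3L, kseg, hidden, group = group),
    bn = layer_bn(paste0(name, ".bn"), hidden, group),
    conv1 = layer_conv(paste0(name, ".conv1"), 1L, hidden, 1L, pad = 0L, group = group)
  )
  mod$forward <- function(tape, S, training) {
    h <- mod$bn$forward(tape, mod$conv3$forward(tape, S, training), training,
                        relu = TRUE)
    av_sigmoid(tape, mod$conv1$forward(tape, h, training))
  }
  mod
}
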