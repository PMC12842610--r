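# The network: shared extractor Gf (with CBAM), segmentation decoder Gseg,
# segmentation-guided spatial attention (SGSA), label predictor Gcls and
# domain discriminator Gdom behind a gradient reversal layer.

#' Model configuration
#'
#' Collects every architectural hyperparameter.  The `resnet18` backbone is
#' the deployment architecture (224x224 inputs, 512x7x7 shared features,
#' heads 512x7x7-2048-1024-K); the `tiny` backbone mirrors the same
#' stride/channel topology at a quarter of the width (64x64 inputs, 128x2x2
#' features) so that models train on a CPU in minutes, and is intended for
#' tests and small synthetic experiments only.
#'
#' @param backbone `"resnet18"` or `"tiny"`.
#' @param input_size input image side in pixels (default 224 for resnet18,
#'   64 for tiny).
#' @param pretrained load backbone weights from `weights_file` instead of
#'   random initialisation.
#' @param weights_file optional RDS file of named backbone parameter values.
#' @param k_cls,k_seg,k_dom output dimensions of the classifier (4 MGD
#'   grades), segmentation head (background/gland) and domain discriminator
#'   (source/target).
#' @param head_hidden hidden widths of the reconstructed wide heads
#'   (default `c(2048, 1024)` for resnet18, `c(512, 256)` for tiny).
#' @param shallow_head_hidden hidden width of the original shallow head used
#'   by the Baseline and DANN variants.
#' @param dropout_p dropout probability between the first two head layers.
#' @param cbam_stages encoder stages (1-4) after which CBAM is applied.
#' @param delta attention activation expectation for the consistency loss.
#' @param gamma steepness of the gradient-reversal weight schedule.
#' @param mu weight of the consistency loss.
#' @param omega segmentation class weights (background, gland).
#' @param use_dom,use_seg,use_cbam,use_sgsa,wide_head capability switches
#'   (see [build_variant()] for the named ablation ladder).
#' @param cons_mode `"pixel"`: mean squared deviation of every attention
#'   value from `delta`; `"spatial_mean"`: squared deviation of each map's
#'   spatial mean (both coincide on per-sample-constant maps).
#' @return a `adamnet_config` list.
#' @export
model_config <- function(backbone = c("resnet18", "tiny"),
                         input_size = NULL,
                         pretrained = FALSE,
                         weights_file = NULL,
                         k_cls = 4L, k_seg = 2L, k_dom = 2L,
                         head_hidden = NULL,
                         shallow_head_hidden = NULL,
                         dropout_p = 0.35,
                         cbam_stages = c(1L, 2L),
                         delta = 0.5, gamma = 8, mu = 0.1,
                         omega = c(0.4, 1.0),
                         use_dom = TRUE, use_seg = TRUE,
                         use_cbam = TRUE, use_sgsa = TRUE,
                         wide_head = TRUE,
                         cons_mode = c("pixel", "spatial_mean")) {
  backbone <- match.arg(backbone)
  cons_mode <- match.arg(cons_mode)
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  if (is.null(input_size)) input_size <- if (backbone == "resnet18") 224L else 64L
  if (is.null(head_hidden)) {
    head_hidden <- if (backbone == "resnet18") c(2048L, 1024L) else c(512L, 256L)
  }
  if (is.null(shallow_head_hidden)) {
    shallow_head_hidden <- if (backbone == "resnet18") 256L else 128L
  }
  structure(list(
    backbone = backbone, input_size = as.integer(input_size),
    pretrained = pretrained, weights_file = weights_file,
    k_cls = as.integer(k_cls), k_seg = as.integer(k_seg),
    k_dom = as.integer(k_dom),
    head_hidden = as.integer(head_hidden),
    shallow_head_hidden = as.integer(shallow_head_hidden),
    dropout_p = dropout_p, cbam_stages = as.integer(cbam_stages),
    delta = delta, gamma = gamma, mu = mu, omega = omega,
    use_dom = use_dom, use_seg = use_seg, use_cbam = use_cbam,
    use_sgsa = use_sgsa, wide_head = wide_head, cons_mode = cons_mode
  ), class = "adamnet_config")
}

backbone_spec <- function(backbone) {
  if (backbone == "resnet18") {
    list(stem = 64L, stages = c(64L, 128L, 256L, 512L), blocks = 2L)
  } else {
    list(stem = 16L, stages = c(16L, 32L, 64L, 128L), blocks = 1L)
  }
}

# ---- encoder -----------------------------------------------------------------

build_encoder <- function(cfg) {
  bs <- backbone_spec(cfg$backbone)
  enc <- list(kind = "encoder", spec = bs)
  enc$stem <- block_cbr("enc.stem", 7L, 3L, bs$stem, 2L, group = "f")
  enc$stages <- list()
  cin <- bs$stem
  for (s in 1:4) {
    stage <- list()
    for (b in seq_len(bs$blocks)) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      stage[[b]] <- block_residual(sprintf("enc.stage%d.block%d", s, b),
                                   cin, bs$stages[s], stride, group = "f")
      cin <- bs$stages[s]
    }
    enc$stages[[s]] <- stage
  }
  enc$cbam <- list()
  for (s in 1:4) {
    enc$cbam[[s]] <- if (cfg$use_cbam && s %in% cfg$cbam_stages) {
      module_cbam(sprintf("enc.cbam%d", s), bs$stages[s], group = "f")
    } else module_identity()
  }
  enc$forward <- function(tape, x, training) {
    h <- enc$stem$forward(tape, x, training)
    skips <- list(h)                               # stem output, pre-pool
    h <- av_maxpool(tape, h, 3L, 2L, 1L)
    for (s in 1:4) {
      for (blk in enc$stages[[s]]) h <- blk$forward(tape, h, training)
      h <- enc$cbam[[s]]$forward(tape, h, training)
      if (s < 4) skips[[s + 1L]] <- h
    }
    list(f = h, skips = skips)
  }
  enc
}

# ---- decoder -----------------------------------------------------------------

build_decoder <- function(cfg) {
  bs <- backbone_spec(cfg$backbone)
  # skip channels from shallow to deep: stem, stage1, stage2, stage3
  skip_ch <- c(bs$stem, bs$stages[1:3])
  # channel schedule: 512->256, 256->128, 128->64, 64->64 (resnet18 widths)
  outs <- c(bs$stages[3], bs$stages[2], bs$stages[1], bs$stages[1])
  ins <- c(bs$stages[4], outs[-4])
  dec <- list(kind = "decoder", outs = outs, blocks = list())
  for (i in 1:4) {
    skc <- rev(skip_ch)[i]
    blk <- list(
      up = layer_convT(sprintf("dec.block%d.up", i), 2L, ins[i], outs[i], group = "seg"),
      cbam = if (cfg$use_cbam) {
        module_cbam(sprintf("dec.block%d.cbam", i), outs[i] + skc, group = "seg")
      } else module_identity(),
      cbr1 = block_cbr(sprintf("dec.block%d.cbr1", i), 3L, outs[i] + skc, outs[i],
                       1L, group = "seg"),
      cbr2 = block_cbr(sprintf("dec.block%d.cbr2", i), 3L, outs[i], outs[i],
                       1L, group = "seg")
    )
    dec$blocks[[i]] <- blk
  }
  dec$final_conv3 <- layer_conv("dec.final.conv3", 3L, outs[4], outs[4], group = "seg")
  dec$final_conv1 <- layer_conv("dec.final.conv1", 1L, outs[4], cfg$k_seg,
                                pad = 0L, group = "seg")
  dec$forward <- function(tape, f, skips, training) {
    h <- f
    for (i in 1:4) {
      blk <- dec$blocks[[i]]
      h <- blk$up$forward(tape, h, training)
      sk <- skips[[5L - i]]
      if (!all(dim(h$value)[1:2] == dim(sk$value)[1:2])) {
        h <- av_resize_bilinear(tape, h, dim(sk$value)[1], dim(sk$value)[2])
      }
      h <- av_concat_c(tape, h, sk)
      h <- blk$cbam$forward(tape, h, training)
      h <- blk$cbr1$forward(tape, h, training)
      h <- blk$cbr2$forward(tape, h, training)
    }
    h <- av_resize_bilinear(tape, h, cfg$input_size, cfg$input_size)
    h <- av_relu(tape, dec$final_conv3$forward(tape, h, training))
    dec$final_conv1$forward(tape, h, training)
  }
  dec
}

# ---- full model --------------------------------------------------------------

#' Build the network
#'
#' Constructs the model described by a [model_config()]: shared encoder,
#' optional segmentation decoder with SGSA, classifier head and domain
#' discriminator head, plus the two trainable log-variances of the
#' uncertainty weighting.
#'
#' @param config a [model_config()].
#' @return an `adamnet_model` list with modules, parameters and config.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "adamnet_config"))
  bs <- backbone_spec(config$backbone)
  fmap_side <- config$input_size %/% 32L
  feat_dim <- bs$stages[4] * fmap_side^2
  m <- list(config = config, feat_dim = feat_dim, fmap_side = fmap_side)
  m$encoder <- build_encoder(config)
  if (config$use_seg) {
    m$decoder <- build_decoder(config)
    if (config$use_sgsa) m$sgsa <- module_sgsa("sgsa", config$k_seg, group = "f")
  }
  hidden <- if (config$wide_head) config$head_hidden else config$shallow_head_hidden
  drop_p <- if (config$wide_head) config$dropout_p else 0
  m$head_cls <- module_head("cls", feat_dim, hidden, config$k_cls, drop_p, "cls")
  if (config$use_dom) {
    m$head_dom <- module_head("dom", feat_dim, hidden, config$k_dom, drop_p, "dom")
  }
  m$s_cls <- new_param("loss.s_cls", 1L, "loss", init = "zeros")
  m$s_seg <- new_param("loss.s_seg", 1L, "loss", init = "zeros")
  m$params <- collect_params(m[c("encoder", "decoder", "sgsa",
                                 "head_cls", "head_dom")])
  m$params <- c(m$params, list(m$s_cls, m$s_seg))
  class(m) <- "adamnet_model"
  if (isTRUE(config$pretrained)) {
    if (is.null(config$weights_file)) {
      stop("pretrained = TRUE requires `weights_file`; ",
           "set pretrained = FALSE for random initialisation", call. = FALSE)
    }
    load_param_values(m, readRDS(config$weights_file), partial = TRUE)
  }
  m
}

#' Forward pass
#'
#' Runs a preprocessed batch through the network and returns every
#' intermediate the losses need.  Input layout is `(H, W, N, 3)`.
#'
#' @param model an `adamnet_model`.
#' @param x numeric array `(H, W, N, 3)`.
#' @param training logical; enables dropout and batch statistics.
#' @param lambda gradient-reversal weight in `[0, 1)`.
#' @param tape optionally, an existing tape to record onto.
#' @return list with `tape` and nodes `f`, `skips`, `seg_logits`,
#'   `attention`, `fprime`, `cls_logits`, `dom_logits` (absent components
#'   are `NULL`).
#' @export
model_forward <- function(model, x, training = FALSE, lambda = 0,
                          tape = NULL) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != 3L ||
      d[1] != model$config$input_size || d[2] != model$config$input_size) {
    stop(sprintf("expected input (H, W, N, 3) with H = W = %d, got (%s)",
                 model$config$input_size, paste(d, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(tape)) tape <- tape_new()
  xin <- av_input(tape, x)
  xin$no_grad <- TRUE   # the stem conv can skip its data gradient
  enc <- model$encoder$forward(tape, xin, training)
  f <- enc$f
  out <- list(tape = tape, input = xin, f = f, skips = enc$skips,
              seg_logits = NULL, attention = NULL, dom_logits = NULL)
  fprime <- f
  if (!is.null(model$decoder)) {
    out$seg_logits <- model$decoder$forward(tape, f, enc$skips, training)
    if (!is.null(model$sgsa)) {
      out$attention <- model$sgsa$forward(tape, out$seg_logits, training)
      a_small <- av_resize_bilinear(tape, out$attention,
                                    dim(f$value)[1], dim(f$value)[2])
      fprime <- av_scale_spatial(tape, f, a_small)
    }
  }
  out$fprime <- fprime
  z <- av_flatten(tape, fprime)
  out$cls_logits <- model$head_cls$forward(tape, z, training)
  if (!is.null(model$head_dom)) {
    zr <- av_flatten(tape, av_grl(tape, fprime, lambda))
    out$dom_logits <- model$head_dom$forward(tape, zr, training)
  }
  out
}

# ---- parameter groups / inspection -------------------------------------------

#' Parameter groups
#'
#' Returns the trainable parameters split into the disjoint groups
#' theta_f (encoder, CBAM and SGSA), theta_seg (decoder), theta_cls,
#' theta_dom and the loss log-variances.
#'
#' @param model an `adamnet_model`.
#' @return named list of lists of parameter environments.
#' @export
param_groups <- function(model) {
  groups <- list(f = list(), seg = list(), cls = list(), dom = list(),
                 loss = list())
  for (p in model$params) groups[[p$group]] <- c(groups[[p$group]], list(p))
  groups
}

n_params <- function(plist) sum(vapply(plist, function(p) length(p$value), 0))

#' Architecture summary
#'
#' Machine-checkable structural description: decoder block count and channel
#' schedule, head layer widths, dropout placement, segmentation channels.
#'
#' @param model an `adamnet_model`.
#' @return a list of structural facts.
#' @export
inspect_model <- function(model) {
  cfg <- model$config
  head_dims <- function(head) {
    if (is.null(head)) return(NULL)
    list(widths = as.integer(c(head$din,
                               vapply(head$fcs, function(fc) fc$dout, 0))),
         dropout_p = head$dropout_p,
         dropout_between_fc = c(1L, 2L))
  }
  gr <- param_groups(model)
  list(
    backbone = cfg$backbone,
    input_size = cfg$input_size,
    feature_shape = c(backbone_spec(cfg$backbone)$stages[4],
                      model$fmap_side, model$fmap_side),
    decoder_blocks = if (is.null(model$decoder)) 0L else length(model$decoder$blocks),
    decoder_out_channels = if (is.null(model$decoder)) integer(0) else model$decoder$outs,
    k_seg = if (is.null(model$decoder)) NA_integer_ else cfg$k_seg,
    seg_resolution = if (is.null(model$decoder)) NA_integer_ else cfg$input_size,
    has_sgsa = !is.null(model$sgsa),
    has_domain_head = !is.null(model$head_dom),
    has_cbam = cfg$use_cbam,
    head_cls = head_dims(model$head_cls),
    head_dom = head_dims(model$head_dom),
    n_params = vapply(gr, n_params, 0)
  )
}

#' @export
print.adamnet_model <- function(x, ...) {
  info <- inspect_model(x)
  cat(sprintf("<adamnet_model> backbone=%s input=%dpx\n", info$backbone,
              info$input_size))
  cat(sprintf("  features: %s\n", paste(info$feature_shape, collapse = "x")))
  if (info$decoder_blocks > 0) {
    cat(sprintf("  decoder: %d blocks, out channels (%s), Kseg=%d at %dpx\n",
                info$decoder_blocks,
                paste(info$decoder_out_channels, collapse = ", "),
                info$k_seg, info$seg_resolution))
  }
  cat(sprintf("  SGSA: %s  CBAM: %s  domain head: %s\n",
              info$has_sgsa, info$has_cbam, info$has_domain_head))
  cat(sprintf("  classifier: %s (dropout %.2f)\n",
              paste(info$head_cls$widths, collapse = "-"),
              info$head_cls$dropout_p))
  if (!is.null(info$head_dom)) {
    cat(sprintf("  discriminator: %s (dropout %.2f)\n",
                paste(info$head_dom$widths, collapse = "-"),
                info$head_dom$dropout_p))
  }
  cat(sprintf("  params: %s\n", paste(sprintf("%s=%d", names(info$n_params),
                                              info$n_params), collapse = " ")))
  invisible(x)
}

# ---- checkpointing -----------------------------------------------------------

collect_bn_states <- function(mod) {
  out <- list()
  # iterate by position: module containers (stage/block lists) are unnamed,
  # so walking names() would stop at the first unnamed level
  walk <- function(x) {
    if (is.list(x)) {
      if (identical(x$kind, "bn")) {
        out[[x$gamma$name]] <<- list(mean = x$state$mean, var = x$state$var)
      } else {
        for (el in x) if (is.list(el)) walk(el)
      }
    }
  }
  walk(mod)
  out
}

restore_bn_states <- function(mod, states) {
  walk <- function(x) {
    if (is.list(x)) {
      if (identical(x$kind, "bn")) {
        st <- states[[x$gamma$name]]
        if (!is.null(st)) {
          x$state$mean <- st$mean
          x$state$var <- st$var
        }
      } else {
        for (el in x) if (is.list(el)) walk(el)
      }
    }
  }
  walk(mod)
  invisible(NULL)
}

load_param_values <- function(model, values, partial = FALSE) {
  for (p in model$params) {
    v <- values[[p$name]]
    if (is.null(v)) {
      if (partial) next
      stop("checkpoint is missing parameter ", p$name, call. = FALSE)
    }
    if (length(v) != length(p$value)) {
      stop("checkpoint shape mismatch for ", p$name, call. = FALSE)
    }
    p$value <- if (is.array(p$value)) array(v, dim(p$value)) else as.numeric(v)
  }
  invisible(model)
}

#' Save / load model checkpoints
#'
#' Checkpoints store the configuration, every parameter group and the batch
#' normalisation running statistics; loading rebuilds the model and restores
#' an identical evaluation state.
#'
#' @param model an `adamnet_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  values <- stats::setNames(
    lapply(model$params, function(p) p$value),
    vapply(model$params, function(p) p$name, "")
  )
  obj <- list(format = "adamnet_checkpoint", version = 1L,
              config = model$config, params = values,
              bn = collect_bn_states(model[c("encoder", "decoder", "sgsa",
                                             "head_cls", "head_dom")]))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adamnet_checkpoint")) {
    stop("not an adamnet checkpoint: ", path, call. = FALSE)
  }
  cfg <- obj$config
  cfg$pretrained <- FALSE        # weights come from the checkpoint itself
  model <- build_model(cfg)
  load_param_values(model, obj$params)
  restore_bn_states(model[c("encoder", "decoder", "sgsa", "head_cls",
                            "head_dom")], obj$bn)
  model
}

#' Ablation-ladder variant factory
#'
#' Builds one of the six named model variants:
#' `"Baseline"` (source-only classifier, shallow head),
#' `"DANN"` (adds the domain discriminator and gradient reversal),
#' `"DANN-Head"` (widened heads `512x7x7-2048-1024-K`),
#' `"DANN-Head+Seg"` (adds the segmentation decoder with uncertainty
#' weighting), `"DANN-Head+Seg+CBAM"` (adds CBAM in encoder and decoder),
#' `"ADAM-Net"` (adds SGSA and the consistency loss).
#'
#' @param name variant name.
#' @param config base [model_config()]; capability flags are overridden.
#' @return an `adamnet_model`.
#' @export
build_variant <- function(name, config = model_config()) {
  ladder <- c("Baseline", "DANN", "DANN-Head", "DANN-Head+Seg",
              "DANN-Head+Seg+CBAM", "ADAM-Net")
  if (!name %in% ladder) {
    stop("unknown variant '", name, "'; valid names: ",
         paste(ladder, collapse = ", "), call. = FALSE)
  }
  i <- match(name, ladder)
  config$use_dom <- i >= 2L
  config$wide_head <- i >= 3L
  config$use_seg <- i >= 4L
  config$use_cbam <- i >= 5L
  config$use_sgsa <- i >= 6L
  if (!config$use_sgsa) config$mu <- 0
  build_model(config)
}
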