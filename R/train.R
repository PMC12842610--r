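# Adversarial multi-task training: per-iteration source+target batch pairing,
# gradient reversal with the sigmoid lambda schedule, uncertainty-weighted
# task losses, Adam, validation-based checkpoint selection, and the
# multi-seed protocol.

#' Training configuration
#'
#' Defaults follow the deployment recipe: Adam with learning rate `1e-4`,
#' batch size 16, 200 epochs (scale `epochs` down for small experiments),
#' `gamma = 8`, `mu = 0.1`.
#'
#' @param source_manifest,target_manifest manifests (or CSV paths); the
#'   source provides grades and masks, the target provides images only --
#'   target labels, if present, are never read during training.
#' @param variant ablation-ladder variant name (see [build_variant()]).
#' @param backbone,input_size passed to [model_config()].
#' @param learning_rate,batch_size,epochs optimizer settings.
#' @param gamma,mu,delta schedule steepness, consistency weight, attention
#'   expectation.
#' @param seeds seed set for [multi_seed_run()].
#' @param source_ratios,target_ratios split ratios for the two domains.
#' @param selection `"best_val"` keeps the checkpoint with the best
#'   source-validation accuracy; `"last"` keeps the final epoch.
#' @param merge_retrain after selection, merge train and validation sets and
#'   retrain for the same number of epochs (final-phase flag).
#' @param out_dir optional directory for checkpoints and training logs.
#' @param pretrained,weights_file backbone initialisation (see
#'   [model_config()]).
#' @return a `train_config` list.
#' @export
train_config <- function(source_manifest, target_manifest = NULL,
                         variant = "ADAM-Net",
                         backbone = "resnet18", input_size = NULL,
                         learning_rate = 1e-4, batch_size = 16L,
                         epochs = 200L, gamma = 8, mu = 0.1, delta = 0.5,
                         seeds = c(42L, 7L, 123L, 999L, 2023L),
                         source_ratios = c(0.7, 0.1, 0.2),
                         target_ratios = c(0.6, 0.1, 0.3),
                         selection = c("best_val", "last"),
                         merge_retrain = FALSE,
                         out_dir = NULL,
                         pretrained = FALSE, weights_file = NULL) {
  structure(list(source_manifest = source_manifest,
                 target_manifest = target_manifest, variant = variant,
                 backbone = backbone, input_size = input_size,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), gamma = gamma, mu = mu,
                 delta = delta, seeds = as.integer(seeds),
                 source_ratios = source_ratios, target_ratios = target_ratios,
                 selection = match.arg(selection),
                 merge_retrain = merge_retrain, out_dir = out_dir,
                 pretrained = pretrained, weights_file = weights_file),
            class = "train_config")
}

# ---- Adam --------------------------------------------------------------------

# fused bias-corrected update; mutates $value, $m and $v in place, so any
# snapshot of parameter values must be a deep copy (see snapshot_params)
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (t == 1L) {
    # `* 0` forces distinct allocations: the in-place update must never let
    # $m or $v alias $grad or each other
    for (p in params) {
      if (is.null(p$m)) {
        p$m <- p$grad * 0
        p$v <- p$grad * 0
      }
    }
  }
  cpp_adam_step(params, lr, t, beta1, beta2, eps)
  invisible(NULL)
}

# ---- data loading ------------------------------------------------------------

# preload a manifest: preprocessed (H,W,3) arrays, aligned masks, grades
preload_records <- function(manifest, size, with_masks) {
  n <- nrow(manifest)
  imgs <- vector("list", n)
  masks <- if (with_masks) vector("list", n)
  for (i in seq_len(n)) {
    img <- load_image(resolve_path(manifest, manifest$path[i]))
    msk <- if (with_masks && nzchar(manifest$mask_path[i])) {
      load_mask(resolve_path(manifest, manifest$mask_path[i]))
    }
    aug <- augment(img, msk, manifest$augment[i],
                   rng_seed = unit_hash(paste0(manifest$path[i], "#",
                                               manifest$augment[i])))
    imgs[[i]] <- preprocess(aug$image, size)
    if (with_masks) {
      masks[[i]] <- if (!is.null(aug$mask)) {
        resize_matrix(aug$mask, size, size, "nearest")
      }
    }
  }
  list(images = imgs, masks = masks, grades = manifest$grade)
}

batch_accuracy <- function(model, data, batch_size = 32L) {
  n <- length(data$images)
  if (n == 0L) return(NA_real_)
  correct <- 0L
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out <- model_forward(model, stack_batch(data$images[idx]),
                         training = FALSE, lambda = 0)
    correct <- correct + sum(max.col(t(out$cls_logits$value)) - 1L ==
                               data$grades[idx])
  }
  correct / n
}

snapshot_params <- function(model) {
  # `p$value + 0` forces a copy: the in-place Adam update would otherwise
  # keep mutating the snapshotted arrays through the shared reference
  list(values = lapply(model$params, function(p) p$value + 0),
       bn = collect_bn_states(model[c("encoder", "decoder", "sgsa",
                                      "head_cls", "head_dom")]))
}

restore_params <- function(model, snap) {
  for (i in seq_along(model$params)) model$params[[i]]$value <- snap$values[[i]]
  restore_bn_states(model[c("encoder", "decoder", "sgsa", "head_cls",
                            "head_dom")], snap$bn)
  invisible(model)
}

# ---- training loop -----------------------------------------------------------

#' Train a model
#'
#' Splits both domains (unit-stratified, leakage-free), strips target-domain
#' labels, oversamples source minority grades, and runs adversarial
#' multi-task training: each iteration pairs a source batch with a target
#' batch (the smaller pool is resampled with replacement), computes the
#' classification and segmentation losses on source samples only, the domain
#' loss on the mixed batch through the gradient reversal layer with
#' `lambda = grl_lambda(p, gamma)`, and the attention consistency loss on
#' all attention maps, then takes one Adam step on the joint objective.
#'
#' @param config a [train_config()].
#' @param seed integer seed; the run is fully deterministic given the seed.
#' @param verbose print per-epoch progress.
#' @return a `train_result` list: `model`, `log` (per-iteration loss
#'   bundle), `val_accuracy` trajectory, `best_val_accuracy`, the held-out
#'   `splits`, `seed`, and `checkpoint` path when `out_dir` is set.
#' @export
train <- function(config, seed = 42L, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  set.seed(seed)
  src_man <- config$source_manifest
  if (is.character(src_man)) src_man <- read_manifest(src_man)
  src_split <- stratified_unit_split(src_man, split_spec(config$source_ratios,
                                                         seed = seed))
  tgt_split <- NULL
  mcfg <- model_config(
    backbone = config$backbone, input_size = config$input_size,
    pretrained = config$pretrained, weights_file = config$weights_file,
    delta = config$delta, gamma = config$gamma, mu = config$mu)
  model <- build_variant(config$variant, mcfg)
  needs_target <- !is.null(model$head_dom)
  if (needs_target) {
    if (is.null(config$target_manifest)) {
      stop("variant '", config$variant, "' needs a target manifest",
           call. = FALSE)
    }
    tgt_man <- config$target_manifest
    if (is.character(tgt_man)) tgt_man <- read_manifest(tgt_man)
    # stratify = FALSE: the target partition must not depend on target
    # labels, which an unsupervised method is not allowed to see
    tgt_split <- stratified_unit_split(tgt_man,
                                       split_spec(config$target_ratios,
                                                  seed = seed + 1L),
                                       stratify = FALSE)
    # UDA guard: target grade labels are discarded before any training code
    # can touch them; only images flow into the loop below.
    tgt_split$train$grade <- NA_integer_
    tgt_split$train$mask_path <- ""
  }
  src_train <- oversample_minority(src_split$train, seed = seed + 2L)
  size <- model$config$input_size
  use_seg <- !is.null(model$decoder)
  src <- preload_records(src_train, size, with_masks = use_seg)
  if (use_seg && any(vapply(src$masks, is.null, TRUE))) {
    stop("source training records must provide masks for variant '",
         config$variant, "'", call. = FALSE)
  }
  tgt <- if (needs_target) preload_records(tgt_split$train, size, FALSE)
  val <- preload_records(src_split$val, size, FALSE)

  # Train-time stochastic augmentation: mirror flips are label-preserving for
  # phantoms (grade and dropout fraction are orientation-invariant) and are
  # applied identically to the image and its mask.  Draws from the seeded
  # global RNG, so runs stay deterministic per seed.
  rand_flip <- function(img, mask = NULL) {
    if (stats::runif(1) < 0.5) {
      img <- img[, dim(img)[2]:1, , drop = FALSE]
      if (!is.null(mask)) mask <- mask[, ncol(mask):1, drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {
      img <- img[dim(img)[1]:1, , , drop = FALSE]
      if (!is.null(mask)) mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    # random translation up to ~10% of the side, edge-replicated; the mask
    # shifts with the image so segmentation stays aligned
    d <- dim(img)
    sh <- c(sample(-6:6, 1), sample(-6:6, 1))
    if (any(sh != 0L)) {
      ri <- pmin(pmax(seq_len(d[1]) + sh[1], 1L), d[1])
      ci <- pmin(pmax(seq_len(d[2]) + sh[2], 1L), d[2])
      img <- img[ri, ci, , drop = FALSE]
      if (!is.null(mask)) mask <- mask[ri, ci, drop = FALSE]
    }
    list(image = img, mask = mask)
  }

  run_phase <- function(src, epochs) {
    n_src <- length(src$images)
    bs <- config$batch_size
    iters_per_epoch <- ceiling(n_src / bs)
    total_iters <- epochs * iters_per_epoch
    log <- vector("list", total_iters)
    it <- 0L
    t_adam <- 0L
    best <- list(acc = -Inf, snap = NULL)
    val_acc <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n_src)
      for (b in seq_len(iters_per_epoch)) {
        it <- it + 1L
        p <- (it - 1L) / max(total_iters - 1L, 1L)
        lambda <- grl_lambda(p, config$gamma)
        si <- ord[((b - 1L) * bs + 1L):min(b * bs, n_src)]
        ns <- length(si)
        sa <- lapply(si, function(i) {
          rand_flip(src$images[[i]], if (use_seg) src$masks[[i]])
        })
        simgs <- lapply(sa, `[[`, "image")
        if (needs_target) {
          ti <- if (length(tgt$images) >= ns) sample.int(length(tgt$images), ns)
                else sample.int(length(tgt$images), ns, replace = TRUE)
          timgs <- lapply(tgt$images[ti], function(im) rand_flip(im)$image)
          x <- stack_batch(c(simgs, timgs))
          domains <- c(rep(0L, ns), rep(1L, length(ti)))
        } else {
          x <- stack_batch(simgs)
          domains <- rep(0L, ns)
        }
        out <- model_forward(model, x, training = TRUE, lambda = lambda)
        tape <- out$tape
        src_idx <- seq_len(ns)
        terms <- list()
        coefs <- numeric(0)
        l_cls_node <- av_softmax_ce(
          tape, av_slice_cols(tape, out$cls_logits, src_idx),
          src$grades[si])
        l_seg_node <- l_dom_node <- l_cons_node <- NULL
        if (use_seg) {
          mask_arr <- array(unlist(lapply(sa, `[[`, "mask")),
                            c(size, size, ns))
          l_seg_node <- av_weighted_seg_ce(
            tape, av_slice_n(tape, out$seg_logits, src_idx), mask_arr,
            model$config$omega)
        }
        if (!is.null(out$attention)) {
          cons_in <- if (model$config$cons_mode == "spatial_mean") {
            av_gap(tape, out$attention)
          } else out$attention
          l_cons_node <- av_mse_const(tape, cons_in, config$delta)
        }
        if (needs_target) {
          l_dom_node <- av_softmax_ce(tape, out$dom_logits, domains)
        }
        terms <- list(av_uncertainty_weight(tape, l_cls_node, model$s_cls))
        coefs <- 1
        if (use_seg) {
          terms <- c(terms, list(av_uncertainty_weight(tape, l_seg_node,
                                                       model$s_seg)))
          coefs <- c(coefs, 1)
        }
        if (needs_target) {
          terms <- c(terms, list(l_dom_node))
          coefs <- c(coefs, 1)
        }
        if (!is.null(l_cons_node)) {
          terms <- c(terms, list(l_cons_node))
          coefs <- c(coefs, config$mu)
        }
        total <- av_weighted_sum(tape, terms, coefs)
        if (!is.finite(total$value)) {
          stop(sprintf(
            paste0("non-finite loss at iteration %d: Lcls=%g Lseg=%g ",
                   "Ldom=%g Lcons=%g"),
            it, l_cls_node$value,
            if (use_seg) l_seg_node$value else NA,
            if (needs_target) l_dom_node$value else NA,
            if (!is.null(l_cons_node)) l_cons_node$value else NA),
            call. = FALSE)
        }
        zero_grads(model$params)
        tape_backward(tape, total)
        t_adam <- t_adam + 1L
        adam_step(model$params, config$learning_rate, t_adam)
        log[[it]] <- data.frame(
          iter = it,
          Lcls = l_cls_node$value,
          Lseg = if (use_seg) l_seg_node$value else NA_real_,
          Ldom = if (needs_target) l_dom_node$value else NA_real_,
          Lcons = if (!is.null(l_cons_node)) l_cons_node$value else NA_real_,
          lambda = lambda,
          s_cls = model$s_cls$value,
          s_seg = model$s_seg$value,
          Ltotal = total$value)
      }
      val_acc[epoch] <- batch_accuracy(model, val)
      if (!is.na(val_acc[epoch]) && val_acc[epoch] >= best$acc) {
        best <- list(acc = val_acc[epoch], snap = snapshot_params(model))
      }
      if (verbose) {
        message(sprintf("epoch %d/%d  Ltotal %.4f  val acc %.3f",
                        epoch, epochs, log[[it]]$Ltotal, val_acc[epoch]))
      }
    }
    list(log = do.call(rbind, log), val_acc = val_acc, best = best)
  }

  phase <- run_phase(src, config$epochs)
  if (config$selection == "best_val" && !is.null(phase$best$snap)) {
    restore_params(model, phase$best$snap)
  }
  if (isTRUE(config$merge_retrain)) {
    merged <- rbind(as.data.frame(src_split$train), as.data.frame(src_split$val))
    attr(merged, "root") <- manifest_root(src_man)
    attr(merged, "role") <- "train"
    class(merged) <- class(src_man)
    merged <- oversample_minority(merged, seed = seed + 3L)
    src2 <- preload_records(merged, size, with_masks = use_seg)
    model2 <- build_variant(config$variant, mcfg)
    # reuse the same loop with the merged pool; last-epoch weights are kept
    model <- model2
    phase2 <- run_phase(src2, config$epochs)
    phase$log <- rbind(phase$log, phase2$log)
  }
  res <- list(model = model, log = phase$log, val_accuracy = phase$val_acc,
              best_val_accuracy = phase$best$acc,
              splits = list(source = src_split, target = tgt_split),
              seed = seed, config = config, checkpoint = NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    ck <- file.path(config$out_dir, sprintf("%s_seed%d.rds",
                                            gsub("[^A-Za-z0-9]+", "_",
                                                 config$variant), seed))
    save_checkpoint(model, ck)
    utils::write.csv(phase$log,
                     file.path(config$out_dir,
                               sprintf("train_log_seed%d.csv", seed)),
                     row.names = FALSE)
    res$checkpoint <- ck
  }
  class(res) <- "train_result"
  res
}

#' Multi-seed protocol
#'
#' For each seed: re-split the units, re-initialise the model, retrain and
#' evaluate on the held-out source and target test sets; randomness across
#' seeds is limited to the stratified unit partitioning, parameter
#' initialisation and data loading order.  Aggregates are reported as
#' mean and standard deviation per metric.
#'
#' @param config a [train_config()].
#' @param seeds integer seeds (default from the config); at least 2.
#' @param verbose print progress.
#' @return a `multi_seed_result` with `per_seed` reports, `mean`, `sd`.
#' @export
multi_seed_run <- function(config, seeds = config$seeds, verbose = FALSE) {
  if (length(seeds) < 2L) stop("need at least two seeds", call. = FALSE)
  per_seed <- lapply(seeds, function(s) {
    fit <- train(config, seed = s, verbose = verbose)
    rep_src <- evaluate(fit$model, fit$splits$source$test)
    rep_tgt <- if (!is.null(fit$splits$target)) {
      evaluate(fit$model, fit$splits$target$test)
    }
    list(seed = s, fit = fit, source = rep_src, target = rep_tgt)
  })
  metric_names <- c("accuracy", "precision", "recall", "f1", "mcc")
  agg <- function(domain) {
    vals <- vapply(per_seed, function(r) {
      rp <- r[[domain]]
      if (is.null(rp)) rep(NA_real_, length(metric_names))
      else vapply(metric_names, function(m) rp[[m]], 0)
    }, numeric(length(metric_names)))
    vals <- matrix(vals, nrow = length(metric_names),
                   dimnames = list(metric_names, NULL))
    list(mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd))
  }
  structure(list(per_seed = per_seed,
                 source = agg("source"),
                 target = if (!is.null(per_seed[[1]]$target)) agg("target"),
                 seeds = seeds),
            class = "multi_seed_result")
}
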