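# Qualitative analysis: t-SNE embeddings of the shared feature space and
# Grad-CAM class activation maps.

#' t-SNE embedding of feature vectors
#'
#' Exact (non-approximated) t-SNE, suitable for the few hundred samples of a
#' feature-alignment figure: per-point Gaussian bandwidths found by binary
#' search on the perplexity, symmetrized affinities, Student-t
#' low-dimensional kernel, gradient descent with momentum and early
#' exaggeration.
#'
#' @param x numeric matrix, one row per sample.
#' @param perplexity target perplexity (must satisfy `3 * perplexity < n`).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the initial layout.
#' @return `(n, 2)` matrix of embedding coordinates.
#' @export
embed_tsne <- function(x, perplexity = 30, n_iter = 500L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (3 * perplexity >= n) {
    stop("perplexity too large: need 3 * perplexity < n", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  log_perp <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { h <- 0; p[] <- 1 / length(p) } else {
        p <- p / sp
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - log_perp) < 1e-5) break
      if (h > log_perp) {                      # entropy too high -> narrow
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exag <- 12
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exag else P
    yd2 <- as.matrix(stats::dist(y))^2
    W <- 1 / (1 + yd2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (Pe - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    mom <- if (it <= 250) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain <- pmax(gain, 0.01)
    inc <- mom * inc - 200 * gain * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  y
}

#' Domain-alignment embedding of a trained model
#'
#' Extracts the shared (attention-reweighted) feature vectors of two
#' manifests and embeds them jointly with [embed_tsne()].
#'
#' @param model an `adamnet_model` or checkpoint path.
#' @param manifests named list of manifests (typically
#'   `list(source = ..., target = ...)`).
#' @param perplexity,n_iter,seed passed to [embed_tsne()].
#' @return data frame with `x`, `y`, `domain`, `grade`.
#' @export
embed_features <- function(model, manifests, perplexity = 30,
                           n_iter = 500L, seed = 1L) {
  if (is.character(model)) model <- load_checkpoint(model)
  feats <- list(); doms <- list(); grades <- list()
  for (nm in names(manifests)) {
    man <- manifests[[nm]]
    if (is.character(man)) man <- read_manifest(man)
    pr <- predict_manifest(model, man, collect_features = TRUE)
    feats[[nm]] <- pr$features
    doms[[nm]] <- rep(nm, nrow(man))
    grades[[nm]] <- man$grade
  }
  emb <- embed_tsne(do.call(rbind, feats), perplexity, n_iter, seed)
  data.frame(x = emb[, 1], y = emb[, 2],
             domain = unlist(doms, use.names = FALSE),
             grade = unlist(grades, use.names = FALSE))
}

#' Grad-CAM class activation map
#'
#' Backpropagates a class logit to the shared feature map, weights each
#' channel by the spatial mean of its gradient, rectifies the weighted sum
#' and normalizes by the maximum; the map is bilinearly upsampled to input
#' resolution.
#'
#' @param model an `adamnet_model` or checkpoint path.
#' @param image `(H, W)` grayscale matrix in `[0, 1]` or a PNG path.
#' @param class target class `0..K-1`; default: the predicted class.
#' @return list with `cam` (`input_size x input_size` map in `[0, 1]`),
#'   `class` and `logits`.
#' @export
gradcam <- function(model, image, class = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(image)) image <- load_image(image)
  x <- stack_batch(list(preprocess(image, model$config$input_size)))
  out <- model_forward(model, x, training = FALSE, lambda = 0)
  logits <- as.vector(out$cls_logits$value)
  if (is.null(class)) class <- which.max(logits) - 1L
  tape <- out$tape
  target <- new_node(tape, logits[class + 1L], list(out$cls_logits),
                     function(nd, g) {
                       gz <- matrix(0, length(logits), 1L)
                       gz[class + 1L, 1L] <- g
                       accum_grad(out$cls_logits, gz)
                     })
  tape_backward(tape, target)
  f <- out$f$value                     # (h, w, 1, C)
  gf <- out$f$grad
  d <- dim(f)
  w <- colMeans(matrix(gf, d[1] * d[2], d[4]))
  cam <- matrix(matrix(f, d[1] * d[2], d[4]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  cam <- resize_bilinear_array(array(cam, c(d[1], d[2], 1L, 1L)),
                               model$config$input_size,
                               model$config$input_size)[, , 1, 1]
  list(cam = cam, class = class, logits = logits)
}
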