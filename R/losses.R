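# Training-time mathematics: the four task losses, the gradient-reversal
# weight schedule and the homoscedastic-uncertainty weighting.
#
# These are the reference numeric implementations used by the public API and
# the evaluation code; the tape ops in autodiff.R compute the same quantities
# with gradients during training.

#' Gradient-reversal weight schedule
#'
#' The adversarial weight follows `lambda(p) = 2 / (1 + exp(-gamma * p)) - 1`,
#' rising monotonically from 0 at the start of training towards 1, so the
#' domain-discrimination signal is introduced gradually.
#'
#' @param p training progress in `[0, 1]` (completed / total iterations).
#' @param gamma steepness, `> 0`; 8 by default (grid-searched value).
#' @return lambda in `[0, 1)`.
#' @examples
#' grl_lambda(0, 8)    # 0
#' grl_lambda(1, 8)    # 0.99933
#' @export
grl_lambda <- function(p, gamma = 8) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  2 / (1 + exp(-gamma * p)) - 1
}

#' Classification loss
#'
#' Mean cross-entropy of grade logits against integer grade labels, applied
#' to source-domain samples only during training.
#'
#' @param logits `(K, N)` matrix of class logits (one column per sample).
#' @param labels integer vector in `0..K-1`.
#' @return non-negative scalar.
#' @export
cls_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  k <- nrow(logits)
  if (any(labels < 0 | labels >= k)) {
    stop("labels must lie in 0..", k - 1, call. = FALSE)
  }
  p <- softmax_cols(logits)
  -mean(log(pmax(p[cbind(labels + 1L, seq_len(ncol(p)))], 1e-12)))
}

#' Segmentation loss
#'
#' Class-weighted pixel-wise cross-entropy between segmentation logits and a
#' binary gland mask; the weighted sum of per-pixel losses is normalised by
#' the sum of the true-class weights, so a uniformly-weighted mask reduces to
#' plain mean cross-entropy.
#'
#' @param seg_logits `(H, W, N, 2)` array (background, gland channels).
#' @param mask `(H, W, N)` (or `(H, W)`) array in `{0, 1}`, 1 = gland.
#' @param omega class weights `(background, gland)`, default `c(0.4, 1)`.
#' @return non-negative scalar.
#' @export
seg_loss <- function(seg_logits, mask, omega = c(0.4, 1.0)) {
  d <- dim(seg_logits)
  if (length(d) == 3L) {
    d <- c(d[1:2], 1L, d[3])
    dim(seg_logits) <- d
  }
  if (!all(as.vector(mask) %in% c(0, 1))) {
    stop("mask must be binary (0 = background, 1 = gland)", call. = FALSE)
  }
  M <- prod(d[1:3])
  z <- matrix(seg_logits, M, d[4])
  zmax <- pmax(z[, 1], z[, 2])
  lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
  yi <- as.integer(as.vector(mask))
  wi <- omega[yi + 1L]
  sum(wi * (lse - z[cbind(seq_len(M), yi + 1L)])) / sum(wi)
}

#' Attention consistency loss
#'
#' Mean squared deviation of the attention map from the predefined activation
#' expectation `delta`; regularises SGSA towards focused, stable responses.
#' With `mode = "spatial_mean"` the squared deviation of each map's spatial
#' mean is penalised instead (both readings coincide for per-sample-constant
#' maps).
#'
#' @param attention array with values in `[0, 1]`; the batch is the
#'   third dimension of an `(H, W, N, 1)` or `(H, W, N)` array.
#' @param delta expectation value in `(0, 1)`.
#' @param mode `"pixel"` (default) or `"spatial_mean"`.
#' @return non-negative scalar.
#' @export
cons_loss <- function(attention, delta = 0.5, mode = c("pixel", "spatial_mean")) {
  mode <- match.arg(mode)
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)", call. = FALSE)
  a <- as.array(attention)
  if (mode == "pixel") return(mean((a - delta)^2))
  d <- dim(a)
  n <- if (length(d) >= 3) d[3] else 1L
  means <- colMeans(matrix(a, prod(d[1:2]), n))
  mean((means - delta)^2)
}

#' Domain discrimination loss
#'
#' Two-class cross-entropy of domain logits over a mixed source/target batch
#' (source label 0, target label 1).  The adversarial maximisation with
#' respect to the shared extractor is realised exclusively by the gradient
#' reversal layer, never by an explicit sign flip here.
#'
#' @param logits `(2, N)` matrix of domain logits.
#' @param domains integer vector in `{0, 1}`.
#' @return non-negative scalar.
#' @export
dom_loss <- function(logits, domains) {
  if (!all(domains %in% c(0, 1))) stop("domains must be 0 or 1", call. = FALSE)
  if (length(unique(domains)) < 2L) {
    warning("single-domain batch: the discriminator objective is degenerate")
  }
  cls_loss(logits, as.integer(domains))
}

#' Uncertainty weighting of a task loss
#'
#' `exp(-s)/2 * L + s` with `s = log(sigma^2)` a trainable log-variance: the
#' homoscedastic-uncertainty weighting that balances task losses.  For fixed
#' `L`, the minimiser over `s` sits at `sigma^2 = L`.
#'
#' @param loss scalar task loss.
#' @param s log-variance `log(sigma^2)`.
#' @return weighted loss.
#' @export
uncertainty_weight <- function(loss, s) {
  if (!is.finite(loss)) stop("loss must be finite", call. = FALSE)
  exp(-s) / 2 * loss + s
}

#' Joint loss
#'
#' Combines the four task losses into the training objective:
#' uncertainty-weighted classification and segmentation terms, the domain
#' term (whose adversarial `-lambda` scaling lives inside the gradient
#' reversal layer, so it enters the total with weight 1), and `mu` times the
#' consistency term.
#'
#' @param l_cls,l_seg,l_dom,l_cons scalar component losses.
#' @param s_cls,s_seg log-variances of the uncertainty weighting.
#' @param lambda current gradient-reversal weight (recorded in the bundle).
#' @param mu consistency weight.
#' @return a `loss_bundle` list with every term and `total`.
#' @export
total_loss <- function(l_cls, l_seg, l_dom, l_cons,
                       s_cls = 0, s_seg = 0, lambda = 0, mu = 0.1) {
  comps <- c(l_cls = l_cls, l_seg = l_seg, l_dom = l_dom, l_cons = l_cons)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) {
    stop("non-finite loss component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  total <- uncertainty_weight(l_cls, s_cls) + uncertainty_weight(l_seg, s_seg) +
    l_dom + mu * l_cons
  structure(list(l_cls = l_cls, l_seg = l_seg, l_dom = l_dom, l_cons = l_cons,
                 s_cls = s_cls, s_seg = s_seg,
                 alpha = exp(-s_cls) / 2, beta = exp(-s_seg) / 2,
                 lambda = lambda, mu = mu, total = total),
            class = "loss_bundle")
}
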