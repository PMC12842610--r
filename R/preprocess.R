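# Image loading, training-time augmentation and model-input preprocessing.

#' Load a grayscale image / binary mask
#'
#' @param path PNG file; RGB images are converted to luminance by channel
#'   averaging.
#' @return `(H, W)` matrix in `[0, 1]` (`load_mask`: in `{0, 1}`).
#' @export
load_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                       c(1, 2), mean)
  x
}

#' @rdname load_image
#' @export
load_mask <- function(path) {
  (load_image(path) > 0.5) * 1L
}

# inverse-mapped rotation about the image centre; bilinear for images,
# nearest for masks; out-of-range samples clamp to the border
warp_rotate <- function(img, degrees, interp = c("bilinear", "nearest")) {
  if (degrees == 0) return(img)
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  if (interp == "nearest") {
    iy <- pmin(pmax(round(sy), 1), h)
    ix <- pmin(pmax(round(sx), 1), w)
    return(matrix(img[cbind(as.vector(iy), as.vector(ix))], h, w))
  }
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  v <- (1 - fy) * (1 - fx) * img[cbind(as.vector(y0), as.vector(x0))] +
       (1 - fy) * fx       * img[cbind(as.vector(y0), as.vector(x1))] +
       fy       * (1 - fx) * img[cbind(as.vector(y1), as.vector(x0))] +
       fy       * fx       * img[cbind(as.vector(y1), as.vector(x1))]
  matrix(v, h, w)
}

resize_matrix <- function(img, oh, ow, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  if (h == oh && w == ow) return(img)
  if (interp == "bilinear") {
    return(interp_matrix(h, oh) %*% img %*% t(interp_matrix(w, ow)))
  }
  iy <- pmin(pmax(round((seq_len(oh) - 0.5) * h / oh + 0.5), 1), h)
  ix <- pmin(pmax(round((seq_len(ow) - 0.5) * w / ow + 0.5), 1), w)
  img[iy, ix, drop = FALSE]
}

#' Apply an augmentation directive
#'
#' Applies a subset of the five training-time operations in a fixed order:
#' flip, rotation, crop (resized back to the original size), Gaussian noise,
#' brightness.  Geometric operations (flip, rotation, crop) are applied
#' identically to the image and the mask (nearest-neighbour for the mask);
#' photometric operations (noise, brightness) touch the image only.
#'
#' @param image `(H, W)` matrix in `[0, 1]`.
#' @param mask optional `(H, W)` binary mask.
#' @param directive named list with any of `flip` (`"horizontal"` /
#'   `"vertical"`), `rotation` (degrees), `crop` (area fraction), `noise_sd`,
#'   `brightness`; or a JSON string of the same.
#' @param rng_seed seed for the noise draw and crop placement.
#' @return list with `image` and (if given) `mask`, sizes preserved.
#' @export
augment <- function(image, mask = NULL, directive = list(), rng_seed = 1L) {
  if (is.character(directive)) {
    directive <- if (nzchar(directive)) jsonlite::fromJSON(directive) else list()
  }
  known <- c("flip", "rotation", "crop", "noise_sd", "brightness")
  bad <- setdiff(names(directive), known)
  if (length(bad)) stop("unknown augmentation operation(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  img <- image
  withr::with_seed(rng_seed, {
    if (!is.null(directive$flip)) {
      if (directive$flip == "horizontal") {
        img <- img[, ncol(img):1]
        if (!is.null(mask)) mask <- mask[, ncol(mask):1]
      } else if (directive$flip == "vertical") {
        img <- img[nrow(img):1, ]
        if (!is.null(mask)) mask <- mask[nrow(mask):1, ]
      } else stop("flip must be 'horizontal' or 'vertical'", call. = FALSE)
    }
    if (!is.null(directive$rotation) && directive$rotation != 0) {
      img <- warp_rotate(img, directive$rotation, "bilinear")
      if (!is.null(mask)) mask <- warp_rotate(mask, directive$rotation, "nearest")
    }
    if (!is.null(directive$crop) && directive$crop < 1) {
      h <- nrow(img); w <- ncol(img)
      side <- sqrt(directive$crop)
      ch <- max(2L, round(h * side)); cw <- max(2L, round(w * side))
      y0 <- sample.int(h - ch + 1L, 1L); x0 <- sample.int(w - cw + 1L, 1L)
      img <- resize_matrix(img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L)], h, w)
      if (!is.null(mask)) {
        mask <- resize_matrix(mask[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L)],
                              h, w, "nearest")
      }
    }
    if (!is.null(directive$noise_sd) && directive$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = directive$noise_sd),
                          nrow(img))
    }
    if (!is.null(directive$brightness) && directive$brightness != 0) {
      img <- img + directive$brightness
    }
    img <- pmin(pmax(img, 0), 1)
  })
  list(image = img, mask = mask)
}

#' Preprocess an image into a model input
#'
#' Bilinear-resizes to `size` x `size`, replicates the grayscale channel to
#' three channels and standardizes each channel; the default constants are
#' the ImageNet-pretraining convention of the ResNet backbone.
#'
#' @param image `(H, W)` matrix in `[0, 1]`.
#' @param size output side in pixels (the network input resolution).
#' @param mean,sd per-channel standardisation constants.
#' @return `(size, size, 3)` array.
#' @export
preprocess <- function(image, size = 224L,
                       mean = c(0.485, 0.456, 0.406),
                       sd = c(0.229, 0.224, 0.225)) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  r <- resize_matrix(image, size, size)
  out <- array(0, c(size, size, 3L))
  for (c in 1:3) out[, , c] <- (r - mean[c]) / sd[c]
  out
}

# assemble a (H, W, N, 3) batch from a list of (H, W, 3) preprocessed images
stack_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], length(imgs), 3L))
  for (i in seq_along(imgs)) out[, , i, ] <- imgs[[i]]
  out
}
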