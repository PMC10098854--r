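#' Preprocessing configuration
#'
#' The artifact-removal chain applied to dermoscopic images before training:
#' Gaussian smoothing, grayscale morphological closing (dilation then erosion
#' with a disk, which refills dark structures narrower than the disk — hairs —
#' while preserving larger dark regions — lesions), and unsharp-mask
#' sharpening to restore edge contrast. Steps run in the configured order;
#' the default order is smooth, close, sharpen.
#'
#' @param gaussian_sigma Gaussian standard deviation in pixels (> 0).
#' @param selem_radius disk structuring-element radius in pixels (>= 1).
#'   The default 5 px at 256x256 exceeds typical hair widths (1-3 px) but is
#'   far below lesion scale.
#' @param sharpen_amount unsharp-mask gain (>= 0); 0 is the identity.
#' @param sharpen_sigma standard deviation of the blur inside the unsharp
#'   mask.
#' @param steps ordered subset of `c("smooth", "close", "sharpen")`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(gaussian_sigma = 1, selem_radius = 5,
                              sharpen_amount = 1, sharpen_sigma = 1,
                              steps = c("smooth", "close", "sharpen")) {
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0")
  if (selem_radius < 1) stop("selem_radius must be >= 1")
  if (sharpen_amount < 0) stop("sharpen_amount must be >= 0")
  if (!all(steps %in% c("smooth", "close", "sharpen")))
    stop("steps must be a subset of smooth/close/sharpen")
  structure(list(gaussian_sigma = gaussian_sigma, selem_radius = selem_radius,
                 sharpen_amount = sharpen_amount, sharpen_sigma = sharpen_sigma,
                 steps = steps),
            class = "preprocess_config")
}

# normalized 1-D Gaussian kernel, radius = ceiling(3 sigma)
gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# whole-sample reflection of out-of-range indices (edge not duplicated)
reflect_idx <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

# separable convolution of one plane with reflect padding
convolve_plane <- function(m, k1) {
  r <- (length(k1) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + k1[o + r + 1L] * m[reflect_idx(1:H + o, H), ]
  m2 <- out
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + k1[o + r + 1L] * m2[, reflect_idx(1:W + o, W)]
  out
}

each_channel <- function(image, f) {
  if (length(dim(image)) == 2L) return(f(image))
  for (ch in seq_len(dim(image)[3L])) image[, , ch] <- f(image[, , ch])
  image
}

#' Gaussian smoothing
#'
#' Per-channel convolution with a normalized discrete Gaussian kernel
#' (radius `3 sigma`, reflect padding); output clipped to `[0, 1]`. Constant
#' images pass through unchanged.
#'
#' @param image array in `[0, 1]` (matrix or `H x W x C`).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Smoothed image, same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  k1 <- gaussian_kernel_1d(sigma)
  pmin(pmax(each_channel(image, function(m) convolve_plane(m, k1)), 0), 1)
}

#' Grayscale morphological closing
#'
#' Per-channel dilation (disk max-filter) followed by erosion (disk
#' min-filter) with the same disk structuring element. Closing is extensive
#' (output >= input everywhere) and idempotent; dark structures narrower than
#' the disk are raised to the surrounding intensity while wider dark regions
#' survive.
#'
#' @param image array in `[0, 1]`.
#' @param selem_radius disk radius in pixels (>= 1).
#' @return Closed image, same shape.
#' @export
morphological_close <- function(image, selem_radius) {
  if (selem_radius < 1) stop("selem_radius must be >= 1")
  brush <- EBImage::makeBrush(2L * as.integer(selem_radius) + 1L, shape = "disc")
  each_channel(image, function(m) EBImage::erode(EBImage::dilate(m, brush), brush))
}

#' Unsharp-mask sharpening
#'
#' `out = clip(image + amount * (image - gaussian_smooth(image, sigma)))`.
#' Constant images are unchanged; `amount = 0` is the identity.
#'
#' @param image array in `[0, 1]`.
#' @param amount high-pass gain (>= 0).
#' @param sigma blur scale of the mask.
#' @return Sharpened image, same shape, clipped to `[0, 1]`.
#' @export
sharpen <- function(image, amount, sigma = 1) {
  if (amount < 0) stop("amount must be >= 0")
  if (amount == 0) return(image)
  blurred <- gaussian_smooth(image, sigma)
  pmin(pmax(image + amount * (image - blurred), 0), 1)
}

#' Preprocess an image/mask pair
#'
#' Applies the configured steps to the image in order; the mask passes
#' through untouched.
#'
#' @param pair an [image_pair()].
#' @param config a [preprocess_config()].
#' @return The preprocessed [image_pair()].
#' @export
preprocess_pair <- function(pair, config = preprocess_config()) {
  stopifnot(inherits(pair, "image_pair"), inherits(config, "preprocess_config"))
  img <- pair$image
  for (step in config$steps) {
    img <- switch(step,
      smooth = gaussian_smooth(img, config$gaussian_sigma),
      close = morphological_close(img, config$selem_radius),
      sharpen = sharpen(img, config$sharpen_amount, config$sharpen_sigma))
  }
  image_pair(img, pair$mask, id = pair$id)
}
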