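# Shared fixtures and independent oracles used across test files.

lum <- function(a) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]

# a clean, easy scene with no artifacts (analytic ellipse when irregularity 0)
clean_scene_params <- function(size = 64, irregularity = 0, seed = 1,
                               contrast = 0.8, ...) {
  scene_params(image_size = size, lesion_center = c(size, size) / 2,
               lesion_axes = c(0.25, 0.2) * size,
               boundary_irregularity = irregularity, contrast = contrast,
               n_hairs = 0, n_bubbles = 0, noise_sd = 0, seed = seed, ...)
}

# micro-scale model specs for fast optimization tests
micro_generator_spec <- function(size = 16L) {
  generator_spec(input_size = size, encoder_widths = c(8L, 8L, 8L),
                 bottleneck_width = 8L)
}

micro_discriminator_spec <- function(...) {
  discriminator_spec(feature_widths = c(8L, 8L), strides = c(2L, 1L), ...)
}

# brute-force grayscale morphology oracle: sliding min/max over the disk,
# out-of-bounds positions ignored
disk_offsets <- function(radius) {
  b <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  which(b == 1, arr.ind = TRUE) - (radius + 1L)
}

bf_morph <- function(m, radius, f) {
  off <- disk_offsets(radius)
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    k <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out[i, j] <- f(m[cbind(ii[k], jj[k])])
  }
  out
}

bf_closing <- function(m, radius) bf_morph(bf_morph(m, radius, max), radius, min)

# nearest-neighbour resize oracle (src = ceiling(i * n / new_n) per axis)
bf_resize_nearest <- function(m, newH, newW) {
  m[ceiling(seq_len(newH) * nrow(m) / newH),
    ceiling(seq_len(newW) * ncol(m) / newW), drop = FALSE]
}

# foreground centroid (rows, cols) of a weight matrix
centroid <- function(w) {
  rows <- matrix(seq_len(nrow(w)), nrow(w), ncol(w))
  cols <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)
  c(sum(rows * w), sum(cols * w)) / sum(w)
}
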