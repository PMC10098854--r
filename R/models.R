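#' U-Net generator architecture specification
#'
#' Declarative layer schedule for the generator: an encoder of stride-2 4x4
#' convolutions (each block conv + normalization + LeakyReLU), a 1x1-spatial
#' bottleneck (conv + ReLU, no normalization), and a mirrored decoder of
#' stride-2 4x4 transposed convolutions (each block tconv + normalization
#' [+ dropout] + ReLU) with skip connections concatenating the mirror
#' encoder activation. A final transposed convolution with tanh maps back to
#' `output_channels` in `[-1, 1]`. Weights initialize from a zero-mean
#' normal with `init_sd`.
#'
#' The depth invariant `input_size == 2^(length(encoder_widths) + 1)` makes
#' the bottleneck exactly 1x1 (256 needs 7 encoder blocks; 64 needs 5).
#'
#' @param input_size input side length in pixels.
#' @param input_channels channels of the source image (3 for RGB).
#' @param encoder_widths filter counts per encoder block.
#' @param bottleneck_width filters in the bottleneck convolution.
#' @param dropout_rate decoder dropout probability.
#' @param dropout_blocks number of innermost decoder blocks with dropout.
#' @param output_channels generated image channels.
#' @param kernel convolution kernel size.
#' @param leaky_alpha LeakyReLU slope for the encoder.
#' @param init_sd standard deviation of the normal weight initializer.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 256L,
                           input_channels = 3L,
                           encoder_widths = c(64L, 128L, 256L, 512L, 512L, 512L, 512L),
                           bottleneck_width = 512L,
                           dropout_rate = 0.5,
                           dropout_blocks = 3L,
                           output_channels = 3L,
                           kernel = 4L,
                           leaky_alpha = 0.2,
                           init_sd = 0.02) {
  if (input_size != 2^(length(encoder_widths) + 1L))
    stop("input_size must equal 2^(length(encoder_widths) + 1) so the ",
         "bottleneck reaches 1x1; got input_size = ", input_size,
         " with ", length(encoder_widths), " encoder blocks")
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 encoder_widths = as.integer(encoder_widths),
                 bottleneck_width = as.integer(bottleneck_width),
                 dropout_rate = dropout_rate,
                 dropout_blocks = as.integer(dropout_blocks),
                 output_channels = as.integer(output_channels),
                 kernel = as.integer(kernel),
                 leaky_alpha = leaky_alpha,
                 init_sd = init_sd),
            class = "generator_spec")
}

#' Tiny desk-scale generator spec (64x64)
#'
#' @param ... overrides passed to [generator_spec()].
#' @return A `generator_spec` with 5 encoder blocks of widths 16-64.
#' @export
tiny_generator_spec <- function(...) {
  generator_spec(input_size = 64L, encoder_widths = c(16L, 32L, 64L, 64L, 64L),
                 bottleneck_width = 64L, ...)
}

#' PatchGAN discriminator architecture specification
#'
#' The discriminator concatenates source and candidate target on channels
#' (6 input channels for RGB pairs) and applies 4x4 convolutions — widths
#' 64, 128, 256, 512, 512 with strides 2, 2, 2, 1, 1 by default — each
#' followed by normalization and LeakyReLU(0.2), then a 1x1 convolution with
#' sigmoid emitting a grid of per-patch real/fake probabilities. With the
#' default schedule each patch cell sees a 70x70-pixel receptive field and a
#' 256x256 input yields a 32x32 patch map.
#'
#' @param feature_widths filter counts per convolution layer.
#' @param strides stride per layer (same length as `feature_widths`).
#' @param kernel convolution kernel size.
#' @param leaky_alpha LeakyReLU slope.
#' @param final_kernel kernel of the prediction head.
#' @param in_channels concatenated input channels (source + target).
#' @param normalized apply per-channel normalization after every convolution
#'   (the default). Disabling it makes the network purely convolutional,
#'   which diagnostic code uses to verify receptive-field locality.
#' @param init_sd standard deviation of the normal weight initializer.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(feature_widths = c(64L, 128L, 256L, 512L, 512L),
                               strides = c(2L, 2L, 2L, 1L, 1L),
                               kernel = 4L,
                               leaky_alpha = 0.2,
                               final_kernel = 1L,
                               in_channels = 6L,
                               normalized = TRUE,
                               init_sd = 0.02) {
  if (length(strides) != length(feature_widths))
    stop("strides and feature_widths must have the same length")
  structure(list(feature_widths = as.integer(feature_widths),
                 strides = as.integer(strides),
                 kernel = as.integer(kernel),
                 leaky_alpha = leaky_alpha,
                 final_kernel = as.integer(final_kernel),
                 in_channels = as.integer(in_channels),
                 normalized = normalized,
                 init_sd = init_sd),
            class = "discriminator_spec")
}

#' Tiny desk-scale discriminator spec
#'
#' @param ... overrides passed to [discriminator_spec()].
#' @return A `discriminator_spec` with widths 16, 32 and strides 2, 1.
#' @export
tiny_discriminator_spec <- function(...) {
  discriminator_spec(feature_widths = c(16L, 32L), strides = c(2L, 1L), ...)
}

#' Receptive field of a convolution chain
#'
#' Folds the recurrence `RF_in = (RF_out - 1) * stride + kernel` from the
#' output layer back to the input, starting at `RF = 1`: the extent, in
#' input pixels per side, influencing one output unit.
#'
#' @param kernels,strides equal-length integer vectors (entries >= 1),
#'   ordered input to output.
#' @return Receptive-field side length in pixels.
#' @export
receptive_field <- function(kernels, strides) {
  if (length(kernels) == 0L || length(kernels) != length(strides))
    stop("kernels and strides must be non-empty and of equal length")
  if (any(kernels < 1) || any(strides < 1))
    stop("kernels and strides must be >= 1")
  rf <- 1
  for (i in rev(seq_along(kernels))) rf <- (rf - 1) * strides[i] + kernels[i]
  rf
}

#' Layer schedule of a discriminator, head included
#'
#' @param spec a [discriminator_spec()].
#' @return List with `kernels` and `strides` covering every convolution from
#'   input to the prediction head, for use with [receptive_field()].
#' @export
discriminator_chain <- function(spec = discriminator_spec()) {
  list(kernels = c(rep(spec$kernel, length(spec$feature_widths)), spec$final_kernel),
       strides = c(spec$strides, 1L))
}

## -- construction -----------------------------------------------------------

#' Build the U-Net generator
#'
#' Instantiates weights for a [generator_spec()] from the current RNG
#' stream (zero-mean normal, sd `init_sd`; zero biases; unit scales).
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer; if given, seeds the RNG first.
#' @return An object of class `cgan_generator` with elements `spec` and
#'   `params`.
#' @export
build_generator <- function(spec = generator_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- spec$kernel
  n <- length(spec$encoder_widths)
  enc <- vector("list", n)
  ci <- spec$input_channels
  for (i in seq_len(n)) {
    enc[[i]] <- init_conv_params(k, ci, spec$encoder_widths[i], spec$init_sd,
                                 bn = TRUE)
    ci <- spec$encoder_widths[i]
  }
  bott <- init_conv_params(k, ci, spec$bottleneck_width, spec$init_sd,
                           bn = FALSE)
  dec <- vector("list", n)
  ci <- spec$bottleneck_width
  for (i in seq_len(n)) {
    co <- spec$encoder_widths[n + 1L - i]
    dec[[i]] <- init_conv_params(k, ci, co, spec$init_sd, bn = TRUE,
                                 transposed = TRUE)
    ci <- co + spec$encoder_widths[n + 1L - i]  # concat with mirror skip
  }
  out <- init_conv_params(k, ci, spec$output_channels, spec$init_sd,
                          bn = FALSE, transposed = TRUE)
  structure(list(spec = spec,
                 params = list(enc = enc, bott = bott, dec = dec, out = out)),
            class = "cgan_generator")
}

#' Build the PatchGAN discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional integer; if given, seeds the RNG first.
#' @return An object of class `cgan_discriminator` with elements `spec` and
#'   `params`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- spec$kernel
  n <- length(spec$feature_widths)
  layers <- vector("list", n)
  ci <- spec$in_channels
  for (i in seq_len(n)) {
    layers[[i]] <- init_conv_params(k, ci, spec$feature_widths[i], spec$init_sd,
                                    bn = spec$normalized)
    ci <- spec$feature_widths[i]
  }
  head <- init_conv_params(spec$final_kernel, ci, 1L, spec$init_sd, bn = FALSE)
  structure(list(spec = spec, params = list(layers = layers, head = head)),
            class = "cgan_discriminator")
}

#' @export
print.cgan_generator <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<cgan_generator> %dx%dx%d -> %dx%dx%d; encoder widths %s; bottleneck %d\n",
              s$input_size, s$input_size, s$input_channels,
              s$input_size, s$input_size, s$output_channels,
              paste(s$encoder_widths, collapse = ","), s$bottleneck_width))
  invisible(x)
}

#' @export
print.cgan_discriminator <- function(x, ...) {
  s <- x$spec
  ch <- discriminator_chain(s)
  cat(sprintf("<cgan_discriminator> widths %s, strides %s; receptive field %d px\n",
              paste(s$feature_widths, collapse = ","),
              paste(s$strides, collapse = ","),
              receptive_field(ch$kernels, ch$strides)))
  invisible(x)
}

## -- forward / backward -----------------------------------------------------

# Generator forward pass. `training = TRUE` activates decoder dropout (drawn
# from the global RNG stream). Returns list(out, cache); cache = NULL unless
# requested.
gen_forward <- function(G, x, training = FALSE, want_cache = FALSE) {
  spec <- G$spec; P <- G$params
  n <- length(P$enc)
  stopifnot(dim(x)[1L] == spec$input_size, dim(x)[3L] == spec$input_channels)
  cache <- if (want_cache) list(enc = vector("list", n),
                                dec = vector("list", n)) else NULL

  e_acts <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    pre <- conv_fwd(h, P$enc[[i]]$W, P$enc[[i]]$b, 2L)
    nf <- norm_fwd(pre, P$enc[[i]]$gamma, P$enc[[i]]$beta)
    a <- act_fwd(nf$y, "leaky_relu", spec$leaky_alpha)
    if (want_cache) cache$enc[[i]] <- list(x = h, norm = nf, pre_act = nf$y)
    e_acts[[i]] <- a
    h <- a
  }
  bpre <- conv_fwd(h, P$bott$W, P$bott$b, 2L)
  bact <- act_fwd(bpre, "relu")
  if (want_cache) cache$bott <- list(x = h, pre_act = bpre)

  h <- bact
  for (i in seq_len(n)) {
    pre <- tconv_fwd(h, P$dec[[i]]$W, P$dec[[i]]$b, 2L)
    nf <- norm_fwd(pre, P$dec[[i]]$gamma, P$dec[[i]]$beta)
    y <- nf$y
    mask <- NULL
    if (training && i <= spec$dropout_blocks && spec$dropout_rate > 0) {
      dp <- dropout_fwd(y, spec$dropout_rate)
      y <- dp$y
      mask <- dp$mask
    }
    a <- act_fwd(y, "relu")
    if (want_cache) cache$dec[[i]] <- list(x = h, norm = nf, pre_act = y,
                                           drop_mask = mask)
    skip <- e_acts[[n + 1L - i]]
    cat_c <- dim(a)[3L]
    h <- array(c(a, skip), c(dim(a)[1:2], cat_c + dim(skip)[3L]))
    if (want_cache) cache$dec[[i]]$cat_split <- cat_c
  }
  opre <- tconv_fwd(h, P$out$W, P$out$b, 2L)
  out <- act_fwd(opre, "tanh")
  if (want_cache) {
    cache$out <- list(x = h, pre_act = opre, y = out)
    cache$n <- n
  }
  list(out = out, cache = cache)
}

# Backward pass through the generator; returns gradients with the same
# nesting as G$params.
gen_backward <- function(G, cache, gy) {
  spec <- G$spec; P <- G$params
  n <- cache$n
  grads <- list(enc = vector("list", n), bott = NULL,
                dec = vector("list", n), out = NULL)

  g <- act_bwd(gy, cache$out$pre_act, cache$out$y, "tanh")
  tb <- tconv_bwd(cache$out$x, P$out$W, g, 2L)
  grads$out <- list(W = tb$gV, b = tb$gb)
  g <- tb$gx

  g_skip <- vector("list", n)  # gradient flowing into encoder activations
  for (i in rev(seq_len(n))) {
    sp <- cache$dec[[i]]$cat_split
    d <- dim(g)
    g_dec <- g[, , seq_len(sp), drop = FALSE]
    g_skip[[n + 1L - i]] <- g[, , (sp + 1L):d[3L], drop = FALSE]
    g1 <- act_bwd(g_dec, cache$dec[[i]]$pre_act, NULL, "relu")
    if (!is.null(cache$dec[[i]]$drop_mask)) g1 <- g1 * cache$dec[[i]]$drop_mask
    nb <- norm_bwd(g1, cache$dec[[i]]$norm, P$dec[[i]]$gamma)
    tb <- tconv_bwd(cache$dec[[i]]$x, P$dec[[i]]$W, nb$gx, 2L)
    grads$dec[[i]] <- list(W = tb$gV, b = tb$gb,
                           gamma = nb$ggamma, beta = nb$gbeta)
    g <- tb$gx
  }

  g <- act_bwd(g, cache$bott$pre_act, NULL, "relu")
  cb <- conv_bwd(cache$bott$x, P$bott$W, g, 2L)
  grads$bott <- list(W = cb$gW, b = cb$gb)
  g <- cb$gx

  for (i in rev(seq_len(n))) {
    g <- g + g_skip[[i]]
    g1 <- act_bwd(g, cache$enc[[i]]$pre_act, NULL, "leaky_relu",
                  spec$leaky_alpha)
    nb <- norm_bwd(g1, cache$enc[[i]]$norm, P$enc[[i]]$gamma)
    cb <- conv_bwd(cache$enc[[i]]$x, P$enc[[i]]$W, nb$gx, 2L,
                   want_gx = (i > 1L))
    grads$enc[[i]] <- list(W = cb$gW, b = cb$gb,
                           gamma = nb$ggamma, beta = nb$gbeta)
    if (i > 1L) g <- cb$gx
  }
  grads
}

# Discriminator forward pass on a (source, target) pair concatenated on
# channels. Returns list(patch, cache).
disc_forward <- function(D, source, target, want_cache = FALSE) {
  spec <- D$spec; P <- D$params
  if (!all(dim(source)[1:2] == dim(target)[1:2]))
    stop("source and target must share spatial dimensions")
  x <- array(c(source, target), c(dim(source)[1:2],
                                  dim(source)[3L] + dim(target)[3L]))
  if (dim(x)[3L] != spec$in_channels)
    stop("concatenated input has ", dim(x)[3L], " channels; spec expects ",
         spec$in_channels)
  n <- length(P$layers)
  cache <- if (want_cache) list(layers = vector("list", n)) else NULL
  h <- x
  for (i in seq_len(n)) {
    pre <- conv_fwd(h, P$layers[[i]]$W, P$layers[[i]]$b, spec$strides[i])
    if (spec$normalized) {
      nf <- norm_fwd(pre, P$layers[[i]]$gamma, P$layers[[i]]$beta)
      y <- nf$y
    } else {
      nf <- NULL
      y <- pre
    }
    a <- act_fwd(y, "leaky_relu", spec$leaky_alpha)
    if (want_cache) cache$layers[[i]] <- list(x = h, norm = nf, pre_act = y)
    h <- a
  }
  zpre <- conv_fwd(h, P$head$W, P$head$b, 1L)
  patch <- act_fwd(zpre, "sigmoid")
  if (want_cache) {
    cache$head <- list(x = h)
    cache$patch <- patch
    cache$n <- n
    cache$source_channels <- dim(source)[3L]
  }
  list(patch = patch, cache = cache)
}

# Backward from dL/dz (gradient at the pre-sigmoid head, which for mean BCE
# against a constant label grid is (patch - label) / n_cells). Returns
# gradients and, when requested, the gradient w.r.t. the target half of the
# input channels (used by the generator update).
disc_backward <- function(D, cache, dz, want_input_grad = FALSE) {
  spec <- D$spec; P <- D$params
  n <- cache$n
  grads <- list(layers = vector("list", n), head = NULL)
  cb <- conv_bwd(cache$head$x, P$head$W, dz, 1L)
  grads$head <- list(W = cb$gW, b = cb$gb)
  g <- cb$gx
  for (i in rev(seq_len(n))) {
    g1 <- act_bwd(g, cache$layers[[i]]$pre_act, NULL, "leaky_relu",
                  spec$leaky_alpha)
    if (spec$normalized) {
      nb <- norm_bwd(g1, cache$layers[[i]]$norm, P$layers[[i]]$gamma)
      gpre <- nb$gx
      extra <- list(gamma = nb$ggamma, beta = nb$gbeta)
    } else {
      gpre <- g1
      extra <- NULL
    }
    cb <- conv_bwd(cache$layers[[i]]$x, P$layers[[i]]$W, gpre, spec$strides[i],
                   want_gx = (i > 1L || want_input_grad))
    grads$layers[[i]] <- c(list(W = cb$gW, b = cb$gb), extra)
    if (i > 1L || want_input_grad) g <- cb$gx
  }
  g_target <- NULL
  if (want_input_grad) {
    sc <- cache$source_channels
    g_target <- g[, , (sc + 1L):dim(g)[3L], drop = FALSE]
  }
  list(grads = grads, g_target = g_target)
}
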