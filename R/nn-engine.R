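# Internal neural-network engine: layer forward/backward passes and Adam.
#
# All feature maps are numeric arrays dim c(H, W, C). Batch size is fixed at 1
# (the training regime used throughout), so batch normalization reduces to
# per-channel normalization over the spatial dimensions of the single sample.

# "same" padding geometry, TensorFlow convention: out = ceil(in / stride),
# total padding split with the smaller half before.
conv_same_geom <- function(H, W, k, stride) {
  outH <- ceiling(H / stride)
  outW <- ceiling(W / stride)
  pt <- max((outH - 1L) * stride + k - H, 0L)
  pw <- max((outW - 1L) * stride + k - W, 0L)
  list(outH = as.integer(outH), outW = as.integer(outW),
       pad_t = as.integer(pt %/% 2L), pad_l = as.integer(pw %/% 2L))
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

## -- convolution ------------------------------------------------------------

conv_fwd <- function(x, W4, b, stride) {
  x <- as_cube(x)
  k <- dim(W4)[1L]
  ci <- dim(W4)[3L]; co <- dim(W4)[4L]
  g <- conv_same_geom(dim(x)[1L], dim(x)[2L], k, stride)
  K <- matrix(W4, k * k * ci, co)
  y <- cpp_conv_fwd(x, K, k, stride, g$pad_t, g$pad_l, g$outH, g$outW)
  y + rep(b, each = g$outH * g$outW)
}

conv_bwd <- function(x, W4, gy, stride, want_gx = TRUE) {
  x <- as_cube(x); gy <- as_cube(gy)
  k <- dim(W4)[1L]
  ci <- dim(W4)[3L]; co <- dim(W4)[4L]
  g <- conv_same_geom(dim(x)[1L], dim(x)[2L], k, stride)
  K <- matrix(W4, k * k * ci, co)
  gW <- cpp_conv_bwd_weight(x, gy, k, stride, g$pad_t, g$pad_l)
  dim(gW) <- dim(W4)
  gb <- apply(gy, 3L, sum)
  gx <- NULL
  if (want_gx)
    gx <- cpp_conv_bwd_data(gy, K, k, stride, g$pad_t, g$pad_l,
                            dim(x)[1L], dim(x)[2L])
  list(gx = gx, gW = gW, gb = gb)
}

## -- transposed convolution -------------------------------------------------
# Stored weights V4 have dim c(k, k, Cout, Cin): they are the weights of the
# "virtual" forward convolution Cout -> Cin whose data-gradient realizes the
# transposed convolution (output spatial size = input * stride).

tconv_fwd <- function(x, V4, b, stride) {
  x <- as_cube(x)
  k <- dim(V4)[1L]
  co <- dim(V4)[3L]; ci <- dim(V4)[4L]
  H <- dim(x)[1L]; W <- dim(x)[2L]
  outH <- H * stride; outW <- W * stride
  g <- conv_same_geom(outH, outW, k, stride)
  stopifnot(g$outH == H, g$outW == W)
  K <- matrix(V4, k * k * co, ci)
  y <- cpp_conv_bwd_data(x, K, k, stride, g$pad_t, g$pad_l, outH, outW)
  y + rep(b, each = outH * outW)
}

tconv_bwd <- function(x, V4, gy, stride) {
  x <- as_cube(x); gy <- as_cube(gy)
  k <- dim(V4)[1L]
  co <- dim(V4)[3L]; ci <- dim(V4)[4L]
  outH <- dim(gy)[1L]; outW <- dim(gy)[2L]
  g <- conv_same_geom(outH, outW, k, stride)
  K <- matrix(V4, k * k * co, ci)
  gx <- cpp_conv_fwd(gy, K, k, stride, g$pad_t, g$pad_l, dim(x)[1L], dim(x)[2L])
  gV <- cpp_conv_bwd_weight(gy, x, k, stride, g$pad_t, g$pad_l)
  dim(gV) <- dim(V4)
  gb <- apply(gy, 3L, sum)
  list(gx = gx, gV = gV, gb = gb)
}

## -- normalization ----------------------------------------------------------
# Per-channel normalization over spatial positions of the single sample
# (batch statistics at batch size 1), with learned scale/shift.

norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1L] * d[2L]
  M <- matrix(x, n, d[3L])
  mu <- colMeans(M)
  xc <- sweep(M, 2L, mu)
  v <- colSums(xc * xc) / n
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, dims = d)
}

norm_bwd <- function(gy, cache, gamma) {
  d <- cache$dims; n <- d[1L] * d[2L]
  G <- matrix(gy, n, d[3L])
  xhat <- cache$xhat
  ggamma <- colSums(G * xhat)
  gbeta <- colSums(G)
  Gh <- sweep(G, 2L, gamma, `*`)
  s1 <- colSums(Gh)
  s2 <- colSums(Gh * xhat)
  gx <- sweep(Gh, 2L, s1 / n) - sweep(xhat, 2L, s2 / n, `*`)
  gx <- sweep(gx, 2L, cache$istd, `*`)
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## -- activations ------------------------------------------------------------

act_fwd <- function(x, kind, alpha = 0.2) {
  switch(kind,
    leaky_relu = ifelse(x > 0, x, alpha * x),
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    none = x)
}

act_bwd <- function(gy, x, y, kind, alpha = 0.2) {
  switch(kind,
    leaky_relu = gy * ifelse(x > 0, 1, alpha),
    relu = gy * (x > 0),
    tanh = gy * (1 - y * y),
    sigmoid = gy * y * (1 - y),
    none = gy)
}

## -- dropout ----------------------------------------------------------------
# Inverted dropout; draws from the caller-seeded global RNG stream.

dropout_fwd <- function(x, rate) {
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

## -- parameter containers ---------------------------------------------------

init_conv_params <- function(k, ci, co, sd, bn, transposed = FALSE) {
  wdim <- if (transposed) c(k, k, co, ci) else c(k, k, ci, co)
  p <- list(W = array(stats::rnorm(prod(wdim), 0, sd), wdim),
            b = numeric(co))
  if (bn) {
    p$gamma <- rep(1, co)
    p$beta <- numeric(co)
  }
  p
}

# Map f over two parallel nested lists of numeric arrays.
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

param_zeros <- function(p) {
  if (is.list(p)) lapply(p, param_zeros) else p * 0
}

## -- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  mv <- param_map2(state$m, state$v, function(m, v) list(m = m, v = v))
  params <- param_map2(params, mv, function(p, s)
    p - lr * (s$m / c1) / (sqrt(s$v / c2) + eps))
  list(params = params, state = state)
}
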