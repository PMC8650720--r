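# Minimal CNN engine for the 3D classifiers and segmentation nets: im2col
# GEMM convolutions (src/kernels.cpp), per-sample channel normalization,
# ReLU, dense layers, softmax cross-entropy, and Adam. Everything operates
# on column-major arrays with dims (X, Y, Z, C); batch size is one sample
# (volumes are processed individually), which is why the normalization is
# per-sample ("instance") rather than batch statistics.

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol) * sqrt(2 / fan_in), nrow, ncol)
}

conv_params <- function(cin, cout, k, norm = TRUE) {
  p <- list(W = he_init(k^3 * cin, cout, k^3 * cin), b = rep(0, cout), k = k)
  if (norm) {
    p$gamma <- rep(1, cout)
    p$beta <- rep(0, cout)
  }
  p
}

conv_fwd <- function(x, p) {
  d <- dim(x)
  cpp_conv3d_fwd(as.numeric(x), as.integer(d), p$W, p$b, p$k)
}

conv_bwd <- function(x, p, gout) {
  d <- dim(x)
  cpp_conv3d_bwd(as.numeric(x), as.integer(d), p$W, as.numeric(gout), p$k)
}

# Per-sample, per-channel normalization with learnable affine parameters.
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- prod(d[1:3])
  m <- matrix(x, n, d[4])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  invstd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = array(y, d), xhat = xhat, invstd = invstd)
}

inorm_bwd <- function(cache, gamma, gout) {
  d <- dim(gout)
  n <- prod(d[1:3])
  g <- matrix(gout, n, d[4])
  gbeta <- colSums(g)
  ggamma <- colSums(g * cache$xhat)
  gxhat <- sweep(g, 2, gamma, `*`)
  mg <- colMeans(gxhat)
  mgx <- colMeans(gxhat * cache$xhat)
  gx <- sweep(gxhat, 2, mg) - sweep(cache$xhat, 2, mgx, `*`)
  gx <- sweep(gx, 2, cache$invstd, `*`)
  list(gin = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# One conv block: convolution [+ instance norm] + ReLU.
block_fwd <- function(x, p) {
  pre <- conv_fwd(x, p)
  if (!is.null(p$gamma)) {
    nm <- inorm_fwd(pre, p$gamma, p$beta)
    act <- pmax(nm$out, 0)
    list(out = act, x = x, pre = pre, norm = nm)
  } else {
    list(out = pmax(pre, 0), x = x, pre = pre, norm = NULL)
  }
}

block_bwd <- function(cache, p, gout) {
  g <- gout * (cache$out > 0)
  if (!is.null(cache$norm)) {
    nb <- inorm_bwd(cache$norm, p$gamma, g)
    cb <- conv_bwd(cache$x, p, nb$gin)
    list(gin = cb$gin,
         grads = list(W = cb$gW, b = cb$gb, gamma = nb$ggamma,
                      beta = nb$gbeta))
  } else {
    cb <- conv_bwd(cache$x, p, g)
    list(gin = cb$gin, grads = list(W = cb$gW, b = cb$gb))
  }
}

dense_params <- function(nin, nout) {
  list(W = he_init(nin, nout, nin), b = rep(0, nout))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Two-layer classifier head: feature vector -> ReLU hidden -> 2-class probs.
head_params <- function(nin, hidden = 12, seed_offset = 0) {
  list(fc1 = dense_params(nin, hidden), fc2 = dense_params(hidden, 2))
}

head_fwd <- function(v, p) {
  h_pre <- as.numeric(v %*% p$fc1$W) + p$fc1$b
  h <- pmax(h_pre, 0)
  logits <- as.numeric(h %*% p$fc2$W) + p$fc2$b
  probs <- softmax(logits)
  list(probs = probs, v = v, h_pre = h_pre, h = h)
}

# glogits: gradient of the loss w.r.t. the logits.
head_bwd <- function(cache, p, glogits) {
  gW2 <- outer(cache$h, glogits)
  gb2 <- glogits
  gh <- as.numeric(p$fc2$W %*% glogits) * (cache$h_pre > 0)
  gW1 <- outer(as.numeric(cache$v), gh)
  gb1 <- gh
  gv <- as.numeric(p$fc1$W %*% gh)
  list(gv = gv,
       grads = list(fc1 = list(W = gW1, b = gb1),
                    fc2 = list(W = gW2, b = gb2)))
}

# ---- parameter-tree utilities (params / grads / optimizer state share the
# same nested-list structure with numeric leaves) ----

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (is.null(b)) NULL
      else if (!is.null(nms) && nzchar(nms[i]) && !is.null(names(b)))
        b[[nms[i]]]
      else if (i <= length(b)) b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else if (is.numeric(a) && !is.null(b)) {
    f(a, b)
  } else {
    # structural leaves (e.g. kernel sizes) carry no gradient: left as-is
    a
  }
}

tree_zero <- function(a) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_zero(a[[i]])
    out
  } else if (is.numeric(a)) {
    a * 0
  } else {
    a
  }
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

# Fixed affine intensity normalization for network inputs. QSM intensities
# are quantitative (ppb), and the diagnostic signal is the absolute
# susceptibility level; a per-sample z-score would normalize that level
# away, so a fixed global affine map is used instead.
scale_intensity <- function(x, center = 70, scale = 70) (x - center) / scale
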