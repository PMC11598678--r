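# Minimal deterministic deep-learning layers with hand-derived
# backpropagation, backed by compiled im2col convolution kernels.
#
# Activations are R arrays of dim (H, W, C, N); dense activations are
# (N, C) matrices. Layers are environments holding parameters, gradient
# accumulators, Adam state and the forward cache; backward must follow its
# forward. All randomness draws from R's RNG so runs are reproducible
# under set.seed().

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

layer_conv <- function(cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                       bias = FALSE) {
  W <- matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  new_layer("conv", W = W, b = numeric(cout), k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            use_bias = bias, params = if (bias) c("W", "b") else "W")
}

layer_bn2d <- function(C, eps = 1e-5, momentum = 0.1) {
  new_layer("bn2d", g = rep(1, C), b = numeric(C), rm = numeric(C),
            rv = rep(1, C), eps = eps, mom = momentum, params = c("g", "b"))
}

layer_bn1d <- function(C, eps = 1e-5, momentum = 0.1) {
  new_layer("bn1d", g = rep(1, C), b = numeric(C), rm = numeric(C),
            rv = rep(1, C), eps = eps, mom = momentum, params = c("g", "b"))
}

layer_relu <- function() new_layer("relu", params = character(0))

layer_maxpool <- function(k = 3, stride = 2, pad = 1)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), params = character(0))

layer_linear <- function(cin, cout) {
  new_layer("linear",
            W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
            b = numeric(cout), params = c("W", "b"))
}

conv_fwd <- function(l, X) {
  l$X <- X
  cpp_conv_fwd(X, l$W, l$b, l$k, l$stride, l$pad, l$use_bias)
}

conv_bwd <- function(l, dY) {
  r <- cpp_conv_bwd(l$X, l$W, dY, l$k, l$stride, l$pad)
  l$gW <- if (is.null(l$gW)) r$dW else l$gW + r$dW
  if (l$use_bias) l$gb <- if (is.null(l$gb)) r$db else l$gb + r$db
  r$dX
}

# channel-last view (H*W*N, C) used by batch-norm statistics
to_cl <- function(X) {
  d <- dim(X)
  Xp <- aperm(X, c(1, 2, 4, 3))
  dim(Xp) <- c(d[1] * d[2] * d[4], d[3])
  Xp
}

from_cl <- function(Xp, d) {
  dim(Xp) <- c(d[1], d[2], d[4], d[3])
  aperm(Xp, c(1, 2, 4, 3))
}

bn2d_fwd <- function(l, X, train) {
  if (train) {
    st <- cpp_channel_stats(X)
    mu <- st$mean; v <- st$var
    l$rm <- (1 - l$mom) * l$rm + l$mom * mu
    l$rv <- (1 - l$mom) * l$rv + l$mom * v
  } else {
    mu <- l$rm; v <- l$rv
  }
  istd <- 1 / sqrt(v + l$eps)
  r <- cpp_bn2d_fwd(X, l$g, l$b, mu, istd)
  if (train) { l$xh <- r$xh; l$istd <- istd }
  r$Y
}

bn2d_bwd <- function(l, dY) {
  r <- cpp_bn2d_bwd(dY, l$xh, l$g, l$istd)
  l$gg <- if (is.null(l$gg)) r$dg else l$gg + r$dg
  l$gb <- if (is.null(l$gb)) r$db else l$gb + r$db
  r$dX
}

bn1d_fwd <- function(l, X, train) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    l$rm <- (1 - l$mom) * l$rm + l$mom * mu
    l$rv <- (1 - l$mom) * l$rv + l$mom * v
  } else {
    mu <- l$rm; v <- l$rv
    xc <- sweep(X, 2, mu)
  }
  istd <- 1 / sqrt(v + l$eps)
  xh <- sweep(xc, 2, istd, "*")
  if (train) { l$xh <- xh; l$istd <- istd }
  sweep(sweep(xh, 2, l$g, "*"), 2, l$b, "+")
}

bn1d_bwd <- function(l, dY) {
  M <- nrow(dY)
  dg <- colSums(dY * l$xh)
  db <- colSums(dY)
  l$gg <- if (is.null(l$gg)) dg else l$gg + dg
  l$gb <- if (is.null(l$gb)) db else l$gb + db
  dxh <- sweep(dY, 2, l$g, "*")
  t1 <- colSums(dxh) / M
  t2 <- colSums(dxh * l$xh) / M
  sweep(sweep(dxh, 2, t1) - sweep(l$xh, 2, t2, "*"), 2, l$istd, "*")
}

relu_fwd <- function(l, X) {
  l$mask <- X > 0
  X * l$mask
}

relu_bwd <- function(l, dY) dY * l$mask

maxpool_fwd <- function(l, X) {
  l$in_dim <- dim(X)
  r <- cpp_maxpool_fwd(X, l$k, l$stride, l$pad)
  l$idx <- r$idx
  r$Y
}

maxpool_bwd <- function(l, dY) cpp_maxpool_bwd(dY, l$idx, l$in_dim)

linear_fwd <- function(l, X) {
  l$X <- X
  sweep(X %*% l$W, 2, l$b, "+")
}

linear_bwd <- function(l, dY) {
  gW <- crossprod(l$X, dY)
  gb <- colSums(dY)
  l$gW <- if (is.null(l$gW)) gW else l$gW + gW
  l$gb <- if (is.null(l$gb)) gb else l$gb + gb
  dY %*% t(l$W)
}

# nearest-neighbour 2x upsampling
up2_fwd <- function(l, X) {
  d <- dim(X)
  l$in_dim <- d
  X[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up2_bwd <- function(l, dY) {
  d <- l$in_dim
  i1 <- seq(1, 2 * d[1], 2); i2 <- i1 + 1
  j1 <- seq(1, 2 * d[2], 2); j2 <- j1 + 1
  dY[i1, j1, , , drop = FALSE] + dY[i1, j2, , , drop = FALSE] +
    dY[i2, j1, , , drop = FALSE] + dY[i2, j2, , , drop = FALSE]
}

# global average pooling, (H, W, C, N) -> (N, C)
gap_fwd_nc <- function(l, X) {
  d <- dim(X)
  l$in_dim <- d
  m <- matrix(X, d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(m), d[3], d[4]))
}

gap_bwd_nc <- function(l, dY) {
  d <- l$in_dim
  g <- t(dY) / (d[1] * d[2])                 # (C, N)
  array(rep(as.numeric(g), each = d[1] * d[2]), d)
}

# --- optimiser ----------------------------------------------------------

zero_grads <- function(layers) {
  for (l in layers) for (p in l$params) l[[paste0("g", p)]] <- NULL
  invisible(NULL)
}

grad_field <- function(p) paste0("g", p)

adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in layers) for (p in l$params) {
    g <- l[[grad_field(p)]]
    if (is.null(g)) next
    mf <- paste0("m_", p); vf <- paste0("v_", p)
    if (is.null(l[[mf]])) { l[[mf]] <- g * 0; l[[vf]] <- g * 0 }
    l[[mf]] <- beta1 * l[[mf]] + (1 - beta1) * g
    l[[vf]] <- beta2 * l[[vf]] + (1 - beta2) * g * g
    l[[p]] <- l[[p]] - lr * (l[[mf]] / bc1) / (sqrt(l[[vf]] / bc2) + eps)
  }
  invisible(NULL)
}

# --- parameter (de)serialisation ---------------------------------------

# Parameters and batch-norm running statistics of a list of named layers.
layers_state <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in c(l$params, intersect(c("rm", "rv"), names(as.list(l)))))
      out[[paste0(nm, ".", p)]] <- l[[p]]
  }
  out
}

load_layers_state <- function(layers, state) {
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in c(l$params, intersect(c("rm", "rv"), names(as.list(l))))) {
      key <- paste0(nm, ".", p)
      if (!key %in% names(state)) next
      new <- state[[key]]
      old <- l[[p]]
      if (!identical(dim(old), dim(new)) || length(old) != length(new))
        stop("parameter shape mismatch at ", key, call. = FALSE)
      l[[p]] <- new
    }
  }
  invisible(layers)
}
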