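# Differentiable layer primitives over 5-d arrays laid out (X, Y, Z, C, N).
# Each *_fwd returns what its paired *_bwd needs; nothing here is exported.

tensor_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 5L)
    stop("expected a 5-d array (X, Y, Z, C, N)")
  as.integer(d)
}

#' @useDynLib fusionseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

conv3d_init <- function(k, cin, cout) {
  # He initialization: variance 2 / fan_in, the standard choice for ReLU nets
  fan_in <- k^3 * cin
  W <- array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
             dim = c(k, k, k, cin, cout))
  list(W = W, b = numeric(cout))
}

conv3d_fwd <- function(x, W, b) {
  cpp_conv3d_fwd(x, tensor_dims(x), W, dim(W), b)
}

conv3d_bwd <- function(x, W, gy) {
  cpp_conv3d_bwd(x, tensor_dims(x), W, dim(W), gy)
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(y, gy) {
  gy * (y > 0)
}

# --- batch normalization -----------------------------------------------------
# Statistics per channel over all voxels and batch items. Running moments for
# inference are tracked with momentum 0.1 (SegNet/VGG convention).

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

channel_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 3L, 5L, 4L))
  dim(m) <- c(prod(d[-4L]), d[4L])
  m
}

channel_unmat <- function(m, d) {
  dim(m) <- c(d[1L], d[2L], d[3L], d[5L], d[4L])
  aperm(m, c(1L, 2L, 3L, 5L, 4L))
}

bn_fwd <- function(x, bn, training, eps = 1e-5, momentum = 0.1) {
  d <- tensor_dims(x)
  m <- channel_mat(x)
  if (training) {
    mu <- colMeans(m)
    ctr <- sweep(m, 2L, mu)
    v <- colMeans(ctr * ctr)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var  <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    ctr <- sweep(m, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2L, istd, `*`)
  y <- channel_unmat(sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`), d)
  list(y = y, bn = bn,
       cache = list(xhat = xhat, istd = istd, gamma = bn$gamma,
                    d = d, training = training))
}

bn_bwd <- function(cache, gy) {
  d <- cache$d
  g <- channel_mat(gy)
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  if (cache$training) {
    M <- nrow(g)
    gxhat <- sweep(g, 2L, cache$gamma, `*`)
    t1 <- sweep(gxhat, 2L, colMeans(gxhat))
    t2 <- sweep(cache$xhat, 2L, colMeans(gxhat * cache$xhat), `*`)
    gx <- sweep(t1 - t2, 2L, cache$istd, `*`)
  } else {
    gx <- sweep(sweep(g, 2L, cache$gamma, `*`), 2L, cache$istd, `*`)
  }
  list(gx = channel_unmat(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# --- pooling / unpooling / upsampling ---------------------------------------

maxpool2_fwd <- function(x) {
  cpp_maxpool2_fwd(x, tensor_dims(x))
}

maxpool2_bwd <- function(gy, ind, xdim) {
  cpp_maxpool2_bwd(gy, ind, as.integer(xdim))
}

unpool2_fwd <- function(x, ind) {
  cpp_unpool2_fwd(x, ind, tensor_dims(x))
}

unpool2_bwd <- function(gy, ind, xdim) {
  cpp_unpool2_bwd(gy, ind, as.integer(xdim))
}

upsample2_fwd <- function(x) {
  cpp_upsample2_fwd(x, tensor_dims(x))
}

upsample2_bwd <- function(gy, xdim) {
  cpp_upsample2_bwd(gy, as.integer(xdim))
}

concat_channels <- function(a, b) {
  da <- tensor_dims(a)
  db <- tensor_dims(b)
  if (!all(da[-4L] == db[-4L]))
    stop("channel concatenation requires matching spatial and batch dims")
  out <- array(0, dim = c(da[1:3], da[4L] + db[4L], da[5L]))
  out[, , , seq_len(da[4L]), ] <- a
  out[, , , da[4L] + seq_len(db[4L]), ] <- b
  out
}

split_channels <- function(g, ca) {
  d <- tensor_dims(g)
  list(a = g[, , , seq_len(ca), , drop = FALSE],
       b = g[, , , (ca + 1L):d[4L], , drop = FALSE])
}

# softmax over the channel axis, numerically stable
softmax_channels <- function(logits) {
  d <- tensor_dims(logits)
  m <- channel_mat(logits)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  channel_unmat(e / rowSums(e), d)
}
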