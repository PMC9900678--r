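# Layer primitives for the reconstruction network. Activations are (C, M)
# matrices with M = H*W*N (column index = i + j*H + n*H*W), the layout the
# compiled kernels in src/ operate on. Stride-1 convolutions and the fused
# efficient-module / batch-norm kernels are compiled; the small strided
# escalate operations and the upsampler are plain R on the same layout.
# Everything here is deliberately self-contained: the learned-reconstruction
# architecture is the package's core contribution, so its numerical
# machinery is authored in-package rather than delegated.

# ---- stride-1 convolution (compiled pointer-shift BLAS path) ----

conv_s1_forward <- function(xm, H, W, N, Wt, b, pad) {
  d <- dim(Wt)
  xp <- .cpp_pad(xm, H, W, N, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  y <- .cpp_conv_fwd(xp, Hp, Wp, N, as.vector(Wt), d, b)
  list(y = y, cache = list(xp = xp, W = Wt, Hp = Hp, Wp = Wp,
                           H = H, W_ = W, N = N, pad = pad))
}

conv_s1_backward <- function(dy, cache) {
  d <- dim(cache$W)
  r <- .cpp_conv_bwd(cache$xp, dy, cache$Hp, cache$Wp, cache$N,
                     as.vector(cache$W), d)
  dx <- .cpp_unpad(r$dxp, cache$H, cache$W_, cache$N, cache$pad)
  list(dx = dx, dW = array(r$dW, d), db = r$db)
}

# ---- generic strided valid convolution (used by the escalate reduction) ----

strided_cols <- function(H, W, N, k, stride, ki, kj) {
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  i <- (seq_len(Ho) - 1L) * stride + ki - 1L
  j <- (seq_len(Wo) - 1L) * stride + kj - 1L
  n <- seq_len(N) - 1L
  1L + outer(outer(i, j * H, `+`), n * H * W, `+`)  # (Ho, Wo, N) col index
}

conv_strided_forward <- function(xm, H, W, N, Wt, b, stride) {
  d <- dim(Wt); Cout <- d[1L]; Cin <- d[2L]; k <- d[3L]
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  y <- matrix(0, Cout, Ho * Wo * N)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    idx <- strided_cols(H, W, N, k, stride, ki, kj)
    y <- y + matrix(Wt[, , ki, kj], Cout, Cin) %*% xm[, idx, drop = FALSE]
  }
  list(y = y + b,
       cache = list(xm = xm, W = Wt, H = H, W_ = W, N = N, stride = stride,
                    Ho = Ho, Wo = Wo))
}

conv_strided_backward <- function(dy, cache) {
  Wt <- cache$W; d <- dim(Wt); Cout <- d[1L]; Cin <- d[2L]; k <- d[3L]
  dW <- array(0, d)
  dx <- matrix(0, nrow(cache$xm), ncol(cache$xm))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    idx <- strided_cols(cache$H, cache$W_, cache$N, k, cache$stride, ki, kj)
    xs <- cache$xm[, idx, drop = FALSE]
    dW[, , ki, kj] <- dy %*% t(xs)
    dx[, idx] <- dx[, idx] +
      crossprod(matrix(Wt[, , ki, kj], Cout, Cin), dy)
  }
  list(dx = dx, dW = dW, db = rowSums(dy))
}

# ---- strided valid max pooling (escalate pool branch) ----

maxpool_strided_forward <- function(xm, H, W, N, k, stride) {
  C <- nrow(xm)
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  y <- matrix(-Inf, C, Ho * Wo * N)
  bestk <- matrix(0L, C, Ho * Wo * N)
  p <- 0L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    p <- p + 1L
    idx <- strided_cols(H, W, N, k, stride, ki, kj)
    xs <- xm[, idx, drop = FALSE]
    upd <- xs > y
    y[upd] <- xs[upd]
    bestk[upd] <- p
  }
  list(y = y, cache = list(bestk = bestk, H = H, W_ = W, N = N, k = k,
                           stride = stride, C = C))
}

maxpool_strided_backward <- function(dy, cache) {
  dx <- matrix(0, cache$C, cache$H * cache$W_ * cache$N)
  p <- 0L
  for (ki in seq_len(cache$k)) for (kj in seq_len(cache$k)) {
    p <- p + 1L
    idx <- strided_cols(cache$H, cache$W_, cache$N, cache$k, cache$stride,
                        ki, kj)
    dx[, idx] <- dx[, idx] + dy * (cache$bestk == p)
  }
  dx
}

# ---- nearest-neighbor 2x upsampling ----

upsample2_forward <- function(xm, H, W, N) {
  H2 <- 2L * H; W2 <- 2L * W
  i2 <- (seq_len(H2) - 1L) %/% 2L
  j2 <- (seq_len(W2) - 1L) %/% 2L
  idx <- 1L + outer(outer(i2, j2 * H, `+`), (seq_len(N) - 1L) * H * W, `+`)
  list(y = xm[, as.vector(idx), drop = FALSE],
       cache = list(H = H, W_ = W, N = N))
}

upsample2_backward <- function(dy, cache) {
  H <- cache$H; W <- cache$W_; N <- cache$N
  H2 <- 2L * H
  cols <- function(a, b) {
    i <- 2L * (seq_len(H) - 1L) + a
    j <- 2L * (seq_len(W) - 1L) + b
    1L + as.vector(outer(outer(i, j * H2, `+`),
                         (seq_len(N) - 1L) * 4L * H * W, `+`))
  }
  dy[, cols(0L, 0L), drop = FALSE] + dy[, cols(1L, 0L), drop = FALSE] +
    dy[, cols(0L, 1L), drop = FALSE] + dy[, cols(1L, 1L), drop = FALSE]
}

# ---- dense ----

dense_forward <- function(x, W, b) list(y = W %*% x + b, cache = x)
dense_backward <- function(dy, cache, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache), db = rowSums(dy))
}

he_uniform <- function(dims, fan_in) {
  limit <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -limit, limit), dims)
}
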