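# Neural-network primitives on [H, W, C] arrays with explicit forward and
# backward passes.  Convolutions are computed by kernel-offset accumulation
# of strided-slice matrix products; no external framework is involved.

as_mat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
as_arr <- function(m, h, w, c) { dim(m) <- c(h, w, c); m }

pad_hw <- function(h, k, s) {
  ho <- ceiling(h / s)
  tot <- max((ho - 1L) * s + k - h, 0L)
  c(before = tot %/% 2L, after = tot - tot %/% 2L, out = ho)
}

zero_pad <- function(x, pr, pc) {
  d <- dim(x)
  if (pr[1] + pr[2] + pc[1] + pc[2] == 0L) return(x)
  xp <- array(0, c(d[1] + pr[1] + pr[2], d[2] + pc[1] + pc[2], d[3]))
  xp[pr[1] + seq_len(d[1]), pc[1] + seq_len(d[2]), ] <- x
  xp
}

# --- standard convolution (same padding) ---------------------------------

conv2d_fwd <- function(x, W, b, stride = 1L) {
  k <- dim(W)[1:2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x)
  pr <- pad_hw(d[1], k[1], stride); pc <- pad_hw(d[2], k[2], stride)
  xp <- zero_pad(x, pr[1:2], pc[1:2])
  ho <- pr[["out"]]; wo <- pc[["out"]]
  i0 <- seq(1L, by = stride, length.out = ho)
  j0 <- seq(1L, by = stride, length.out = wo)
  out <- matrix(rep(b, each = ho * wo), ho * wo, cout)
  for (i in seq_len(k[1])) for (j in seq_len(k[2])) {
    xs <- xp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE]
    dim(xs) <- c(ho * wo, cin)
    out <- out + xs %*% matrix(W[i, j, , ], cin, cout)
  }
  list(out = as_arr(out, ho, wo, cout),
       cache = list(xp = xp, dx_dim = d, k = k, stride = stride,
                    pr = pr, pc = pc, i0 = i0, j0 = j0))
}

conv2d_bwd <- function(dout, cache, W) {
  k <- cache$k; cin <- dim(W)[3]; cout <- dim(W)[4]
  ho <- dim(dout)[1]; wo <- dim(dout)[2]
  dm <- as_mat(dout)
  dW <- array(0, dim(W))
  db <- colSums(dm)
  dxp <- array(0, dim(cache$xp))
  i0 <- cache$i0; j0 <- cache$j0
  for (i in seq_len(k[1])) for (j in seq_len(k[2])) {
    xs <- cache$xp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE]
    dim(xs) <- c(ho * wo, cin)
    dW[i, j, , ] <- crossprod(xs, dm)
    contrib <- dm %*% t(matrix(W[i, j, , ], cin, cout))
    dxp[i0 + i - 1L, j0 + j - 1L, ] <-
      dxp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE] +
      as_arr(contrib, ho, wo, cin)
  }
  d <- cache$dx_dim
  dx <- dxp[cache$pr[1] + seq_len(d[1]), cache$pc[1] + seq_len(d[2]), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# --- depthwise convolution -----------------------------------------------

dwconv_fwd <- function(x, W, b, stride = 1L) {
  k <- dim(W)[1:2]; ch <- dim(W)[3]
  d <- dim(x)
  pr <- pad_hw(d[1], k[1], stride); pc <- pad_hw(d[2], k[2], stride)
  xp <- zero_pad(x, pr[1:2], pc[1:2])
  ho <- pr[["out"]]; wo <- pc[["out"]]
  i0 <- seq(1L, by = stride, length.out = ho)
  j0 <- seq(1L, by = stride, length.out = wo)
  n <- ho * wo
  out <- matrix(rep(b, each = n), n, ch)
  for (i in seq_len(k[1])) for (j in seq_len(k[2])) {
    xs <- xp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE]
    dim(xs) <- c(n, ch)
    out <- out + xs * matrix(W[i, j, ], n, ch, byrow = TRUE)
  }
  list(out = as_arr(out, ho, wo, ch),
       cache = list(xp = xp, dx_dim = d, k = k, stride = stride,
                    pr = pr, pc = pc, i0 = i0, j0 = j0))
}

dwconv_bwd <- function(dout, cache, W) {
  k <- cache$k; ch <- dim(W)[3]
  ho <- dim(dout)[1]; wo <- dim(dout)[2]; n <- ho * wo
  dm <- as_mat(dout)
  dW <- array(0, dim(W))
  db <- colSums(dm)
  dxp <- array(0, dim(cache$xp))
  i0 <- cache$i0; j0 <- cache$j0
  for (i in seq_len(k[1])) for (j in seq_len(k[2])) {
    xs <- cache$xp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE]
    dim(xs) <- c(n, ch)
    dW[i, j, ] <- colSums(xs * dm)
    contrib <- dm * matrix(W[i, j, ], n, ch, byrow = TRUE)
    dxp[i0 + i - 1L, j0 + j - 1L, ] <-
      dxp[i0 + i - 1L, j0 + j - 1L, , drop = FALSE] +
      as_arr(contrib, ho, wo, ch)
  }
  d <- cache$dx_dim
  dx <- dxp[cache$pr[1] + seq_len(d[1]), cache$pc[1] + seq_len(d[2]), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# --- batch normalization (per channel over spatial positions) ------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(x, gamma, beta, running, training) {
  d <- dim(x)
  xm <- as_mat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- BN_MOMENTUM * running$mean + (1 - BN_MOMENTUM) * mu
    running$var <- BN_MOMENTUM * running$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - matrix(mu, nrow(xm), d[3], byrow = TRUE)) *
    matrix(ivar, nrow(xm), d[3], byrow = TRUE)
  out <- xhat * matrix(gamma, nrow(xm), d[3], byrow = TRUE) +
    matrix(beta, nrow(xm), d[3], byrow = TRUE)
  list(out = as_arr(out, d[1], d[2], d[3]), running = running,
       cache = list(xhat = xhat, ivar = ivar, dim = d))
}

bn_bwd <- function(dout, cache, gamma) {
  d <- cache$dim
  n <- d[1] * d[2]
  dm <- as_mat(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * matrix(gamma, n, d[3], byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - matrix(s1 / n, n, d[3], byrow = TRUE) -
           xhat * matrix(s2 / n, n, d[3], byrow = TRUE)) *
    matrix(cache$ivar, n, d[3], byrow = TRUE)
  list(dx = as_arr(dx, d[1], d[2], d[3]), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

# --- squeeze-and-excitation ----------------------------------------------

se_fwd <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- as_mat(x)
  s <- colMeans(xm)
  h <- pmax(drop(s %*% W1) + b1, 0)
  z <- drop(h %*% W2) + b2
  g <- 1 / (1 + exp(-z))
  out <- xm * matrix(g, n, d[3], byrow = TRUE)
  list(out = as_arr(out, d[1], d[2], d[3]),
       cache = list(xm = xm, s = s, h = h, g = g, dim = d))
}

se_bwd <- function(dout, cache, W1, W2) {
  d <- cache$dim
  n <- d[1] * d[2]
  dm <- as_mat(dout)
  g <- cache$g
  dg <- colSums(dm * cache$xm)
  dx <- dm * matrix(g, n, d[3], byrow = TRUE)
  dz2 <- dg * g * (1 - g)
  dW2 <- outer(cache$h, dz2)
  db2 <- dz2
  dh <- drop(W2 %*% dz2) * (cache$h > 0)
  dW1 <- outer(cache$s, dh)
  db1 <- dh
  ds <- drop(W1 %*% dh)
  dx <- dx + matrix(ds / n, n, d[3], byrow = TRUE)
  list(dx = as_arr(dx, d[1], d[2], d[3]),
       dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# --- 2x2 stride-2 transposed convolution (upsampling) --------------------

tconv_fwd <- function(x, W, b) {
  d <- dim(x)
  cin <- dim(W)[3]; cout <- dim(W)[4]
  xm <- as_mat(x)
  out <- array(0, c(2L * d[1], 2L * d[2], cout))
  for (di in 1:2) for (dj in 1:2) {
    om <- xm %*% matrix(W[di, dj, , ], cin, cout) +
      matrix(b, nrow(xm), cout, byrow = TRUE)
    out[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), ] <-
      as_arr(om, d[1], d[2], cout)
  }
  list(out = out, cache = list(xm = xm, dim = d))
}

tconv_bwd <- function(dout, cache, W) {
  d <- cache$dim
  cin <- dim(W)[3]; cout <- dim(W)[4]
  dW <- array(0, dim(W))
  db <- numeric(cout)
  dxm <- matrix(0, d[1] * d[2], cin)
  for (di in 1:2) for (dj in 1:2) {
    par <- dout[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), , drop = FALSE]
    pm <- as_mat(par)
    dW[di, dj, , ] <- crossprod(cache$xm, pm)
    db <- db + colSums(pm)
    dxm <- dxm + pm %*% t(matrix(W[di, dj, , ], cin, cout))
  }
  list(dx = as_arr(dxm, d[1], d[2], cin), dW = dW, db = db)
}

# --- softmax head and cross-entropy --------------------------------------

softmax_probs <- function(logits) {
  d <- dim(logits)
  lm <- as_mat(logits)
  lm <- lm - apply(lm, 1, max)
  e <- exp(lm)
  p <- e / rowSums(e)
  as_arr(p, d[1], d[2], d[3])
}

# labels: integer matrix [H, W] with classes 0..K-1
softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  p <- as_mat(softmax_probs(logits))
  idx <- cbind(seq_len(nrow(p)), as.integer(labels) + 1L)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, dlogits = as_arr(dlog / n, d[1], d[2], d[3]))
}

# --- parameter-tree utilities --------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(el) tree_map(f, el)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

tree_sum <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, function(el) tree_sum(f, el), 0)))
  f(a)
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

adam_init <- function(params) {
  list(m = tree_map(function(a) array(0, dim(a) %||% length(a)), params),
       v = tree_map(function(a) array(0, dim(a) %||% length(a)), params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
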