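# Minimal convolutional building blocks with analytic backward passes.
# All tensors are column-major R arrays [H, W, C, N]; convolutions run
# through compiled im2col + GEMM kernels.

conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  conv2d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad), FALSE)
}

conv2d_backward <- function(x, w, dy, stride = 1L, pad = 1L, want_dx = TRUE) {
  conv2d_bwd_cpp(x, w, dy, as.integer(stride), as.integer(pad), want_dx,
                 numeric(0))
}

relu <- function(x) relu_fwd_cpp(x)

# --- Per-sample layer normalization -----------------------------------
# Normalizes each sample's feature tensor to zero mean / unit variance
# over all (H, W, C) elements, then applies a per-channel learnable gain
# and bias. Statistics are per sample, so eval-mode behavior needs no
# running averages and stays deterministic; unlike per-channel spatial
# statistics this remains well defined on 1x1 maps.

LN_EPS <- 1e-5

layernorm_fwd <- function(x, gamma, beta) {
  d <- dim(x); M <- d[1] * d[2] * d[3]; N <- d[4]
  xm <- matrix(x, M, N)
  mu <- colMeans(xm)
  ctr <- xm - rep(mu, each = M)
  sig <- sqrt(colMeans(ctr^2) + LN_EPS)
  xhat <- ctr * rep(1 / sig, each = M)
  gb <- rep(rep(gamma, each = d[1] * d[2]), N)
  bb <- rep(rep(beta, each = d[1] * d[2]), N)
  y <- xhat * gb + bb
  dim(y) <- d; dim(xhat) <- d
  list(y = y, xhat = xhat, sig = sig)
}

layernorm_bwd <- function(dy, cache, gamma) {
  d <- dim(dy); HW <- d[1] * d[2]; M <- HW * d[3]; N <- d[4]
  xhat <- cache$xhat
  gb <- rep(rep(gamma, each = HW), N)
  g <- matrix(dy * gb, M, N)
  xh <- matrix(xhat, M, N)
  mg <- colMeans(g)
  mgx <- colMeans(g * xh)
  dx <- (g - rep(mg, each = M) - xh * rep(mgx, each = M)) *
    rep(1 / cache$sig, each = M)
  dim(dx) <- d
  per_cn <- function(a) {
    s <- colSums(matrix(a, HW, d[3] * N))
    rowSums(matrix(s, d[3], N))
  }
  list(dx = dx, dgamma = per_cn(dy * xhat), dbeta = per_cn(dy))
}

# --- Weight-normalized filters --------------------------------------------
# Backbone kernels are stored as raw vectors v and applied as unit-norm
# filters v/||v|| (per output channel); the layer norm downstream makes
# the overall scale irrelevant. As with the cosine head, a small ||v||
# turns the fixed learning rate into a usable angular rate on the filter
# direction, so the feature extractor itself is trainable from scratch
# under a small fixed lr.

normalize_filters <- function(v) {
  d <- dim(v)
  m <- matrix(v, prod(d[1:3]), d[4])
  n <- sqrt(colSums(m^2)) + WNORM_EPS
  list(w = array(sweep(m, 2, n, "/"), d), n = n)
}

filters_backward <- function(dwn, v, n) {
  d <- dim(v)
  m <- matrix(v, prod(d[1:3]), d[4])
  dm <- matrix(dwn, prod(d[1:3]), d[4])
  vhat <- sweep(m, 2, n, "/")
  proj <- colSums(vhat * dm)
  array(sweep(dm - sweep(vhat, 2, proj, "*"), 2, n, "/"), d)
}

# Convolution (weight-normalized) + layer-norm + ReLU block of the trunk.
conv_block_fwd <- function(x, p, stride) {
  nf <- normalize_filters(p$w)
  pre <- conv2d(x, nf$w, p$b, stride = stride, pad = 1L)
  nrm <- layernorm_fwd(pre, p$gamma, p$beta)
  y <- relu(nrm$y)
  list(y = y, x = x, stride = stride, xhat = nrm$xhat, sig = nrm$sig,
       wn = nf)
}

conv_block_bwd <- function(dy, cache, p, want_dx = TRUE) {
  dn <- relu_bwd_cpp(dy, cache$y)
  ln <- layernorm_bwd(dn, cache, p$gamma)
  g <- conv2d_backward(cache$x, cache$wn$w, ln$dx, stride = cache$stride,
                       pad = 1L, want_dx = want_dx)
  list(dx = g$dx, dw = filters_backward(g$dw, p$w, cache$wn$n), db = g$db,
       dgamma = ln$dgamma, dbeta = ln$dbeta)
}

# --- Efficient channel attention (ECA) neck -------------------------------
# Global average pool per channel, 1-D convolution of adaptive odd kernel
# size over the channel descriptor, sigmoid gate, channel-wise rescale.

#' Adaptive kernel size for the channel-attention neck
#'
#' Odd 1-D kernel size derived from the channel count by the published
#' efficient-channel-attention rule `k = |log2(C)/gamma + b/gamma|_odd`
#' with `gamma = 2`, `b = 1`.
#'
#' @param channels Number of feature channels.
#' @return An odd integer kernel size (at least 1).
#' @export
eca_kernel_size <- function(channels) {
  t <- abs(log2(channels) / 2 + 1 / 2)
  k <- max(1L, as.integer(floor(t)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

conv1d_channels <- function(v, w) {
  # v: C x N channel descriptors; w: odd-length kernel, zero padded.
  k <- length(w); off <- (k + 1L) %/% 2L
  C <- nrow(v)
  out <- matrix(0, C, ncol(v))
  for (t in seq_len(k)) {
    src <- seq_len(C) + (t - off)
    ok <- src >= 1 & src <= C
    out[ok, ] <- out[ok, ] + w[t] * v[src[ok], , drop = FALSE]
  }
  out
}

conv1d_channels_adjoint <- function(d, w) {
  # forward is pre[c] = sum_t w[t] * v[c + t - off], so the adjoint is
  # dv[m] = sum_t w[t] * d[m - t + off]
  k <- length(w); off <- (k + 1L) %/% 2L
  C <- nrow(d)
  out <- matrix(0, C, ncol(d))
  for (t in seq_len(k)) {
    src <- seq_len(C) - (t - off)
    ok <- src >= 1 & src <= C
    out[ok, ] <- out[ok, , drop = FALSE] + w[t] * d[src[ok], , drop = FALSE]
  }
  out
}

eca_fwd <- function(x, w) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gap <- colMeans(matrix(x, H * W, C * N))
  dim(gap) <- c(C, N)
  pre <- conv1d_channels(gap, w)
  g <- sigmoid(pre)
  y <- x * rep(g, each = H * W)
  list(y = y, g = g, gap = gap, x = x)
}

eca_bwd <- function(dy, cache, w) {
  d <- dim(dy); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- cache$g
  dg <- colSums(matrix(dy * cache$x, H * W, C * N))
  dim(dg) <- c(C, N)
  dpre <- dg * g * (1 - g)
  # kernel gradient: dpre[c] pairs with gap[c + t - off]
  k <- length(w); off <- (k + 1L) %/% 2L
  dw <- numeric(k)
  for (t in seq_len(k)) {
    src <- seq_len(C) + (t - off)
    ok <- src >= 1 & src <= C
    dw[t] <- sum(dpre[ok, , drop = FALSE] * cache$gap[src[ok], , drop = FALSE])
  }
  dgap <- conv1d_channels_adjoint(dpre, w)
  dx <- dy * rep(g, each = H * W) + rep(dgap, each = H * W) / (H * W)
  list(dx = dx, dw = dw)
}

# --- Class-specific residual attention (CSRA) head ------------------------
# Per class: a base score from average-pooled per-position class scores plus
# a residual temperature-softmax spatial attention score. The per-class
# classifier vectors are L2-normalized and multiplied by a fixed score
# scale (a cosine-style classifier): the score magnitude is then
# independent of the weight norm, and the direction — the part that
# matters for class separation — trains at an effective rate of lr/||w||,
# which keeps the head fully learnable under small fixed learning rates.

WNORM_EPS <- 1e-12

head_weight_matrix <- function(p, score_scale) {
  if (is.null(score_scale)) return(p$w)  # raw (un-normalized) classifier
  nrm <- sqrt(colSums(p$w^2)) + WNORM_EPS
  sweep(p$w, 2, score_scale / nrm, "*")
}

csra_fwd <- function(x, p, temperature, residual_weight, score_scale) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  J <- H * W; K <- ncol(p$w)
  Wn <- head_weight_matrix(p, score_scale)
  logits <- matrix(0, N, K)
  smaps <- vector("list", N); amaps <- vector("list", N); atts <- vector("list", N)
  for (n in seq_len(N)) {
    M <- matrix(x[, , , n], J, C)
    S <- M %*% Wn                        # J x K per-position class scores
    Sc <- sweep(S, 2, apply(S, 2, max))  # stable softmax
    A <- exp(Sc / temperature)
    A <- sweep(A, 2, colSums(A), "/")
    att <- colSums(A * S)
    logits[n, ] <- colMeans(S) + residual_weight * att + p$b
    smaps[[n]] <- S; amaps[[n]] <- A; atts[[n]] <- att
  }
  list(logits = logits, S = smaps, A = amaps, att = atts, x = x)
}

csra_bwd <- function(dlogits, cache, p, temperature, residual_weight,
                     score_scale) {
  x <- cache$x
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  J <- H * W; K <- ncol(p$w)
  Wn <- head_weight_matrix(p, score_scale)
  dx <- array(0, dim = d)
  dWn <- matrix(0, C, K)
  db <- colSums(matrix(dlogits, N, K))
  for (n in seq_len(N)) {
    S <- cache$S[[n]]; A <- cache$A[[n]]; att <- cache$att[[n]]
    dl <- dlogits[n, ]
    datt_dS <- A + A * sweep(S, 2, att) / temperature
    dS <- matrix(dl, J, K, byrow = TRUE) * (1 / J + residual_weight * datt_dS)
    M <- matrix(x[, , , n], J, C)
    dWn <- dWn + t(M) %*% dS
    dM <- dS %*% t(Wn)
    dx[, , , n] <- array(dM, dim = c(H, W, C))
  }
  if (is.null(score_scale)) {
    dw <- dWn
  } else {
    # pull the gradient back through the weight normalization
    nrm <- sqrt(colSums(p$w^2)) + WNORM_EPS
    what <- sweep(p$w, 2, nrm, "/")
    proj <- colSums(what * dWn)
    dw <- sweep(dWn - sweep(what, 2, proj, "*"), 2, score_scale / nrm, "*")
  }
  list(dx = dx, dw = dw, db = db)
}
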