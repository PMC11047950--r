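# Internal numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @useDynLib pvib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic seed derivation: one master seed fans out to independent
# streams (weight init, shuffling, noise draws). Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    v <- if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.numeric(t)
    h <- (h * 69069 + v + 12345) %% 2147483629
  }
  as.integer(h)
}

# Promote a [H,W,C] array or a plain matrix to a [H,W,C,N] batch array.
as_batch4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) {
    stop("expected an array with dims [H, W, C] or [H, W, C, N]", call. = FALSE)
  }
  x
}

# Stack a list of H x W grayscale matrices into a [H, W, 1, N] batch.
stack_images <- function(images, idx = seq_along(images)) {
  H <- nrow(images[[idx[1]]]); W <- ncol(images[[idx[1]]])
  out <- array(0, dim = c(H, W, 1L, length(idx)))
  for (i in seq_along(idx)) out[, , 1L, i] <- images[[idx[i]]]
  out
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# Glorot-uniform initialization for a [kh, kw, Cin, Cout] convolution kernel.
init_conv_weights <- function(kh, kw, cin, cout, gain = 1) {
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  lim <- gain * sqrt(6 / (fan_in + fan_out))
  array(stats::runif(kh * kw * cin * cout, -lim, lim), dim = c(kh, kw, cin, cout))
}

# Bilinear resize of a single-channel matrix; used when importing images
# whose on-disk size differs from the model resolution.
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  if (H == out_h && W == out_w) return(img)
  # map output pixel centers into input coordinates
  ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- clamp(floor(ys), 1, H); y1 <- clamp(y0 + 1, 1, H)
  x0 <- clamp(floor(xs), 1, W); x1 <- clamp(x0 + 1, 1, W)
  wy <- clamp(ys - y0, 0, 1); wx <- clamp(xs - x0, 0, 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
  bot <- c_ * outer(rep(1, out_h), 1 - wx) + d * outer(rep(1, out_h), wx)
  top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
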