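# The patch-level variational information bottleneck (P-VIB) layer.
#
# Two parallel 3x3 same-padded convolutions map a feature map F of shape
# [C_in, W, H] to the parameters of a per-position Gaussian posterior:
# one predicts the mean field mu, the other the log standard deviation,
# so sigma = exp(log sigma) is strictly positive by construction
# (log sigma clamped to [-10, 10] for numerical safety). In training mode
# the latent map is the reparameterized sample z = mu + eps * sigma with
# eps drawn i.i.d. standard normal per element; in eval mode z = mu.

LOGSIG_CLAMP <- 10

#' Create a P-VIB layer parameter set
#'
#' Initializes the two parallel 3x3 convolutions of a patch-level
#' variational bottleneck layer. The mean convolution gets small-variance
#' (Glorot-uniform) weights with zero bias; the log-sigma convolution
#' starts at zero weights with constant bias `log(sigma0)`, so the
#' initial posterior standard deviation is exactly `sigma0` everywhere
#' and the initial KL penalty depends only on the mean field and
#' `sigma0`.
#'
#' @param in_channels Input channel count of the feature map.
#' @param out_channels Latent channel count; defaults to `in_channels` so
#'   the layer is drop-in shape preserving.
#' @param sigma0 Initial posterior standard deviation (the log-sigma
#'   convolution starts at zero weights with bias `log(sigma0)`). In a
#'   short training run the sigma branch barely moves under a small
#'   fixed learning rate, so this value effectively sets the strength of
#'   the noise regularization relative to the (normalized) feature
#'   scale; the default 0.5 injects noise at half the feature scale.
#' @return A list of parameter arrays (`w_mu`, `b_mu`, `w_ls`, `b_ls`)
#'   with class `pvib_layer`.
#' @export
pvib_layer <- function(in_channels, out_channels = in_channels,
                       sigma0 = 0.5) {
  stopifnot(in_channels >= 1, out_channels >= 1, sigma0 > 0)
  structure(list(
    w_mu = init_conv_weights(3L, 3L, in_channels, out_channels),
    b_mu = numeric(out_channels),
    w_ls = array(0, dim = c(3L, 3L, in_channels, out_channels)),
    b_ls = rep(log(sigma0), out_channels),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels)
  ), class = "pvib_layer")
}

#' Forward pass of the P-VIB layer
#'
#' Predicts the per-position Gaussian posterior (mu, sigma) of the latent
#' feature map with two parallel 3x3 same-padded convolutions and returns a
#' latent sample. In `"train"` mode every element is sampled as
#' `z = mu + eps * sigma` with fresh i.i.d. standard-normal `eps` (the
#' reparameterization trick, applied at every spatial position); in
#' `"eval"` mode `z = mu` and no sampling occurs. The output spatial shape
#' always equals the input spatial shape.
#'
#' @param feature Feature map array `[H, W, C]` or batch `[H, W, C, N]`.
#' @param layer A [pvib_layer()] parameter set.
#' @param mode `"train"` (sample) or `"eval"` (deterministic `z = mu`).
#' @param eps Optional array of standard-normal draws matching the latent
#'   shape; when `NULL` in train mode it is drawn from the current RNG
#'   stream (seed with `set.seed()` for reproducibility).
#' @return A list with the latent sample `z`, the posterior `field`
#'   (list with `mu`, `sigma`), and `epsilon` (`NULL` in eval mode).
#' @export
pvib_forward <- function(feature, layer, mode = c("train", "eval"), eps = NULL) {
  mode <- match.arg(mode)
  x <- as_batch4d(feature)
  check_finite(x, "feature map")
  if (dim(x)[3] != layer$in_channels) {
    stop(sprintf("P-VIB layer expects %d input channels, got %d",
                 layer$in_channels, dim(x)[3]), call. = FALSE)
  }
  mu <- conv2d(x, layer$w_mu, layer$b_mu, stride = 1L, pad = 1L)
  lsp <- conv2d(x, layer$w_ls, layer$b_ls, stride = 1L, pad = 1L)
  ls <- clamp(lsp, -LOGSIG_CLAMP, LOGSIG_CLAMP)
  sigma <- exp(ls)
  if (mode == "train") {
    if (is.null(eps)) {
      eps <- array(stats::rnorm(length(mu)), dim = dim(mu))
    } else {
      stopifnot(all(dim(eps) == dim(mu)))
    }
    z <- mu + eps * sigma
  } else {
    eps <- NULL
    z <- mu
  }
  list(z = z, field = gaussian_field(mu, sigma), epsilon = eps,
       cache = list(x = x, mu = mu, lsp = lsp, sigma = sigma, eps = eps,
                    mode = mode))
}

# Backward pass through the layer. dz is the gradient arriving at the
# latent sample; dmu_extra / dsigma_extra inject the (beta-weighted) KL
# gradients on the posterior parameters.
pvib_backward <- function(dz, cache, layer, dmu_extra = 0, dsigma_extra = 0) {
  dmu <- dz + dmu_extra
  dsigma <- dsigma_extra
  if (cache$mode == "train") dsigma <- dsigma + dz * cache$eps
  if (identical(dsigma, 0)) dsigma <- array(0, dim = dim(cache$mu))
  inside <- abs(cache$lsp) < LOGSIG_CLAMP
  dls <- dsigma * cache$sigma * inside
  gmu <- conv2d_backward(cache$x, layer$w_mu, dmu, stride = 1L, pad = 1L)
  gls <- conv2d_backward(cache$x, layer$w_ls, dls, stride = 1L, pad = 1L)
  list(dx = gmu$dx + gls$dx,
       dw_mu = gmu$dw, db_mu = gmu$db, dw_ls = gls$dw, db_ls = gls$db)
}

#' Gaussian posterior field over a feature map
#'
#' Pairs the mean and standard-deviation maps predicted by a P-VIB layer.
#'
#' @param mu,sigma Numeric arrays of identical shape; `sigma` must be
#'   strictly positive everywhere.
#' @return A list with elements `mu` and `sigma`, class `pvib_field`.
#' @export
gaussian_field <- function(mu, sigma) {
  if (!identical(dim(mu) %||% length(mu), dim(sigma) %||% length(sigma))) {
    stop("mu and sigma must have identical shape", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma), class = "pvib_field")
}

#' Per-scale KL feature-selection loss
#'
#' The patch-level bottleneck penalty at one scale: the mean over all
#' positions j and channels k of
#' `mu[j,k]^2 + sigma[j,k]^2 - 2*log(sigma[j,k]) - 1`,
#' i.e. twice the per-element KL divergence of the posterior
#' `N(mu, sigma^2)` from the standard-normal prior, averaged over the
#' `C * W * H` latent elements. The value is nonnegative and zero exactly
#' when `mu == 0` and `sigma == 1` everywhere.
#'
#' @param field A [gaussian_field()] (or any list with `mu` and `sigma`).
#' @return A nonnegative scalar.
#' @export
kl_loss_scale <- function(field) {
  mu <- field$mu; sigma <- field$sigma
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  mean(mu^2 + sigma^2 - 2 * log(sigma) - 1)
}

#' Total KL feature-selection loss over scales
#'
#' Sum of [kl_loss_scale()] over the supplied posterior fields (one per
#' active scale; fewer than three when multi-scale is ablated).
#'
#' @param fields Non-empty list of [gaussian_field()] objects.
#' @return A nonnegative scalar.
#' @export
kl_loss_total <- function(fields) {
  if (length(fields) == 0) {
    stop("kl_loss_total needs at least one Gaussian field", call. = FALSE)
  }
  sum(vapply(fields, kl_loss_scale, numeric(1)))
}

# Gradient of kl_loss_scale with respect to mu and sigma.
kl_grad_scale <- function(field) {
  m <- length(field$mu)
  list(dmu = 2 * field$mu / m,
       dsigma = (2 * field$sigma - 2 / field$sigma) / m)
}

#' Quadrature oracle for the per-element bottleneck penalty
#'
#' Computes `2 * KL(N(mu, sigma^2) || N(0, 1))` by numerical integration
#' of the KL integrand, independent of the closed form used by
#' [kl_loss_scale()]. Intended for verification in tests.
#'
#' @param mu,sigma Scalars; `sigma > 0`.
#' @return The elementwise penalty to quadrature tolerance.
#' @export
kl_oracle <- function(mu, sigma) {
  stopifnot(length(mu) == 1, length(sigma) == 1, sigma > 0)
  f <- function(x) {
    lp <- stats::dnorm(x, mu, sigma, log = TRUE)
    lq <- stats::dnorm(x, log = TRUE)
    exp(lp) * (lp - lq)
  }
  q <- stats::integrate(f, mu - 15 * sigma, mu + 15 * sigma,
                        rel.tol = 1e-11, abs.tol = 1e-13, subdivisions = 400L)
  if (q$message != "OK") stop("quadrature failed: ", q$message, call. = FALSE)
  2 * q$value
}
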