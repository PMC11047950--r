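# Bias focal classification loss, its multi-scale aggregation, and the
# beta-weighted combined training objective.

#' Loss configuration
#'
#' Hyperparameters of the combined objective: the positive/negative bias
#' `alpha` of the bias focal loss, the per-scale focusing exponents
#' `lambda_per_scale` (one per scale l = 1, 2, 3, i.e. P2, P3, P4), and
#' the bottleneck weight `beta` multiplying the KL feature-selection loss.
#'
#' `lambda_mode = "exponent"` applies `lambda_l` as the focal exponent on
#' the modulating factors, the literal form of the loss;
#' `"multiplier"` instead multiplies each scale's (unfocused) loss by
#' `lambda_l`, provided for sensitivity study since the default values
#' (0.5, 0.3, 0.1) also read naturally as per-scale weights.
#'
#' @param alpha Bias between the positive and negative terms, in (0, 1).
#' @param lambda_per_scale Numeric vector of per-scale focusing values.
#' @param beta Nonnegative weight of the KL feature-selection loss.
#' @param eps Probability clamp applied on both sides before logs.
#' @param lambda_mode `"exponent"` (literal) or `"multiplier"`.
#' @return A list with class `pvib_loss_config`.
#' @export
loss_config <- function(alpha = 0.4, lambda_per_scale = c(0.5, 0.3, 0.1),
                        beta = 0.1, eps = 1e-7,
                        lambda_mode = c("exponent", "multiplier")) {
  lambda_mode <- match.arg(lambda_mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (any(lambda_per_scale < 0)) stop("lambda values must be nonnegative", call. = FALSE)
  structure(list(alpha = alpha, lambda_per_scale = lambda_per_scale,
                 beta = beta, eps = eps, lambda_mode = lambda_mode),
            class = "pvib_loss_config")
}

check_probs <- function(probs) {
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1] before clamping", call. = FALSE)
  }
  invisible(probs)
}

#' Bias focal loss at one scale
#'
#' Class-imbalance-aware multi-label loss. Per sample it averages over the
#' C classes
#' `-alpha * (1-p)^lambda_l * y * log(p) - (1-alpha) * p^lambda_l * (1-y) * log(1-p)`
#' and the result is the arithmetic mean over the N samples. With
#' `lambda_l = 0` and `alpha = 0.5` it reduces to half the mean binary
#' cross-entropy.
#'
#' @param probs `N x C` matrix of sigmoid probabilities.
#' @param labels `N x C` binary matrix (or a dataset's label matrix).
#' @param alpha Positive/negative bias in (0, 1).
#' @param lambda_l Focusing value for this scale.
#' @param eps Clamp width keeping probabilities inside (0, 1).
#' @param lambda_mode See [loss_config()].
#' @return A finite nonnegative scalar.
#' @export
bias_focal_loss_scale <- function(probs, labels, alpha = 0.4, lambda_l = 0.5,
                                  eps = 1e-7,
                                  lambda_mode = c("exponent", "multiplier")) {
  lambda_mode <- match.arg(lambda_mode)
  probs <- as.matrix(probs); y <- as.matrix(labels)
  if (!all(dim(probs) == dim(y))) {
    stop("probs and labels must have matching dimensions", call. = FALSE)
  }
  check_probs(probs)
  p <- clamp(probs, eps, 1 - eps)
  if (lambda_mode == "exponent") {
    pos <- -alpha * (1 - p)^lambda_l * y * log(p)
    neg <- -(1 - alpha) * p^lambda_l * (1 - y) * log(1 - p)
    mean(pos + neg)
  } else {
    pos <- -alpha * y * log(p)
    neg <- -(1 - alpha) * (1 - y) * log(1 - p)
    lambda_l * mean(pos + neg)
  }
}

# Gradient of bias_focal_loss_scale w.r.t. the (clamped) probabilities,
# including the 1/(N*C) averaging; entries where the clamp is active get
# zero gradient.
bias_focal_grad <- function(probs, y, alpha, lambda_l, eps = 1e-7,
                            lambda_mode = "exponent") {
  p <- clamp(probs, eps, 1 - eps)
  n <- length(p)
  if (lambda_mode == "exponent") {
    gpos <- -alpha * ((1 - p)^lambda_l) / p
    gneg <- (1 - alpha) * (p^lambda_l) / (1 - p)
    if (lambda_l > 0) {
      gpos <- gpos + alpha * lambda_l * (1 - p)^(lambda_l - 1) * log(p)
      gneg <- gneg - (1 - alpha) * lambda_l * p^(lambda_l - 1) * log(1 - p)
    }
    g <- (y * gpos + (1 - y) * gneg) / n
  } else {
    g <- lambda_l * (y * (-alpha / p) + (1 - y) * ((1 - alpha) / (1 - p))) / n
  }
  g * (probs > eps & probs < 1 - eps)
}

#' Total classification loss over scales
#'
#' Sum over the active scales of [bias_focal_loss_scale()] evaluated with
#' that scale's `lambda_l`.
#'
#' @param probs_per_scale List (one per active scale) of `N x C`
#'   probability matrices.
#' @param labels `N x C` binary matrix.
#' @param cfg A [loss_config()]; `cfg$lambda_per_scale` must have one
#'   entry per supplied scale.
#' @return A nonnegative scalar.
#' @export
classification_loss_total <- function(probs_per_scale, labels, cfg = loss_config()) {
  L <- length(probs_per_scale)
  if (L == 0) stop("no scale predictions supplied", call. = FALSE)
  if (L != length(cfg$lambda_per_scale)) {
    stop(sprintf("%d scales but %d lambda values configured",
                 L, length(cfg$lambda_per_scale)), call. = FALSE)
  }
  sum(vapply(seq_len(L), function(l) {
    bias_focal_loss_scale(probs_per_scale[[l]], labels, alpha = cfg$alpha,
                          lambda_l = cfg$lambda_per_scale[l], eps = cfg$eps,
                          lambda_mode = cfg$lambda_mode)
  }, numeric(1)))
}

#' Combined training objective
#'
#' The beta-weighted sum `total = cls + beta * kl` of the classification
#' loss and the KL feature-selection loss, with the per-scale components
#' recorded alongside.
#'
#' @param cls Classification loss: a scalar total or a per-scale vector.
#' @param kl KL loss: a scalar total or a per-scale vector (use 0 when the
#'   bottleneck is disabled).
#' @param beta Nonnegative weight of the KL term.
#' @return A `pvib_loss_breakdown`: list with `cls_per_scale`,
#'   `kl_per_scale`, `cls_total`, `kl_total`, `beta` and `total`.
#' @export
total_loss <- function(cls, kl, beta) {
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  structure(list(
    cls_per_scale = cls, kl_per_scale = kl,
    cls_total = sum(cls), kl_total = sum(kl),
    beta = beta, total = sum(cls) + beta * sum(kl)
  ), class = "pvib_loss_breakdown")
}

#' @export
print.pvib_loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.6g = cls %.6g + beta %.3g * kl %.6g\n",
              x$total, x$cls_total, x$beta, x$kl_total))
  invisible(x)
}
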