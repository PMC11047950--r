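# Model assembly: stride-pyramid backbone -> (optional P-VIB) -> channel
# attention neck -> class-specific residual attention head, at up to three
# pyramid scales (P2/P3/P4 at strides 8/16/32 of the input image).

SCALE_ORDER <- c("P2", "P3", "P4")

#' Model configuration
#'
#' Describes the architecture: which pyramid scales feed a classification
#' head, where (if anywhere) the patch-level bottleneck sits relative to
#' the channel-attention neck, and the head settings. All ablation
#' variants (no neck, single scale, bottleneck before/after the neck or
#' absent) are reachable from this configuration alone.
#'
#' @param num_classes Number of binary labels.
#' @param backbone One of `"small_cnn"` (the compact desk-scale pyramid
#'   shipped with the package), or `"res2net50"`, `"resnet50"`,
#'   `"densenet121"` — named hooks for externally supplied pretrained
#'   backbones, not bundled.
#' @param scales Non-empty subset of `c("P2","P3","P4")`; `"P4"` must be
#'   included (single-scale ablation keeps only the coarsest head).
#' @param vib_position `"before_neck"`, `"after_neck"`, or `"none"`.
#' @param use_neck Keep the channel-attention neck?
#' @param vib_out_channels `"same"` (latent channels equal the scale's
#'   feature channels) or a named integer vector per scale.
#' @param head_temperature Softmax temperature of the attention head.
#' @param head_residual_weight Weight of the residual attention score.
#' @param head_score_scale Fixed score scale of the weight-normalized
#'   (cosine) classifier in the head; `NULL` uses raw weights.
#' @param backbone_channels Four channel widths of the small backbone
#'   (stem, P2, P3, P4).
#' @param image_channels Input image channels (1 = grayscale).
#' @param image_size Expected input resolution `(H, W)`.
#' @param norm_mean,norm_sd Input normalization applied inside the model.
#' @return A `pvib_model_config` list.
#' @export
model_config <- function(num_classes,
                         backbone = c("small_cnn", "res2net50", "resnet50", "densenet121"),
                         scales = c("P2", "P3", "P4"),
                         vib_position = c("before_neck", "after_neck", "none"),
                         use_neck = TRUE,
                         vib_out_channels = "same",
                         head_temperature = 1.0,
                         head_residual_weight = 0.1,
                         head_score_scale = 4.0,
                         backbone_channels = c(8L, 16L, 32L, 64L),
                         image_channels = 1L,
                         image_size = c(224L, 224L),
                         norm_mean = 0.5, norm_sd = 0.25) {
  backbone <- match.arg(backbone)
  vib_position <- match.arg(vib_position)
  if (length(scales) == 0 || !all(scales %in% SCALE_ORDER)) {
    stop("scales must be a non-empty subset of P2/P3/P4", call. = FALSE)
  }
  if (!"P4" %in% scales) {
    stop("the coarsest scale P4 must always be active", call. = FALSE)
  }
  if (length(backbone_channels) != 4) {
    stop("backbone_channels must give four widths", call. = FALSE)
  }
  scales <- SCALE_ORDER[SCALE_ORDER %in% scales]
  structure(list(
    num_classes = as.integer(num_classes), backbone = backbone,
    scales = scales, vib_position = vib_position, use_neck = use_neck,
    vib_out_channels = vib_out_channels,
    head_temperature = head_temperature,
    head_residual_weight = head_residual_weight,
    head_score_scale = head_score_scale,
    backbone_channels = as.integer(backbone_channels),
    image_channels = as.integer(image_channels),
    image_size = as.integer(image_size),
    norm_mean = norm_mean, norm_sd = norm_sd
  ), class = "pvib_model_config")
}

scale_channels <- function(cfg) {
  ch <- cfg$backbone_channels
  c(P2 = ch[2], P3 = ch[3], P4 = ch[4])
}

vib_channels_for <- function(cfg, scale) {
  sc <- scale_channels(cfg)[[scale]]
  v <- cfg$vib_out_channels
  if (identical(v, "same")) sc else as.integer(v[[scale]])
}

#' Build a model from a configuration
#'
#' Initializes all learnable parameters. Only the `small_cnn` backbone is
#' bundled; the named large backbones are hooks for user-supplied weights.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `pvib_model` (list with `cfg` and `params`).
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pvib_model_config"))
  if (cfg$backbone != "small_cnn") {
    stop(sprintf(paste0("backbone '%s' is a hook for externally supplied ",
                        "pretrained weights; only 'small_cnn' is bundled"),
                 cfg$backbone), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, "init"))
  ch <- cfg$backbone_channels
  conv_p <- function(cin, cout) {
    # random directions at small norm 0.05 per filter: the direction is
    # what the weight-normalized convolution uses, and the small raw norm
    # keeps it trainable at the default learning rate
    v <- array(stats::rnorm(9 * cin * cout), c(3L, 3L, cin, cout))
    m <- matrix(v, 9 * cin, cout)
    v <- array(sweep(m, 2, sqrt(colSums(m^2)) / 0.05, "/"), dim(v))
    list(w = v, b = numeric(cout), gamma = rep(1, cout),
         beta = numeric(cout))
  }
  params <- list(trunk = list(
    stem1 = conv_p(cfg$image_channels, ch[1]),
    stem2 = conv_p(ch[1], ch[1]),
    b2 = conv_p(ch[1], ch[2]),
    b3 = conv_p(ch[2], ch[3]),
    b4 = conv_p(ch[3], ch[4])
  ))
  params$scales <- list()
  for (s in cfg$scales) {
    sc <- scale_channels(cfg)[[s]]
    vc <- vib_channels_for(cfg, s)
    branch_ch <- if (cfg$vib_position == "none") sc else vc
    neck_ch <- if (cfg$vib_position == "before_neck") vc else sc
    layer <- list()
    if (cfg$vib_position != "none") layer$vib <- pvib_layer(sc, vc)
    if (cfg$use_neck) {
      k <- eca_kernel_size(neck_ch)
      layer$neck <- list(w = rep(1 / k, k))
    }
    # small-norm random classifier: with weight normalization the
    # direction trains at an effective rate lr/||w||, so a small initial
    # norm keeps the head fully learnable under a small fixed lr, while
    # logits still start near zero (p ~ 0.5)
    layer$head <- list(
      w = matrix(stats::rnorm(branch_ch * cfg$num_classes, 0, 0.01),
                 branch_ch, cfg$num_classes),
      b = numeric(cfg$num_classes))
    params$scales[[s]] <- layer
  }
  structure(list(cfg = cfg, params = params), class = "pvib_model")
}

#' @export
print.pvib_model <- function(x, ...) {
  n_par <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf("pvib model: %s backbone, scales %s, bottleneck %s, neck %s (%d parameters)\n",
              x$cfg$backbone, paste(x$cfg$scales, collapse = "/"),
              x$cfg$vib_position, ifelse(x$cfg$use_neck, "on", "off"), n_par))
  invisible(x)
}

# Coerce user input (dataset, list of matrices, or array) to [H, W, C, N].
coerce_images <- function(images) {
  if (inherits(images, "pvib_dataset")) images <- images$images
  if (is.list(images)) images <- stack_images(images)
  as_batch4d(images)
}

#' Backbone forward pass
#'
#' Extracts the pyramid of feature maps at the active scales (strides 8,
#' 16 and 32 of the input resolution).
#'
#' @param model A `pvib_model`.
#' @param images Batch array `[H, W, C, N]`, a list of grayscale matrices,
#'   or a dataset.
#' @return Named list (one `[H, W, C, N]` array per active scale).
#' @export
backbone_forward <- function(model, images) {
  x <- coerce_images(images)
  check_finite(x, "images")
  fw <- trunk_forward(model$params$trunk,
                      (x - model$cfg$norm_mean) / model$cfg$norm_sd)
  fw$feats[model$cfg$scales]
}

trunk_forward <- function(tp, xn) {
  c1 <- conv_block_fwd(xn, tp$stem1, 2L)
  c2 <- conv_block_fwd(c1$y, tp$stem2, 2L)
  c3 <- conv_block_fwd(c2$y, tp$b2, 2L)
  c4 <- conv_block_fwd(c3$y, tp$b3, 2L)
  c5 <- conv_block_fwd(c4$y, tp$b4, 2L)
  list(feats = list(P2 = c3$y, P3 = c4$y, P4 = c5$y),
       caches = list(c1, c2, c3, c4, c5))
}

#' Channel-attention neck
#'
#' Recalibrates a feature map by channel: global average pool, 1-D
#' convolution over the channel descriptor, sigmoid gate, channel-wise
#' rescale. Spatial shape is unchanged and every gate lies in (0, 1).
#'
#' @param feature `[H, W, C]` or `[H, W, C, N]` array.
#' @param kernel_weights Optional 1-D kernel; defaults to a uniform kernel
#'   of the adaptive odd size for the channel count.
#' @return Array of the same shape as `feature`.
#' @export
eca_neck <- function(feature, kernel_weights = NULL) {
  x <- as_batch4d(feature)
  if (is.null(kernel_weights)) {
    k <- eca_kernel_size(dim(x)[3])
    kernel_weights <- rep(1 / k, k)
  }
  y <- eca_fwd(x, kernel_weights)$y
  if (length(dim(feature) %||% 0) == 3) dim(y) <- dim(feature)
  y
}

#' Class-specific residual attention head
#'
#' Per class: a base score from average-pooled per-position class scores
#' plus a residual spatial-attention score (temperature softmax over the
#' per-position scores), combined with the configured residual weight.
#'
#' @param feature `[H, W, C]` or `[H, W, C, N]` array.
#' @param weights `C x num_classes` classifier matrix.
#' @param bias Per-class bias vector.
#' @param temperature Softmax temperature (> 0).
#' @param residual_weight Weight of the attention score.
#' @param score_scale Optional cosine-classifier score scale; the default
#'   `NULL` uses the supplied weights as-is.
#' @return `N x num_classes` logit matrix.
#' @export
csra_head <- function(feature, weights, bias = NULL, temperature = 1.0,
                      residual_weight = 0.1, score_scale = NULL) {
  x <- as_batch4d(feature)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  csra_fwd(x, list(w = weights, b = bias), temperature, residual_weight,
           score_scale)$logits
}

# Full forward pass with optional cache retention for backprop.
model_forward_impl <- function(model, x, mode, eps_list = NULL,
                               want_cache = FALSE) {
  cfg <- model$cfg; params <- model$params
  xn <- (x - cfg$norm_mean) / cfg$norm_sd
  tr <- trunk_forward(params$trunk, xn)
  probs <- list(); logits <- list(); fields <- list(); branches <- list()
  for (s in cfg$scales) {
    h <- tr$feats[[s]]
    br <- list()
    sp <- params$scales[[s]]
    if (cfg$vib_position == "before_neck") {
      vr <- pvib_forward(h, sp$vib, mode = mode, eps = eps_list[[s]])
      fields[[s]] <- vr$field; br$vib <- vr$cache; h <- vr$z
    }
    if (cfg$use_neck) {
      er <- eca_fwd(h, sp$neck$w)
      br$eca <- er; h <- er$y
    }
    if (cfg$vib_position == "after_neck") {
      vr <- pvib_forward(h, sp$vib, mode = mode, eps = eps_list[[s]])
      fields[[s]] <- vr$field; br$vib <- vr$cache; h <- vr$z
    }
    hd <- csra_fwd(h, sp$head, cfg$head_temperature,
                   cfg$head_residual_weight, cfg$head_score_scale)
    br$head <- hd
    logits[[s]] <- hd$logits
    probs[[s]] <- sigmoid(hd$logits)
    branches[[s]] <- br
  }
  out <- list(probs_per_scale = probs, logits_per_scale = logits,
              fields = fields)
  if (want_cache) out$cache <- list(trunk = tr, branches = branches)
  out
}

#' Model forward pass
#'
#' Runs images through backbone, optional patch-level bottleneck, optional
#' neck and the per-scale heads. In `"train"` mode the bottleneck samples
#' its latent maps (seed the RNG for reproducibility); in `"eval"` mode
#' the latent equals the posterior mean and the output is deterministic.
#'
#' @param model A `pvib_model`.
#' @param images Batch array, list of matrices, or dataset.
#' @param mode `"eval"` or `"train"`.
#' @param sample Set `TRUE` to Monte-Carlo sample the bottleneck even in
#'   eval mode (off by default; study flag).
#' @return List with `probs_per_scale`, `logits_per_scale` and `fields`
#'   (per-scale Gaussian posteriors; empty when the bottleneck is off).
#' @export
model_forward <- function(model, images, mode = c("eval", "train"),
                          sample = FALSE) {
  mode <- match.arg(mode)
  x <- coerce_images(images)
  check_finite(x, "images")
  eff_mode <- if (mode == "train" || sample) "train" else "eval"
  model_forward_impl(model, x, mode = eff_mode)
}

#' Fuse per-scale predictions
#'
#' Combines the per-scale sigmoid probabilities into a single prediction
#' matrix; the default is the arithmetic mean over scales.
#'
#' @param probs_per_scale List of `N x num_classes` probability matrices.
#' @param method `"mean"` or the name of a single scale (e.g. `"P4"`).
#' @return `N x num_classes` matrix.
#' @export
combine_scale_predictions <- function(probs_per_scale, method = "mean") {
  stopifnot(length(probs_per_scale) >= 1)
  if (method == "mean") {
    Reduce(`+`, probs_per_scale) / length(probs_per_scale)
  } else {
    if (!method %in% names(probs_per_scale)) {
      stop(sprintf("no predictions for scale '%s'", method), call. = FALSE)
    }
    probs_per_scale[[method]]
  }
}

#' Predicted class probabilities
#'
#' Deterministic (eval-mode) fused probabilities for a batch or dataset.
#'
#' @param object A `pvib_model`.
#' @param images Images or dataset.
#' @param batch_size Mini-batch size used for the forward passes.
#' @param ... Unused.
#' @return `N x num_classes` matrix of probabilities.
#' @export
predict.pvib_model <- function(object, images, batch_size = 64L, ...) {
  if (inherits(images, "pvib_dataset")) {
    imgs <- images$images
  } else if (is.list(images)) {
    imgs <- images
  } else {
    x <- as_batch4d(images)
    imgs <- lapply(seq_len(dim(x)[4]), function(n) x[, , 1L, n])
  }
  n <- length(imgs)
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward_impl(object, stack_images(imgs, idx), mode = "eval")
    p <- combine_scale_predictions(fw$probs_per_scale)
    out <- rbind(out, p)
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file containing all weights together with
#' the model configuration; loading reproduces bit-identical eval-mode
#' outputs.
#'
#' @param model A `pvib_model` (or a `pvib_fit`, whose best model is saved).
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `pvib_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "pvib_fit")) model <- model$model
  stopifnot(inherits(model, "pvib_model"))
  saveRDS(list(format = "pvib-checkpoint-1", cfg = model$cfg,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pvib-checkpoint-1")) {
    stop("not a pvib checkpoint: ", path, call. = FALSE)
  }
  structure(list(cfg = obj$cfg, params = obj$params), class = "pvib_model")
}
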