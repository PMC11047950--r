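# Seeded generator of multi-label lesion images. Labels carry latent-factor
# co-occurrence structure and configurable class imbalance; images are
# soft-disc (Gaussian-profile) lesion blobs with class-characteristic
# locations over a shared anatomy-like background. A domain-shifted variant
# re-renders the anatomy with an aspect-ratio distortion, an off-center
# translation and extra acquisition noise, emulating a cross-dataset gap.

#' Synthetic dataset configuration
#'
#' @param num_classes Number of lesion classes.
#' @param image_size `(H, W)` of the rendered images.
#' @param n_train,n_val,n_test Default split sizes.
#' @param positive_rate Per-class marginal probability of a positive label
#'   (the imbalance control; the default includes one rare class).
#' @param loadings `num_classes x n_factors` latent-factor loading matrix;
#'   classes loading on a common factor co-occur. Row norms must be < 1.
#' @param lesions Data frame with one row per class: `cx`, `cy` (location
#'   prior as fractions of width/height), `r_min`, `r_max` (radius range as
#'   fraction of the short side), `contrast` (peak added intensity) and
#'   `texture_sd` (intra-lesion noise).
#' @param background List: `base`, `grad_amp` (vertical gradient),
#'   `ridge_amp`, `ridge_sd` (bright central ridge), `noise_sd` (speckle).
#' @param center_jitter_sd Per-image lesion-center jitter (fraction).
#' @param seed Default generation seed.
#' @return A `pvib_synth_config` list.
#' @export
synth_config <- function(num_classes = 4L,
                         image_size = c(224L, 224L),
                         n_train = 2000L, n_val = 500L, n_test = 500L,
                         positive_rate = c(0.30, 0.30, 0.15, 0.05),
                         loadings = NULL,
                         lesions = NULL,
                         background = list(base = 0.25, grad_amp = 0.20,
                                           ridge_amp = 0.15, ridge_sd = 0.12,
                                           noise_sd = 0.06),
                         center_jitter_sd = 0.02,
                         seed = 0L) {
  num_classes <- as.integer(num_classes)
  if (length(positive_rate) == 1) positive_rate <- rep(positive_rate, num_classes)
  stopifnot(length(positive_rate) == num_classes,
            all(positive_rate >= 0 & positive_rate <= 1))
  if (is.null(loadings)) {
    # two latent factors, each shared by half of the classes
    loadings <- matrix(0, num_classes, 2)
    half <- ceiling(num_classes / 2)
    loadings[seq_len(half), 1] <- 0.6
    loadings[setdiff(seq_len(num_classes), seq_len(half)), 2] <- 0.6
  }
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != num_classes) {
    stop("loadings must have one row per class", call. = FALSE)
  }
  if (any(rowSums(loadings^2) >= 1)) {
    stop("loading row norms must be < 1", call. = FALSE)
  }
  if (is.null(lesions)) {
    # each class gets a distinct appearance signature (size, signed
    # contrast, internal texture) plus a characteristic location prior:
    # a compact bright nodule, a large faint opacity, a darker
    # hypodense region, and a bright strongly textured mass
    ang <- seq(0, 2 * pi, length.out = num_classes + 1)[seq_len(num_classes)]
    proto <- data.frame(
      r_min = c(0.040, 0.120, 0.080, 0.070),
      r_max = c(0.060, 0.160, 0.120, 0.100),
      contrast = c(0.50, 0.18, -0.30, 0.35),
      texture_sd = c(0.02, 0.02, 0.02, 0.15))
    idx <- (seq_len(num_classes) - 1L) %% 4L + 1L
    lesions <- tibble::tibble(
      class = seq_len(num_classes),
      cx = 0.5 + 0.18 * cos(ang + pi / 4),
      cy = 0.5 + 0.18 * sin(ang + pi / 4),
      r_min = proto$r_min[idx], r_max = proto$r_max[idx],
      contrast = proto$contrast[idx], texture_sd = proto$texture_sd[idx]
    )
  }
  structure(list(
    num_classes = num_classes, image_size = as.integer(image_size),
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    n_test = as.integer(n_test),
    positive_rate = positive_rate, loadings = loadings,
    lesions = tibble::as_tibble(lesions), background = background,
    center_jitter_sd = center_jitter_sd, seed = as.integer(seed)
  ), class = "pvib_synth_config")
}

#' Domain-shift description
#'
#' Parameters of the shifted rendering domain: a width-to-height
#' aspect-ratio distortion (default 1.22, a typical cross-dataset value),
#' a horizontal translation moving the anatomy off-center, and extra
#' acquisition noise.
#'
#' @param aspect_ratio_factor Positive stretch factor applied to the
#'   anatomy's horizontal coordinate before resampling to the training
#'   resolution.
#' @param translation Horizontal anatomy offset as a fraction of width.
#' @param extra_noise_sigma Standard deviation of additional pixel noise.
#' @return A `pvib_domain_shift` list.
#' @export
domain_shift <- function(aspect_ratio_factor = 1.22, translation = 0.08,
                         extra_noise_sigma = 0.03) {
  stopifnot(aspect_ratio_factor > 0)
  structure(list(aspect_ratio_factor = aspect_ratio_factor,
                 translation = translation,
                 extra_noise_sigma = extra_noise_sigma),
            class = "pvib_domain_shift")
}

# Draw the binary label matrix through a Gaussian-copula latent-factor
# model: u_c = loadings_c . f + sqrt(1 - |loadings_c|^2) e_c is standard
# normal, and y_c = 1{u_c < qnorm(positive_rate_c)}, so the configured
# positive rates are the exact marginals and shared factors induce
# positive label co-occurrence.
draw_labels <- function(cfg, n, seed) {
  set.seed(derive_seed(seed, "labels"))
  G <- ncol(cfg$loadings)
  f <- matrix(stats::rnorm(n * G), n, G)
  e <- matrix(stats::rnorm(n * cfg$num_classes), n, cfg$num_classes)
  resid <- sqrt(1 - rowSums(cfg$loadings^2))
  u <- f %*% t(cfg$loadings) + e * rep(resid, each = n)
  y <- 1L * (u < rep(stats::qnorm(cfg$positive_rate), each = n))
  colnames(y) <- paste0("class", seq_len(cfg$num_classes))
  y
}

# Per-image stochastic rendering parameters, stored so the image can be
# re-rendered deterministically under a different geometry.
draw_meta <- function(cfg, n, seed) {
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, "meta", i))
    les <- cfg$lesions
    list(
      img_seed = derive_seed(seed, "noise", i),
      bg_grad_jit = stats::runif(1, 0.9, 1.1),
      bg_ridge_jit = stats::runif(1, 0.9, 1.1),
      bg_phase = stats::runif(1, -0.05, 0.05),
      cx = les$cx + stats::rnorm(cfg$num_classes, 0, cfg$center_jitter_sd),
      cy = les$cy + stats::rnorm(cfg$num_classes, 0, cfg$center_jitter_sd),
      radius = stats::runif(cfg$num_classes, les$r_min, les$r_max),
      amp = les$contrast * stats::runif(cfg$num_classes, 0.9, 1.1)
    )
  })
}

render_image <- function(meta, y_row, cfg, ar = 1, tx = 0) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  bgp <- cfg$background
  xs <- (seq_len(W) - 0.5) / W
  ys <- (seq_len(H) - 0.5) / H
  # anatomy coordinates: horizontal stretch + translation (labels unchanged)
  u <- 0.5 + (xs - 0.5 - tx) * ar
  U <- matrix(u, H, W, byrow = TRUE)
  V <- matrix(ys, H, W)
  img <- bgp$base + bgp$grad_amp * meta$bg_grad_jit * (1 - V + meta$bg_phase) +
    bgp$ridge_amp * meta$bg_ridge_jit * exp(-(U - 0.5)^2 / (2 * bgp$ridge_sd^2))
  set.seed(meta$img_seed)
  img <- img + matrix(stats::rnorm(H * W, 0, bgp$noise_sd), H, W)
  for (c in seq_len(cfg$num_classes)) {
    tex <- if (cfg$lesions$texture_sd[c] > 0) {
      matrix(stats::rnorm(H * W, 0, cfg$lesions$texture_sd[c]), H, W)
    } else 0
    if (y_row[c] == 1) {
      ker <- exp(-((U - meta$cx[c])^2 + (V - meta$cy[c])^2) /
                   (2 * meta$radius[c]^2))
      img <- img + meta$amp[c] * ker + tex * ker
    }
  }
  clamp(img, 0, 1)
}

#' Generate a synthetic labeled image set
#'
#' Draws labels from the latent-factor co-occurrence model and renders one
#' lesion blob per active class at its class-characteristic location over
#' the shared background. Fully deterministic given the seed.
#'
#' @param cfg A [synth_config()].
#' @param n Number of samples.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param render Set `FALSE` to skip image rendering (labels and
#'   per-image metadata only; useful for large label-statistics checks).
#' @return A `pvib_dataset`: list with `images` (list of `H x W` matrices
#'   in `[0, 1]`), `labels` (`n x num_classes` binary matrix),
#'   `class_names`, per-image `meta`, and the generating `cfg`.
#' @export
generate_dataset <- function(cfg = synth_config(), n = cfg$n_train,
                             seed = cfg$seed, render = TRUE) {
  y <- draw_labels(cfg, n, seed)
  meta <- draw_meta(cfg, n, seed)
  images <- if (render) {
    lapply(seq_len(n), function(i) render_image(meta[[i]], y[i, ], cfg))
  } else NULL
  structure(list(images = images, labels = y,
                 class_names = colnames(y), meta = meta, cfg = cfg,
                 seed = seed, shift = NULL),
            class = "pvib_dataset")
}

#' @export
print.pvib_dataset <- function(x, ...) {
  cat(sprintf("pvib dataset: %d samples, %d classes (%s)%s\n",
              nrow(x$labels), ncol(x$labels),
              paste(colnames(x$labels), collapse = ", "),
              if (!is.null(x$shift)) ", domain-shifted" else ""))
  cat("positive counts:", paste(colSums(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset
#'
#' @param ds A `pvib_dataset`.
#' @param idx Integer indices of the samples to keep.
#' @return A `pvib_dataset` with the selected samples.
#' @export
dataset_subset <- function(ds, idx) {
  ds$images <- ds$images[idx]
  ds$labels <- ds$labels[idx, , drop = FALSE]
  ds$meta <- ds$meta[idx]
  ds
}

#' Apply a domain shift to a generated dataset
#'
#' Re-renders every image with the anatomy stretched by the aspect-ratio
#' factor, translated off-center, and overlaid with extra noise, at the
#' original training resolution. Labels are unchanged. The identity shift
#' (factor 1, translation 0, no noise) reproduces the source images
#' exactly.
#'
#' @param ds A dataset produced by [generate_dataset()] (the per-image
#'   rendering metadata is required).
#' @param shift A [domain_shift()].
#' @param seed Seed for the extra noise overlay.
#' @return A new `pvib_dataset` with shifted images.
#' @export
apply_domain_shift <- function(ds, shift = domain_shift(), seed = 1L) {
  if (is.null(ds$meta)) {
    stop("domain shift needs a dataset rendered by generate_dataset()",
         call. = FALSE)
  }
  n <- nrow(ds$labels)
  images <- lapply(seq_len(n), function(i) {
    img <- render_image(ds$meta[[i]], ds$labels[i, ], ds$cfg,
                        ar = shift$aspect_ratio_factor,
                        tx = shift$translation)
    if (shift$extra_noise_sigma > 0) {
      set.seed(derive_seed(seed, "shiftnoise", i))
      img <- clamp(img + matrix(stats::rnorm(length(img), 0,
                                             shift$extra_noise_sigma),
                                nrow(img), ncol(img)), 0, 1)
    }
    img
  })
  ds$images <- images
  ds$shift <- shift
  ds
}

#' Export a dataset as PNG images plus a CSV manifest
#'
#' Writes one grayscale PNG per sample and a manifest CSV whose columns
#' are `image_path` followed by one binary column per class; the layout
#' round-trips through [read_image_manifest()].
#'
#' @param ds A `pvib_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the images.
#' @return The manifest path, invisibly.
#' @export
export_manifest <- function(ds, dir, prefix = "img") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(ds$labels)
  paths <- sprintf("%s_%05d.png", prefix, seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(ds$images[[i]], file.path(dir, paths[i]))
  }
  man <- data.frame(image_path = paths, ds$labels, check.names = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Read a labeled image set from a manifest CSV
#'
#' The manifest has a column `image_path` (relative to the manifest's
#' directory) and one binary column per class.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param image_size Optional `(H, W)`; images are bilinearly resized to
#'   it when their on-disk size differs.
#' @return A `pvib_dataset` (without rendering metadata).
#' @export
read_image_manifest <- function(manifest_path, image_size = NULL) {
  man <- utils::read.csv(manifest_path, check.names = FALSE)
  if (!"image_path" %in% names(man)) {
    stop("manifest must have an image_path column: ", manifest_path,
         call. = FALSE)
  }
  root <- dirname(manifest_path)
  class_names <- setdiff(names(man), "image_path")
  y <- as.matrix(man[, class_names, drop = FALSE])
  storage.mode(y) <- "integer"
  images <- lapply(man$image_path, function(p) {
    img <- png::readPNG(file.path(root, p))
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    if (!is.null(image_size)) img <- resize_bilinear(img, image_size[1], image_size[2])
    img
  })
  structure(list(images = images, labels = y, class_names = class_names,
                 meta = NULL, cfg = NULL, seed = NA_integer_, shift = NULL),
            class = "pvib_dataset")
}

#' Template-matching detection scores
#'
#' Correlates each image with a localized zero-mean template of each
#' class's nominal lesion (its Gaussian profile at the location prior).
#' Serves as a simple non-learned reference detector establishing that
#' the generated task is solvable.
#'
#' @param ds A `pvib_dataset`.
#' @param cfg The generating [synth_config()] (defaults to `ds$cfg`).
#' @return `n x num_classes` score matrix.
#' @export
template_match_scores <- function(ds, cfg = ds$cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  les <- cfg$lesions
  xs <- (seq_len(W) - 0.5) / W
  ys <- (seq_len(H) - 0.5) / H
  U <- matrix(xs, H, W, byrow = TRUE)
  V <- matrix(ys, H, W)
  templates <- lapply(seq_len(cfg$num_classes), function(c) {
    r <- (les$r_min[c] + les$r_max[c]) / 2
    ker <- exp(-((U - les$cx[c])^2 + (V - les$cy[c])^2) / (2 * r^2))
    win <- ker > exp(-4.5)  # local window ~ 3 radii
    tpl <- ker
    tpl[!win] <- 0
    tpl[win] <- tpl[win] - mean(tpl[win])
    tpl * sign(les$contrast[c])  # dark lesions score by darkness
  })
  scores <- vapply(templates, function(tpl) {
    vapply(ds$images, function(img) sum(img * tpl), numeric(1))
  }, numeric(length(ds$images)))
  colnames(scores) <- ds$class_names
  scores
}
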