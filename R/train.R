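# End-to-end training with early stopping on validation AUC, plus the
# beta-sweep, fraction-sweep and source-vs-shifted-domain experiment
# runners.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param lr_decay Multiplicative learning-rate factor.
#' @param lr_decay_every Apply the decay every this many epochs.
#' @param epochs Number of training epochs.
#' @param seed Master seed; it fans out to weight initialization, data
#'   shuffling, augmentation and the bottleneck's noise draws.
#' @param early_stop_metric Validation metric that selects the best
#'   checkpoint: `"micro_auc"` or `"macro_auc"`.
#' @param augment Apply random horizontal flip and mild contrast jitter to
#'   training batches. Off by default: the synthetic classes are
#'   location-coded, so mirroring destroys label information.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param verbose Print one line per epoch.
#' @return A `pvib_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         lr_decay = 0.9, lr_decay_every = 2L, epochs = 20L,
                         seed = 0L,
                         early_stop_metric = c("micro_auc", "macro_auc"),
                         augment = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, verbose = FALSE) {
  early_stop_metric <- match.arg(early_stop_metric)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 lr_decay = lr_decay, lr_decay_every = as.integer(lr_decay_every),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 early_stop_metric = early_stop_metric, augment = augment,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, verbose = verbose),
            class = "pvib_train_config")
}

augment_batch <- function(x) {
  # random horizontal flip + contrast jitter in [0.9, 1.1] about mid-gray
  N <- dim(x)[4]
  flip <- stats::runif(N) < 0.5
  fac <- stats::runif(N, 0.9, 1.1)
  for (n in seq_len(N)) {
    img <- x[, , , n]
    if (flip[n]) img <- img[, rev(seq_len(ncol(img)))]
    x[, , , n] <- clamp(0.5 + (img - 0.5) * fac[n], 0, 1)
  }
  x
}

# One eval-mode pass over a dataset: classification + KL losses and the
# fused prediction scores, batched.
dataset_losses <- function(model, ds, loss_cfg, batch_size) {
  n <- nrow(ds$labels)
  cls <- 0; kl <- 0
  scores <- NULL
  lambdas <- lambda_for_scales(loss_cfg, model$cfg$scales)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward_impl(model, stack_images(ds$images, idx), mode = "eval")
    y <- ds$labels[idx, , drop = FALSE]
    cls_b <- sum(vapply(seq_along(model$cfg$scales), function(l) {
      bias_focal_loss_scale(fw$probs_per_scale[[l]], y, alpha = loss_cfg$alpha,
                            lambda_l = lambdas[l], eps = loss_cfg$eps,
                            lambda_mode = loss_cfg$lambda_mode)
    }, numeric(1)))
    kl_b <- if (length(fw$fields) > 0) kl_loss_total(fw$fields) else 0
    cls <- cls + cls_b * length(idx)
    kl <- kl + kl_b * length(idx)
    scores <- rbind(scores, combine_scale_predictions(fw$probs_per_scale))
  }
  list(cls = cls / n, kl = kl / n, scores = scores)
}

#' Train a model with early stopping on validation AUC
#'
#' Optimizes the combined objective (bias focal classification loss plus
#' beta times the KL feature-selection loss) with Adam. After every epoch
#' the fused eval-mode predictions on the validation set are scored; the
#' returned model is the snapshot with the highest validation AUC, never
#' simply the last epoch. Fully seeded: the same seed reproduces the same
#' run history.
#'
#' @param train_set,val_set `pvib_dataset`s sharing the class schema.
#' @param model_cfg A [model_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return A `pvib_fit`: list with the best `model`, the per-epoch
#'   `history` tibble (train/val classification and KL losses, validation
#'   AUCs), `best_epoch` and `best_val_auc`.
#' @export
train_model <- function(train_set, val_set, model_cfg,
                        loss_cfg = loss_config(),
                        train_cfg = train_config()) {
  if (nrow(train_set$labels) == 0 || nrow(val_set$labels) == 0) {
    stop("empty dataset", call. = FALSE)
  }
  if (!identical(train_set$class_names, val_set$class_names)) {
    stop("train and validation sets must share the class schema", call. = FALSE)
  }
  model <- build_model(model_cfg, seed = train_cfg$seed)
  state <- adam_init(model$params)
  n <- nrow(train_set$labels)
  history <- NULL
  best <- list(epoch = 0L, auc = -Inf, params = model$params)

  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- train_cfg$learning_rate *
      train_cfg$lr_decay^((epoch - 1) %/% train_cfg$lr_decay_every)
    set.seed(derive_seed(train_cfg$seed, "epoch", epoch))
    ord <- sample.int(n)
    tr_cls <- 0; tr_kl <- 0
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
      x <- stack_images(train_set$images, idx)
      if (train_cfg$augment) x <- augment_batch(x)
      y <- train_set$labels[idx, , drop = FALSE]
      lg <- loss_and_grad(model, x, y, loss_cfg)
      if (!is.finite(lg$breakdown$total)) {
        stop(sprintf("non-finite loss at epoch %d (cls %.4g, kl %.4g)",
                     epoch, lg$breakdown$cls_total, lg$breakdown$kl_total),
             call. = FALSE)
      }
      up <- adam_step(model$params, lg$grads, state, lr,
                      train_cfg$adam_beta1, train_cfg$adam_beta2,
                      train_cfg$adam_eps)
      model$params <- up$params; state <- up$state
      tr_cls <- tr_cls + lg$breakdown$cls_total * length(idx)
      tr_kl <- tr_kl + lg$breakdown$kl_total * length(idx)
    }
    vl <- dataset_losses(model, val_set, loss_cfg, train_cfg$batch_size)
    ev <- multilabel_auc(vl$scores, val_set$labels,
                         class_names = val_set$class_names)
    val_auc <- if (train_cfg$early_stop_metric == "micro_auc") {
      ev$micro_auc
    } else ev$macro_auc
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      train_cls = tr_cls / n, train_kl = tr_kl / n,
      val_cls = vl$cls, val_kl = vl$kl,
      val_macro_auc = ev$macro_auc, val_micro_auc = ev$micro_auc,
      val_auc = val_auc))
    if (isTRUE(val_auc > best$auc)) {
      best <- list(epoch = epoch, auc = val_auc, params = model$params)
    }
    if (train_cfg$verbose) {
      message(sprintf(
        "epoch %2d  lr %.2e  train cls %.4f kl %.4f  val cls %.4f  val AUC %.4f%s",
        epoch, lr, tr_cls / n, tr_kl / n, vl$cls, val_auc,
        if (best$epoch == epoch) " *" else ""))
    }
  }
  best_model <- structure(list(cfg = model_cfg, params = best$params),
                          class = "pvib_model")
  structure(list(model = best_model, history = tibble::as_tibble(history),
                 best_epoch = best$epoch, best_val_auc = best$auc,
                 model_cfg = model_cfg, loss_cfg = loss_cfg,
                 train_cfg = train_cfg),
            class = "pvib_fit")
}

#' @export
print.pvib_fit <- function(x, ...) {
  cat(sprintf("pvib fit: %d epochs, best %s %.4f at epoch %d\n",
              nrow(x$history), x$train_cfg$early_stop_metric,
              x$best_val_auc, x$best_epoch))
  invisible(x)
}

#' @export
tidy.pvib_fit <- function(x, ...) x$history

#' @export
glance.pvib_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_auc = x$best_val_auc,
                 final_train_cls = x$history$train_cls[nrow(x$history)],
                 final_train_kl = x$history$train_kl[nrow(x$history)])
}

#' Plot the loss and validation-AUC curves of a fit
#'
#' @param object A `pvib_fit`.
#' @param ... Unused.
#' @return A ggplot object (loss curves and validation AUC per epoch).
#' @export
autoplot.pvib_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_cls", "train_kl", "val_cls", "val_kl",
                             "val_auc"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Write a fit's run history to CSV
#'
#' @param fit A `pvib_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_history_csv <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}

#' Sweep the bottleneck weight beta
#'
#' Trains one seeded model per beta value (plus, optionally, the
#' bottleneck-free baseline) and evaluates each on the supplied test
#' sets.
#'
#' @param betas Numeric vector of beta values.
#' @param train_set,val_set Training and validation datasets.
#' @param test_sets Named list of datasets to evaluate the best model on.
#' @param model_cfg,loss_cfg,train_cfg Configurations shared across runs.
#' @param include_baseline Also train the `vib_position = "none"` model.
#' @return A `pvib_sweep` tibble: one row per (model, test set) with
#'   micro/macro AUC and the best validation AUC.
#' @export
beta_sweep <- function(betas, train_set, val_set, test_sets = list(),
                       model_cfg, loss_cfg = loss_config(),
                       train_cfg = train_config(),
                       include_baseline = FALSE) {
  stopifnot(length(betas) >= 1)
  runs <- lapply(betas, function(b) {
    list(label = sprintf("beta=%g", b), beta = b, cfg = model_cfg)
  })
  if (include_baseline) {
    base_cfg <- model_cfg; base_cfg$vib_position <- "none"
    runs <- c(runs, list(list(label = "baseline", beta = 0, cfg = base_cfg)))
  }
  out <- purrr::map_dfr(runs, function(r) {
    lc <- loss_cfg; lc$beta <- r$beta
    fit <- train_model(train_set, val_set, r$cfg, lc, train_cfg)
    rows <- tibble::tibble(model = r$label, beta = r$beta, split = "val",
                           micro_auc = NA_real_, macro_auc = NA_real_,
                           best_val_auc = fit$best_val_auc)
    ev_val <- evaluate_model(fit, val_set)
    rows$micro_auc <- ev_val$micro_auc; rows$macro_auc <- ev_val$macro_auc
    extra <- purrr::imap_dfr(test_sets, function(ds, nm) {
      ev <- evaluate_model(fit, ds)
      tibble::tibble(model = r$label, beta = r$beta, split = nm,
                     micro_auc = ev$micro_auc, macro_auc = ev$macro_auc,
                     best_val_auc = fit$best_val_auc)
    })
    dplyr::bind_rows(rows, extra)
  })
  class(out) <- c("pvib_sweep", class(out))
  out
}

#' Sweep the training-set fraction
#'
#' Subsamples the training set at each fraction (deterministically under
#' the training seed), trains, and reports train/validation/test AUC —
#' the generalization-versus-dataset-size experiment.
#'
#' @param fractions Fractions in (0, 1].
#' @param train_set,val_set,test_set Datasets.
#' @param model_cfg,loss_cfg,train_cfg Configurations shared across runs.
#' @return A `pvib_sweep` tibble: one row per fraction with
#'   train/val/test micro and macro AUC.
#' @export
fraction_sweep <- function(fractions, train_set, val_set, test_set,
                           model_cfg, loss_cfg = loss_config(),
                           train_cfg = train_config()) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  n <- nrow(train_set$labels)
  out <- purrr::map_dfr(fractions, function(f) {
    m <- max(1L, floor(f * n))
    if (f < 1) {
      set.seed(derive_seed(train_cfg$seed, "fraction", round(1e6 * f)))
      sub <- dataset_subset(train_set, sample.int(n, m))
    } else {
      sub <- train_set
    }
    fit <- train_model(sub, val_set, model_cfg, loss_cfg, train_cfg)
    evs <- list(train = evaluate_model(fit, sub),
                val = evaluate_model(fit, val_set),
                test = evaluate_model(fit, test_set))
    purrr::imap_dfr(evs, function(ev, nm) {
      tibble::tibble(fraction = f, n_train = m, split = nm,
                     micro_auc = ev$micro_auc, macro_auc = ev$macro_auc,
                     best_epoch = fit$best_epoch)
    })
  })
  class(out) <- c("pvib_sweep", class(out))
  out
}

#' Plot a sweep table
#'
#' @param object A `pvib_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvib_sweep <- function(object, ...) {
  xvar <- if ("fraction" %in% names(object)) "fraction" else "model"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$micro_auc,
                                       colour = .data$split,
                                       group = .data$split)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(y = "micro AUC")
}

#' Source-versus-shifted-domain generalization experiment
#'
#' For every (seed, fraction) pair, trains the bottleneck model and the
#' bottleneck-free baseline on a subsample of the source-domain training
#' set and evaluates both on a source-domain and a domain-shifted test
#' set. This is the scaled-down analogue of training on one dataset and
#' testing on another with a different aspect ratio and centering.
#'
#' @param train_set,val_set Source-domain datasets.
#' @param test_source Source-domain test set.
#' @param test_shifted Domain-shifted test set (same labels, shifted
#'   rendering).
#' @param fractions Training-set fractions to evaluate.
#' @param seeds Integer vector of replicate seeds.
#' @param model_cfg,loss_cfg,train_cfg Shared configurations; the
#'   baseline uses `vib_position = "none"`.
#' @return A tibble: one row per (seed, fraction, model) with validation,
#'   source-test and shifted-test micro AUC.
#' @export
domain_shift_experiment <- function(train_set, val_set, test_source,
                                    test_shifted,
                                    fractions = c(0.25, 1.0),
                                    seeds = 1:5,
                                    model_cfg,
                                    loss_cfg = loss_config(),
                                    train_cfg = train_config()) {
  base_cfg <- model_cfg; base_cfg$vib_position <- "none"
  grid <- expand.grid(seed = seeds, fraction = fractions,
                      model = c("pvib", "baseline"),
                      stringsAsFactors = FALSE)
  n <- nrow(train_set$labels)
  purrr::pmap_dfr(grid, function(seed, fraction, model) {
    tc <- train_cfg; tc$seed <- as.integer(seed)
    m <- max(1L, floor(fraction * n))
    if (fraction < 1) {
      set.seed(derive_seed(seed, "fraction", round(1e6 * fraction)))
      sub <- dataset_subset(train_set, sample.int(n, m))
    } else {
      sub <- train_set
    }
    cfg <- if (model == "pvib") model_cfg else base_cfg
    lc <- loss_cfg
    if (model == "baseline") lc$beta <- 0
    fit <- train_model(sub, val_set, cfg, lc, tc)
    tibble::tibble(
      seed = seed, fraction = fraction, model = model, n_train = m,
      best_epoch = fit$best_epoch,
      val_micro_auc = evaluate_model(fit, val_set)$micro_auc,
      test_source_micro_auc = evaluate_model(fit, test_source)$micro_auc,
      test_shifted_micro_auc = evaluate_model(fit, test_shifted)$micro_auc)
  })
}
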