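# ROC / AUC evaluation for multi-label predictions: per-class one-vs-all
# AUCs, their macro average, and a pooled micro AUC.

#' Rank-based binary AUC
#'
#' Area under the empirical ROC curve computed from ranks
#' (Mann-Whitney form), with tied positive-negative pairs counted half.
#' Equals the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary vector of the same length.
#' @return AUC in `[0, 1]`, or `NA_real_` when only one class is present
#'   (the undefined-AUC signal, not an error).
#' @export
auc_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Empirical ROC curve
#'
#' Points of the empirical ROC, from (0, 0) to (1, 1), with one point per
#' distinct score threshold; both coordinates are monotone nondecreasing.
#'
#' @inheritParams auc_binary
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at the last index of each tie group = one ROC point
  # per distinct threshold
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / max(nneg, 1L)),
    tpr = c(0, tp[last_of_tie] / max(npos, 1L))
  )
}

#' Multi-label AUC report
#'
#' One-vs-all AUC per class, the macro average over classes with both
#' label values present, and the micro AUC obtained by pooling every
#' (sample, class) pair of the defined classes into one binary problem.
#' Classes with a single label value are excluded (with a warning) rather
#' than raising an error.
#'
#' @param scores `N x C` score matrix.
#' @param labels `N x C` binary matrix; column names become class names.
#' @param class_names Optional class names overriding column names.
#' @return A `pvib_eval` object: list with `per_class` (tibble),
#'   `macro_auc`, `micro_auc`, `roc` (tibble of ROC points per class) and
#'   `excluded_classes`.
#' @export
multilabel_auc <- function(scores, labels, class_names = NULL) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  if (is.null(class_names)) {
    class_names <- colnames(labels) %||% paste0("class_", seq_len(ncol(labels)))
  }
  per <- tibble::tibble(
    class = class_names,
    n_pos = colSums(labels == 1),
    n_neg = colSums(labels == 0),
    auc = vapply(seq_len(ncol(scores)),
                 function(c) auc_binary(scores[, c], labels[, c]), numeric(1))
  )
  excluded <- per$class[is.na(per$auc)]
  if (length(excluded) > 0) {
    warning("classes with a single label value excluded from AUC: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  defined <- !is.na(per$auc)
  roc <- purrr::map_dfr(which(defined), function(c) {
    dplyr::mutate(roc_curve(scores[, c], labels[, c]),
                  class = class_names[c], .before = 1)
  })
  structure(list(
    per_class = per,
    macro_auc = mean(per$auc[defined]),
    micro_auc = auc_binary(as.vector(scores[, defined, drop = FALSE]),
                           as.vector(labels[, defined, drop = FALSE])),
    roc = roc,
    excluded_classes = excluded
  ), class = "pvib_eval")
}

#' @export
print.pvib_eval <- function(x, ...) {
  cat(sprintf("multi-label AUC: macro %.4f, micro %.4f (%d classes",
              x$macro_auc, x$micro_auc, nrow(x$per_class)))
  if (length(x$excluded_classes)) {
    cat(sprintf(", %d excluded", length(x$excluded_classes)))
  }
  cat(")\n")
  print(x$per_class)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pvib_eval <- function(x, ...) x$per_class

#' @importFrom generics glance
#' @export
glance.pvib_eval <- function(x, ...) {
  tibble::tibble(macro_auc = x$macro_auc, micro_auc = x$micro_auc,
                 n_classes = nrow(x$per_class),
                 n_excluded = length(x$excluded_classes))
}

#' Plot ROC curves of an evaluation report
#'
#' @param object A `pvib_eval`.
#' @param ... Unused.
#' @return A ggplot object with one ROC curve per class.
#' @export
autoplot.pvib_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("macro AUC %.3f, micro AUC %.3f",
                                  object$macro_auc, object$micro_auc))
}

#' Evaluate a model on a labeled dataset
#'
#' Runs deterministic eval-mode predictions and computes the multi-label
#' AUC report.
#'
#' @param model A `pvib_model` or `pvib_fit`.
#' @param dataset A `pvib_dataset` (images + label matrix).
#' @param batch_size Forward-pass batch size.
#' @return A `pvib_eval`.
#' @export
evaluate_model <- function(model, dataset, batch_size = 64L) {
  if (inherits(model, "pvib_fit")) model <- model$model
  scores <- predict(model, dataset, batch_size = batch_size)
  multilabel_auc(scores, dataset$labels, class_names = dataset$class_names)
}

#' Write per-class ROC points to CSV
#'
#' @param report A `pvib_eval`.
#' @param path Output CSV path (columns class, fpr, tpr, threshold).
#' @return `path`, invisibly.
#' @export
export_roc_csv <- function(report, path) {
  utils::write.csv(report$roc[, c("class", "fpr", "tpr", "threshold")],
                   path, row.names = FALSE)
  invisible(path)
}
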