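#' Confusion-matrix accumulation for segmentation masks
#'
#' Pixel counts are pooled into a (C x C) matrix with rows = ground-truth
#' class and columns = predicted class (background included), across as
#' many mask pairs as are accumulated. All reported metrics derive from
#' these pooled counts, so they are invariant to how pixels are split into
#' images.
#'
#' @param class_order Character vector naming the classes (background
#'   first).
#' @return `empty_confusion()` returns a zero `wound_confusion` matrix.
#' @export
empty_confusion <- function(class_order = default_class_order()) {
  C <- length(class_order)
  m <- matrix(0, nrow = C, ncol = C,
              dimnames = list(truth = class_order, prediction = class_order))
  structure(m, class = c("wound_confusion", "matrix", "array"))
}

#' @rdname empty_confusion
#' @param pred_mask,gt_mask Integer matrices of equal shape with values in
#'   `0..C-1`.
#' @param running A `wound_confusion` matrix to add to.
#' @export
accumulate_confusion <- function(pred_mask, gt_mask,
                                 running = empty_confusion()) {
  stopifnot(inherits(running, "wound_confusion"))
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("prediction and ground-truth masks differ in shape")
  }
  C <- nrow(running)
  if (length(gt_mask) == 0) return(running)
  rng <- range(c(pred_mask, gt_mask))
  if (rng[1] < 0 || rng[2] >= C) {
    stop("mask values outside 0..", C - 1)
  }
  idx <- as.integer(gt_mask) * C + as.integer(pred_mask) + 1L
  counts <- tabulate(idx, nbins = C * C)
  running + matrix(counts, nrow = C, ncol = C, byrow = TRUE)
}

#' Mean pixel accuracy from a pooled confusion matrix
#'
#' Per-class pixel accuracy is the row-normalised diagonal
#' `counts[c, c] / row_sum[c]` (the recall of class c); the mean is the
#' macro average over the classes present in the ground truth. Classes
#' absent from the ground truth are excluded from the mean (not scored 0)
#' and listed in the result, since rare wound classes routinely vanish
#' from small validation folds.
#'
#' @param cm A `wound_confusion` matrix.
#' @return List with `value` (macro mean), `per_class` (named vector, `NA`
#'   for absent classes) and `excluded` (names of absent classes).
#' @export
mean_pixel_accuracy <- function(cm) {
  stopifnot(inherits(cm, "wound_confusion"))
  rs <- rowSums(cm)
  if (all(rs == 0)) stop("empty confusion matrix")
  per <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(per) <- rownames(cm)
  list(value = mean(per[rs > 0]), per_class = per,
       excluded = rownames(cm)[rs == 0])
}

#' Mean intersection-over-union from a pooled confusion matrix
#'
#' `IoU_c = counts[c, c] / (row_sum[c] + col_sum[c] - counts[c, c])`,
#' macro-averaged over classes present in the ground truth (absent classes
#' excluded, as for [mean_pixel_accuracy()]).
#'
#' @inheritParams mean_pixel_accuracy
#' @return List with `value`, `per_class`, `excluded`.
#' @export
mean_iou <- function(cm) {
  stopifnot(inherits(cm, "wound_confusion"))
  rs <- rowSums(cm)
  cs <- colSums(cm)
  if (all(rs == 0)) stop("empty confusion matrix")
  union <- rs + cs - diag(cm)
  per <- ifelse(rs > 0, diag(cm) / union, NA_real_)
  names(per) <- rownames(cm)
  list(value = mean(per[rs > 0]), per_class = per,
       excluded = rownames(cm)[rs == 0])
}

#' Metrics report for an evaluation set
#'
#' Bundles the pooled confusion matrix with per-class and macro pixel
#' accuracy and IoU.
#'
#' @inheritParams mean_pixel_accuracy
#' @return A `metrics_report` object.
#' @export
metrics_report <- function(cm) {
  mpa <- mean_pixel_accuracy(cm)
  iou <- mean_iou(cm)
  structure(
    list(confusion = cm, mean_pixel_accuracy = mpa$value,
         mean_iou = iou$value, per_class_accuracy = mpa$per_class,
         per_class_iou = iou$per_class, excluded = mpa$excluded),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  mean pixel accuracy:", sprintf("%.4f", x$mean_pixel_accuracy), "\n")
  cat("  mean IoU:           ", sprintf("%.4f", x$mean_iou), "\n")
  if (length(x$excluded) > 0) {
    cat("  excluded (absent):  ", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    class = names(x$per_class_accuracy),
    pixel_accuracy = unname(x$per_class_accuracy),
    iou = unname(x$per_class_iou),
    present = !names(x$per_class_accuracy) %in% x$excluded
  )
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    mean_pixel_accuracy = x$mean_pixel_accuracy,
    mean_iou = x$mean_iou,
    n_classes_scored = sum(!names(x$per_class_accuracy) %in% x$excluded)
  )
}

#' Row-normalised confusion matrix
#'
#' @inheritParams mean_pixel_accuracy
#' @return Numeric matrix whose non-empty rows sum to 1.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- NA_real_
  out
}

#' @export
tidy.wound_confusion <- function(x, ...) {
  nm <- normalize_confusion(x)
  tibble::tibble(
    truth = rep(rownames(x), times = ncol(x)),
    prediction = rep(colnames(x), each = nrow(x)),
    n = as.vector(unclass(x)),
    fraction = as.vector(nm)
  )
}

#' Heatmap of a row-normalised confusion matrix
#'
#' @param object A `wound_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wound_confusion <- function(object, ...) {
  df <- tidy.wound_confusion(object)
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$prediction <- factor(df$prediction, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$fraction), "",
                     sprintf("%.2f", .data$fraction))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "row fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
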