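#' Rasterize polygon annotations into class and certainty maps
#'
#' Converts the polygon regions of one image into the label representation
#' used by the loss and the trainer: an integer class mask (0 = background,
#' 1..7 = active wound class) plus a per-pixel certainty-weight map over
#' \{0.5, 1.0, 1.5\}. A pixel (r, c) belongs to a polygon iff its center
#' (c + 0.5, r + 0.5) lies inside under the even-odd rule. Overlapping
#' active regions are resolved by file order: the later region overwrites
#' the earlier one (the annotation protocol already assigns overlaps to the
#' visually dominant class, so on-disk overlaps are rare). Regions of
#' inactive (post-hoc removed) classes rasterize to background, and
#' `certainty_map` is 1.0 on background.
#'
#' @param annotations A `via_annotations` object.
#' @param image_id Which image to rasterize.
#' @param width,height Optional dimension overrides (needed if the
#'   annotation file does not record them).
#' @param class_order Character vector fixing the class-to-index mapping;
#'   defaults to background plus the seven active classes.
#' @return A `label_maps` object: list with `class_mask` (H x W integer
#'   matrix), `certainty_map` (H x W numeric matrix), `class_order`, `C`.
#' @export
rasterize <- function(annotations, image_id, width = NULL, height = NULL,
                      class_order = default_class_order()) {
  stopifnot(inherits(annotations, "via_annotations"))
  img <- annotations$images[annotations$images$image_id == image_id, ]
  if (nrow(img) != 1) stop("image_id not found: ", image_id)
  width <- width %||% img$width
  height <- height %||% img$height
  if (is.na(width) || is.na(height)) {
    stop("image dimensions unknown for ", image_id,
         "; pass width/height explicitly")
  }
  regs <- annotations$regions[annotations$regions$image_id == image_id, ]
  class_mask <- matrix(0L, nrow = height, ncol = width)
  certainty_map <- matrix(1.0, nrow = height, ncol = width)
  for (j in seq_len(nrow(regs))) {
    xs <- pmin(pmax(regs$xs[[j]], 0), width)
    ys <- pmin(pmax(regs$ys[[j]], 0), height)
    if (nrow(unique(cbind(xs, ys))) < 3) {
      stop("degenerate polygon (<3 distinct vertices) in image ", image_id,
           ", region ", regs$region_id[j])
    }
    if (!polygon_is_simple(xs, ys)) {
      stop("self-intersecting polygon in image ", image_id,
           ", region ", regs$region_id[j])
    }
    inside <- polygon_fill(xs, ys, height, width)
    if (!any(inside)) {
      warning("polygon covers no pixel centers in image ", image_id,
              ", region ", regs$region_id[j])
      next
    }
    if (!regs$active[j]) next  # inactive classes map to background
    cls_idx <- match(regs$wound_class[j], class_order) - 1L
    if (is.na(cls_idx)) {
      stop("class ", regs$wound_class[j], " not in class_order")
    }
    class_mask[inside] <- cls_idx
    certainty_map[inside] <- certainty_weight(regs$certainty[j])
  }
  # background pixels (including those uncovered by overwritten regions)
  certainty_map[class_mask == 0L] <- 1.0
  label_maps(class_mask, certainty_map, class_order)
}

#' @rdname rasterize
#' @param class_mask Integer H x W matrix of class indices.
#' @param certainty_map Numeric H x W matrix of certainty weights.
#' @export
label_maps <- function(class_mask, certainty_map = NULL,
                       class_order = default_class_order()) {
  storage.mode(class_mask) <- "integer"
  if (is.null(certainty_map)) {
    certainty_map <- matrix(1.0, nrow = nrow(class_mask),
                            ncol = ncol(class_mask))
  }
  stopifnot(identical(dim(class_mask), dim(certainty_map)))
  rng <- range(class_mask)
  if (rng[1] < 0 || rng[2] >= length(class_order)) {
    stop("class_mask values outside 0..", length(class_order) - 1L)
  }
  if (any(certainty_map[class_mask == 0L] != 1.0)) {
    stop("certainty_map must be 1.0 on background pixels")
  }
  structure(
    list(class_mask = class_mask, certainty_map = certainty_map,
         class_order = class_order, C = length(class_order)),
    class = "label_maps"
  )
}

#' @export
print.label_maps <- function(x, ...) {
  cat("<label_maps> ", nrow(x$class_mask), "x", ncol(x$class_mask),
      ", ", x$C, " channels; wound fraction ",
      signif(mean(x$class_mask > 0), 3), "\n", sep = "")
  invisible(x)
}

#' Rasterize every image of an annotation set
#'
#' @inheritParams rasterize
#' @return Named list of `label_maps`, one per image.
#' @export
rasterize_all <- function(annotations, class_order = default_class_order()) {
  ids <- annotations$images$image_id
  out <- lapply(ids, function(id) rasterize(annotations, id,
                                            class_order = class_order))
  names(out) <- ids
  out
}

#' Pixelwise class frequencies of a mask collection
#'
#' Per-class label frequencies f_c = (pixels of class c) / (all pixels),
#' pooled over the supplied masks. These frequencies feed the
#' inverse-frequency class weights of the training loss, so in an
#' experiment they are computed over the training split only.
#'
#' @param masks A list of `label_maps` (or a single one).
#' @return Named numeric vector of frequencies over all classes including
#'   background; sums to 1. Classes absent from the data get 0 and are
#'   reported in the `"absent"` attribute.
#' @export
class_frequencies <- function(masks) {
  if (inherits(masks, "label_maps")) masks <- list(masks)
  if (length(masks) == 0) stop("empty mask collection")
  class_order <- masks[[1]]$class_order
  C <- length(class_order)
  counts <- numeric(C)
  total <- 0
  for (m in masks) {
    stopifnot(identical(m$class_order, class_order))
    counts <- counts + tabulate(m$class_mask + 1L, nbins = C)
    total <- total + length(m$class_mask)
  }
  f <- counts / total
  names(f) <- class_order
  absent <- class_order[counts == 0]
  if (length(absent) > 0) attr(f, "absent") <- absent
  f
}

#' Summary statistics of an annotated dataset
#'
#' Per-class region counts (from the annotations) and per-class
#' wound-area-to-image-area fractions (pooled over the masks), the two
#' quantities that characterise a wound dataset's class imbalance.
#' Inactive-class regions are counted but carry no area (they rasterize to
#' background).
#'
#' @param annotations A `via_annotations` object.
#' @param masks List of `label_maps` named by image id, corresponding to
#'   the annotation set.
#' @return A tibble (class `wound_dataset_stats`) with columns `class`,
#'   `active`, `n_regions`, `area_fraction`; the total wound fraction is
#'   attached as attribute `"total_wound_fraction"`.
#' @export
dataset_stats <- function(annotations, masks) {
  stopifnot(inherits(annotations, "via_annotations"))
  ids <- annotations$images$image_id
  if (!setequal(names(masks), ids)) {
    stop("mask names do not match annotation image ids")
  }
  f <- if (length(masks) > 0) class_frequencies(masks) else NULL
  all_cls <- wound_classes(active_only = FALSE)
  all_cls <- all_cls[all_cls$name != "background", ]
  counts <- table(factor(annotations$regions$wound_class,
                         levels = all_cls$name))
  area <- stats::setNames(rep(0, nrow(all_cls)), all_cls$name)
  if (!is.null(f)) {
    shared <- intersect(names(f), all_cls$name)
    area[shared] <- f[shared]
  }
  out <- tibble::tibble(
    class = all_cls$name,
    active = all_cls$active,
    n_regions = as.integer(counts),
    area_fraction = unname(area)
  )
  attr(out, "total_wound_fraction") <- sum(out$area_fraction)
  class(out) <- c("wound_dataset_stats", class(out))
  out
}
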