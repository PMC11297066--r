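#' Wound class catalogue
#'
#' The class vocabulary used throughout the pipeline: seven active wound
#' classes plus background, and three additional classes that occur in raw
#' annotation exports but are too rare to train on. Inactive classes are
#' parsed and counted, but always rasterize to background and never appear
#' in training targets.
#'
#' @param active_only If `TRUE` (default), return only background plus the
#'   seven active wound classes, in mask-index order.
#' @return A tibble with columns `id` (mask integer code; `NA` for inactive
#'   classes), `name`, and `active`.
#' @export
#' @examples
#' wound_classes()
wound_classes <- function(active_only = TRUE) {
  tbl <- tibble::tibble(
    id = c(0:7, NA_integer_, NA_integer_, NA_integer_),
    name = c(
      "background", "skin_abrasion", "subcutaneous_hematoma",
      "dermatorrhagia", "cut", "contused_lacerated", "stab", "thermal",
      "semisharp_force", "puncture_gunshot", "laceration"
    ),
    active = c(rep(TRUE, 8), rep(FALSE, 3))
  )
  if (active_only) tbl[tbl$active, ] else tbl
}

#' @rdname wound_classes
#' @export
active_wound_classes <- function() {
  wc <- wound_classes(active_only = TRUE)
  wc$name[wc$id > 0]
}

#' @rdname wound_classes
#' @export
inactive_wound_classes <- function() {
  wc <- wound_classes(active_only = FALSE)
  wc$name[!wc$active]
}

# mask-index order of all channels (background first), used everywhere
default_class_order <- function() wound_classes(active_only = TRUE)$name

#' Annotation certainty levels and their loss weights
#'
#' Each annotated wound region carries a likelihood attribute recording how
#' confidently the annotator could classify it. The three levels map
#' one-to-one onto per-pixel loss multipliers: regions labelled with low
#' certainty contribute less to the training loss, confident regions more.
#'
#' @return `certainty_levels()` returns a tibble with columns `level`,
#'   `via_string` (the label used in VIA project files) and `weight`.
#' @export
#' @examples
#' certainty_levels()
#' certainty_weight("very_certain")
certainty_levels <- function() {
  tibble::tibble(
    level = c("not_certain", "quite_certain", "very_certain"),
    via_string = c("not certain", "quite certain", "very certain"),
    weight = c(0.5, 1.0, 1.5)
  )
}

#' @rdname certainty_levels
#' @param level Character vector of certainty levels
#'   (`"not_certain"`, `"quite_certain"`, `"very_certain"`).
#' @return `certainty_weight()` returns the numeric weight(s)
#'   \{0.5, 1.0, 1.5\}.
#' @export
certainty_weight <- function(level) {
  lv <- certainty_levels()
  idx <- match(level, lv$level)
  if (anyNA(idx)) {
    stop("unknown certainty level(s): ",
         paste(unique(level[is.na(idx)]), collapse = ", "))
  }
  lv$weight[idx]
}

certainty_from_via <- function(via_string) {
  lv <- certainty_levels()
  idx <- match(via_string, lv$via_string)
  lv$level[idx]
}

certainty_to_via <- function(level) {
  lv <- certainty_levels()
  lv$via_string[match(level, lv$level)]
}
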