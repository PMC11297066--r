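#' Construct an annotation set
#'
#' An annotation set bundles per-image metadata with polygon wound regions.
#' It is the in-memory form of a VIA (VGG Image Annotator) v2 project:
#' every region is a polygon in 0-based pixel coordinates (x = column,
#' y = row) with a wound class and an annotator-certainty level.
#'
#' @param images Tibble/data frame with columns `image_id`, `filename`,
#'   `width`, `height` (dimensions may be `NA` if unknown).
#' @param regions Tibble/data frame with columns `image_id`, `region_id`,
#'   `xs`, `ys` (list columns of numeric vertex coordinates), `wound_class`,
#'   `certainty`; a logical `active` column is derived if absent.
#' @return An object of class `via_annotations`: a list with tibbles
#'   `$images` and `$regions`.
#' @export
annotation_set <- function(images, regions) {
  images <- tibble::as_tibble(images)
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("image_id", "filename", "width", "height") %in% names(images)))
  if (anyDuplicated(images$image_id)) {
    stop("duplicate image_id in annotation set")
  }
  if (any(!is.na(images$width) & images$width <= 0) ||
      any(!is.na(images$height) & images$height <= 0)) {
    stop("image dimensions must be positive")
  }
  if (nrow(regions) > 0) {
    stopifnot(all(c("image_id", "region_id", "xs", "ys",
                    "wound_class", "certainty") %in% names(regions)))
    known <- wound_classes(active_only = FALSE)$name
    bad <- setdiff(unique(regions$wound_class), setdiff(known, "background"))
    if (length(bad) > 0) {
      stop("unknown wound class(es): ", paste(bad, collapse = ", "))
    }
    nv <- vapply(regions$xs, length, integer(1))
    if (any(nv < 3)) stop("polygon regions need at least 3 vertices")
    if (!"active" %in% names(regions)) {
      regions$active <- regions$wound_class %in% active_wound_classes()
    }
  } else {
    regions <- tibble::tibble(
      image_id = character(), region_id = integer(),
      xs = list(), ys = list(),
      wound_class = character(), certainty = character(), active = logical()
    )
  }
  structure(list(images = images, regions = regions), class = "via_annotations")
}

#' @export
print.via_annotations <- function(x, ...) {
  cat("<via_annotations> ", nrow(x$images), " image(s), ",
      nrow(x$regions), " region(s)\n", sep = "")
  if (nrow(x$regions) > 0) {
    counts <- table(x$regions$wound_class)
    cat("  classes:", paste(names(counts), counts, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.via_annotations <- function(x, ...) {
  dplyr::mutate(
    x$regions,
    n_vertices = vapply(.data$xs, length, integer(1))
  )
}

#' Parse a VIA v2-style project document
#'
#' Reads polygon wound annotations from a VGG Image Annotator v2 project
#' JSON. Each per-image record's `regions` entries with
#' `shape_attributes$name == "polygon"` become wound regions; the region
#' attributes `class` and `likelihood` carry the wound class and the
#' annotator certainty ("not certain" / "quite certain" / "very certain").
#' Regions whose class is one of the rare, post-hoc removed categories are
#' parsed but flagged inactive. A missing likelihood defaults to
#' `quite_certain` with a warning. Non-polygon shapes are skipped; each skip
#' is recorded in the `"skipped"` attribute of the result.
#'
#' @param x Path to a JSON file, a JSON string, or an already-parsed list.
#'   Both a bare per-image dictionary and a full project file with a
#'   `_via_img_metadata` entry are accepted.
#' @return A `via_annotations` object (see [annotation_set()]).
#' @export
parse_via <- function(x) {
  doc <- if (is.list(x)) x else jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  if (length(doc) == 0) {
    return(annotation_set(
      tibble::tibble(image_id = character(), filename = character(),
                     width = integer(), height = integer()),
      tibble::tibble()
    ))
  }
  known <- setdiff(wound_classes(active_only = FALSE)$name, "background")
  lv <- certainty_levels()
  images <- list()
  regions <- list()
  skipped <- list()
  missing_likelihood <- 0L
  for (key in names(doc)) {
    rec <- doc[[key]]
    fname <- rec$filename %||% key
    fa <- rec$file_attributes %||% list()
    width <- as.integer(fa$width %||% NA_integer_)
    height <- as.integer(fa$height %||% NA_integer_)
    image_id <- tools::file_path_sans_ext(fname)
    images[[length(images) + 1L]] <- tibble::tibble(
      image_id = image_id, filename = fname, width = width, height = height
    )
    regs <- rec$regions %||% list()
    for (ri in seq_along(regs)) {
      reg <- regs[[ri]]
      sa <- reg$shape_attributes
      if (is.null(sa$name) || !identical(sa$name, "polygon")) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          image_id = image_id, region_index = ri,
          reason = paste0("non-polygon shape: ", sa$name %||% "<missing>")
        )
        next
      }
      ra <- reg$region_attributes %||% list()
      cls <- ra$class
      if (is.null(cls) || !cls %in% known) {
        stop("unknown wound class ", if (is.null(cls)) "<missing>" else
             shQuote(cls), " in image ", image_id, ", region ", ri)
      }
      lk <- ra$likelihood
      if (is.null(lk) || !nzchar(lk)) {
        certainty <- "quite_certain"
        missing_likelihood <- missing_likelihood + 1L
      } else {
        certainty <- certainty_from_via(lk)
        if (is.na(certainty)) {
          certainty <- "quite_certain"
          missing_likelihood <- missing_likelihood + 1L
        }
      }
      regions[[length(regions) + 1L]] <- tibble::tibble(
        image_id = image_id, region_id = ri,
        xs = list(as.numeric(unlist(sa$all_points_x))),
        ys = list(as.numeric(unlist(sa$all_points_y))),
        wound_class = cls, certainty = certainty,
        active = cls %in% active_wound_classes()
      )
    }
  }
  if (missing_likelihood > 0L) {
    warning(missing_likelihood,
            " region(s) had a missing or unrecognised likelihood; ",
            "defaulting to quite_certain")
  }
  out <- annotation_set(
    dplyr::bind_rows(images),
    if (length(regions) > 0) dplyr::bind_rows(regions) else tibble::tibble()
  )
  if (length(skipped) > 0) {
    attr(out, "skipped") <- dplyr::bind_rows(skipped)
    warning(length(skipped), " non-polygon region(s) skipped")
  }
  out
}

#' Write an annotation set as a VIA v2-style document
#'
#' Serialises a `via_annotations` object back to the VIA per-image JSON
#' dialect, so that `parse_via(write_via(a))` reproduces `a` exactly.
#' Image dimensions are stored in `file_attributes` so masks can be
#' rebuilt without the pixel data.
#'
#' @param annotations A `via_annotations` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly, when `path` is given).
#' @export
write_via <- function(annotations, path = NULL) {
  stopifnot(inherits(annotations, "via_annotations"))
  doc <- list()
  for (i in seq_len(nrow(annotations$images))) {
    img <- annotations$images[i, ]
    regs <- annotations$regions[annotations$regions$image_id == img$image_id, ]
    region_list <- lapply(seq_len(nrow(regs)), function(j) {
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = I(regs$xs[[j]]),
          all_points_y = I(regs$ys[[j]])
        ),
        region_attributes = list(
          class = regs$wound_class[j],
          likelihood = certainty_to_via(regs$certainty[j])
        )
      )
    })
    key <- paste0(img$filename, "-1")  # VIA uses filename + byte size; size unknown
    doc[[key]] <- list(
      filename = img$filename,
      size = -1L,
      regions = region_list,
      file_attributes = list(width = img$width, height = img$height)
    )
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
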