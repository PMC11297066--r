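#' Configuration of the synthetic wound-photograph generator
#'
#' The generator emulates the statistical structure of forensic wound
#' photograph collections rather than their appearance: a skin-toned
#' textured background; polygonal wound regions whose per-class area
#' fractions reproduce the extreme area imbalance (the dominant class,
#' subcutaneous hematoma, covers about 1% of all pixels and all wounds
#' together about 2%); a strongly skewed per-class region-count mixture;
#' fuzzy, soft-edged wound boundaries; distractor content (tattoo-like
#' line patterns and blood-like background stains that belong to the
#' background class); blur/exposure degradation; and per-region certainty
#' labels correlated with rendering contrast (hard-to-see wounds tend to
#' be annotated "not certain").
#'
#' @param n_images Number of images.
#' @param image_size `c(H, W)` in pixels (default desk-scale 96 x 96;
#'   full-scale experiments use 512).
#' @param class_area_fractions Named vector of per-class target
#'   wound-area-to-image-area fractions. Defaults: dominant class 0.01,
#'   all classes together 0.02.
#' @param class_count_weights Named vector of relative expected region
#'   counts (imbalanced, hematoma most frequent).
#' @param regions_per_image Expected total wound regions per image
#'   (Poisson).
#' @param certainty_probs Base probabilities of the three certainty
#'   levels.
#' @param low_contrast_not_certain_prob Probability that a low-contrast
#'   rendering is labelled `not_certain` regardless of the base
#'   distribution.
#' @param tattoo_rate,stain_rate,blur_rate,exposure_rate Per-image
#'   probabilities of the distractor/degradation effects.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   datasets.
#' @return A `synth_config` object.
#' @export
synth_config <- function(
    n_images = 100,
    image_size = c(96, 96),
    class_area_fractions = c(
      skin_abrasion = 0.0020, subcutaneous_hematoma = 0.0100,
      dermatorrhagia = 0.0020, cut = 0.0015, contused_lacerated = 0.0015,
      stab = 0.0010, thermal = 0.0020
    ),
    class_count_weights = c(
      skin_abrasion = 12, subcutaneous_hematoma = 20, dermatorrhagia = 8,
      cut = 6, contused_lacerated = 5, stab = 3, thermal = 2
    ),
    regions_per_image = 2.5,
    certainty_probs = c(not_certain = 0.15, quite_certain = 0.55,
                        very_certain = 0.30),
    low_contrast_not_certain_prob = 0.7,
    tattoo_rate = 0.2, stain_rate = 0.2, blur_rate = 0.15,
    exposure_rate = 0.15, seed = 1) {
  stopifnot(n_images >= 1, length(image_size) == 2, all(image_size >= 32),
            all(image_size %% 4 == 0))
  stopifnot(setequal(names(class_area_fractions), active_wound_classes()),
            setequal(names(class_count_weights), active_wound_classes()))
  if (any(class_area_fractions < 0) || sum(class_area_fractions) >= 0.5) {
    stop("class area fractions must be >= 0 and sum to < 0.5")
  }
  stopifnot(abs(sum(certainty_probs) - 1) < 1e-8)
  structure(
    list(n_images = as.integer(n_images),
         image_size = as.integer(image_size),
         class_area_fractions = class_area_fractions,
         class_count_weights = class_count_weights,
         regions_per_image = regions_per_image,
         certainty_probs = certainty_probs,
         low_contrast_not_certain_prob = low_contrast_not_certain_prob,
         tattoo_rate = tattoo_rate, stain_rate = stain_rate,
         blur_rate = blur_rate, exposure_rate = exposure_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# per-class geometry/appearance templates: one per active class.
# aspect stretches the footprint, roughness modulates the radial noise,
# edge_sigma is the boundary blur in pixels, color the mean RGB.
wound_templates <- function() {
  tibble::tribble(
    ~wound_class, ~aspect, ~roughness, ~edge_sigma, ~r, ~g, ~b, ~texture,
    "skin_abrasion",         1.6, 0.35, 1.2, 0.70, 0.30, 0.22, "speckle",
    "subcutaneous_hematoma", 1.3, 0.25, 2.5, 0.38, 0.25, 0.52, "none",
    "dermatorrhagia",        1.2, 0.20, 1.5, 0.80, 0.33, 0.45, "dots",
    "cut",                   5.0, 0.15, 0.5, 0.62, 0.04, 0.10, "none",
    "contused_lacerated",    1.5, 0.50, 1.2, 0.33, 0.22, 0.10, "speckle",
    "stab",                  2.2, 0.12, 0.5, 0.10, 0.02, 0.06, "none",
    "thermal",               1.3, 0.20, 1.5, 0.88, 0.76, 0.33, "rim"
  )
}

# star-shaped (hence simple) random polygon with exact target area,
# centered at (cx, cy); returns list(xs, ys)
radial_polygon <- function(area, aspect, roughness, cx, cy, n_vertices = 20) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  raw <- stats::rnorm(n_vertices)
  sm <- (raw + c(raw[-1], raw[1]) + c(raw[n_vertices], raw[-n_vertices])) / 3
  radii <- exp(roughness * sm)
  x <- radii * cos(theta) * sqrt(aspect)
  y <- radii * sin(theta) / sqrt(aspect)
  phi <- stats::runif(1, 0, 2 * pi)
  xr <- x * cos(phi) - y * sin(phi)
  yr <- x * sin(phi) + y * cos(phi)
  a0 <- shoelace_area(xr, yr)
  s <- sqrt(area / a0)
  list(xs = cx + s * xr, ys = cy + s * yr)
}

# deterministic allocation of region counts to images: each class gets
# round(n_images * lambda_c) regions over the whole dataset, assigned to
# images by seeded sampling. Keeps realized per-class area fractions
# tightly around their targets (count noise would otherwise dominate).
region_allocation <- function(config) {
  cw <- config$class_count_weights / sum(config$class_count_weights)
  lambda <- config$regions_per_image * cw
  set.seed((config$seed * 7919L + 11L) %% .Machine$integer.max)
  counts <- matrix(0L, config$n_images, length(lambda),
                   dimnames = list(NULL, names(lambda)))
  for (cls in names(lambda)) {
    n_tot <- round(config$n_images * lambda[[cls]])
    if (n_tot > 0) {
      tab <- table(sample.int(config$n_images, n_tot, replace = TRUE))
      counts[as.integer(names(tab)), cls] <- as.integer(tab)
    }
  }
  counts
}

shoelace_area <- function(xs, ys) {
  n <- length(xs)
  j <- c(2:n, 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# reference even-odd point-in-polygon fill at pixel centers. Kept in R and
# independent of the scanline rasterizer so generated ground truth can
# cross-check it.
ref_polygon_fill <- function(xs, ys, height, width) {
  yc <- seq_len(height) - 0.5
  xc <- seq_len(width) - 0.5
  count <- matrix(0L, height, width)
  n <- length(xs)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- ys[i]; y2 <- ys[j]
    act <- (y1 <= yc) != (y2 <= yc)
    if (!any(act)) next
    xcr <- xs[i] + (yc - y1) * (xs[j] - xs[i]) / (y2 - y1)
    count[act, ] <- count[act, ] + outer(xcr[act], xc, ">")
  }
  count %% 2L == 1L
}

smooth_noise <- function(h, w, sigma) {
  gaussian_blur(matrix(stats::rnorm(h * w), h, w), sigma)
}

draw_tattoo <- function(img, h, w) {
  mask <- matrix(0, h, w)
  x <- stats::runif(1, 10, w - 10)
  y <- stats::runif(1, 10, h - 10)
  dir <- stats::runif(1, 0, 2 * pi)
  for (step in seq_len(60)) {
    dir <- dir + stats::rnorm(1, sd = 0.35)
    x <- pmin(pmax(x + 1.5 * cos(dir), 2), w - 1)
    y <- pmin(pmax(y + 1.5 * sin(dir), 2), h - 1)
    rr <- round(y) + c(0L, 0L, 1L, -1L, 0L)
    cc <- round(x) + c(0L, 1L, 0L, 0L, -1L)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- 1
  }
  alpha <- clamp01(gaussian_blur(mask, 0.6) * 1.6) * 0.85
  ink <- c(0.12, 0.16, 0.24)
  for (k in 1:3) img[, , k] <- img[, , k] * (1 - alpha) + ink[k] * alpha
  img
}

draw_stain <- function(img, h, w) {
  area <- stats::runif(1, 80, 220) * (h * w) / 9216
  poly <- radial_polygon(area, stats::runif(1, 1.1, 1.8), 0.4,
                         stats::runif(1, 12, w - 12),
                         stats::runif(1, 12, h - 12))
  fill <- ref_polygon_fill(poly$xs, poly$ys, h, w)
  alpha <- clamp01(gaussian_blur(fill * 1, 1.5))
  col <- c(0.55, 0.10, 0.12)
  for (k in 1:3) img[, , k] <- img[, , k] * (1 - alpha) + col[k] * alpha
  img
}

#' Generate one synthetic wound photograph
#'
#' Draws a skin-toned textured background, optional distractors, and a
#' seeded mixture of polygonal wound regions from the per-class templates.
#' The emitted polygon annotations delineate the region footprint before
#' edge blurring (equivalently, the 0.5 level of the rendered alpha), and
#' the reference label maps are produced by the generator's own even-odd
#' fill, independently of the scanline rasterizer.
#'
#' @param config A [synth_config()].
#' @param index Image index in `1..n_images`; drives the per-image seed.
#' @return List with `image` (H x W x 3 array), `annotation`
#'   (`via_annotations` with one image), `ref_maps` (`label_maps`), and a
#'   `placement` tibble of bookkeeping (class, target and realized pixel
#'   area, certainty, contrast).
#' @export
generate_image <- function(config, index = 1) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  alloc <- region_allocation(config)
  set.seed((config$seed * 10007L + index) %% .Machine$integer.max)
  templates <- wound_templates()
  class_order <- default_class_order()

  # skin background with smooth tone variation and fine texture
  base <- c(0.82, 0.66, 0.54) + stats::rnorm(3, sd = 0.04)
  low <- smooth_noise(h, w, 8)
  low <- low / max(abs(low), 1e-9)
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    img[, , k] <- clamp01(base[k] + 0.05 * low +
                            matrix(stats::rnorm(h * w, sd = 0.015), h, w))
  }
  if (stats::runif(1) < config$tattoo_rate) img <- draw_tattoo(img, h, w)
  if (stats::runif(1) < config$stain_rate) img <- draw_stain(img, h, w)

  # expected per-class region counts per image
  cw <- config$class_count_weights / sum(config$class_count_weights)
  lambda <- config$regions_per_image * cw
  mean_area <- config$class_area_fractions * (h * w) /
    pmax(lambda[names(config$class_area_fractions)], 1e-9)

  occupied <- matrix(FALSE, h, w)
  class_mask <- matrix(0L, h, w)
  certainty_map <- matrix(1.0, h, w)
  regions <- list()
  placement <- list()
  dropped <- 0L
  for (cls in names(lambda)) {
    n_c <- alloc[index, cls]
    if (n_c == 0) next
    tpl <- templates[templates$wound_class == cls, ]
    for (rep_i in seq_len(n_c)) {
      area <- min(mean_area[[cls]] * stats::runif(1, 0.6, 1.4), 0.05 * h * w)
      placed <- FALSE
      for (attempt in seq_len(100)) {
        rad <- sqrt(area / pi) * sqrt(tpl$aspect) * exp(tpl$roughness) + 2
        if (2 * rad >= min(h, w)) rad <- min(h, w) / 2 - 1
        poly <- radial_polygon(area, tpl$aspect, tpl$roughness,
                               stats::runif(1, rad, w - rad),
                               stats::runif(1, rad, h - rad))
        poly$xs <- pmin(pmax(poly$xs, 0), w)
        poly$ys <- pmin(pmax(poly$ys, 0), h)
        fill <- ref_polygon_fill(poly$xs, poly$ys, h, w)
        if (!any(fill) || any(fill & occupied)) next
        placed <- TRUE
        break
      }
      if (!placed) {
        dropped <- dropped + 1L
        next
      }
      occupied <- occupied | fill
      # render the wound with a soft boundary and class-specific texture
      alpha <- clamp01(gaussian_blur(fill * 1, tpl$edge_sigma))
      col <- array(0, dim = c(h, w, 3))
      base_col <- c(tpl$r, tpl$g, tpl$b)
      for (k in 1:3) {
        col[, , k] <- clamp01(base_col[k] +
                                matrix(stats::rnorm(h * w, sd = 0.03), h, w))
      }
      if (tpl$texture == "speckle") {
        spots <- smooth_noise(h, w, 1) > 0.25
        dk <- if (cls == "skin_abrasion") 0.15 else 0.35
        for (k in 1:3) col[, , k] <- col[, , k] - dk * spots
      } else if (tpl$texture == "dots") {
        dots <- smooth_noise(h, w, 0.8) > 0.35
        dot_col <- c(0.62, 0.10, 0.33)
        for (k in 1:3) {
          col[, , k] <- ifelse(dots, dot_col[k], col[, , k])
        }
      } else if (tpl$texture == "rim") {
        rim <- alpha > 0.15 & alpha < 0.6
        rim_col <- c(0.78, 0.35, 0.27)
        for (k in 1:3) col[, , k] <- ifelse(rim, rim_col[k], col[, , k])
      }
      contrast_px <- abs(col[, , 1] - img[, , 1]) +
        abs(col[, , 2] - img[, , 2]) + abs(col[, , 3] - img[, , 3])
      contrast <- mean(contrast_px[fill]) / 3 * exp(-tpl$edge_sigma / 2)
      for (k in 1:3) {
        img[, , k] <- img[, , k] * (1 - alpha) + clamp01(col[, , k]) * alpha
      }
      # low-contrast renderings tend to be annotated "not certain"
      if (contrast < 0.12 &&
          stats::runif(1) < config$low_contrast_not_certain_prob) {
        certainty <- "not_certain"
      } else {
        certainty <- sample(names(config$certainty_probs), 1,
                            prob = config$certainty_probs)
      }
      cls_idx <- match(cls, class_order) - 1L
      class_mask[fill] <- cls_idx
      certainty_map[fill] <- certainty_weight(certainty)
      regions[[length(regions) + 1L]] <- tibble::tibble(
        image_id = NA_character_, region_id = length(regions) + 1L,
        xs = list(poly$xs), ys = list(poly$ys),
        wound_class = cls, certainty = certainty, active = TRUE
      )
      placement[[length(placement) + 1L]] <- tibble::tibble(
        wound_class = cls, target_area = area,
        realized_area = sum(fill), certainty = certainty,
        contrast = contrast
      )
    }
  }
  if (dropped > 0L) {
    message("image ", index, ": dropped ", dropped,
            " unplaceable region(s) after 100 attempts")
  }
  if (stats::runif(1) < config$blur_rate) {
    for (k in 1:3) img[, , k] <- gaussian_blur(img[, , k], 0.8)
  }
  if (stats::runif(1) < config$exposure_rate) {
    img <- clamp01(img * stats::runif(1, 0.6, 1.4))
  }
  image_id <- sprintf("img_%04d", index)
  regs <- if (length(regions) > 0) {
    tmp <- dplyr::bind_rows(regions)
    tmp$image_id <- image_id
    tmp
  } else tibble::tibble()
  ann <- annotation_set(
    tibble::tibble(image_id = image_id,
                   filename = paste0(image_id, ".png"),
                   width = w, height = h),
    regs
  )
  list(
    image = img,
    annotation = ann,
    ref_maps = label_maps(class_mask, certainty_map, class_order),
    placement = if (length(placement) > 0) dplyr::bind_rows(placement)
                else tibble::tibble(),
    dropped = dropped
  )
}

certainty_png_codes <- c(not_certain = 1L, quite_certain = 2L,
                         very_certain = 3L)

#' Generate a synthetic dataset on disk
#'
#' Writes PNG photographs, a VIA-style annotation JSON, reference mask and
#' certainty PNGs, a class-order sidecar and a manifest recording the
#' seed, a config hash and the realized per-class statistics.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list with `dir`, `manifest`, `annotations`, and
#'   the in-memory `images` and `masks`.
#' @export
generate_dataset <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  anns <- list()
  images <- list()
  masks <- list()
  placements <- list()
  dropped <- 0L
  for (i in seq_len(config$n_images)) {
    gi <- generate_image(config, i)
    id <- gi$annotation$images$image_id[1]
    images[[id]] <- gi$image
    masks[[id]] <- gi$ref_maps
    anns[[i]] <- gi$annotation
    placements[[i]] <- gi$placement
    dropped <- dropped + gi$dropped
    png::writePNG(gi$image, file.path(out_dir, "images",
                                      paste0(id, ".png")))
    png::writePNG(gi$ref_maps$class_mask / 255,
                  file.path(out_dir, "masks", paste0(id, "_mask.png")))
    cert_codes <- matrix(
      certainty_png_codes[match(gi$ref_maps$certainty_map,
                                certainty_levels()$weight)],
      nrow = nrow(gi$ref_maps$certainty_map)
    )
    png::writePNG(cert_codes / 255,
                  file.path(out_dir, "masks", paste0(id, "_cert.png")))
  }
  annotations <- merge_annotation_sets(anns)
  write_via(annotations, file.path(out_dir, "via_annotations.json"))
  jsonlite::write_json(
    list(class_order = default_class_order(),
         certainty_png_codes = as.list(certainty_png_codes),
         certainty_weights = as.list(
           stats::setNames(certainty_levels()$weight,
                           certainty_levels()$level))),
    file.path(out_dir, "class_order.json"), auto_unbox = TRUE
  )
  freq <- class_frequencies(masks)
  counts <- table(factor(annotations$regions$wound_class,
                         levels = active_wound_classes()))
  manifest <- list(
    seed = config$seed,
    n_images = config$n_images,
    image_size = config$image_size,
    config_hash = rlang::hash(config),
    realized_class_fractions = as.list(freq),
    realized_region_counts = as.list(counts),
    total_wound_fraction = sum(freq[names(freq) != "background"]),
    dropped_regions = dropped
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, manifest = manifest,
                 annotations = annotations, images = images, masks = masks))
}

merge_annotation_sets <- function(sets) {
  annotation_set(
    dplyr::bind_rows(lapply(sets, function(a) a$images)),
    dplyr::bind_rows(lapply(sets, function(a) a$regions))
  )
}

#' Load a generated dataset from disk
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @return List with `images`, `masks` (named lists), `annotations`,
#'   `manifest`.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sidecar <- jsonlite::read_json(file.path(dir, "class_order.json"),
                                 simplifyVector = TRUE)
  annotations <- parse_via(file.path(dir, "via_annotations.json"))
  ids <- annotations$images$image_id
  images <- list()
  masks <- list()
  weights_by_code <- stats::setNames(
    unlist(sidecar$certainty_weights)[names(sidecar$certainty_png_codes)],
    as.character(unlist(sidecar$certainty_png_codes))
  )
  for (id in ids) {
    images[[id]] <- png::readPNG(file.path(dir, "images",
                                           paste0(id, ".png")))
    cm <- round(png::readPNG(file.path(dir, "masks",
                                       paste0(id, "_mask.png"))) * 255)
    codes <- round(png::readPNG(file.path(dir, "masks",
                                          paste0(id, "_cert.png"))) * 255)
    cert <- matrix(weights_by_code[as.character(codes)], nrow = nrow(cm))
    cert[cm == 0] <- 1.0
    masks[[id]] <- label_maps(cm, cert, sidecar$class_order)
  }
  list(images = images, masks = masks, annotations = annotations,
       manifest = manifest)
}
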