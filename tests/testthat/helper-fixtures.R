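# shared fixtures, all built in code

# a small annotation set: 2 images, mixed classes/certainties, one
# inactive-class region
fixture_annotations <- function() {
  annotation_set(
    images = tibble::tibble(
      image_id = c("a", "b"),
      filename = c("a.png", "b.png"),
      width = c(20L, 16L), height = c(20L, 16L)
    ),
    regions = tibble::tibble(
      image_id = c("a", "a", "b"),
      region_id = c(1L, 2L, 1L),
      xs = list(c(0, 10, 10, 0), c(12, 18, 18, 12), c(2, 9, 9, 2)),
      ys = list(c(0, 0, 10, 10), c(12, 12, 18, 18), c(2, 2, 9, 9)),
      wound_class = c("stab", "cut", "laceration"),
      certainty = c("very_certain", "not_certain", "quite_certain")
    )
  )
}

# random softmax prediction tensor
fixture_probs <- function(h, w, C) {
  p <- array(stats::runif(h * w * C, 0.05, 1), dim = c(h, w, C))
  s <- apply(p, c(1, 2), sum)
  for (k in seq_len(C)) p[, , k] <- p[, , k] / s
  p
}

fixture_target <- function(h, w, C, wound_only_m = FALSE) {
  mask <- matrix(sample(0:(C - 1), h * w, replace = TRUE), h, w)
  cert <- matrix(sample(c(0.5, 1, 1.5), h * w, replace = TRUE), h, w)
  cert[mask == 0] <- 1
  label_maps(mask, cert, class_order = paste0("k", seq_len(C) - 1))
}

one_hot_mask_for_test <- function(mask, C) {
  p <- array(0, dim = c(nrow(mask), ncol(mask), C))
  for (k in seq_len(C)) p[, , k] <- as.numeric(mask == (k - 1L))
  p
}

# triple-loop reference implementation of the certainty- and
# class-weighted BCE (independent oracle: explicit sums over pixels and
# channels, no vectorisation)
bce_reference <- function(p, target, w, config) {
  C <- dim(p)[3]
  H <- dim(p)[1]; W <- dim(p)[2]
  N <- H * W
  pref <- 1 / if (config$prefactor_channels == "all") C else (C - 1)
  total <- 0
  for (cc in seq_len(C)) {
    t1 <- 0; t2 <- 0
    for (r in seq_len(H)) {
      for (col in seq_len(W)) {
        g <- as.numeric(target$class_mask[r, col] == (cc - 1))
        m <- if (config$use_certainty_weights) {
          target$certainty_map[r, col]
        } else 1
        t1 <- t1 + m * g * log(p[r, col, cc] + config$eps)
        t2 <- t2 + m * (1 - g) * log(1 - p[r, col, cc] + config$eps)
      }
    }
    total <- total + w[cc] / N * t1 + 1 / N * t2
  }
  -pref * total
}

# random convex polygon (convex hull of random points), for the
# rasterization boundary-bound property
random_convex_polygon <- function(width, height, n_pts = 12) {
  x <- stats::runif(n_pts, 1, width - 1)
  y <- stats::runif(n_pts, 1, height - 1)
  h <- grDevices::chull(x, y)
  list(xs = x[h], ys = y[h])
}

polygon_perimeter <- function(xs, ys) {
  j <- c(seq_along(xs)[-1], 1)
  sum(sqrt((xs[j] - xs)^2 + (ys[j] - ys)^2))
}

shoelace <- function(xs, ys) {
  j <- c(seq_along(xs)[-1], 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# single-image annotation set around one polygon
one_region_set <- function(xs, ys, width, height, class = "stab",
                           certainty = "very_certain") {
  annotation_set(
    images = tibble::tibble(image_id = "img", filename = "img.png",
                            width = width, height = height),
    regions = tibble::tibble(image_id = "img", region_id = 1L,
                             xs = list(xs), ys = list(ys),
                             wound_class = class, certainty = certainty)
  )
}

# small deterministic dataset shared by training/experiment smoke tests,
# generated once per test session
smoke_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_images = 16, image_size = c(48, 48), seed = 99)
      dir <- file.path(tempdir(), "woundseg-smoke-ds")
      cache <<- generate_dataset(cfg, dir, overwrite = TRUE)
    }
    cache
  }
})
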