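test_that("identical config and seed give bit-identical output", {
  cfg <- synth_config(n_images = 2, image_size = c(48, 48), seed = 7)
  a <- generate_image(cfg, 1)
  b <- generate_image(cfg, 1)
  expect_identical(a$image, b$image)
  expect_identical(a$annotation$regions, b$annotation$regions)
  expect_identical(a$ref_maps$class_mask, b$ref_maps$class_mask)

  d1 <- file.path(tempdir(), "synth-det-1")
  d2 <- file.path(tempdir(), "synth-det-2")
  g1 <- generate_dataset(cfg, d1, overwrite = TRUE)
  g2 <- generate_dataset(cfg, d2, overwrite = TRUE)
  h <- function(d) {
    files <- sort(dir(d, recursive = TRUE))
    vapply(files, function(f) rlang::hash(readBin(file.path(d, f), "raw",
                                                  5e6)), character(1))
  }
  expect_identical(unname(h(d1)), unname(h(d2)))
  expect_equal(g1$manifest$config_hash, g2$manifest$config_hash)
})

test_that("emitted annotations agree with the reference masks within the
           boundary bound", {
  cfg <- synth_config(n_images = 4, seed = 13)
  for (i in 1:4) {
    gi <- generate_image(cfg, i)
    if (nrow(gi$annotation$regions) == 0) next
    lm <- rasterize(gi$annotation, gi$annotation$images$image_id[1])
    disagree <- sum(lm$class_mask != gi$ref_maps$class_mask)
    total_perim <- sum(vapply(seq_len(nrow(gi$annotation$regions)),
      function(j) polygon_perimeter(gi$annotation$regions$xs[[j]],
                                    gi$annotation$regions$ys[[j]]),
      numeric(1)))
    bound <- total_perim + 4 * nrow(gi$annotation$regions)
    expect_lte(disagree, bound)
  }
})

test_that("distractor stains are background in the reference mask", {
  cfg <- synth_config(n_images = 1, seed = 23, stain_rate = 1,
                      tattoo_rate = 1, regions_per_image = 0.5)
  gi <- generate_image(cfg, 1)
  # every labelled pixel traces back to an annotated wound region, so the
  # stain/tattoo pixels stay background
  labelled <- sum(gi$ref_maps$class_mask > 0)
  region_px <- sum(vapply(seq_len(nrow(gi$annotation$regions)), function(j) {
    sum(woundseg:::ref_polygon_fill(gi$annotation$regions$xs[[j]],
                                    gi$annotation$regions$ys[[j]],
                                    96, 96))
  }, numeric(1)))
  expect_equal(labelled, region_px)
})

test_that("degenerate mixtures and minimal datasets are valid", {
  cw <- c(skin_abrasion = 0, subcutaneous_hematoma = 0, dermatorrhagia = 0,
          cut = 0, contused_lacerated = 0, stab = 1, thermal = 0)
  cfg <- synth_config(n_images = 3, image_size = c(48, 48),
                      class_count_weights = cw, regions_per_image = 3,
                      seed = 3)
  for (i in 1:3) {
    gi <- generate_image(cfg, i)
    if (nrow(gi$annotation$regions) > 0) {
      expect_true(all(gi$annotation$regions$wound_class == "stab"))
    }
  }
  d <- file.path(tempdir(), "synth-single")
  g <- generate_dataset(synth_config(n_images = 1, seed = 2), d,
                        overwrite = TRUE)
  expect_length(g$images, 1)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_error(generate_dataset(synth_config(n_images = 1, seed = 2), d),
               "not empty")
})

test_that("realized dominant-class fraction tracks its target at n = 100", {
  cfg <- synth_config(n_images = 100, seed = 31)
  d <- file.path(tempdir(), "synth-100")
  g <- generate_dataset(cfg, d, overwrite = TRUE)
  realized <- g$manifest$realized_class_fractions$subcutaneous_hematoma
  expect_gt(realized, 0.008)
  expect_lt(realized, 0.012)
  total <- g$manifest$total_wound_fraction
  expect_gt(total, 0.016)
  expect_lt(total, 0.024)
  # manifest round-trips through load_dataset
  ds <- load_dataset(d)
  expect_equal(length(ds$images), 100)
  expect_equal(ds$manifest$config_hash, g$manifest$config_hash)
  expect_identical(ds$masks[[5]]$class_mask, g$masks[[5]]$class_mask)
  expect_identical(ds$masks[[5]]$certainty_map, g$masks[[5]]$certainty_map)
  st <- dataset_stats(ds$annotations, ds$masks)
  expect_equal(st$area_fraction[st$class == "subcutaneous_hematoma"],
               realized, tolerance = 1e-12)
})

test_that("wound classes are separable from raw colors by a linear probe", {
  skip_if_not_installed("nnet")
  cfg <- synth_config(n_images = 40, seed = 17)
  px <- list()
  for (i in seq_len(40)) {
    gi <- generate_image(cfg, i)
    m <- gi$ref_maps$class_mask
    idx <- which(m > 0)
    if (length(idx) == 0) next
    px[[length(px) + 1L]] <- data.frame(
      class = m[idx],
      r = gi$image[, , 1][idx],
      g = gi$image[, , 2][idx],
      b = gi$image[, , 3][idx]
    )
  }
  df <- do.call(rbind, px)
  set.seed(1)
  if (nrow(df) > 10000) df <- df[sample.int(nrow(df), 10000), ]
  df$class <- factor(df$class)
  fit <- nnet::multinom(class ~ r + g + b, data = df, trace = FALSE,
                        maxit = 400)
  pred <- predict(fit, df)
  recall <- vapply(levels(df$class), function(k) {
    mean(pred[df$class == k] == k)
  }, numeric(1))
  expect_true(all(recall >= 0.8))
})
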