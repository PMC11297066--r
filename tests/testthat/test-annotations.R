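test_that("VIA round trip is the identity on annotation sets", {
  ann <- fixture_annotations()
  json <- write_via(ann)
  back <- parse_via(json)
  expect_equal(back$images, ann$images)
  expect_equal(back$regions, ann$regions)
  # empty set round-trips too
  empty <- annotation_set(
    tibble::tibble(image_id = "x", filename = "x.png",
                   width = 8L, height = 8L),
    tibble::tibble()
  )
  back2 <- parse_via(write_via(empty))
  expect_equal(nrow(back2$regions), 0L)
  expect_equal(back2$images, empty$images)
})

test_that("certainty levels serialise to the VIA likelihood strings", {
  ann <- fixture_annotations()
  json <- write_via(ann)
  expect_match(json, "\"not certain\"", fixed = TRUE)
  expect_match(json, "\"very certain\"", fixed = TRUE)
  expect_match(json, "\"quite certain\"", fixed = TRUE)
})

test_that("missing likelihood defaults to quite_certain with a warning", {
  doc <- list(
    "x.png-1" = list(
      filename = "x.png",
      file_attributes = list(width = 10L, height = 10L),
      regions = list(list(
        shape_attributes = list(name = "polygon",
                                all_points_x = c(1, 5, 5, 1),
                                all_points_y = c(1, 1, 5, 5)),
        region_attributes = list(class = "cut")
      ))
    )
  )
  expect_warning(ann <- parse_via(doc), "quite_certain")
  expect_equal(ann$regions$certainty, "quite_certain")
})

test_that("inactive classes are parsed, flagged, and rasterize to background", {
  ann <- fixture_annotations()
  expect_false(ann$regions$active[ann$regions$wound_class == "laceration"])
  lm <- rasterize(ann, "b")
  expect_true(all(lm$class_mask == 0L))
  expect_true(all(lm$certainty_map == 1.0))
})

test_that("non-polygon regions are skipped with a record; unknown classes error", {
  doc <- list(
    "x.png-1" = list(
      filename = "x.png",
      file_attributes = list(width = 10L, height = 10L),
      regions = list(
        list(shape_attributes = list(name = "circle", cx = 3, cy = 3, r = 2),
             region_attributes = list(class = "cut",
                                      likelihood = "quite certain")),
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = c(1, 5, 5),
                                     all_points_y = c(1, 1, 5)),
             region_attributes = list(class = "stab",
                                      likelihood = "very certain"))
      )
    )
  )
  expect_warning(ann <- parse_via(doc), "non-polygon")
  expect_equal(nrow(ann$regions), 1L)
  expect_equal(attr(ann, "skipped")$reason, "non-polygon shape: circle")

  doc$`x.png-1`$regions[[1]]$shape_attributes <-
    list(name = "polygon", all_points_x = c(1, 2, 3),
         all_points_y = c(1, 3, 1))
  doc$`x.png-1`$regions[[1]]$region_attributes$class <- "bitemark"
  expect_error(parse_via(doc), "bitemark")
})

test_that("a 10x10 axis-aligned square rasterizes to exactly 100 pixels", {
  ann <- one_region_set(c(0, 10, 10, 0), c(0, 0, 10, 10), 20L, 20L)
  lm <- rasterize(ann, "img")
  expect_equal(sum(lm$class_mask > 0), 100L)
  stab_idx <- match("stab", lm$class_order) - 1L
  expect_true(all(lm$class_mask[lm$class_mask > 0] == stab_idx))
  expect_true(all(lm$certainty_map[lm$class_mask > 0] == 1.5))
})

test_that("overlap resolves by file order: the later region wins", {
  mk <- function(order) {
    regs <- tibble::tibble(
      image_id = "img", region_id = 1:2,
      xs = list(c(0, 6, 6, 0), c(4, 10, 10, 4))[order],
      ys = list(c(0, 0, 6, 6), c(0, 0, 6, 6))[order],
      wound_class = c("stab", "cut")[order],
      certainty = c("very_certain", "not_certain")[order]
    )
    ann <- annotation_set(
      tibble::tibble(image_id = "img", filename = "img.png",
                     width = 12L, height = 12L), regs)
    rasterize(ann, "img")
  }
  lm12 <- mk(1:2)
  lm21 <- mk(2:1)
  co <- lm12$class_order
  # overlap column range x in [4, 6): pixel (1, 5) center (4.5, 0.5)
  expect_equal(lm12$class_mask[1, 5], match("cut", co) - 1L)
  expect_equal(lm12$certainty_map[1, 5], 0.5)
  expect_equal(lm21$class_mask[1, 5], match("stab", co) - 1L)
  expect_equal(lm21$certainty_map[1, 5], 1.5)
})

test_that("zero regions give an all-background mask; degenerate and
           self-intersecting polygons are rejected", {
  empty <- annotation_set(
    tibble::tibble(image_id = "e", filename = "e.png",
                   width = 6L, height = 6L),
    tibble::tibble()
  )
  lm <- rasterize(empty, "e")
  expect_true(all(lm$class_mask == 0L))
  expect_true(all(lm$certainty_map == 1.0))

  degen <- one_region_set(c(1, 1, 4), c(1, 1, 3), 6L, 6L)
  expect_error(rasterize(degen, "img"), "degenerate")

  bowtie <- one_region_set(c(0, 4, 0, 4), c(0, 4, 4, 0), 6L, 6L)
  expect_error(rasterize(bowtie, "img"), "self-intersecting")
})

test_that("convex polygons rasterize within the boundary-discretization
           bound of their shoelace area", {
  set.seed(7)
  for (i in 1:50) {
    poly <- random_convex_polygon(40, 40)
    ann <- one_region_set(poly$xs, poly$ys, 40L, 40L)
    lm <- rasterize(ann, "img")
    px <- sum(lm$class_mask > 0)
    bound <- polygon_perimeter(poly$xs, poly$ys) + 4
    expect_lt(abs(px - shoelace(poly$xs, poly$ys)), bound)
  }
})

test_that("certainty map is 1.0 exactly on the background support", {
  set.seed(21)
  cfg <- synth_config(n_images = 3, image_size = c(48, 48), seed = 5)
  for (i in 1:3) {
    gi <- generate_image(cfg, i)
    lm <- gi$ref_maps
    expect_true(all(lm$certainty_map[lm$class_mask == 0L] == 1.0))
    expect_true(all(lm$certainty_map %in% c(0.5, 1.0, 1.5)))
  }
})

test_that("class frequencies count pixels and sum to one", {
  mask <- matrix(0L, 10, 10)
  mask[3, 4] <- 2L
  lm <- label_maps(mask)
  f <- class_frequencies(list(lm))
  expect_equal(unname(f["subcutaneous_hematoma"]), 0.01)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  bg <- label_maps(matrix(0L, 5, 5))
  f0 <- class_frequencies(list(bg))
  expect_equal(sum(f0[-1]), 0)
  expect_true("stab" %in% attr(f0, "absent"))
})

test_that("dataset_stats tabulates counts and area fractions", {
  ann <- fixture_annotations()
  masks <- rasterize_all(ann)
  st <- dataset_stats(ann, masks)
  expect_equal(st$n_regions[st$class == "stab"], 1L)
  expect_equal(st$n_regions[st$class == "laceration"], 1L)
  expect_false(st$active[st$class == "laceration"])
  expect_equal(st$area_fraction[st$class == "laceration"], 0)
  # stab square: 100 px of 20x20 + 16x16 = 656 px total
  expect_equal(st$area_fraction[st$class == "stab"], 100 / 656)
  expect_error(dataset_stats(ann, masks[1]), "match")
})
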