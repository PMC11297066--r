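test_that("certainty levels map to the weights 0.5 / 1.0 / 1.5", {
  expect_identical(certainty_weight("not_certain"), 0.5)
  expect_identical(certainty_weight("quite_certain"), 1.0)
  expect_identical(certainty_weight("very_certain"), 1.5)
  expect_error(certainty_weight("sure"), "unknown")
})

test_that("inverse-frequency class weights follow the 1/(100 f) schemes", {
  expect_equal(class_weights(0.01, "inverse")$w, 1.0)
  expect_equal(class_weights(0.01, "inverse_sqrt")$w, 1.0)
  expect_equal(class_weights(1e-4, "inverse")$w, 100)
  expect_equal(class_weights(1e-4, "inverse_sqrt")$w, 10)
  expect_error(class_weights(-0.1, "inverse"), "negative")
  # zero frequency capped at the one-pixel weight
  expect_warning(
    cw <- class_weights(c(a = 0.5, b = 0), "inverse", n_pixels = 400),
    "zero frequency"
  )
  expect_equal(unname(cw$w["b"]), 1 / (100 / 400))
})

test_that("weighted BCE reproduces closed-form scalar values", {
  cfg <- loss_config("weighted_bce")
  tgt1 <- label_maps(matrix(0L, 1, 1), class_order = "wound")
  p1 <- array(1, dim = c(1, 1, 1))
  expect_equal(weighted_bce(p1, tgt1, 1, cfg), -log(1.001),
               tolerance = 1e-9)
  p05 <- array(0.5, dim = c(1, 1, 1))
  expect_equal(weighted_bce(p05, tgt1, 1, cfg), -log(0.501),
               tolerance = 1e-9)
})

test_that("focal Tversky loss reproduces its closed form and endpoints", {
  cfg <- loss_config("focal_tversky")
  # 10 true pixels, p == 0, s = 1: TI = 1/(1 + 0.7*10)
  tgt <- label_maps(matrix(0L, 2, 5), class_order = "wound")
  p0 <- array(0, dim = c(2, 5, 1))
  ti <- 1 / (1 + 0.7 * 10)
  expect_equal(focal_tversky(p0, tgt, cfg), (1 - ti)^1.3, tolerance = 1e-9)
  # exact one-hot prediction gives zero
  set.seed(5)
  C <- 4
  tgt2 <- fixture_target(6, 6, C)
  ph <- one_hot_mask_for_test(tgt2$class_mask, C)
  expect_equal(focal_tversky(ph, tgt2, cfg), 0)
  expect_true(focal_tversky(fixture_probs(6, 6, C), tgt2, cfg) <= C)
})

test_that("alpha = beta makes the Tversky loss symmetric in FP and FN", {
  cfg <- loss_config("focal_tversky", alpha = 0.5, beta = 0.5)
  # two-class world where swapping prediction and truth swaps FP and FN
  mask <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  tgt <- label_maps(mask, class_order = c("bg", "w"))
  p <- fixture_probs(2, 2, 2)
  swapped_mask <- 1L - mask
  tgt2 <- label_maps(swapped_mask, class_order = c("bg", "w"))
  p2 <- p[, , c(2, 1)]
  expect_equal(focal_tversky(p, tgt, cfg), focal_tversky(p2, tgt2, cfg),
               tolerance = 1e-12)
})

test_that("combined loss interpolates between its components", {
  set.seed(11)
  C <- 3
  p <- fixture_probs(4, 4, C)
  tgt <- fixture_target(4, 4, C)
  w <- c(0.5, 1, 3)
  c1 <- loss_config("combo", lambda = 1)
  c0 <- loss_config("combo", lambda = 0)
  ch <- loss_config("combo", lambda = 0.5)
  bce <- weighted_bce(p, tgt, w, c1)
  ftl <- focal_tversky(p, tgt, c0)
  expect_equal(combined_loss(p, tgt, w, c1), bce)
  expect_equal(combined_loss(p, tgt, w, c0), ftl)
  expect_equal(combined_loss(p, tgt, w, ch), (bce + ftl) / 2)
  expect_error(loss_config("combo", lambda = 1.2), "lambda")
})

test_that("the loss is linear in the certainty weights", {
  # all-wound fixture: every pixel carries its region's m, so scaling the
  # certainty map scales the whole loss
  mask <- matrix(1L, 3, 3)
  p <- fixture_probs(3, 3, 2)
  cfg <- loss_config("weighted_bce")
  t1 <- label_maps(mask, matrix(0.5, 3, 3), class_order = c("bg", "w"))
  t2 <- label_maps(mask, matrix(1.0, 3, 3), class_order = c("bg", "w"))
  l1 <- weighted_bce(p, t1, c(1, 2), cfg)
  l2 <- weighted_bce(p, t2, c(1, 2), cfg)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("vectorised weighted BCE matches the triple-loop reference", {
  set.seed(31)
  for (i in 1:5) {
    C <- sample(2:4, 1)
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    p <- fixture_probs(h, w, C)
    tgt <- fixture_target(h, w, C)
    wv <- stats::runif(C, 0.1, 10)
    for (use_m in c(TRUE, FALSE)) {
      cfg <- loss_config("weighted_bce", use_certainty_weights = use_m)
      expect_equal(weighted_bce(p, tgt, wv, cfg),
                   bce_reference(p, tgt, wv, cfg), tolerance = 1e-10)
    }
  }
})

test_that("increasing p at a true pixel decreases the BCE", {
  set.seed(13)
  C <- 3
  p <- fixture_probs(4, 4, C)
  tgt <- fixture_target(4, 4, C)
  w <- rep(1, C)
  cfg <- loss_config("weighted_bce")
  r <- 2; cc <- 3
  k <- tgt$class_mask[r, cc] + 1L
  l0 <- weighted_bce(p, tgt, w, cfg)
  # move probability mass from a wrong channel onto the true one
  k2 <- if (k == 1L) 2L else 1L
  d <- min(0.05, p[r, cc, k2] - 0.01)
  p2 <- p
  p2[r, cc, k] <- p2[r, cc, k] + d
  p2[r, cc, k2] <- p2[r, cc, k2] - d
  expect_lt(weighted_bce(p2, tgt, w, cfg), l0)
})

test_that("raising w_c only increases that class's false-negative cost", {
  set.seed(17)
  C <- 3
  p <- fixture_probs(5, 5, C)
  tgt <- fixture_target(5, 5, C)
  cfg <- loss_config("weighted_bce")
  w <- c(1, 1, 1)
  w2 <- c(1, 5, 1)
  l <- weighted_bce(p, tgt, w, cfg)
  l2 <- weighted_bce(p, tgt, w2, cfg)
  # class 2 has imperfect predictions, so its weighted term grows
  expect_gt(l2, l)
  # difference equals (w2 - w) times that class's first term only
  N <- 25
  g2 <- tgt$class_mask == 1L
  t1 <- sum(tgt$certainty_map[g2] * log(p[, , 2][g2] + cfg$eps))
  expect_equal(l2 - l, -(1 / C) * (4 / N) * t1, tolerance = 1e-12)
})

test_that("FTL is non-increasing in TP at fixed FP and FN", {
  cfg <- loss_config("focal_tversky")
  # one class, direct soft-count manipulation through p on true pixels
  tgt <- label_maps(matrix(0L, 1, 10), class_order = "w")
  vals <- seq(0, 1, by = 0.25)
  losses <- vapply(vals, function(v) {
    focal_tversky(array(v, dim = c(1, 10, 1)), tgt, cfg)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("malformed prediction tensors are rejected", {
  tgt <- fixture_target(2, 2, 2)
  bad <- array(2, dim = c(2, 2, 2))
  expect_error(weighted_bce(bad, tgt, c(1, 1), loss_config()), "outside")
  uneven <- array(0.2, dim = c(2, 2, 2))
  expect_error(weighted_bce(uneven, tgt, c(1, 1), loss_config()), "sum")
  p <- fixture_probs(3, 3, 2)
  expect_error(weighted_bce(p, tgt, c(1, 1), loss_config()), "shape")
})
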