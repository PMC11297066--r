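test_that("the split geometry reproduces the 182/225/1346 arithmetic", {
  ids <- sprintf("im%04d", 1:1753)
  plan <- make_splits(ids, n_test = 182, k = 7, seed = 5)
  expect_length(plan$test, 182)
  val_sizes <- vapply(plan$folds, function(f) length(f$val), integer(1))
  expect_equal(sum(val_sizes == 225L), 3L)  # three groups of 225
  expect_equal(sum(val_sizes == 224L), 4L)  # four groups of 224
  big <- which(val_sizes == 225)[1]
  expect_length(plan$folds[[big]]$train, 1346)
  # determinism
  plan2 <- make_splits(ids, n_test = 182, k = 7, seed = 5)
  expect_identical(plan, plan2)
  expect_error(make_splits(ids, n_test = 0), "positive")
  expect_error(make_splits(ids, n_test = 10, k = 1), "at least 2")
})

test_that("fold plans partition the ids for many seeds", {
  ids <- paste0("x", 1:60)
  for (seed in 1:100) {
    plan <- make_splits(ids, n_test = 10, k = 7, seed = seed)
    rest <- setdiff(ids, plan$test)
    vals <- unlist(lapply(plan$folds, function(f) f$val))
    expect_setequal(vals, rest)           # validation groups partition
    expect_equal(anyDuplicated(vals), 0L)
    for (f in plan$folds) {
      expect_length(intersect(f$train, f$val), 0)
      expect_setequal(c(f$train, f$val), rest)
      expect_length(intersect(f$train, plan$test), 0)
    }
  }
})

test_that("the learning-rate schedule decays exponentially from 1e-4", {
  tc <- train_config()
  expect_equal(lr_schedule(0, tc), 1e-4)
  expect_equal(lr_schedule(1, tc), 9.8e-5)
  expect_equal(lr_schedule(100, tc), 1e-4 * 0.98^100)
  lrs <- vapply(0:100, lr_schedule, numeric(1), config = tc)
  expect_true(all(diff(lrs) < 0))
})

test_that("train_fold records curves and dual checkpoints", {
  ds <- smoke_dataset()
  ids <- names(ds$images)
  model <- build_model(model_spec("unet_like", width = 4), seed = 1)
  tc <- train_config(epochs = 2, input_size = 48, lr0 = 3e-3, seed = 1)
  lc <- loss_config("weighted_bce")
  fit <- train_fold(model, ds$images, ds$masks, ids[1:12], ids[13:16],
                    lc, tc, fold_seed = 1)
  expect_equal(nrow(fit$curve), 2)
  expect_named(fit$curve, c("epoch", "lr", "train_loss", "val_mpa",
                            "val_miou"))
  expect_true(all(is.finite(fit$curve$train_loss)))
  expect_equal(fit$best$criterion, "best_val_mpa")
  expect_equal(fit$final$criterion, "final_epoch")
  expect_equal(fit$best$val_mpa, max(fit$curve$val_mpa))
  expect_equal(fit$final$epoch, 2)
  # frequencies come from the training split only
  f_train <- class_frequencies(ds$masks[ids[1:12]])
  expect_equal(fit$frequencies, f_train)
  p <- autoplot(fit$curve)
  expect_s3_class(p, "ggplot")
})

test_that("training reruns identically under the same seeds", {
  ds <- smoke_dataset()
  ids <- names(ds$images)
  tc <- train_config(epochs = 2, input_size = 48, lr0 = 3e-3, seed = 1)
  lc <- loss_config("weighted_bce")
  f1 <- train_fold(build_model(model_spec("unet_like", width = 4), seed = 1),
                   ds$images, ds$masks, ids[1:10], ids[11:13], lc, tc,
                   fold_seed = 7)
  f2 <- train_fold(build_model(model_spec("unet_like", width = 4), seed = 1),
                   ds$images, ds$masks, ids[1:10], ids[11:13], lc, tc,
                   fold_seed = 7)
  expect_equal(f1$curve, f2$curve)
  expect_identical(f1$final$weights, f2$final$weights)
})

test_that("cross-validation aggregates fold reports and their mean", {
  ds <- smoke_dataset()
  ids <- names(ds$images)
  plan <- make_splits(ids, n_test = 4, k = 2, seed = 3)
  cv <- run_cross_validation(
    ds$images, ds$masks, plan, model_spec("unet_like", width = 4),
    loss_config("weighted_bce"),
    train_config(epochs = 2, input_size = 48, lr0 = 3e-3, seed = 1)
  )
  td <- tidy(cv)
  expect_equal(nrow(td), 4)  # 2 folds x 2 criteria
  expect_setequal(unique(td$criterion), c("best_val_mpa", "final_epoch"))
  for (crit in c("best_val_mpa", "final_epoch")) {
    sub <- td[td$criterion == crit, ]
    expect_equal(
      cv$summary$mean_pixel_accuracy[cv$summary$criterion == crit],
      mean(sub$mean_pixel_accuracy)
    )
    expect_equal(cv$summary$mean_iou[cv$summary$criterion == crit],
                 mean(sub$mean_iou))
  }
  g <- glance(cv)
  expect_equal(nrow(g), 1)
  expect_s3_class(cv$pooled_confusion$best_val_mpa, "wound_confusion")
})

test_that("augmentation preserves the image/mask/certainty alignment", {
  set.seed(5)
  img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  mask <- matrix(sample(0:2, 144, replace = TRUE), 12, 12)
  cert <- matrix(sample(c(0.5, 1, 1.5), 144, replace = TRUE), 12, 12)
  for (i in 1:10) {
    out <- woundseg:::augment_sample(img, mask, cert)
    expect_equal(dim(out$img), dim(img))
    expect_equal(sort(as.integer(table(out$mask))),
                 sort(as.integer(table(mask))))
    # certainty stays attached to the same pixels as the mask
    expect_equal(out$cert[out$mask == 1L][order(out$cert[out$mask == 1L])],
                 cert[mask == 1L][order(cert[mask == 1L])])
  }
})
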