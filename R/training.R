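#' Test split plus k-fold cross-validation plan
#'
#' Uniformly samples a held-out test set, shuffles the remaining ids and
#' cuts them into `k` near-equal validation groups (sizes differ by at
#' most one); fold i trains on all non-test ids outside group i and
#' validates on group i. With 1753 ids, 182 test images and k = 7 this
#' reproduces the 225-validation / 1346-training fold geometry.
#'
#' @param ids Vector of image ids.
#' @param n_test Number of test ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `test`, `folds` (each a list with
#'   `train` and `val`), `k`, `seed`.
#' @export
make_splits <- function(ids, n_test, k = 7, seed = 1) {
  n <- length(ids)
  if (n_test <= 0) stop("n_test must be positive")
  if (k < 2) stop("k must be at least 2")
  if (n <= n_test + k) stop("too few ids for the requested split")
  set.seed(seed)
  test_idx <- sample.int(n, n_test)
  test <- ids[test_idx]
  rest <- ids[-test_idx]
  rest <- rest[sample.int(length(rest))]
  m <- length(rest)
  base <- m %/% k
  extra <- m %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  folds <- lapply(seq_len(k), function(i) {
    val <- rest[starts[i]:ends[i]]
    list(train = setdiff(rest, val), val = val)
  })
  structure(list(test = test, folds = folds, k = k, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> k =", x$k, ", test =", length(x$test), "ids; folds:",
      paste(vapply(x$folds, function(f) length(f$val), integer(1)),
            collapse = "/"), "validation ids\n")
  invisible(x)
}

#' Exponentially decayed learning rate
#'
#' `lr = lr0 * decay^completed_epochs`; with the defaults
#' (`lr0 = 1e-4`, `decay = 0.98`) the rate falls to about 1.3e-5 after
#' 100 epochs.
#'
#' @param completed_epochs Number of completed epochs E (the rate used
#'   during epoch E + 1).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(completed_epochs, config = train_config()) {
  stopifnot(completed_epochs >= 0)
  config$lr0 * config$decay^completed_epochs
}

#' Training protocol configuration
#'
#' @param batch_size Images per optimisation step.
#' @param epochs Number of epochs (fixed; no early stopping).
#' @param lr0 Initial Adam learning rate.
#' @param decay Per-epoch multiplicative learning-rate decay.
#' @param input_size Square network input resolution (96 desk-scale;
#'   512 for full-scale photographs).
#' @param augment Enable flip/rotation/brightness augmentation.
#' @param seed Integer seed governing shuffling and augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 8, epochs = 100, lr0 = 1e-4,
                         decay = 0.98, input_size = 96, augment = FALSE,
                         seed = 1) {
  stopifnot(batch_size >= 1, epochs >= 1, lr0 > 0, decay > 0,
            input_size >= 8, input_size %% 4 == 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, decay = decay,
                 input_size = as.integer(input_size),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam optimiser over a named list of weight matrices ----

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# flip/rotate/brightness augmentation applied identically to image, mask
# and certainty map (square inputs)
augment_sample <- function(img, mask, cert) {
  if (stats::runif(1) < 0.5) {  # horizontal flip
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    cert <- cert[, rev(seq_len(ncol(cert))), drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {  # vertical flip
    img <- img[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    cert <- cert[rev(seq_len(nrow(cert))), , drop = FALSE]
  }
  rot <- sample.int(4, 1) - 1L  # number of 90-degree rotations
  rot90 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  if (rot > 0) {
    for (i in seq_len(rot)) {
      mask <- rot90(mask)
      cert <- rot90(cert)
      img <- array(c(rot90(img[, , 1]), rot90(img[, , 2]), rot90(img[, , 3])),
                   dim = dim(img))
    }
  }
  img <- clamp01(img * stats::runif(1, 0.9, 1.1))
  list(img = img, mask = mask, cert = cert)
}

prepare_sample <- function(image, maps, input_size) {
  img <- resize_bilinear(image, input_size, input_size)
  mask <- resize_nearest(maps$class_mask, input_size, input_size)
  cert <- resize_nearest(maps$certainty_map, input_size, input_size)
  list(img = img, mask = mask, cert = cert)
}

validation_metrics <- function(family, weights, samples, idx, n_classes,
                               class_order) {
  cm <- empty_confusion(class_order)
  for (i in idx) {
    s <- samples[[i]]
    P <- nn_forward_cpp(family, weights, image_to_mat(net_input(s$img)),
                        nrow(s$mask), ncol(s$mask))
    pred <- matrix(max.col(t(P), ties.method = "first") - 1L,
                   nrow = nrow(s$mask))
    cm <- accumulate_confusion(pred, s$mask, cm)
  }
  list(mpa = mean_pixel_accuracy(cm)$value, miou = mean_iou(cm)$value,
       cm = cm)
}

#' Train one cross-validation fold
#'
#' Runs the full optimisation protocol on one train/validation split:
#' per-epoch shuffling, Adam updates with the exponentially decayed
#' learning rate, per-epoch validation of mean pixel accuracy and mean
#' IoU, and dual checkpointing (the weights with the best validation mean
#' pixel accuracy, and the weights after the final epoch). Class weights
#' for the loss are computed from the label frequencies of the training
#' split only.
#'
#' @param model A `wound_model` (its weights are the starting point).
#' @param images Named list of H x W x 3 arrays.
#' @param masks Named list of `label_maps` aligned with `images`.
#' @param train_ids,val_ids Image ids of the split.
#' @param loss_cfg A [loss_config()].
#' @param tc A [train_config()].
#' @param fold_seed Seed for this fold's shuffling/augmentation stream
#'   (defaults to `tc$seed`).
#' @param verbose Print one line per epoch.
#' @return A `fold_result`: list with `best` and `final` checkpoints
#'   (weights, criterion, epoch, val_mpa, val_miou), the per-epoch `curve`
#'   tibble, the class `frequencies` and `class_weights` used.
#' @export
train_fold <- function(model, images, masks, train_ids, val_ids, loss_cfg,
                       tc = train_config(), fold_seed = tc$seed,
                       verbose = FALSE) {
  stopifnot(inherits(model, "wound_model"), length(train_ids) > 0,
            length(val_ids) > 0)
  class_order <- masks[[1]]$class_order
  n_classes <- model$spec$n_classes
  stopifnot(length(class_order) == n_classes)

  samples <- lapply(names(images), function(id) {
    prepare_sample(images[[id]], masks[[id]], tc$input_size)
  })
  names(samples) <- names(images)

  # class weights from the training split only
  f <- class_frequencies(masks[names(masks) %in% train_ids])
  n_px <- length(train_ids) * tc$input_size^2
  cw <- suppressWarnings(
    class_weights(f, scheme = loss_cfg$weight_scheme, n_pixels = n_px)
  )
  cfg_cpp <- loss_config_cpp(loss_cfg)

  weights <- model$weights
  opt <- adam_init(weights)
  curve <- vector("list", tc$epochs)
  best <- NULL
  set.seed(fold_seed)
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(epoch - 1L, tc)
    order_ids <- train_ids[sample.int(length(train_ids))]
    losses <- c()
    for (start in seq(1, length(order_ids), by = tc$batch_size)) {
      batch <- order_ids[start:min(start + tc$batch_size - 1L,
                                   length(order_ids))]
      xs <- list(); gs <- list(); ms <- list()
      for (id in batch) {
        s <- samples[[id]]
        if (tc$augment) s <- augment_sample(s$img, s$mask, s$cert)
        xs[[length(xs) + 1L]] <- image_to_mat(net_input(s$img))
        gs[[length(gs) + 1L]] <- as.integer(s$mask)
        ms[[length(ms) + 1L]] <- as.numeric(s$cert)
      }
      res <- nn_train_batch_cpp(model$spec$family, weights, xs, gs, ms,
                                cw$w, cfg_cpp, tc$input_size, tc$input_size)
      if (!is.finite(res$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch starting ",
             start, ", lr ", lr)
      }
      losses <- c(losses, res$loss)
      upd <- adam_step(weights, res$grads, opt, lr)
      weights <- upd$weights
      opt <- upd$state
    }
    vm <- validation_metrics(model$spec$family, weights, samples,
                             val_ids, n_classes, class_order)
    curve[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_mpa = vm$mpa, val_miou = vm$miou
    )
    if (is.null(best) || vm$mpa > best$val_mpa) {
      best <- list(weights = weights, criterion = "best_val_mpa",
                   epoch = epoch, val_mpa = vm$mpa, val_miou = vm$miou)
    }
    if (verbose) {
      message(sprintf("epoch %3d lr %.3g loss %.4f val_mpa %.4f val_miou %.4f",
                      epoch, lr, mean(losses), vm$mpa, vm$miou))
    }
  }
  curve <- dplyr::bind_rows(curve)
  class(curve) <- c("epoch_curve", class(curve))
  final <- list(weights = weights, criterion = "final_epoch",
                epoch = tc$epochs,
                val_mpa = curve$val_mpa[tc$epochs],
                val_miou = curve$val_miou[tc$epochs])
  structure(list(best = best, final = final, curve = curve,
                 frequencies = f, class_weights = cw),
            class = "fold_result")
}

#' Epoch-curve plot (validation metrics per epoch)
#'
#' @param object An `epoch_curve` tibble from [train_fold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epoch_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "epoch", "val_mpa", "val_miou"),
    cols = c("val_mpa", "val_miou"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "validation metric", colour = NULL) +
    ggplot2::theme_minimal()
}

evaluate_checkpoint <- function(family, checkpoint, samples, ids,
                                class_order) {
  vm <- validation_metrics(family, checkpoint$weights, samples, ids,
                           length(class_order), class_order)
  metrics_report(vm$cm)
}

#' Run k-fold cross-validation
#'
#' Trains one model per fold of the plan, evaluates both checkpoints
#' (best-validation-accuracy and final-epoch) of every fold on the shared
#' held-out test set, and averages the metrics across folds.
#'
#' @param images Named list of H x W x 3 arrays.
#' @param masks Named list of `label_maps`.
#' @param plan A [make_splits()] plan.
#' @param spec A [model_spec()].
#' @param loss_cfg A [loss_config()].
#' @param tc A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `wound_cv` object: per-fold results, per-fold test
#'   `metrics_report`s for both checkpoint criteria, the fold-averaged
#'   summary and pooled test confusion matrices.
#' @export
run_cross_validation <- function(images, masks, plan, spec, loss_cfg,
                                 tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(plan, "fold_plan"))
  class_order <- masks[[1]]$class_order
  test_samples <- lapply(plan$test, function(id) {
    prepare_sample(images[[id]], masks[[id]], tc$input_size)
  })
  names(test_samples) <- plan$test

  folds <- list()
  reports <- list()
  for (i in seq_along(plan$folds)) {
    fd <- plan$folds[[i]]
    model <- build_model(spec, seed = tc$seed + i)
    fit <- train_fold(model, images, masks, fd$train, fd$val, loss_cfg, tc,
                      fold_seed = tc$seed + 1000L + i, verbose = verbose)
    folds[[i]] <- fit
    for (crit in c("best", "final")) {
      rep <- evaluate_checkpoint(spec$family, fit[[crit]], test_samples,
                                 plan$test, class_order)
      reports[[length(reports) + 1L]] <- tibble::tibble(
        fold = i,
        criterion = fit[[crit]]$criterion,
        mean_pixel_accuracy = rep$mean_pixel_accuracy,
        mean_iou = rep$mean_iou,
        report = list(rep)
      )
    }
  }
  per_fold <- dplyr::bind_rows(reports)
  summary <- per_fold |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(
      mean_pixel_accuracy = mean(.data$mean_pixel_accuracy),
      mean_iou = mean(.data$mean_iou),
      n_folds = dplyr::n(), .groups = "drop"
    )
  pooled <- lapply(split(per_fold, per_fold$criterion), function(df) {
    cms <- lapply(df$report, function(r) unclass(r$confusion))
    cm <- Reduce(`+`, cms)
    structure(cm, class = c("wound_confusion", "matrix", "array"))
  })
  structure(list(folds = folds, per_fold = per_fold, summary = summary,
                 pooled_confusion = pooled, plan = plan, spec = spec,
                 loss_config = loss_cfg, train_config = tc),
            class = "wound_cv")
}

#' @export
print.wound_cv <- function(x, ...) {
  cat("<wound_cv>", length(x$folds), "fold(s), test set of",
      length(x$plan$test), "images\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wound_cv <- function(x, ...) {
  dplyr::select(x$per_fold, "fold", "criterion",
                "mean_pixel_accuracy", "mean_iou")
}

#' @export
glance.wound_cv <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary,
    names_from = "criterion",
    values_from = c("mean_pixel_accuracy", "mean_iou"),
    id_cols = NULL, unused_fn = list(n_folds = max)
  )
}
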