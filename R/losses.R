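#' Inverse-frequency class weights
#'
#' Class weights counteracting the extreme class imbalance of wound
#' photographs: `w_c = 1 / (constant * f_c)` (scheme `"inverse"`) or its
#' square root (scheme `"inverse_sqrt"`). With `constant = 100` and the
#' dominant wound class covering about 1% of pixels, the dominant class
#' gets weight ~1 and every rarer class a larger weight. A zero frequency
#' (a class absent from a training split) is capped at the weight a single
#' pixel would produce, i.e. the formula evaluated at
#' `f = 1 / n_pixels`, and flagged with a warning.
#'
#' @param f Named (or plain) non-negative frequency vector, typically from
#'   [class_frequencies()].
#' @param scheme `"inverse"` or `"inverse_sqrt"`.
#' @param constant Scale constant in the denominator; default 100.
#' @param n_pixels Total number of pixels behind `f`, used only to cap
#'   zero-frequency classes (defaults to `1e8`, i.e. an effectively large
#'   dataset, if any `f` is zero and no size is given).
#' @return A `class_weight_vector` object: list with `w`, `f`, `scheme`,
#'   `constant`.
#' @export
#' @examples
#' class_weights(c(background = 0.98, subcutaneous_hematoma = 0.01), "inverse")
class_weights <- function(f, scheme = c("inverse", "inverse_sqrt"),
                          constant = 100, n_pixels = NULL) {
  scheme <- match.arg(scheme)
  if (any(f < 0)) stop("negative class frequency")
  fx <- f
  if (any(f == 0)) {
    if (is.null(n_pixels)) n_pixels <- 1e8
    floor_f <- 1 / n_pixels
    warning("class(es) with zero frequency: ",
            paste(names(f)[f == 0], collapse = ", "),
            "; weight capped at f = 1/", format(n_pixels))
    fx[fx == 0] <- floor_f
  }
  w <- 1 / (constant * fx)
  if (scheme == "inverse_sqrt") w <- sqrt(w)
  structure(list(w = w, f = f, scheme = scheme, constant = constant),
            class = "class_weight_vector")
}

#' @export
print.class_weight_vector <- function(x, ...) {
  cat("<class_weight_vector> scheme =", x$scheme,
      ", constant =", x$constant, "\n")
  print(signif(x$w, 4))
  invisible(x)
}

#' @export
tidy.class_weight_vector <- function(x, ...) {
  tibble::tibble(
    class = if (is.null(names(x$w))) as.character(seq_along(x$w)) else names(x$w),
    frequency = unname(x$f),
    weight = unname(x$w)
  )
}

#' Loss configuration
#'
#' Bundles every tunable of the segmentation losses: the loss family, the
#' log-smoothing `eps` of the weighted cross-entropy, the Tversky
#' parameters (`alpha` penalises false negatives, `beta` false positives,
#' `gamma` is the focal exponent), the BCE/FTL mixing coefficient `lambda`
#' of the combined loss, whether per-pixel annotation-certainty weights are
#' applied, and the class-weight scheme.
#'
#' @param family `"weighted_bce"`, `"focal_tversky"` or `"combo"`.
#' @param eps Smoothing added inside the logs to avoid extreme gradients.
#' @param alpha,beta,gamma Tversky/focal parameters.
#' @param lambda Mixing coefficient of the combined loss
#'   (`lambda * BCE + (1 - lambda) * FTL`), in \[0, 1\].
#' @param smooth Additive smoothing of the Tversky index.
#' @param use_certainty_weights Apply the per-pixel certainty map.
#' @param weight_scheme Class-weight scheme, `"inverse"` or
#'   `"inverse_sqrt"`.
#' @param prefactor_channels Whether the 1/C prefactor of the weighted BCE
#'   counts all softmax channels (`"all"`, default) or the wound channels
#'   only (`"wound_only"`); a constant scale that does not change the
#'   optimisation direction.
#' @return A `loss_config` object (a list).
#' @export
loss_config <- function(family = c("weighted_bce", "focal_tversky", "combo"),
                        eps = 1e-3, alpha = 0.7, beta = 0.3, gamma = 1.3,
                        lambda = 0.5, smooth = 1.0,
                        use_certainty_weights = TRUE,
                        weight_scheme = c("inverse", "inverse_sqrt"),
                        prefactor_channels = c("all", "wound_only")) {
  family <- match.arg(family)
  weight_scheme <- match.arg(weight_scheme)
  prefactor_channels <- match.arg(prefactor_channels)
  stopifnot(eps > 0, alpha > 0, beta > 0, gamma > 0, smooth > 0)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  structure(
    list(family = family, eps = eps, alpha = alpha, beta = beta,
         gamma = gamma, lambda = lambda, smooth = smooth,
         use_certainty_weights = isTRUE(use_certainty_weights),
         weight_scheme = weight_scheme,
         prefactor_channels = prefactor_channels),
    class = "loss_config"
  )
}

loss_config_cpp <- function(config) {
  list(
    family_code = match(config$family,
                        c("weighted_bce", "focal_tversky", "combo")) - 1L,
    eps = config$eps, alpha = config$alpha, beta = config$beta,
    gamma = config$gamma, lambda = config$lambda, smooth = config$smooth,
    use_certainty_weights = config$use_certainty_weights,
    prefactor_all = config$prefactor_channels == "all"
  )
}

check_prediction_tensor <- function(p, tol = 1e-5) {
  if (length(dim(p)) != 3) stop("prediction tensor must be H x W x C")
  if (min(p) < -tol || max(p) > 1 + tol) {
    stop("prediction probabilities outside [0, 1]")
  }
  # single-channel tensors are degenerate fixtures used for formula
  # verification; the softmax sum constraint only binds for C >= 2
  if (dim(p)[3] >= 2) {
    sums <- apply(p, c(1, 2), sum)
    if (max(abs(sums - 1)) > tol) {
      stop("prediction channels do not sum to 1 per pixel")
    }
  }
  invisible(TRUE)
}

one_hot_mask <- function(class_mask, C) {
  g <- array(0, dim = c(nrow(class_mask), ncol(class_mask), C))
  for (c in seq_len(C)) {
    g[, , c] <- as.numeric(class_mask == (c - 1L))
  }
  g
}

#' Certainty- and class-weighted binary cross-entropy loss
#'
#' The pixelwise weighted BCE of a softmax prediction against a one-hot
#' ground truth:
#' \deqn{-\frac{1}{C}\sum_c \left[\frac{w_c}{N}\sum_i m_i g_{ic}
#'   \log(p_{ic}+\epsilon) + \frac{1}{N}\sum_i m_i (1-g_{ic})
#'   \log(1-p_{ic}+\epsilon)\right]}
#' Only the first (false-negative) term carries the class weight `w_c`, so
#' missing wound pixels costs more than hallucinating them; the per-pixel
#' multiplier `m_i` encodes annotation certainty (1.0 when certainty
#' weighting is off). `N` is the pixel count, `C` the number of channels.
#'
#' @param p Prediction array H x W x C of post-softmax probabilities.
#' @param target A `label_maps` object (class mask + certainty map).
#' @param weights A `class_weight_vector`, or a bare numeric vector of
#'   per-class weights of length C.
#' @param config A [loss_config()].
#' @return Scalar loss value.
#' @export
weighted_bce <- function(p, target, weights, config = loss_config()) {
  check_prediction_tensor(p)
  C <- dim(p)[3]
  if (!identical(dim(target$class_mask), dim(p)[1:2])) {
    stop("prediction and target shapes disagree")
  }
  w <- if (inherits(weights, "class_weight_vector")) weights$w else weights
  if (length(w) != C) stop("need one class weight per channel")
  N <- prod(dim(p)[1:2])
  g <- one_hot_mask(target$class_mask, C)
  m <- if (config$use_certainty_weights) target$certainty_map else
    matrix(1, nrow(target$class_mask), ncol(target$class_mask))
  pref <- 1 / if (config$prefactor_channels == "all") C else max(1, C - 1)
  total <- 0
  for (cc in seq_len(C)) {
    t1 <- sum(m * g[, , cc] * log(p[, , cc] + config$eps))
    t2 <- sum(m * (1 - g[, , cc]) * log(1 - p[, , cc] + config$eps))
    total <- total + w[cc] / N * t1 + t2 / N
  }
  -pref * total
}

#' Focal Tversky loss
#'
#' Per-class soft Tversky index
#' `TI_c = (TP_c + s) / (TP_c + alpha*FN_c + beta*FP_c + s)` with soft
#' counts `TP_c = sum_i p_ic g_ic`, `FN_c = sum_i (1-p_ic) g_ic`,
#' `FP_c = sum_i p_ic (1-g_ic)`, focused and summed over channels:
#' `FTL = sum_c (1 - TI_c)^gamma`. Lies in \[0, C\] and is 0 iff the
#' prediction equals the one-hot truth.
#'
#' @inheritParams weighted_bce
#' @return Scalar loss value.
#' @export
focal_tversky <- function(p, target, config = loss_config()) {
  check_prediction_tensor(p)
  C <- dim(p)[3]
  if (!identical(dim(target$class_mask), dim(p)[1:2])) {
    stop("prediction and target shapes disagree")
  }
  g <- one_hot_mask(target$class_mask, C)
  total <- 0
  for (cc in seq_len(C)) {
    tp <- sum(p[, , cc] * g[, , cc])
    fn <- sum((1 - p[, , cc]) * g[, , cc])
    fp <- sum(p[, , cc] * (1 - g[, , cc]))
    ti <- (tp + config$smooth) /
      (tp + config$alpha * fn + config$beta * fp + config$smooth)
    total <- total + (1 - ti)^config$gamma
  }
  total
}

#' Combined BCE + focal Tversky loss
#'
#' `lambda * weighted_bce + (1 - lambda) * focal_tversky`.
#'
#' @inheritParams weighted_bce
#' @return Scalar loss value.
#' @export
combined_loss <- function(p, target, weights, config) {
  if (config$lambda < 0 || config$lambda > 1) stop("lambda must be in [0, 1]")
  config$lambda * weighted_bce(p, target, weights, config) +
    (1 - config$lambda) * focal_tversky(p, target, config)
}

#' Evaluate a loss configuration
#'
#' Dispatches on `config$family`.
#'
#' @inheritParams weighted_bce
#' @return Scalar loss value.
#' @export
segmentation_loss <- function(p, target, weights, config = loss_config()) {
  switch(config$family,
    weighted_bce = weighted_bce(p, target, weights, config),
    focal_tversky = focal_tversky(p, target, config),
    combo = combined_loss(p, target, weights, config)
  )
}
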