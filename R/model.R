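#' Specify a compact segmentation network
#'
#' Desk-scale reference encoder-decoder models. `"unet_like"` is a
#' three-level encoder-decoder with skip connections; `"fpn_like"` is a
#' three-level bottom-up pathway with 1x1 lateral connections and a
#' top-down merge. Both end in a C-channel 1x1 head with a per-pixel
#' softmax, so the output at every pixel is a probability distribution
#' over background plus the seven wound classes. The architectures are
#' deliberately tiny (well under 500k parameters at the default width);
#' larger pretrained encoders can be substituted by supplying a different
#' forward/backward implementation under the same weight-list contract.
#'
#' @param family `"unet_like"` or `"fpn_like"`.
#' @param width Base channel width; deeper levels use 2x and 4x this.
#' @param n_classes Number of output channels (background + wound classes).
#' @param input_channels Number of input image channels.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("unet_like", "fpn_like"), width = 16,
                       n_classes = 8, input_channels = 3) {
  family <- match.arg(family)
  stopifnot(width >= 1, n_classes >= 2)
  structure(list(family = family, width = as.integer(width),
                 n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels)),
            class = "model_spec")
}

# weight shapes per family; conv kernels are stored (C_out x 9*C_in),
# 1x1 layers (C_out x C_in), biases (C_out x 1)
model_shapes <- function(spec) {
  w <- spec$width
  ci <- spec$input_channels
  k <- spec$n_classes
  if (spec$family == "unet_like") {
    list(
      enc1_W = c(w, 9 * ci), enc1_b = c(w, 1),
      enc2_W = c(2 * w, 9 * w), enc2_b = c(2 * w, 1),
      bott_W = c(4 * w, 9 * 2 * w), bott_b = c(4 * w, 1),
      dec2_W = c(2 * w, 9 * 6 * w), dec2_b = c(2 * w, 1),
      dec1_W = c(w, 9 * 3 * w), dec1_b = c(w, 1),
      head_W = c(k, w), head_b = c(k, 1)
    )
  } else {
    list(
      c1_W = c(w, 9 * ci), c1_b = c(w, 1),
      c2_W = c(2 * w, 9 * w), c2_b = c(2 * w, 1),
      c3_W = c(4 * w, 9 * 2 * w), c3_b = c(4 * w, 1),
      l3_W = c(w, 4 * w), l3_b = c(w, 1),
      l2_W = c(w, 2 * w), l2_b = c(w, 1),
      l1_W = c(w, w), l1_b = c(w, 1),
      smooth_W = c(w, 9 * w), smooth_b = c(w, 1),
      head_W = c(k, w), head_b = c(k, 1)
    )
  }
}

#' Build a segmentation model
#'
#' Instantiates the network of a [model_spec()] with He-initialised
#' weights (seeded, so identical seeds give identical models).
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for the weight initialisation.
#' @return A `wound_model` object: the spec plus a named list of weight
#'   matrices.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  shapes <- model_shapes(spec)
  set.seed(seed)
  weights <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (grepl("_b$", nm)) {
      matrix(0, nrow = sh[1], ncol = sh[2])
    } else {
      sd <- sqrt(2 / sh[2])
      matrix(stats::rnorm(prod(sh), sd = sd), nrow = sh[1], ncol = sh[2])
    }
  })
  names(weights) <- names(shapes)
  structure(list(spec = spec, weights = weights), class = "wound_model")
}

#' @export
print.wound_model <- function(x, ...) {
  cat("<wound_model> family =", x$spec$family,
      ", width =", x$spec$width,
      ", channels out =", x$spec$n_classes,
      ", parameters =", n_parameters(x), "\n")
  invisible(x)
}

#' @rdname build_model
#' @param model A `wound_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

#' Forward pass: per-pixel class probabilities
#'
#' @param model A `wound_model`.
#' @param image H x W x channels array in \[0, 1\]. H and W must be
#'   multiples of 4 (two pooling levels).
#' @return H x W x C array of softmax probabilities.
#' @export
predict_probs <- function(model, image) {
  stopifnot(inherits(model, "wound_model"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$spec$input_channels) {
    stop("expected an H x W x ", model$spec$input_channels, " image array")
  }
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0) {
    stop("image height and width must be multiples of 4")
  }
  P <- nn_forward_cpp(model$spec$family, model$weights,
                      image_to_mat(net_input(image)), d[1], d[2])
  probs_to_array(P, d[1], d[2])
}

#' Predict a class mask for a photograph
#'
#' Resizes the image to `input_size` x `input_size` (bilinear; the aspect
#' ratio is stretched to square), runs the network, and assigns each pixel
#' to the channel with the highest probability. Ties break toward the
#' lowest class index (background first).
#'
#' @param model A `wound_model`.
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param input_size Side length of the square network input.
#' @return Integer `input_size` x `input_size` matrix of class indices
#'   (0 = background).
#' @export
predict_mask <- function(model, image, input_size = 96) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("expected an RGB (H x W x 3) image")
  img <- resize_bilinear(image, input_size, input_size)
  P <- nn_forward_cpp(model$spec$family, model$weights,
                      image_to_mat(net_input(img)), input_size, input_size)
  cls <- max.col(t(P), ties.method = "first") - 1L
  matrix(as.integer(cls), nrow = input_size, ncol = input_size)
}
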