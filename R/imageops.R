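# Small raster utilities shared by the generator, the trainer and
# prediction. All operate on plain matrices / H x W x C arrays in [0, 1].

# bilinear resampling; used for photographs
resize_bilinear <- function(img, out_h, out_w) {
  dims <- dim(img)
  h <- dims[1]; w <- dims[2]
  if (h == out_h && w == out_w) return(img)
  # map output pixel centers into input coordinates
  ry <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  ry <- pmin(pmax(ry, 0), h - 1)
  rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- pmin(floor(ry), h - 2) + 1L
  x0 <- pmin(floor(rx), w - 2) + 1L
  fy <- ry - (y0 - 1L)
  fx <- rx - (x0 - 1L)
  interp_plane <- function(m) {
    a <- m[y0, x0, drop = FALSE]
    b <- m[y0, x0 + 1L, drop = FALSE]
    cc <- m[y0 + 1L, x0, drop = FALSE]
    d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
    wa <- outer(1 - fy, 1 - fx)
    wb <- outer(1 - fy, fx)
    wc <- outer(fy, 1 - fx)
    wd <- outer(fy, fx)
    a * wa + b * wb + cc * wc + d * wd
  }
  if (length(dims) == 2) return(interp_plane(img))
  out <- array(0, dim = c(out_h, out_w, dims[3]))
  for (k in seq_len(dims[3])) out[, , k] <- interp_plane(img[, , k])
  out
}

# nearest-neighbour resampling; used for class masks and certainty maps
resize_nearest <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1L), h)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1L), w)
  m[ri, ci, drop = FALSE]
}

# row/column Gaussian smoothing operator (rows normalised)
blur_operator <- function(n, sigma) {
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  k <- exp(-d^2 / (2 * sigma^2))
  k[d > ceiling(3 * sigma)] <- 0
  sweep(k, 1, rowSums(k), "/")
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  br <- blur_operator(nrow(m), sigma)
  bc <- blur_operator(ncol(m), sigma)
  br %*% m %*% t(bc)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# H x W x 3 array -> 3 x (H*W) activation matrix (pixel column j = r + c*H)
image_to_mat <- function(img) {
  t(matrix(img, ncol = dim(img)[3]))
}

# network input normalisation: photographs arrive in [0, 1]; the reference
# nets see them centered to [-1, 1], which conditions from-scratch training
net_input <- function(img) (img - 0.5) * 2

# K x (H*W) probability matrix -> H x W x K array
probs_to_array <- function(P, h, w) {
  array(t(P), dim = c(h, w, nrow(P)))
}
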