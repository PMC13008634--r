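## Bicubic resampling (Keys kernel, a = -0.5), separable, with kernel
## widening on downscale so decimation is antialiased. This is the sole
## degradation model used to build LR inputs and blurred reference copies.

cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

## dense n_out x n_in interpolation matrix for one axis; rows sum to 1
resize_matrix <- function(n_in, n_out) {
  key <- paste("rz", n_in, n_out, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  scale <- n_in / n_out
  kscale <- max(1, scale)            # widen kernel when decimating
  support <- 2 * kscale
  centers <- (seq_len(n_out) - 0.5) * scale + 0.5
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- max(1L, floor(centers[i] - support))
    hi <- min(n_in, ceiling(centers[i] + support))
    j <- lo:hi
    w <- cubic_kernel((centers[i] - j) / kscale)
    sw <- sum(w)
    if (sw == 0) { w <- rep(1, length(j)); sw <- length(j) }
    M[i, j] <- w / sw
  }
  .geom_cache[[key]] <- M
  M
}

#' Bicubic resize of a grayscale image
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5). On
#' downscale the kernel is widened by the scale factor so the result is
#' antialiased, matching the conventional degradation used to simulate
#' low-resolution MRI acquisitions. Output intensities are clipped to
#' \[0, 1\].
#'
#' @param img numeric matrix, intensities in \[0, 1\].
#' @param out_height,out_width target dimensions (>= 1).
#' @param clip clip the result to \[0, 1\] (default TRUE).
#' @return numeric matrix `out_height` x `out_width`.
#' @export
#' @examples
#' img <- matrix(0.5, 16, 16)
#' range(bicubic_resize(img, 8, 8))  # constants survive resampling
bicubic_resize <- function(img, out_height, out_width, clip = TRUE) {
  stopifnot(is.matrix(img), out_height >= 1, out_width >= 1)
  if (out_height == nrow(img) && out_width == ncol(img)) return(img)
  out <- resize_matrix(nrow(img), out_height) %*% img %*%
    t(resize_matrix(ncol(img), out_width))
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Center-crop an image to dimensions divisible by a scale factor
#'
#' Resolves the mismatch between slice sizes (e.g. 256) and scale factors
#' that do not divide them (e.g. x3) before constructing LR/HR pairs.
#'
#' @param img numeric matrix.
#' @param scale integer scale factor (2, 3 or 4).
#' @return the largest centered sub-image whose sides are multiples of
#'   `scale`.
#' @export
crop_to_multiple <- function(img, scale) {
  stopifnot(is.matrix(img), scale %in% c(2L, 3L, 4L))
  H <- nrow(img); W <- ncol(img)
  Hc <- (H %/% scale) * scale
  Wc <- (W %/% scale) * scale
  if (Hc < 8L || Wc < 8L) stop("crop_to_multiple: result smaller than 8x8")
  r0 <- (H - Hc) %/% 2L
  c0 <- (W - Wc) %/% 2L
  img[(r0 + 1L):(r0 + Hc), (c0 + 1L):(c0 + Wc), drop = FALSE]
}

#' Remove a border of given width from each side
#'
#' Boundary pixels are cropped before evaluation to avoid border effects of
#' convolutional processing.
#'
#' @param img numeric matrix.
#' @param pixels border width per side; `2*pixels` must be smaller than the
#'   smallest image dimension.
#' @return cropped matrix.
#' @export
crop_border <- function(img, pixels) {
  stopifnot(is.matrix(img), pixels >= 0)
  if (pixels == 0) return(img)
  if (2 * pixels >= min(dim(img))) stop("crop_border: border exceeds image")
  img[(pixels + 1L):(nrow(img) - pixels),
      (pixels + 1L):(ncol(img) - pixels), drop = FALSE]
}
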