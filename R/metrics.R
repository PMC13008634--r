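## Quantitative evaluation: PSNR = 10*log10(MAX^2 / MSE) and SSIM, both on
## border-cropped images. SSIM comes in two modes: "global" applies the
## two-constant formula to whole-image moments, "local" (default reported
## metric) evaluates it per Gaussian window (11x11, sigma 1.5, valid
## support) and averages.

#' SSIM parameters
#'
#' @param k1,k2 stabilizer fractions; `C1 = (k1*MAX)^2`, `C2 = (k2*MAX)^2`.
#' @param data_range maximum possible intensity MAX (1 after
#'   normalization).
#' @param window_size odd side of the local Gaussian window.
#' @param window_sigma Gaussian sigma of the window.
#' @param mode `"local"` (windowed, averaged) or `"global"` (whole-image
#'   moments).
#' @return validated `ssim_params` list.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, data_range = 1,
                        window_size = 11L, window_sigma = 1.5,
                        mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(k1 > 0, k2 > 0, data_range > 0, window_size %% 2L == 1L)
  structure(list(k1 = k1, k2 = k2, data_range = data_range,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma, mode = mode),
            class = "ssim_params")
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10*log10(MAX^2 / MSE)` after removing `border` pixels per side.
#' Identical images yield `Inf`.
#'
#' @param x,y equal-size numeric matrices.
#' @param max_val maximum possible intensity (1 after normalization).
#' @param border pixels cropped from each side before evaluation.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(x, y, max_val = 1, border = 0L) {
  if (!all(dim(x) == dim(y))) stop("psnr: dimension mismatch")
  x <- crop_border(x, border)
  y <- crop_border(y, border)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

## valid-support Gaussian filtering matrix for one axis
gauss_valid_matrix <- function(n, size, sigma) {
  key <- paste("gv", n, size, sigma, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (size - 1L) %/% 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  n_out <- n - size + 1L
  M <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) M[i, i:(i + size - 1L)] <- g
  .geom_cache[[key]] <- M
  M
}

#' Structural similarity index
#'
#' Global mode evaluates the two-constant formula
#' `(2 ux uy + C1)(2 sxy + C2) / ((ux^2 + uy^2 + C1)(sx^2 + sy^2 + C2))`
#' on whole-image moments; local mode evaluates it per Gaussian window and
#' averages. Symmetric in its two arguments.
#'
#' @param x,y equal-size numeric matrices.
#' @param params an [ssim_params()].
#' @param border pixels cropped from each side first.
#' @return SSIM score.
#' @export
ssim <- function(x, y, params = ssim_params(), border = 0L) {
  if (!all(dim(x) == dim(y))) stop("ssim: dimension mismatch")
  if (!inherits(params, "ssim_params")) params <- do.call(ssim_params, params)
  x <- crop_border(x, border)
  y <- crop_border(y, border)
  C1 <- (params$k1 * params$data_range)^2
  C2 <- (params$k2 * params$data_range)^2
  if (params$mode == "global") {
    ux <- mean(x); uy <- mean(y)
    vx <- mean((x - ux)^2); vy <- mean((y - uy)^2)
    cxy <- mean((x - ux) * (y - uy))
    return(((2 * ux * uy + C1) * (2 * cxy + C2)) /
             ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }
  w <- params$window_size
  if (nrow(x) < w || ncol(x) < w)
    stop("ssim: image smaller than the local window")
  Gr <- gauss_valid_matrix(nrow(x), w, params$window_sigma)
  Gc <- t(gauss_valid_matrix(ncol(x), w, params$window_sigma))
  mu_x <- Gr %*% x %*% Gc
  mu_y <- Gr %*% y %*% Gc
  sxx <- Gr %*% (x * x) %*% Gc - mu_x^2
  syy <- Gr %*% (y * y) %*% Gc - mu_y^2
  sxy <- Gr %*% (x * y) %*% Gc - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Evaluate paired reconstructions against references
#'
#' Per-sample PSNR/SSIM with border crop = `scale` pixels per side (the
#' convention for convolutional SR models), plus a summary row of means.
#' Infinite PSNR values (exact reconstructions) are excluded from the mean
#' with a warning.
#'
#' @param model_outputs list (or named list) of reconstructed HR matrices.
#' @param references list of ground-truth HR matrices, same length/order.
#' @param scale upscaling factor; sets the default border.
#' @param params an [ssim_params()].
#' @param border border crop per side (default `scale`).
#' @param csv_path optional path to also write the table as CSV.
#' @return data.frame with columns `sample_id`, `psnr_db`, `ssim`, `scale`,
#'   `border`; the last row (`sample_id = "mean"`) holds the means.
#' @export
evaluate_dataset <- function(model_outputs, references, scale,
                             params = ssim_params(), border = scale,
                             csv_path = NULL) {
  n <- length(model_outputs)
  if (n == 0L) stop("evaluate_dataset: empty sample set")
  stopifnot(length(references) == n)
  ids <- names(model_outputs) %||% sprintf("s%04d", seq_len(n))
  ps <- vapply(seq_len(n), function(i)
    psnr(model_outputs[[i]], references[[i]], params$data_range, border),
    numeric(1))
  ss <- vapply(seq_len(n), function(i)
    ssim(model_outputs[[i]], references[[i]], params, border), numeric(1))
  fin <- is.finite(ps)
  if (!all(fin))
    warning("evaluate_dataset: ", sum(!fin),
            " sample(s) with infinite PSNR excluded from the mean")
  tab <- data.frame(sample_id = ids, psnr_db = ps, ssim = ss,
                    scale = scale, border = border,
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(sample_id = "mean",
                               psnr_db = mean(ps[fin]), ssim = mean(ss),
                               scale = scale, border = border,
                               stringsAsFactors = FALSE))
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  tab
}
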