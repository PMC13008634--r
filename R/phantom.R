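## Synthetic brain-like slice generator. Emulates the gross geometry of an
## axial T1-ish slice: nested smooth tissue regions (background, skull ring,
## CSF gap, gray-matter ribbon, white-matter core) bounded by a randomly
## deformed ellipse, with ridge-like sulcal texture inside the cortical
## ribbon and optional Gaussian or Rician noise.

## evaluate an expression under a fixed seed without disturbing the caller's
## RNG stream
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Parameters of the synthetic brain phantom
#'
#' @param size output side length in pixels (>= 32).
#' @param tissue_levels named numeric vector of intensities in \[0, 1\] for
#'   `background`, `skull`, `csf`, `gray`, `white`; must be pairwise
#'   distinct.
#' @param deformation_amplitude boundary deformation as a fraction of the
#'   brain radius.
#' @param texture_frequency sulcal ridge frequency, cycles around the
#'   cortical ribbon.
#' @param noise_sigma standard deviation of additive noise (>= 0).
#' @param noise_type `"gaussian"` (default) or `"rician"`.
#' @param seed RNG seed; the phantom is a pure function of these parameters.
#' @return a `phantom_params` list, validated.
#' @export
phantom_params <- function(size = 256L,
                           tissue_levels = c(background = 0.02, skull = 0.95,
                                             csf = 0.35, gray = 0.55,
                                             white = 0.75),
                           deformation_amplitude = 0.05,
                           texture_frequency = 24,
                           noise_sigma = 0,
                           noise_type = c("gaussian", "rician"),
                           seed = 0L) {
  noise_type <- match.arg(noise_type)
  if (size < 32L) stop("phantom_params: size must be >= 32")
  lv <- tissue_levels
  if (length(lv) != 5L || anyNA(lv) || any(lv < 0 | lv > 1))
    stop("phantom_params: need 5 tissue levels in [0, 1]")
  if (anyDuplicated(lv)) stop("phantom_params: tissue levels must be distinct")
  if (noise_sigma < 0) stop("phantom_params: noise_sigma must be >= 0")
  structure(list(size = as.integer(size), tissue_levels = lv,
                 deformation_amplitude = deformation_amplitude,
                 texture_frequency = texture_frequency,
                 noise_sigma = noise_sigma, noise_type = noise_type,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a synthetic brain-like slice
#'
#' Deterministic for a fixed parameter set. The slice contains five nested
#' tissue regions with smooth (sub-pixel blended) boundaries, a deformed
#' elliptical outline, and sulcal ridge texture confined to the gray-matter
#' ribbon, so the four remaining regions sit exactly at their configured
#' intensity levels before noise.
#'
#' @param params a [phantom_params()] object.
#' @return numeric `size` x `size` matrix with values in \[0, 1\].
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(size = 64, seed = 1))
#' dim(ph)
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    params <- do.call(phantom_params, params)
  n <- params$size
  lv <- params$tissue_levels
  with_seed_local(params$seed, {
    ## boundary deformation: low-order random Fourier modes of the radius
    nmodes <- 4L
    amp_k <- stats::rnorm(nmodes, 0, 1) * params$deformation_amplitude /
      sqrt(nmodes)
    phi_k <- stats::runif(nmodes, 0, 2 * pi)
    ## smooth warp field for the sulcal ridges
    wa <- stats::rnorm(3L, 0, 0.8)
    wf <- stats::runif(3L, 1, 3)
    wp <- stats::runif(3L, 0, 2 * pi)
    xs <- (seq_len(n) - 0.5) / n - 0.5
    x <- matrix(rep(xs, times = n), n)        # row coordinate
    y <- matrix(rep(xs, each = n), n)         # column coordinate
    theta <- atan2(y, x)
    d <- sqrt((x / 0.42)^2 + (y / 0.36)^2)
    defo <- 1
    for (k in seq_len(nmodes))
      defo <- defo + amp_k[k] * cos((k + 1L) * theta + phi_k[k])
    rho <- d / pmax(defo, 0.5)
    ## nested regions, blended over a narrow band in rho units
    w <- 0.015
    t_skull <- smoothstep((1.00 - rho) / w)
    t_csf   <- smoothstep((0.90 - rho) / w)
    t_gray  <- smoothstep((0.82 - rho) / w)
    t_white <- smoothstep((0.62 - rho) / w)
    img <- lv[["background"]] +
      (lv[["skull"]] - lv[["background"]]) * t_skull +
      (lv[["csf"]] - lv[["skull"]]) * t_csf +
      (lv[["gray"]] - lv[["csf"]]) * t_gray +
      (lv[["white"]] - lv[["gray"]]) * t_white
    ## sulcal ridges: warped angular sinusoid, gray-matter ribbon only
    warp <- 0
    for (j in 1:3)
      warp <- warp + wa[j] * sin(2 * pi * wf[j] * (x * cos(wp[j]) +
                                                     y * sin(wp[j])))
    ridge <- abs(sin(params$texture_frequency * theta / 2 + warp))
    gm_mask <- t_gray * (1 - t_white)
    img <- img + 0.12 * (ridge - 0.5) * gm_mask
    if (params$noise_sigma > 0) {
      if (params$noise_type == "gaussian") {
        img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sigma), n)
      } else {
        n1 <- matrix(stats::rnorm(n * n, 0, params$noise_sigma), n)
        n2 <- matrix(stats::rnorm(n * n, 0, params$noise_sigma), n)
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Assemble an LR/Ref training quadruple from two HR slices
#'
#' The LR input is the bicubic downsampling of `hr`; the reference is kept at
#' HR resolution and additionally degraded (bicubic down by
#' `ref_blur_factor`, then back up to its original size) to produce the
#' blurred key copy whose frequency content matches the LR query.
#'
#' @param hr HR target slice; both sides must be divisible by `scale`
#'   (see [crop_to_multiple()]).
#' @param ref_hr reference slice with the same dimensions as `hr`.
#' @param scale integer upscaling factor in `{2, 3, 4}`.
#' @param ref_blur_factor degradation factor for the blurred reference copy;
#'   defaults to `scale` so the key matches the query's degradation level
#'   (a fixed factor of 4 is the configurable alternative).
#' @return a `training_sample` list: `lr`, `ref`, `ref_blurred`, `hr`,
#'   `scale`.
#' @export
make_training_sample <- function(hr, ref_hr, scale, ref_blur_factor = scale) {
  stopifnot(is.matrix(hr), is.matrix(ref_hr), scale %in% c(2L, 3L, 4L))
  if (nrow(hr) %% scale != 0L || ncol(hr) %% scale != 0L)
    stop("make_training_sample: hr dims not divisible by scale; ",
         "crop first with crop_to_multiple()")
  if (!all(dim(ref_hr) == dim(hr)))
    stop("make_training_sample: ref_hr must share hr's dimensions")
  lr <- bicubic_resize(hr, nrow(hr) %/% scale, ncol(hr) %/% scale)
  dn_h <- max(1L, round(nrow(ref_hr) / ref_blur_factor))
  dn_w <- max(1L, round(ncol(ref_hr) / ref_blur_factor))
  ref_blurred <- bicubic_resize(bicubic_resize(ref_hr, dn_h, dn_w),
                                nrow(ref_hr), ncol(ref_hr))
  structure(list(lr = lr, ref = ref_hr, ref_blurred = ref_blurred, hr = hr,
                 scale = as.integer(scale)),
            class = "training_sample")
}

## ---- dihedral-group augmentation -------------------------------------------

rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])
hflip <- function(m) m[, ncol(m):1L, drop = FALSE]

#' Apply one of the 8 dihedral transforms to an image
#'
#' Transform `i` (0..7) is `rot90cw^(i %% 4)` followed by a horizontal flip
#' when `i >= 4`.
#'
#' @param img numeric matrix.
#' @param i transform index, 0 to 7.
#' @return transformed matrix.
#' @export
apply_dihedral <- function(img, i) {
  stopifnot(i %in% 0:7)
  k <- i %% 4L
  for (j in seq_len(k)) img <- rot90cw(img)
  if (i >= 4L) img <- hflip(img)
  img
}

#' Randomly flip/rotate a training sample
#'
#' Draws one dihedral transform (identity, flips, 90/180/270-degree
#' rotations) from the seed and applies the same transform to the LR, HR,
#' reference and blurred-reference images so spatial correspondence is
#' preserved.
#'
#' @param sample a `training_sample`.
#' @param seed RNG seed (deterministic augmentation).
#' @param transform optional explicit transform index 0..7, bypassing the
#'   seed.
#' @return an augmented `training_sample`.
#' @export
augment <- function(sample, seed = 0L, transform = NULL) {
  stopifnot(inherits(sample, "training_sample"))
  i <- if (!is.null(transform)) as.integer(transform)
  else with_seed_local(seed, sample.int(8L, 1L) - 1L)
  out <- sample
  for (f in c("lr", "ref", "ref_blurred", "hr"))
    out[[f]] <- apply_dihedral(sample[[f]], i)
  out
}
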