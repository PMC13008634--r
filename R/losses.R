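## Hierarchical training objective: pixel L1 on the final reconstruction,
## L1 structure supervision on the auxiliary structural image, L1 +
## perceptual texture supervision on the auxiliary alignment image, combined
## as lambda1 * L_SR + lambda2 * L_CWT + lambda3 * L_SAT, with an optional
## non-saturating adversarial term.

#' Loss weights
#'
#' Defaults follow the hierarchical weighting that prioritizes the final
#' reconstruction: lambda1 = 1, lambda2 = 0.1, lambda3 = 0.01, with
#' lambda_p = 0.1 inside the texture term.
#'
#' @param lambda1 weight of the final reconstruction L1.
#' @param lambda2 weight of the structure term.
#' @param lambda3 weight of the texture term.
#' @param lambda_p perceptual weight inside the texture term.
#' @param lambda_adv adversarial weight (used only when adversarial training
#'   is enabled; never part of the core objective).
#' @return validated `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 0.1, lambda3 = 0.01,
                         lambda_p = 0.1, lambda_adv = 1e-3) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda_p = lambda_p, lambda_adv = lambda_adv)
  if (any(unlist(w) < 0)) stop("loss_weights: weights must be >= 0")
  structure(w, class = "loss_weights")
}

#' Frozen perceptual feature extractor
#'
#' `kind = "rand_conv"` (default) builds a seeded, fixed-weight multi-scale
#' convolutional feature stack (three 3x3 convolutions, the last two with
#' stride 2, ReLU in between). Its parameters never update; gradients flow
#' only to its input. `kind = "vgg19"` would require pretrained weights and
#' errors with guidance to either supply them or disable the perceptual
#' term.
#'
#' @param kind `"rand_conv"` or `"vgg19"`.
#' @param seed seed of the fixed random weights.
#' @param channels channel widths of the three stages.
#' @return a `perceptual_extractor` object.
#' @export
perceptual_extractor <- function(kind = c("rand_conv", "vgg19"), seed = 909L,
                                 channels = c(8L, 16L, 32L)) {
  kind <- match.arg(kind)
  if (kind == "vgg19")
    stop("perceptual_extractor: pretrained VGG-19 weights are not bundled; ",
         "use kind = 'rand_conv' or disable the perceptual term ",
         "(use_perceptual = FALSE / --no-perceptual)")
  stopifnot(length(channels) == 3L)
  w <- with_seed_local(seed, list(
    w1 = init_conv(3L, 1L, channels[1L]), b1 = rep(0, channels[1L]),
    w2 = init_conv(3L, channels[1L], channels[2L]), b2 = rep(0, channels[2L]),
    w3 = init_conv(3L, channels[2L], channels[3L]), b3 = rep(0, channels[3L])
  ))
  structure(list(kind = kind, seed = seed, channels = channels, weights = w),
            class = "perceptual_extractor")
}

## node-level application of the frozen extractor (weights enter as plain
## constants, so no gradient ever reaches them)
phi_nd <- function(phi, x, H, W) {
  w <- phi$weights
  h <- ad_relu(ad_conv2d(x, w$w1, w$b1, H, W, 3L, 1L))
  hw <- conv_out_hw(H, W, 3L, 2L)
  h <- ad_relu(ad_conv2d(h, w$w2, w$b2, H, W, 3L, 2L))
  hw2 <- conv_out_hw(hw[1L], hw[2L], 3L, 2L)
  ad_relu(ad_conv2d(h, w$w3, w$b3, hw[1L], hw[2L], 3L, 2L))
}

#' Apply the frozen perceptual extractor to an image
#' @param phi a [perceptual_extractor()].
#' @param img H x W numeric matrix.
#' @return feature array (H/4-ish x W/4-ish x C3).
#' @export
perceptual_features <- function(phi, img) {
  stopifnot(inherits(phi, "perceptual_extractor"), is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  out <- phi_nd(phi, ad_const(matrix(img, length(img), 1L)), H, W)
  hw <- conv_out_hw(H, W, 3L, 2L)
  hw2 <- conv_out_hw(hw[1L], hw[2L], 3L, 2L)
  fm_arr(nval(out), hw2[1L], hw2[2L])
}

#' Structure loss: pixel-level L1
#'
#' @param i_cwt,i_hr equal-size numeric matrices.
#' @return mean absolute difference (scalar).
#' @export
structure_loss <- function(i_cwt, i_hr) {
  if (!all(dim(i_cwt) == dim(i_hr)))
    stop("structure_loss: dimension mismatch")
  mean(abs(i_cwt - i_hr))
}

#' Texture loss: L1 plus perceptual distance
#'
#' `L1(i_sat, i_hr) + lambda_p * mean((phi(i_sat) - phi(i_hr))^2)`. The
#' perceptual distance uses the mean (not sum) of squared feature
#' differences so `lambda_p` is resolution-independent. The perceptual term
#' is evaluated on the alignment branch's image (`perceptual_on = "cwt"`
#' reproduces the alternative reading of the objective).
#'
#' @param i_sat,i_hr equal-size numeric matrices.
#' @param phi a [perceptual_extractor()], or `NULL` to drop the perceptual
#'   term.
#' @param lambda_p perceptual weight.
#' @return scalar loss.
#' @export
texture_loss <- function(i_sat, i_hr, phi = NULL, lambda_p = 0.1) {
  if (!all(dim(i_sat) == dim(i_hr)))
    stop("texture_loss: dimension mismatch")
  l1 <- mean(abs(i_sat - i_hr))
  if (is.null(phi) || lambda_p == 0) return(l1)
  fa <- perceptual_features(phi, i_sat)
  fb <- perceptual_features(phi, i_hr)
  l1 + lambda_p * mean((fa - fb)^2)
}

#' Total hierarchical loss
#'
#' `lambda1 * L1(i_sr, i_hr) + lambda2 * L_CWT + lambda3 * L_SAT`; terms of
#' disabled branches (missing auxiliary images) are dropped. Returns the
#' weighted total together with the raw per-term breakdown for logging.
#'
#' @param outputs list with `i_sr` and optional `i_cwt`, `i_sat` (HR
#'   matrices, e.g. from [daasr_forward()]).
#' @param i_hr ground-truth HR matrix.
#' @param w a [loss_weights()].
#' @param phi optional [perceptual_extractor()] for the texture term.
#' @param perceptual_on `"sat"` (default) or `"cwt"`: which auxiliary image
#'   feeds the perceptual distance.
#' @return list `total`, `breakdown` (named: l_sr, l_cwt, l_sat).
#' @export
total_loss <- function(outputs, i_hr, w = loss_weights(), phi = NULL,
                       perceptual_on = c("sat", "cwt")) {
  perceptual_on <- match.arg(perceptual_on)
  if (!inherits(w, "loss_weights")) w <- do.call(loss_weights, w)
  l_sr <- structure_loss(outputs$i_sr, i_hr)
  l_cwt <- if (!is.null(outputs$i_cwt)) structure_loss(outputs$i_cwt, i_hr)
  else 0
  l_sat <- if (!is.null(outputs$i_sat)) {
    src <- if (perceptual_on == "cwt" && !is.null(outputs$i_cwt))
      outputs$i_cwt else outputs$i_sat
    l1 <- structure_loss(outputs$i_sat, i_hr)
    if (is.null(phi)) l1
    else l1 + w$lambda_p * mean((perceptual_features(phi, src) -
                                   perceptual_features(phi, i_hr))^2)
  } else 0
  total <- w$lambda1 * l_sr + w$lambda2 * l_cwt + w$lambda3 * l_sat
  list(total = total,
       breakdown = c(l_sr = l_sr, l_cwt = l_cwt, l_sat = l_sat))
}

## node-level total loss used by the trainer; fw is the result of
## daasr_forward_nd, hr a plain HR matrix
total_loss_nd <- function(fw, hr, w, phi = NULL,
                          perceptual_on = "sat") {
  hr_col <- matrix(hr, length(hr), 1L)
  l_sr <- ad_mean_abs_diff(fw$i_sr, hr_col)
  terms <- ad_scale(l_sr, w$lambda1)
  bd <- c(l_sr = nval(l_sr))
  if (!is.null(fw$i_cwt)) {
    l_cwt <- ad_mean_abs_diff(fw$i_cwt, hr_col)
    terms <- ad_add(terms, ad_scale(l_cwt, w$lambda2))
    bd <- c(bd, l_cwt = nval(l_cwt))
  }
  if (!is.null(fw$i_sat)) {
    l_sat <- ad_mean_abs_diff(fw$i_sat, hr_col)
    if (!is.null(phi) && w$lambda_p > 0) {
      src <- if (perceptual_on == "cwt" && !is.null(fw$i_cwt)) fw$i_cwt
      else fw$i_sat
      pa <- phi_nd(phi, src, fw$H_hr, fw$W_hr)
      pb <- phi_nd(phi, ad_const(hr_col), fw$H_hr, fw$W_hr)
      l_sat <- ad_add(l_sat, ad_scale(ad_mean_sq_diff(pa, pb), w$lambda_p))
    }
    terms <- ad_add(terms, ad_scale(l_sat, w$lambda3))
    bd <- c(bd, l_sat = nval(l_sat))
  }
  list(node = terms, breakdown = bd)
}

## ---- adversarial objective (optional) --------------------------------------

#' Initialize the patch discriminator
#'
#' Small convolutional stack producing one logit per image patch
#' (three 3x3 convolutions, the first two strided with ReLU).
#'
#' @param seed RNG seed.
#' @param channels widths of the two hidden stages.
#' @return named parameter list.
#' @export
init_discriminator <- function(seed = 0L, channels = c(8L, 16L)) {
  with_seed_local(seed, list(
    w1 = init_conv(3L, 1L, channels[1L]), b1 = rep(0, channels[1L]),
    w2 = init_conv(3L, channels[1L], channels[2L]), b2 = rep(0, channels[2L]),
    w3 = init_conv(3L, channels[2L], 1L), b3 = 0
  ))
}

disc_nd <- function(dp, x, H, W) {
  h <- ad_relu(ad_conv2d(x, dp$w1, dp$b1, H, W, 3L, 2L))
  hw <- conv_out_hw(H, W, 3L, 2L)
  h <- ad_relu(ad_conv2d(h, dp$w2, dp$b2, hw[1L], hw[2L], 3L, 2L))
  hw2 <- conv_out_hw(hw[1L], hw[2L], 3L, 2L)
  ad_conv2d(h, dp$w3, dp$b3, hw2[1L], hw2[2L], 3L, 1L)
}

#' Adversarial generator/discriminator losses
#'
#' Non-saturating GAN objective with a patch-level convolutional
#' discriminator: the generator term is `mean(softplus(-D(fake)))`
#' (equal to -log(0.5) per patch when the discriminator is indifferent) and
#' the discriminator term `mean(softplus(-D(real))) + mean(softplus(D(fake)))`.
#'
#' @param i_sr,i_hr HR matrices (fake / real).
#' @param disc_params list from [init_discriminator()].
#' @param enabled adversarial mode flag; calling with `FALSE` errors, which
#'   keeps the optional term strictly isolated from the core objective.
#' @return list `generator`, `discriminator` (scalars).
#' @export
adversarial_losses <- function(i_sr, i_hr, disc_params, enabled = TRUE) {
  if (!enabled) stop("adversarial_losses: adversarial mode is disabled")
  H <- nrow(i_sr); W <- ncol(i_sr)
  dp <- lapply(disc_params, ad_const)
  d_fake <- disc_nd(dp, ad_const(matrix(i_sr, length(i_sr), 1L)), H, W)
  d_real <- disc_nd(dp, ad_const(matrix(i_hr, length(i_hr), 1L)), H, W)
  gen <- mean(nval(ad_softplus(ad_scale(d_fake, -1))))
  dsc <- mean(nval(ad_softplus(ad_scale(d_real, -1)))) +
    mean(nval(ad_softplus(d_fake)))
  list(generator = gen, discriminator = dsc)
}
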