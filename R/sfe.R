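## Spatial Feature Extractor: a lightweight, fully learnable texture encoder
## (head conv + ReLU + three residual blocks) applied with shared weights to
## the reference slice and its blurred copy. No pretrained features are used
## anywhere: fixed classification features transfer poorly to low-level MRI
## texture, so the extractor trains jointly with the rest of the network.
## When the working grid is the LR feature grid, the head convolution runs
## with stride = scale so reference features land directly on that grid.

#' Initialize one residual block
#'
#' Two 3x3 convolutions each followed by batch normalization; ReLU after the
#' first BN and after the second, with an identity skip connection.
#'
#' @param channels feature channels (input = output).
#' @param seed RNG seed.
#' @return list with `params` (kernels, biases, BN scale/shift) and `bn`
#'   (running mean/var per BN layer).
#' @export
init_residual_block_params <- function(channels, seed = 0L) {
  C <- channels
  params <- with_seed_local(seed, list(
    conv1_w = init_conv(3L, C, C), conv1_b = rep(0, C),
    bn1_g = rep(1, C), bn1_b = rep(0, C),
    conv2_w = init_conv(3L, C, C), conv2_b = rep(0, C),
    bn2_g = rep(1, C), bn2_b = rep(0, C)
  ))
  bn <- list(bn1 = list(mean = rep(0, C), var = rep(1, C)),
             bn2 = list(mean = rep(0, C), var = rep(1, C)))
  list(params = params, bn = bn)
}

bn_env <- function(st) {
  e <- new.env(parent = emptyenv())
  e$mean <- st$mean; e$var <- st$var
  e
}

## node-level residual block: f + ReLU(BN(conv(ReLU(BN(conv(f))))))
residual_block_nd <- function(x, pp, H, W, bn1, bn2, training = FALSE) {
  h <- ad_conv2d(x, pp$conv1_w, pp$conv1_b, H, W, 3L)
  h <- ad_relu(ad_batchnorm_cols(h, pp$bn1_g, pp$bn1_b, bn1, training))
  h <- ad_conv2d(h, pp$conv2_w, pp$conv2_b, H, W, 3L)
  h <- ad_relu(ad_batchnorm_cols(h, pp$bn2_g, pp$bn2_b, bn2, training))
  ad_add(x, h)
}

#' Residual block forward pass
#'
#' @param f H x W x C numeric array.
#' @param params parameter list from [init_residual_block_params()]`$params`.
#' @param stats BN running statistics (`$bn` slot of the initializer); used
#'   in eval mode. Defaults to mean 0 / var 1.
#' @param training compute BN statistics from the input instead of `stats`.
#' @return H x W x C numeric array.
#' @export
residual_block <- function(f, params, stats = NULL, training = FALSE) {
  C <- dim(f)[3L] %||% 1L
  if (ncol(params$conv1_w) != C)
    stop("residual_block: channel mismatch between input and parameters")
  if (is.null(stats))
    stats <- list(bn1 = list(mean = rep(0, C), var = rep(1, C)),
                  bn2 = list(mean = rep(0, C), var = rep(1, C)))
  m <- fm_mat(f)
  out <- residual_block_nd(ad_const(m), lapply(params, ad_const),
                           dim(f)[1L], dim(f)[2L],
                           bn_env(stats$bn1), bn_env(stats$bn2), training)
  fm_arr(out$value, dim(f)[1L], dim(f)[2L])
}

#' Initialize the spatial feature extractor
#'
#' Head 3x3 convolution (1 -> C channels) + ReLU followed by exactly three
#' residual blocks.
#'
#' @param channels output feature channels.
#' @param seed RNG seed.
#' @return list with flat `params` (names `head_w`, `head_b`,
#'   `rb<i>_...`) and `bn` running statistics (names `rb<i>_bn<j>`).
#' @export
init_sfe_params <- function(channels, seed = 0L) {
  C <- channels
  params <- with_seed_local(seed, list(head_w = init_conv(3L, 1L, C),
                                       head_b = rep(0, C)))
  bn <- list()
  for (i in 1:3) {
    rb <- init_residual_block_params(C, seed + 100L * i)
    names(rb$params) <- paste0("rb", i, "_", names(rb$params))
    params <- c(params, rb$params)
    bn[[paste0("rb", i, "_bn1")]] <- rb$bn$bn1
    bn[[paste0("rb", i, "_bn2")]] <- rb$bn$bn2
  }
  list(params = params, bn = bn)
}

## node-level SFE; pp is the flat param-node list, bnenv maps names to
## environments. Returns list(out, H, W).
sfe_nd <- function(x, pp, H, W, stride = 1L, bnenv = NULL, training = FALSE,
                   bn_prefix = "") {
  if (is.null(bnenv)) {
    bnenv <- new.env(parent = emptyenv())
    C <- ncol(nval(pp$head_w))
    for (i in 1:3) for (j in 1:2)
      bnenv[[paste0(bn_prefix, "rb", i, "_bn", j)]] <-
        bn_env(list(mean = rep(0, C), var = rep(1, C)))
  }
  hw <- conv_out_hw(H, W, 3L, stride)
  h <- ad_relu(ad_conv2d(x, pp$head_w, pp$head_b, H, W, 3L, stride))
  for (i in 1:3) {
    fields <- c("conv1_w", "conv1_b", "bn1_g", "bn1_b",
                "conv2_w", "conv2_b", "bn2_g", "bn2_b")
    sub <- pp[paste0("rb", i, "_", fields)]
    names(sub) <- fields
    st1 <- bnenv[[paste0(bn_prefix, "rb", i, "_bn1")]]
    st2 <- bnenv[[paste0(bn_prefix, "rb", i, "_bn2")]]
    if (is.null(st1) || is.null(st2))
      stop("sfe_nd: missing batch-norm state for residual block ", i)
    h <- residual_block_nd(h, sub, hw[1L], hw[2L], st1, st2, training)
  }
  list(out = h, H = hw[1L], W = hw[2L])
}

#' Extract spatial texture features from an image
#'
#' Applies the SFE (head conv + ReLU + 3 residual blocks). With
#' `out_stride > 1` the head convolution is strided so the reference features
#' land on the LR working grid. Deterministic in eval mode. The same
#' parameter set is applied to the reference and its blurred copy (weight
#' sharing).
#'
#' @param img H x W numeric matrix in \[0, 1\].
#' @param sfe list from [init_sfe_params()] (params + bn running stats).
#' @param out_stride head-conv stride, 1 or the training scale.
#' @param training use batch statistics in BN layers.
#' @return (H/stride) x (W/stride) x C numeric array.
#' @export
extract_spatial_features <- function(img, sfe, out_stride = 1L,
                                     training = FALSE) {
  stopifnot(is.matrix(img))
  bnenv <- new.env(parent = emptyenv())
  for (nm in names(sfe$bn)) bnenv[[nm]] <- bn_env(sfe$bn[[nm]])
  res <- sfe_nd(ad_const(matrix(img, length(img), 1L)),
                lapply(sfe$params, ad_const),
                nrow(img), ncol(img), out_stride, bnenv, training)
  fm_arr(res$out$value, res$H, res$W)
}
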