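## Model assembly: shallow feature extraction on the LR slice, reference
## encoding through the shared SFE, a stack of hierarchical feature
## alignment groups (structural block -> alignment transformer with residual
## aggregation F_out = F_CWT + F_SAT + F_in), and sub-pixel reconstruction
## heads for the final output and the two auxiliary supervision images.

#' Model configuration
#'
#' @param channels feature channels C (default 64).
#' @param n_hfag number of stacked alignment groups (default 6).
#' @param scale upscaling factor, 2, 3 or 4.
#' @param use_cwt,use_sat enable the structural / alignment branches.
#' @param cwt_variant structural block: `"cwt"` (channel-wise transformer),
#'   `"conv"`, `"se"`, `"window_attention"` (ablation comparators).
#' @param mlp_ratio MLP expansion inside transformer-style blocks.
#' @param cwt_temperature optional logit multiplier of the channel attention
#'   (the formulation itself uses unscaled logits).
#' @param window_size window side for the window-attention variant.
#' @param sat_patch_size,sat_stride patch geometry of the alignment matcher.
#' @param sat_grid `"lr"` (default: reference features strided down to the
#'   working grid) or `"hr"` (match at HR grid, pool the result back).
#' @param disable_index_map,disable_score_map,disable_kv_matching,disable_fcwt_fusion
#'   alignment-transformer ablation toggles.
#' @param global_skip add a bicubic upsample of the LR input to every
#'   reconstruction head so the network learns a residual.
#' @param ref_blur_factor degradation factor of the blurred reference copy;
#'   `NULL` means "use the training scale".
#' @param per_stage_supervision attach auxiliary heads to every stage
#'   instead of the last (off by default).
#' @param seed parameter-initialization seed.
#' @return a validated `daasr_config` list.
#' @export
daasr_config <- function(channels = 64L, n_hfag = 6L, scale = 2L,
                         use_cwt = TRUE, use_sat = TRUE,
                         cwt_variant = c("cwt", "conv", "se",
                                         "window_attention"),
                         mlp_ratio = 2, cwt_temperature = 1,
                         window_size = 8L,
                         sat_patch_size = 3L, sat_stride = 1L,
                         sat_grid = c("lr", "hr"),
                         disable_index_map = FALSE,
                         disable_score_map = FALSE,
                         disable_kv_matching = FALSE,
                         disable_fcwt_fusion = FALSE,
                         global_skip = TRUE,
                         ref_blur_factor = NULL,
                         per_stage_supervision = FALSE,
                         seed = 0L) {
  cwt_variant <- match.arg(cwt_variant)
  sat_grid <- match.arg(sat_grid)
  stopifnot(channels >= 1L, n_hfag >= 1L, scale %in% c(2L, 3L, 4L),
            sat_patch_size >= 1L, sat_stride >= 1L,
            sat_stride <= sat_patch_size)
  structure(list(channels = as.integer(channels), n_hfag = as.integer(n_hfag),
                 scale = as.integer(scale), use_cwt = use_cwt,
                 use_sat = use_sat, cwt_variant = cwt_variant,
                 mlp_ratio = mlp_ratio, cwt_temperature = cwt_temperature,
                 window_size = as.integer(window_size),
                 sat_patch_size = as.integer(sat_patch_size),
                 sat_stride = as.integer(sat_stride), sat_grid = sat_grid,
                 disable_index_map = disable_index_map,
                 disable_score_map = disable_score_map,
                 disable_kv_matching = disable_kv_matching,
                 disable_fcwt_fusion = disable_fcwt_fusion,
                 global_skip = global_skip,
                 ref_blur_factor = ref_blur_factor,
                 per_stage_supervision = per_stage_supervision,
                 seed = as.integer(seed)),
            class = "daasr_config")
}

## parameters of one sub-pixel reconstruction head
## the final 1-channel conv starts at 0.01x the fan-in scale so that, with
## the global bicubic skip, the head's initial prediction sits at the
## interpolation baseline while every parameter still receives gradient
init_head_params <- function(C, scale, seed) {
  with_seed_local(seed, {
    if (scale == 4L) {
      list(up1_w = init_conv(3L, C, C * 4L), up1_b = rep(0, C * 4L),
           up2_w = init_conv(3L, C, C * 4L), up2_b = rep(0, C * 4L),
           out_w = init_conv(3L, C, 1L) * 0.01, out_b = 0)
    } else {
      list(up1_w = init_conv(3L, C, C * scale^2), up1_b = rep(0, C * scale^2),
           out_w = init_conv(3L, C, 1L) * 0.01, out_b = 0)
    }
  })
}

prefix_names <- function(lst, prefix) {
  names(lst) <- paste0(prefix, names(lst))
  lst
}

#' Initialize a DAASR model
#'
#' @param cfg a [daasr_config()].
#' @return a `daasr_model`: flat named parameter list, batch-norm running
#'   statistics, and the resolved config.
#' @export
init_daasr <- function(cfg = daasr_config()) {
  C <- cfg$channels
  params <- with_seed_local(cfg$seed, list(
    shallow_w = init_conv(3L, 1L, C), shallow_b = rep(0, C)))
  bn <- list()
  if (cfg$use_sat) {
    sfe <- init_sfe_params(C, cfg$seed + 1L)
    params <- c(params, prefix_names(sfe$params, "sfe."))
    bn <- c(bn, prefix_names(sfe$bn, "sfe."))
  }
  for (i in seq_len(cfg$n_hfag)) {
    if (cfg$use_cwt) {
      sp <- init_structure_params(cfg$cwt_variant, C, cfg$mlp_ratio,
                                  cfg$seed + 10L * i)
      params <- c(params, prefix_names(sp, sprintf("hfag%d.cwt.", i)))
    }
    if (cfg$use_sat) {
      fuse_in <- if (cfg$disable_fcwt_fusion) C else 2L * C
      ap <- init_sat_params(C, fuse_in, cfg$seed + 10L * i + 5L)
      params <- c(params, prefix_names(ap, sprintf("hfag%d.sat.", i)))
    }
  }
  params <- c(params, prefix_names(init_head_params(C, cfg$scale,
                                                    cfg$seed + 900L),
                                   "head."))
  if (cfg$use_cwt)
    params <- c(params, prefix_names(init_head_params(C, cfg$scale,
                                                      cfg$seed + 901L),
                                     "head_cwt."))
  if (cfg$use_sat)
    params <- c(params, prefix_names(init_head_params(C, cfg$scale,
                                                      cfg$seed + 902L),
                                     "head_sat."))
  structure(list(params = params, bn = bn, cfg = cfg), class = "daasr_model")
}

#' Total number of learnable parameters
#' @param model a `daasr_model` (or flat parameter list).
#' @return integer count.
#' @export
n_parameters <- function(model) {
  p <- if (inherits(model, "daasr_model")) model$params else model
  sum(vapply(p, length, integer(1)))
}

## pull the sub-list of parameter nodes with a given prefix, stripped
subp <- function(pn, prefix) {
  sel <- startsWith(names(pn), prefix)
  out <- pn[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

## ---- forward passes ---------------------------------------------------------

## sub-pixel head on an (H*W) x C node; returns (H*scale * W*scale) x 1 node
upsample_head_nd <- function(f, H, W, scale, hp, skip = NULL) {
  C <- ncol(nval(f))
  if (scale == 4L) {
    u <- ad_pixel_shuffle(ad_conv2d(f, hp$up1_w, hp$up1_b, H, W, 3L),
                          H, W, 2L)
    H <- H * 2L; W <- W * 2L
    u <- ad_pixel_shuffle(ad_conv2d(u, hp$up2_w, hp$up2_b, H, W, 3L),
                          H, W, 2L)
    H <- H * 2L; W <- W * 2L
  } else {
    u <- ad_pixel_shuffle(ad_conv2d(f, hp$up1_w, hp$up1_b, H, W, 3L),
                          H, W, scale)
    H <- H * scale; W <- W * scale
  }
  out <- ad_conv2d(u, hp$out_w, hp$out_b, H, W, 3L)
  if (!is.null(skip)) out <- ad_add(out, skip)
  out
}

## one alignment group. f is the working-grid feature node; vfeat/kfeat the
## shared reference features (value / blurred key). Returns the aggregated
## output, the two branch outputs and the stage confidence.
hfag_nd <- function(f, vfeat, kfeat, pn, i, H, W, cfg) {
  f_cwt <- if (cfg$use_cwt)
    structure_block_variant_nd(f, subp(pn, sprintf("hfag%d.cwt.", i)),
                               cfg$cwt_variant, H, W, cfg)
  else f
  f_sat <- NULL
  conf <- NA_real_
  if (cfg$use_sat) {
    sp <- subp(pn, sprintf("hfag%d.sat.", i))
    if (cfg$sat_grid == "hr") {
      s <- cfg$scale
      q_hr <- ad_nn_upsample(f_cwt, H, W, s)
      res <- sat_nd(q_hr, vfeat, kfeat, sp, H * s, W * s, cfg)
      f_sat <- ad_avg_pool(res$out, H * s, W * s, s)
    } else {
      res <- sat_nd(f_cwt, vfeat, kfeat, sp, H, W, cfg)
      f_sat <- res$out
    }
    conf <- res$mean_confidence
  }
  out <- if (cfg$use_cwt && cfg$use_sat) ad_add(ad_add(f_cwt, f_sat), f)
  else if (cfg$use_cwt) ad_add(f_cwt, f)
  else if (cfg$use_sat) ad_add(f_sat, f)
  else f
  list(out = out, f_cwt = f_cwt, f_sat = f_sat, confidence = conf)
}

## full forward pass on nodes. lr/ref/refblur are plain matrices; pn the
## parameter-node list. Returns image nodes plus diagnostics.
daasr_forward_nd <- function(lr, ref, refblur, pn, bnenv, cfg,
                             training = FALSE) {
  H <- nrow(lr); W <- ncol(lr)
  s <- cfg$scale
  f <- ad_conv2d(ad_const(matrix(lr, length(lr), 1L)),
                 pn$shallow_w, pn$shallow_b, H, W, 3L)
  vfeat <- kfeat <- NULL
  if (cfg$use_sat) {
    stride <- if (cfg$sat_grid == "hr") 1L else s
    sfe_pn <- subp(pn, "sfe.")
    vfeat <- sfe_nd(ad_const(matrix(ref, length(ref), 1L)), sfe_pn,
                    nrow(ref), ncol(ref), stride, bnenv, training,
                    bn_prefix = "sfe.")$out
    kfeat <- sfe_nd(ad_const(matrix(refblur, length(refblur), 1L)), sfe_pn,
                    nrow(refblur), ncol(refblur), stride, bnenv,
                    training, bn_prefix = "sfe.")$out
  }
  confs <- numeric(0)
  last <- NULL
  for (i in seq_len(cfg$n_hfag)) {
    last <- hfag_nd(f, vfeat, kfeat, pn, i, H, W, cfg)
    f <- last$out
    confs <- c(confs, last$confidence)
  }
  skip <- if (isTRUE(cfg$global_skip))
    ad_const(matrix(bicubic_resize(lr, H * s, W * s, clip = FALSE),
                    H * W * s * s, 1L))
  else NULL
  i_sr <- upsample_head_nd(f, H, W, s, subp(pn, "head."), skip)
  i_cwt <- if (cfg$use_cwt)
    upsample_head_nd(last$f_cwt, H, W, s, subp(pn, "head_cwt."), skip)
  else NULL
  i_sat <- if (cfg$use_sat)
    upsample_head_nd(last$f_sat, H, W, s, subp(pn, "head_sat."), skip)
  else NULL
  list(i_sr = i_sr, i_cwt = i_cwt, i_sat = i_sat,
       stage_confidence = confs, H_hr = H * s, W_hr = W * s)
}

## ---- public array-level API -------------------------------------------------

#' Shallow feature extraction
#'
#' Single 3x3 convolution lifting the LR slice to C feature channels.
#'
#' @param i_lr H x W numeric matrix.
#' @param params list with `shallow_w` ((9) x C kernel matrix) and
#'   `shallow_b`.
#' @return H x W x C array.
#' @export
shallow_extract <- function(i_lr, params) {
  out <- ad_conv2d(ad_const(matrix(i_lr, length(i_lr), 1L)),
                   params$shallow_w, params$shallow_b,
                   nrow(i_lr), ncol(i_lr), 3L)
  fm_arr(nval(out), nrow(i_lr), ncol(i_lr))
}

#' One hierarchical feature alignment group
#'
#' Structural block on `f_in`, alignment transfer against the reference
#' features, and residual aggregation `F_out = F_CWT + F_SAT + F_in`. With a
#' disabled alignment branch the output is `F_CWT + F_in`; with a disabled
#' structural branch the identity stands in for the structural features.
#'
#' @param f_in working-grid feature map, H x W x C array.
#' @param f_ref,f_ref_blur reference feature maps on the same grid.
#' @param params list with elements `cwt` (structural block parameters) and
#'   `sat` (alignment parameters).
#' @param cfg a [daasr_config()] (branch toggles, patch geometry).
#' @return H x W x C array.
#' @export
hfag_forward <- function(f_in, f_ref, f_ref_blur, params,
                         cfg = daasr_config(channels = dim(f_in)[3L],
                                            n_hfag = 1L)) {
  pn <- list()
  if (cfg$use_cwt)
    pn <- c(pn, prefix_names(lapply(params$cwt, ad_const), "hfag1.cwt."))
  if (cfg$use_sat)
    pn <- c(pn, prefix_names(lapply(params$sat, ad_const), "hfag1.sat."))
  d <- dim(f_in)
  res <- hfag_nd(ad_const(fm_mat(f_in)),
                 if (cfg$use_sat) ad_const(fm_mat(f_ref)) else NULL,
                 if (cfg$use_sat) ad_const(fm_mat(f_ref_blur)) else NULL,
                 pn, 1L, d[1L], d[2L], cfg)
  fm_arr(nval(res$out), d[1L], d[2L])
}

#' Sub-pixel reconstruction head
#'
#' Convolution to `C * scale^2` channels, pixel rearrangement to the HR
#' grid (two 2x stages for scale 4), and a final 3x3 convolution to one
#' channel; an optional bicubic upsample of the LR input is added so the
#' head predicts a residual.
#'
#' @param f H x W x C feature array.
#' @param scale 2, 3 or 4.
#' @param params head parameter list (`up1_w`, `up1_b`, `up2_*` for scale 4,
#'   `out_w`, `out_b`).
#' @param i_lr optional LR image for the bicubic skip.
#' @return (H*scale) x (W*scale) numeric matrix.
#' @export
upsample_head <- function(f, scale, params, i_lr = NULL) {
  d <- dim(f)
  skip <- if (!is.null(i_lr))
    ad_const(matrix(bicubic_resize(i_lr, d[1L] * scale, d[2L] * scale,
                                   clip = FALSE),
                    d[1L] * d[2L] * scale^2, 1L))
  else NULL
  out <- upsample_head_nd(ad_const(fm_mat(f)), d[1L], d[2L], scale,
                          lapply(params, ad_const), skip)
  matrix(nval(out), d[1L] * scale, d[2L] * scale)
}

#' Full DAASR forward pass
#'
#' Encodes the reference pair once through the shared SFE, propagates the LR
#' features through the stacked alignment groups, and reconstructs the final
#' image plus the two auxiliary supervision images from the last stage's
#' branch outputs.
#'
#' @param i_lr LR slice (H x W matrix).
#' @param i_ref reference slice at HR size.
#' @param i_ref_blur blurred reference copy (same size as `i_ref`); computed
#'   from `i_ref` with the configured blur factor when `NULL`.
#' @param model a `daasr_model` from [init_daasr()].
#' @param training run batch-norm layers in training mode.
#' @return list with `i_sr`, `i_cwt`, `i_sat` (HR matrices; `NULL` for
#'   disabled branches) and `diagnostics$stage_confidence`.
#' @export
daasr_forward <- function(i_lr, i_ref, i_ref_blur = NULL, model,
                          training = FALSE) {
  cfg <- model$cfg
  if (is.null(i_ref_blur) && cfg$use_sat) {
    fac <- cfg$ref_blur_factor %||% cfg$scale
    dn_h <- max(1L, round(nrow(i_ref) / fac))
    dn_w <- max(1L, round(ncol(i_ref) / fac))
    i_ref_blur <- bicubic_resize(bicubic_resize(i_ref, dn_h, dn_w),
                                 nrow(i_ref), ncol(i_ref))
  }
  pn <- lapply(model$params, ad_const)
  bnenv <- new.env(parent = emptyenv())
  for (nm in names(model$bn)) bnenv[[nm]] <- bn_env(model$bn[[nm]])
  res <- daasr_forward_nd(i_lr, i_ref, i_ref_blur, pn, bnenv, cfg, training)
  as_img <- function(nd) if (is.null(nd)) NULL
  else matrix(nval(nd), res$H_hr, res$W_hr)
  list(i_sr = as_img(res$i_sr), i_cwt = as_img(res$i_cwt),
       i_sat = as_img(res$i_sat),
       diagnostics = list(stage_confidence = res$stage_confidence))
}

## ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' One file holding every parameter tensor keyed by hierarchical name, the
#' BN running statistics, the resolved config, the RNG state and any extra
#' training state; [load_checkpoint()] restores it bit-exactly.
#'
#' @param model a `daasr_model`.
#' @param path output file (.rds).
#' @param extra optional list (optimizer state, epoch counter, run log).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(params = model$params, bn = model$bn, cfg = model$cfg,
               extra = extra, rng = rng), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @param restore_rng restore the RNG state stored in the checkpoint
#'   (used for deterministic training resumption).
#' @return list with `model` (a `daasr_model`) and `extra`.
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  ck <- readRDS(path)
  if (restore_rng && !is.null(ck$rng))
    assign(".Random.seed", ck$rng, envir = globalenv())
  list(model = structure(list(params = ck$params, bn = ck$bn, cfg = ck$cfg),
                         class = "daasr_model"),
       extra = ck$extra)
}
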