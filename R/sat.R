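## Spatial Alignment Transformer: patch-level cosine matching between the
## query (projected structural features) and the blurred-reference key,
## hard retrieval of the best-matching value patch per query (index map P),
## confidence weighting by the maximal cosine (score map C), and fusion with
## the structural features through a 1x1 convolution.
##
## The argmax that produces P is discrete and carries no gradient; the
## confidence c_i = max_j M_ij does, and is kept on the autodiff tape via the
## selected normalized-patch inner products, so training shapes both the
## query and key encoders. The full N x M similarity matrix is only needed
## for the argmax and is computed off-tape.

#' Initialize SAT fusion parameters
#'
#' @param channels feature channels C of the working grid.
#' @param fuse_in input channels of the 1x1 fusion convolution (2C when the
#'   retrieved texture is concatenated with the structural features, C for
#'   the texture-only ablation).
#' @param seed RNG seed.
#' @return list with `w_qprime` (C x C), `fuse_w` (`fuse_in` x C), `fuse_b`.
#' @export
init_sat_params <- function(channels, fuse_in = 2L * channels, seed = 0L) {
  with_seed_local(seed, list(
    w_qprime = init_linear(channels, channels),
    fuse_w = init_linear(fuse_in, channels),
    fuse_b = rep(0, channels)
  ))
}

#' Build SAT query/key/value feature maps
#'
#' Query: structural features resampled to the matching grid and projected
#' by the learnable C x C matrix (the resampling is the identity on the
#' default LR working grid). Key: features of the blurred reference. Value:
#' features of the original reference; key and value pass through untouched.
#'
#' @param f_cwt structural feature map, H x W x C array.
#' @param f_ref,f_ref_blur reference / blurred-reference feature maps with
#'   matching dimensions.
#' @param w_qprime C x C projection matrix.
#' @return list `q`, `k`, `v` of H x W x C arrays (`k`, `v` are the inputs
#'   themselves).
#' @export
build_qkv <- function(f_cwt, f_ref, f_ref_blur, w_qprime) {
  stopifnot(all(dim(f_ref) == dim(f_ref_blur)))
  if (!all(dim(f_cwt) == dim(f_ref)))
    stop("build_qkv: query and reference features must share the working grid")
  C <- dim(f_cwt)[3L]
  stopifnot(all(dim(w_qprime) == c(C, C)))
  q <- fm_arr(fm_mat(f_cwt) %*% w_qprime, dim(f_cwt)[1L], dim(f_cwt)[2L])
  list(q = q, k = f_ref_blur, v = f_ref)
}

#' Decompose a feature map into flattened patches
#'
#' Patches of side `p` at stride `s`, row-major over the patch grid;
#' reflection padding on the bottom/right edge when needed so the grid tiles
#' the map. `unpatchify` (overlap-averaging fold) of an untouched patch set
#' reproduces the map exactly.
#'
#' @param f H x W x C numeric array.
#' @param p patch side (>= 1); `s` stride (1 <= s <= p).
#' @return a `patch_set`: `patches` (N x p*p*C), `patch_size`, `stride`,
#'   `grid` (rows, cols), `source_dims` (H, W, C).
#' @export
patchify <- function(f, p, s) {
  d <- dim(f); if (length(d) == 2L) d <- c(d, 1L)
  geom <- patch_geom(d[1L], d[2L], as.integer(p), as.integer(s))
  m <- fm_mat(f)
  patches <- nval(ad_unfold(ad_const(m), geom))
  structure(list(patches = patches, patch_size = as.integer(p),
                 stride = as.integer(s), grid = geom$grid,
                 source_dims = d),
            class = "patch_set")
}

#' Reassemble a patch set into a feature map (overlap-averaging fold)
#'
#' @param ps a `patch_set` (possibly with modified patches).
#' @return H x W x C numeric array.
#' @export
unpatchify <- function(ps) {
  d <- ps$source_dims
  geom <- patch_geom(d[1L], d[2L], ps$patch_size, ps$stride)
  out <- nval(ad_fold_mean(ad_const(ps$patches), geom, d[3L]))
  fm_arr(out, d[1L], d[2L])
}

## row-normalize a plain matrix; zero rows stay zero so a zero-norm operand
## yields similarity 0 (neutral, never selected over a positive match)
unit_rows <- function(m, eps = 1e-12) {
  nr <- sqrt(rowSums(m * m))
  m / pmax(nr, eps)
}

#' Cosine similarity between two patch sets
#'
#' Entry (i, j) is the normalized dot product between query patch i and key
#' patch j; zero-norm patches are assigned similarity 0 by convention.
#'
#' @param q,k `patch_set` objects (or plain patch matrices) with equal patch
#'   vector length.
#' @return N x M similarity matrix with entries in \[-1, 1\].
#' @export
similarity_matrix <- function(q, k) {
  qm <- if (inherits(q, "patch_set")) q$patches else q
  km <- if (inherits(k, "patch_set")) k$patches else k
  if (ncol(qm) != ncol(km))
    stop("similarity_matrix: patch vector lengths differ")
  tcrossprod(unit_rows(qm), unit_rows(km))
}

#' Hard patch matching: index map and score map
#'
#' Per query patch, the argmax over key patches (index map P) and the
#' attained maximum similarity (score map C). Ties break to the smallest
#' index.
#'
#' @param m similarity matrix (finite, non-empty).
#' @return list with integer `index_map` and numeric `score_map`.
#' @export
hard_match <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("hard_match: empty similarity matrix")
  if (!all(is.finite(m))) stop("hard_match: non-finite similarity values")
  p <- max.col(m, ties.method = "first")
  list(index_map = p, score_map = m[cbind(seq_len(nrow(m)), p)])
}

## ---- node-level SAT ---------------------------------------------------------

## f_cwt, f_ref (value), f_ref_blur (key) are (H*W) x C nodes on the same
## grid. Returns list(out = F_SAT node, mean_confidence).
sat_nd <- function(f_cwt, f_ref, f_ref_blur, pp, H, W, cfg) {
  C <- ncol(nval(f_cwt))
  p <- cfg$sat_patch_size %||% 3L
  s <- cfg$sat_stride %||% 1L
  if (isTRUE(cfg$disable_kv_matching)) {
    vprime <- if (isTRUE(cfg$disable_fcwt_fusion)) f_ref
    else ad_cbind(f_cwt, f_ref)
    fused <- ad_add_bias(ad_matmul(vprime, pp$fuse_w), pp$fuse_b)
    return(list(out = fused, mean_confidence = NA_real_))
  }
  geom <- patch_geom(H, W, as.integer(p), as.integer(s))
  q <- ad_matmul(f_cwt, pp$w_qprime)
  qp <- ad_unfold(q, geom)
  kp <- ad_unfold(f_ref_blur, geom)
  vp <- ad_unfold(f_ref, geom)
  sim <- tcrossprod(unit_rows(nval(qp)), unit_rows(nval(kp)))
  mt <- hard_match(sim)
  if (isTRUE(cfg$disable_index_map)) {
    ## soft-attention comparator: softmax-weighted average of value patches
    ## (weights treated as constants in the backward pass)
    wsoft <- exp(sim - apply(sim, 1L, max))
    wsoft <- wsoft / rowSums(wsoft)
    retrieved <- ad_matmul(ad_const(wsoft), vp)
  } else {
    retrieved <- ad_gather_rows(vp, mt$index_map)
  }
  tex <- ad_fold_mean(retrieved, geom, C)
  vprime <- if (isTRUE(cfg$disable_fcwt_fusion)) tex
  else ad_cbind(f_cwt, tex)
  fused <- ad_add_bias(ad_matmul(vprime, pp$fuse_w), pp$fuse_b)
  if (!isTRUE(cfg$disable_score_map)) {
    ## confidence on-tape: cosine of the selected pair per query patch
    conf <- ad_rowdot(ad_unit_rows(qp),
                      ad_gather_rows(ad_unit_rows(kp), mt$index_map))
    conf_patch <- ad_matmul(ad_set_dim(conf, c(geom$n_out, 1L)),
                            matrix(1, 1L, geom$kk))
    conf_pix <- ad_fold_mean(conf_patch, geom, 1L)
    fused <- ad_mul_rows(fused, ad_set_dim(conf_pix, H * W))
  }
  list(out = fused, mean_confidence = mean(mt$score_map))
}

#' Retrieve matched reference patches and fuse with structural features
#'
#' Gathers value patch `P[i]` for each query location, folds the retrieved
#' patches back to the working grid with overlap averaging (texture map T),
#' concatenates `[F_CWT, T]` channel-wise, refines by a 1x1 convolution and
#' modulates by the confidence score map broadcast to pixels through the
#' same fold.
#'
#' @param v value feature map (H x W x C array) from the reference branch.
#' @param match result of [hard_match()] for the same patch geometry.
#' @param f_cwt structural feature map on the working grid.
#' @param p,s patch side and stride used for matching.
#' @param fusion_params list from [init_sat_params()] (`fuse_w`, `fuse_b`).
#' @param disable_score_map skip the confidence product (ablation).
#' @param disable_fcwt_fusion fuse the retrieved texture alone (ablation;
#'   `fuse_w` must then be C x C).
#' @return H x W x C numeric array (F_SAT).
#' @export
transfer_and_fuse <- function(v, match, f_cwt, p, s, fusion_params,
                              disable_score_map = FALSE,
                              disable_fcwt_fusion = FALSE) {
  d <- dim(f_cwt)
  geom <- patch_geom(d[1L], d[2L], as.integer(p), as.integer(s))
  if (length(match$index_map) != geom$n_out)
    stop("transfer_and_fuse: match geometry does not fit the feature map")
  vp <- ad_unfold(ad_const(fm_mat(v)), geom)
  retrieved <- ad_gather_rows(vp, match$index_map)
  tex <- ad_fold_mean(retrieved, geom, d[3L])
  vprime <- if (disable_fcwt_fusion) tex
  else ad_cbind(ad_const(fm_mat(f_cwt)), tex)
  fused <- ad_add_bias(ad_matmul(vprime, fusion_params$fuse_w),
                       fusion_params$fuse_b)
  if (!disable_score_map) {
    cpix <- fold_scalar_mean(match$score_map, geom)
    fused <- ad_mul_rows(fused, cpix)
  }
  fm_arr(nval(fused), d[1L], d[2L])
}
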