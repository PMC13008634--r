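## Channel-Wise Transformer: attention computed over the channel dimension.
## Q/K/V are linear projections of the (HW) x C feature matrix, transposed to
## C x HW so the attention map is C x C and captures inter-channel
## dependencies; the block wraps the attention as LN-CWT-LN-MLP with pre-norm
## residuals. In this attention design the logits carry no 1/sqrt(d)
## scaling; an optional temperature is exposed instead.

## ---- initializers ----------------------------------------------------------

trunc_normal <- function(n, sd = 0.02) pmin(pmax(stats::rnorm(n, 0, sd),
                                                 -2 * sd), 2 * sd)

init_linear <- function(c_in, c_out) matrix(trunc_normal(c_in * c_out),
                                            c_in, c_out)

## fan-in scaled conv kernel, stored as (k*k*c_in) x c_out
init_conv <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
}

#' Initialize standalone CWT block parameters
#'
#' @param channels feature channels C.
#' @param mlp_ratio expansion ratio of the position-wise MLP (default 2).
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
init_cwt_params <- function(channels, mlp_ratio = 2, seed = 0L) {
  C <- channels
  hid <- round(C * mlp_ratio)
  with_seed_local(seed, list(
    ln1_g = rep(1, C), ln1_b = rep(0, C),
    w_q = init_linear(C, C), w_k = init_linear(C, C), w_v = init_linear(C, C),
    ln2_g = rep(1, C), ln2_b = rep(0, C),
    mlp_w1 = init_linear(C, hid), mlp_b1 = rep(0, hid),
    mlp_w2 = init_linear(hid, C), mlp_b2 = rep(0, C)
  ))
}

## ---- node-level building blocks --------------------------------------------

## Q/K/V channel projections of an N x C node: returns C x N nodes
channel_projections_nd <- function(x, w_q, w_k, w_v) {
  list(q = ad_transpose(ad_matmul(x, w_q)),
       k = ad_transpose(ad_matmul(x, w_k)),
       v = ad_transpose(ad_matmul(x, w_v)))
}

## channel attention on C x N nodes; returns list(attention C x C, out N x C)
channel_attention_nd <- function(q, k, v, temperature = 1) {
  logits <- ad_matmul(q, ad_transpose(k))
  if (temperature != 1) logits <- ad_scale(logits, temperature)
  a <- ad_softmax_rows(logits)
  list(attention = a, out = ad_transpose(ad_matmul(a, v)))
}

## full LN-CWT-LN-MLP block on an N x C node
cwt_block_nd <- function(x, pp, temperature = 1) {
  xn <- ad_layernorm_rows(x, pp$ln1_g, pp$ln1_b)
  qkv <- channel_projections_nd(xn, pp$w_q, pp$w_k, pp$w_v)
  att <- channel_attention_nd(qkv$q, qkv$k, qkv$v, temperature)
  x2 <- ad_add(x, att$out)
  xn2 <- ad_layernorm_rows(x2, pp$ln2_g, pp$ln2_b)
  h <- ad_gelu(ad_add_bias(ad_matmul(xn2, pp$mlp_w1), pp$mlp_b1))
  mlp <- ad_add_bias(ad_matmul(h, pp$mlp_w2), pp$mlp_b2)
  ad_add(x2, mlp)
}

## ---- public array-level API -------------------------------------------------

#' Channel-domain Q/K/V projections
#'
#' Flattens an H x W x C feature map to (HW) x C, applies the three learnable
#' C x C projections and transposes, yielding C x (HW) matrices ready for
#' channel attention.
#'
#' @param f_in H x W x C numeric array.
#' @param weights list with C x C matrices `w_q`, `w_k`, `w_v`.
#' @return list of matrices `q`, `k`, `v`, each C x (H*W).
#' @export
channel_projections <- function(f_in, weights) {
  m <- fm_mat(f_in)
  C <- ncol(m)
  for (nm in c("w_q", "w_k", "w_v"))
    if (!all(dim(weights[[nm]]) == c(C, C)))
      stop("channel_projections: ", nm, " must be ", C, "x", C)
  list(q = t(m %*% weights$w_q), k = t(m %*% weights$w_k),
       v = t(m %*% weights$w_v))
}

#' Channel attention
#'
#' Computes `softmax(Q K^T)` over channel pairs (rows sum to 1) and applies
#' it to V, restoring the spatial layout. No 1/sqrt(d) scaling is applied;
#' `temperature` optionally multiplies the logits.
#'
#' @param q,k,v C x (H*W) matrices (see [channel_projections()]).
#' @param h,w spatial extents used to restore the output feature map.
#' @param temperature optional logit multiplier (default 1).
#' @return list with `attention` (C x C) and `output` (H x W x C array).
#' @export
channel_attention <- function(q, k, v, h, w, temperature = 1) {
  if (!all(is.finite(q)) || !all(is.finite(k)) || !all(is.finite(v)))
    stop("channel_attention: non-finite input")
  stopifnot(ncol(q) == ncol(k), ncol(k) == ncol(v), nrow(q) == nrow(k))
  res <- channel_attention_nd(ad_const(q), ad_const(k), ad_const(v),
                              temperature)
  list(attention = res$attention$value,
       output = fm_arr(res$out$value, h, w))
}

#' Channel-wise transformer block
#'
#' Pre-norm residual block `x = f + Attn(LN(f)); out = x + MLP(LN(x))` where
#' the attention acts over channels. Output shape equals input shape.
#'
#' @param f_in H x W x C numeric array.
#' @param params parameter list from [init_cwt_params()].
#' @param temperature optional logit multiplier.
#' @return H x W x C numeric array.
#' @export
cwt_block <- function(f_in, params, temperature = 1) {
  m <- fm_mat(f_in)
  out <- cwt_block_nd(ad_const(m), lapply(params, ad_const), temperature)
  fm_arr(out$value, dim(f_in)[1L], dim(f_in)[2L])
}

## ---- structural-model ablation variants -------------------------------------

#' Initialize parameters for a structural-model variant
#'
#' Alternatives to the channel-wise transformer used in ablations: plain
#' convolutions, squeeze-excite channel gating, or window-restricted spatial
#' self-attention. Each preserves the input/output contract of [cwt_block()].
#'
#' @param variant one of `"cwt"`, `"conv"`, `"se"`, `"window_attention"`.
#' @param channels feature channels.
#' @param mlp_ratio MLP expansion ratio (transformer-style variants).
#' @param seed RNG seed.
#' @return named parameter list.
#' @export
init_structure_params <- function(variant, channels, mlp_ratio = 2,
                                  seed = 0L) {
  C <- channels
  switch(variant,
         cwt = init_cwt_params(C, mlp_ratio, seed),
         conv = with_seed_local(seed, list(
           conv1_w = init_conv(3L, C, C), conv1_b = rep(0, C),
           conv2_w = init_conv(3L, C, C), conv2_b = rep(0, C))),
         se = with_seed_local(seed, {
           hid <- max(1L, C %/% 4L)
           p <- init_cwt_params(C, mlp_ratio, seed)
           p$w_q <- p$w_k <- p$w_v <- NULL
           c(p, list(se_w1 = init_linear(C, hid), se_b1 = rep(0, hid),
                     se_w2 = init_linear(hid, C), se_b2 = rep(0, C)))
         }),
         window_attention = with_seed_local(seed, {
           p <- init_cwt_params(C, mlp_ratio, seed)
           p  # same parameter shapes; attention runs spatially per window
         }),
         stop("unknown structural variant: ", variant))
}

## window partition index: orders pixels window-by-window (column-major
## windows, column-major pixels inside); map must be divisible by win
window_index <- function(H, W, win) {
  stopifnot(H %% win == 0L, W %% win == 0L)
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  wr <- (r - 1L) %/% win
  wc <- (c - 1L) %/% win
  widx <- wr + wc * (H %/% win)                 # window id, 0-based
  inner <- ((r - 1L) %% win) + ((c - 1L) %% win) * win
  ord <- order(widx, inner)
  list(gather = ord, n_win = (H %/% win) * (W %/% win), tokens = win * win)
}

## spatial self-attention in non-overlapping windows (single head, scaled)
wmsa_nd <- function(x, pp, H, W, win) {
  C <- ncol(nval(x))
  wi <- window_index(H, W, win)
  xg <- ad_gather_rows(x, wi$gather)
  outs <- vector("list", wi$n_win)
  sc <- 1 / sqrt(C)
  for (b in seq_len(wi$n_win)) {
    rows <- (b - 1L) * wi$tokens + seq_len(wi$tokens)
    xb <- ad_gather_rows(xg, rows)
    qb <- ad_matmul(xb, pp$w_q)
    kb <- ad_matmul(xb, pp$w_k)
    vb <- ad_matmul(xb, pp$w_v)
    a <- ad_softmax_rows(ad_scale(ad_matmul(qb, ad_transpose(kb)), sc))
    outs[[b]] <- ad_matmul(a, vb)
  }
  stacked <- ad_rbind_list(outs)
  inv <- integer(length(wi$gather))
  inv[wi$gather] <- seq_along(wi$gather)
  ad_gather_rows(stacked, inv)
}

## dispatch the structural branch of one HFAG stage
structure_block_variant_nd <- function(x, pp, variant, H, W, cfg) {
  switch(variant,
         cwt = cwt_block_nd(x, pp, cfg$cwt_temperature %||% 1),
         conv = {
           h <- ad_relu(ad_conv2d(x, pp$conv1_w, pp$conv1_b, H, W, 3L))
           ad_add(x, ad_conv2d(h, pp$conv2_w, pp$conv2_b, H, W, 3L))
         },
         se = {
           xn <- ad_layernorm_rows(x, pp$ln1_g, pp$ln1_b)
           pooled <- ad_set_dim(ad_colmeans(xn), c(1L, ncol(nval(x))))
           g1 <- ad_relu(ad_add_bias(ad_matmul(pooled, pp$se_w1), pp$se_b1))
           gates <- ad_sigmoid(ad_add_bias(ad_matmul(g1, pp$se_w2), pp$se_b2))
           att <- ad_mul_cols(xn, ad_set_dim(gates, ncol(nval(x))))
           x2 <- ad_add(x, att)
           xn2 <- ad_layernorm_rows(x2, pp$ln2_g, pp$ln2_b)
           h <- ad_gelu(ad_add_bias(ad_matmul(xn2, pp$mlp_w1), pp$mlp_b1))
           ad_add(x2, ad_add_bias(ad_matmul(h, pp$mlp_w2), pp$mlp_b2))
         },
         window_attention = {
           xn <- ad_layernorm_rows(x, pp$ln1_g, pp$ln1_b)
           win <- cfg$window_size %||% 8L
           if (H %% win != 0L || W %% win != 0L)
             win <- max(1L, gcd_int(H, W))
           att <- wmsa_nd(xn, pp, H, W, win)
           x2 <- ad_add(x, att)
           xn2 <- ad_layernorm_rows(x2, pp$ln2_g, pp$ln2_b)
           h <- ad_gelu(ad_add_bias(ad_matmul(xn2, pp$mlp_w1), pp$mlp_b1))
           ad_add(x2, ad_add_bias(ad_matmul(h, pp$mlp_w2), pp$mlp_b2))
         },
         stop("unknown structural variant: ", variant))
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}
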