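## Spatial operators built on the gather/scatter autodiff primitives.
##
## Feature maps travel through the network as (H*W) x C matrices in
## column-major spatial order (row index = h + (w-1)*H). Convolution is
## im2col + matmul where im2col is a single precomputed row-gather, so both
## the forward and the backward pass are one BLAS call plus one rowsum().

.geom_cache <- new.env(parent = emptyenv())

## reflect an out-of-range coordinate into 1..n (no edge repetition)
reflect_coord <- function(p, n) {
  if (n == 1L) return(rep(1L, length(p)))
  period <- 2L * (n - 1L)
  q <- (p - 1L) %% period
  q <- ifelse(q >= n, period - q, q)
  q + 1L
}

#' Convolution/patch geometry for a feature grid
#'
#' Precomputes (and caches) the gather index that turns an (H*W) x C feature
#' matrix into im2col patch rows, using reflection padding.
#'
#' @param H,W spatial extents of the source grid.
#' @param k patch/kernel side length.
#' @param stride sampling stride.
#' @param pad_lo pixels of reflection padding added before row/col 1.
#' @param pad_hi pixels added after the last row/col (defaults to `pad_lo`).
#' @return list with `col_idx` (gather index, output-position fastest),
#'   `H_out`, `W_out`, `n_out`, `kk`, and the padded extent.
#' @keywords internal
conv_geom <- function(H, W, k, stride = 1L, pad_lo = (k - 1L) %/% 2L,
                      pad_hi = pad_lo) {
  key <- paste(H, W, k, stride, pad_lo, pad_hi, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + pad_lo + pad_hi
  Wp <- W + pad_lo + pad_hi
  stopifnot(k <= Hp, k <= Wp)
  H_out <- (Hp - k) %/% stride + 1L
  W_out <- (Wp - k) %/% stride + 1L
  n_out <- H_out * W_out
  ## source row/col for each padded coordinate
  src_r <- reflect_coord(seq_len(Hp) - pad_lo, H)
  src_c <- reflect_coord(seq_len(Wp) - pad_lo, W)
  ## top-left padded coords of each output position (column-major order)
  r0 <- rep(seq.int(1L, by = stride, length.out = H_out), times = W_out)
  c0 <- rep(seq.int(1L, by = stride, length.out = W_out), each = H_out)
  ## offsets enumerated dr fastest, then dc (matches column-major kernel flatten)
  kk <- k * k
  dr <- rep(seq_len(k) - 1L, times = k)
  dc <- rep(seq_len(k) - 1L, each = k)
  ## col_idx[l], l = i + (j-1)*n_out : padded pixel of offset j at output i,
  ## mapped straight to the unpadded source via the reflection tables
  col_idx <- integer(n_out * kk)
  for (j in seq_len(kk)) {
    rr <- src_r[r0 + dr[j]]
    cc <- src_c[c0 + dc[j]]
    col_idx[(j - 1L) * n_out + seq_len(n_out)] <- rr + (cc - 1L) * H
  }
  g <- list(col_idx = col_idx, H_out = H_out, W_out = W_out, n_out = n_out,
            kk = kk, Hp = Hp, Wp = Wp, k = k, stride = stride,
            pad_lo = pad_lo, pad_hi = pad_hi, H = H, W = W)
  .geom_cache[[key]] <- g
  g
}

## im2col as an autodiff op: (H*W) x C  ->  n_out x (k*k*C)
ad_im2col <- function(x, geom) {
  C <- ncol(nval(x))
  cols <- ad_gather_rows(x, geom$col_idx)
  ad_set_dim(cols, c(geom$n_out, geom$kk * C))
}

#' 2D convolution over an (H*W) x C feature matrix
#'
#' Reflection padding, kernel stored as a (k*k*C_in) x C_out matrix whose rows
#' follow the column-major flatten of a (k, k, C_in) array.
#'
#' @param x `ad_node` or matrix, (H*W) x C_in.
#' @param w kernel matrix (k*k*C_in) x C_out.
#' @param b optional bias, length C_out.
#' @param H,W spatial extents of `x`.
#' @param k kernel side; `stride` sampling stride.
#' @return `ad_node`, (H_out*W_out) x C_out.
#' @keywords internal
ad_conv2d <- function(x, w, b = NULL, H, W, k = 3L, stride = 1L) {
  geom <- conv_geom(H, W, k, stride)
  out <- ad_matmul(ad_im2col(x, geom), w)
  if (!is.null(b)) out <- ad_add_bias(out, b)
  out
}

conv_out_hw <- function(H, W, k = 3L, stride = 1L) {
  g <- conv_geom(H, W, k, stride)
  c(g$H_out, g$W_out)
}

#' Patch-grid geometry used by the alignment transformer
#'
#' Pads only the bottom/right edge (reflection) so that a patch grid of size
#' `p` with stride `s` tiles the map exactly; enumeration is row-major over
#' the grid in the column-major pixel sense (grid rows fastest).
#'
#' @param H,W source extents; `p` patch side; `s` stride (1 <= s <= p).
#' @return geometry list as [conv_geom()] plus `grid = c(rows, cols)` and the
#'   per-pixel overlap `counts` used by the averaging fold.
#' @keywords internal
patch_geom <- function(H, W, p, s) {
  stopifnot(p >= 1L, s >= 1L, s <= p)
  gr <- if (H <= p) 1L else as.integer(ceiling((H - p) / s)) + 1L
  gc <- if (W <= p) 1L else as.integer(ceiling((W - p) / s)) + 1L
  pad_h <- (gr - 1L) * s + p - H
  pad_w <- (gc - 1L) * s + p - W
  key <- paste("patch", H, W, p, s, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (p > H + pad_h || p > W + pad_w) stop("patch size exceeds padded map")
  Hp <- H + pad_h
  Wp <- W + pad_w
  src_r <- reflect_coord(seq_len(Hp), H)
  src_c <- reflect_coord(seq_len(Wp), W)
  n_out <- gr * gc
  kk <- p * p
  r0 <- rep(seq.int(1L, by = s, length.out = gr), times = gc)
  c0 <- rep(seq.int(1L, by = s, length.out = gc), each = gr)
  dr <- rep(seq_len(p) - 1L, times = p)
  dc <- rep(seq_len(p) - 1L, each = p)
  col_idx <- integer(n_out * kk)
  for (j in seq_len(kk)) {
    rr <- src_r[r0 + dr[j]]
    cc <- src_c[c0 + dc[j]]
    col_idx[(j - 1L) * n_out + seq_len(n_out)] <- rr + (cc - 1L) * H
  }
  counts <- tabulate(col_idx, nbins = H * W)
  g <- list(col_idx = col_idx, n_out = n_out, kk = kk, grid = c(gr, gc),
            H = H, W = W, p = p, s = s, counts = counts)
  .geom_cache[[key]] <- g
  g
}

## unfold into patch rows: n_patches x (p*p*C)
ad_unfold <- function(x, geom) {
  C <- ncol(nval(x))
  cols <- ad_gather_rows(x, geom$col_idx)
  ad_set_dim(cols, c(geom$n_out, geom$kk * C))
}

## overlap-averaging fold: n_patches x (p*p*C) -> (H*W) x C
ad_fold_mean <- function(patches, geom, C) {
  flat <- ad_set_dim(patches, c(geom$n_out * geom$kk, C))
  acc <- ad_scatter_rows(flat, geom$col_idx, geom$H * geom$W)
  ad_mul_rows(acc, 1 / pmax(geom$counts, 1L))
}

## broadcast one scalar per patch over its footprint, overlap-averaged;
## returns a plain length-(H*W) vector (scores are used as weights)
fold_scalar_mean <- function(scores, geom) {
  flat <- rep(scores, times = geom$kk)
  acc <- rowsum(flat, group = geom$col_idx)
  out <- numeric(geom$H * geom$W)
  out[as.integer(rownames(acc))] <- acc
  out / pmax(geom$counts, 1L)
}

#' Pixel-shuffle permutation index
#'
#' Output pixel `(r_out, c_out)` of channel `c` (1-based) reads input channel
#' `(c-1)*s^2 + dr*s + dc + 1` at pixel `(r_in, c_in)` where
#' `r_out = (r_in-1)*s + dr + 1`, `c_out = (c_in-1)*s + dc + 1`.
#'
#' @param H,W input extents; `C_out` output channels; `s` upscale factor.
#' @return integer permutation over the flattened (column-major) matrices.
#' @keywords internal
pixel_shuffle_index <- function(H, W, C_out, s) {
  key <- paste("ps", H, W, C_out, s, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H * s; Wo <- W * s
  n_in <- H * W
  n_out <- Ho * Wo
  perm <- integer(n_out * C_out)
  ro <- rep(seq_len(Ho), times = Wo)          # output rows, column-major
  co <- rep(seq_len(Wo), each = Ho)
  ri <- (ro - 1L) %/% s + 1L
  ci <- (co - 1L) %/% s + 1L
  dr <- (ro - 1L) %% s
  dc <- (co - 1L) %% s
  pix_in <- ri + (ci - 1L) * H
  for (c in seq_len(C_out)) {
    ch_in <- (c - 1L) * s * s + dr * s + dc + 1L
    perm[(c - 1L) * n_out + seq_len(n_out)] <- pix_in + (ch_in - 1L) * n_in
  }
  .geom_cache[[key]] <- perm
  perm
}

## pixel shuffle: (H*W) x (C*s^2) -> (H*s*W*s) x C
ad_pixel_shuffle <- function(x, H, W, s) {
  vx <- nval(x)
  C_out <- ncol(vx) %/% (s * s)
  stopifnot(C_out * s * s == ncol(vx))
  perm <- pixel_shuffle_index(H, W, C_out, s)
  flat <- ad_set_dim(x, c(length(vx), 1L))
  shuffled <- ad_gather_rows(flat, perm)
  ad_set_dim(shuffled, c(H * W * s * s, C_out))
}

## non-overlapping s x s average pooling: (H*W) x C -> (H/s * W/s) x C
ad_avg_pool <- function(x, H, W, s) {
  stopifnot(H %% s == 0L, W %% s == 0L)
  Ho <- H %/% s; Wo <- W %/% s
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  cell <- ((r - 1L) %/% s + 1L) + ((c - 1L) %/% s) * Ho
  pooled <- ad_scatter_rows(x, cell, Ho * Wo)
  ad_scale(pooled, 1 / (s * s))
}

## nearest-neighbour upsample: (H*W) x C -> (H*s * W*s) x C
ad_nn_upsample <- function(x, H, W, s) {
  Ho <- H * s; Wo <- W * s
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  idx <- ((ro - 1L) %/% s + 1L) + ((co - 1L) %/% s) * H
  ad_gather_rows(x, idx)
}

## ---- array <-> matrix conversions for the public API ----------------------

#' Convert an H x W x C array to the internal (H*W) x C matrix
#' @param a 3D array (or H x W matrix treated as C = 1).
#' @return matrix with attributes `fm_h`, `fm_w`.
#' @keywords internal
fm_mat <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  m <- matrix(a, d[1L] * d[2L], d[3L])
  attr(m, "fm_h") <- d[1L]
  attr(m, "fm_w") <- d[2L]
  m
}

#' Convert an internal (H*W) x C matrix back to an H x W x C array
#' @param m matrix; `H`, `W` spatial extents (default from attributes).
#' @keywords internal
fm_arr <- function(m, H = attr(m, "fm_h"), W = attr(m, "fm_w")) {
  array(m, dim = c(H, W, ncol(m)))
}
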