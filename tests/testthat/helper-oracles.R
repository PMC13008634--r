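## Independent brute-force oracles: plain scalar loops, sharing no code with
## the package's vectorized implementations.

rand_fm <- function(H, W, C, sd = 1) array(rnorm(H * W * C, 0, sd),
                                           dim = c(H, W, C))

## scalar reflection of an out-of-range coordinate into 1..n
refl1 <- function(q, n) {
  if (n == 1) return(1)
  while (q < 1 || q > n) {
    if (q < 1) q <- 2 - q
    if (q > n) q <- 2 * n - q
  }
  q
}

## direct convolution of an H x W x Cin array with a k x k x Cin x Cout
## kernel array, reflection padding, arbitrary stride
oracle_conv2d <- function(x, w_arr, bias, stride = 1L) {
  k <- dim(w_arr)[1L]
  H <- dim(x)[1L]; W <- dim(x)[2L]
  Cin <- dim(x)[3L]; Cout <- dim(w_arr)[4L]
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, Cout))
  for (r in seq_len(Ho)) for (c in seq_len(Wo)) for (co in seq_len(Cout)) {
    acc <- bias[co]
    for (dr in 0:(k - 1)) for (dc in 0:(k - 1)) for (ci in seq_len(Cin)) {
      sr <- refl1((r - 1L) * stride + 1L + dr - pad, H)
      sc <- refl1((c - 1L) * stride + 1L + dc - pad, W)
      acc <- acc + x[sr, sc, ci] * w_arr[dr + 1L, dc + 1L, ci, co]
    }
    out[r, c, co] <- acc
  }
  out
}

## package kernel matrix ((k*k*Cin) x Cout, offsets row-fastest) -> 4D array
kernel_mat_to_array <- function(wm, k, Cin, Cout) {
  array(wm, dim = c(k, k, Cin, Cout))
}

## channel attention from first principles, elementwise loops
oracle_channel_attention <- function(Q, K, V, tau = 1) {
  C <- nrow(Q); N <- ncol(Q)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C))
    A[i, j] <- sum(Q[i, ] * K[j, ]) * tau
  for (i in seq_len(C)) {
    e <- exp(A[i, ] - max(A[i, ]))
    A[i, ] <- e / sum(e)
  }
  out <- matrix(0, N, C)
  for (n in seq_len(N)) for (c in seq_len(C))
    out[n, c] <- sum(A[c, ] * V[, n])
  list(attention = A, out = out)
}

## cosine similarity by explicit double loop
oracle_cosine <- function(qm, km) {
  M <- matrix(0, nrow(qm), nrow(km))
  for (i in seq_len(nrow(qm))) for (j in seq_len(nrow(km))) {
    nq <- sqrt(sum(qm[i, ]^2)); nk <- sqrt(sum(km[j, ]^2))
    M[i, j] <- if (nq == 0 || nk == 0) 0 else sum(qm[i, ] * km[j, ]) / (nq * nk)
  }
  M
}

## naive patch extraction on an H x W x C array (same geometry convention:
## grid rows fastest, bottom/right reflection padding, offsets row-fastest
## then column, channel slowest)
oracle_patches <- function(f, p, s) {
  H <- dim(f)[1L]; W <- dim(f)[2L]; C <- dim(f)[3L]
  gr <- if (H <= p) 1L else as.integer(ceiling((H - p) / s)) + 1L
  gc <- if (W <= p) 1L else as.integer(ceiling((W - p) / s)) + 1L
  out <- matrix(0, gr * gc, p * p * C)
  for (j in seq_len(gc)) for (i in seq_len(gr)) {
    idx <- i + (j - 1L) * gr
    v <- numeric(0)
    for (ci in seq_len(C)) for (dc in 0:(p - 1)) for (dr in 0:(p - 1)) {
      sr <- refl1((i - 1L) * s + 1L + dr, H)
      sc <- refl1((j - 1L) * s + 1L + dc, W)
      v <- c(v, f[sr, sc, ci])
    }
    out[idx, ] <- v
  }
  list(patches = out, grid = c(gr, gc))
}

## naive transfer-and-fuse: materialize every retrieved patch, average
## overlaps per pixel, concat, 1x1 conv, confidence product
oracle_transfer_fuse <- function(v, index_map, score_map, f_cwt, p, s,
                                 fuse_w, fuse_b, use_score = TRUE) {
  H <- dim(f_cwt)[1L]; W <- dim(f_cwt)[2L]; C <- dim(f_cwt)[3L]
  vp <- oracle_patches(v, p, s)
  gr <- vp$grid[1L]; gc <- vp$grid[2L]
  acc <- array(0, dim = c(H, W, C)); cnt <- matrix(0, H, W)
  cacc <- matrix(0, H, W)
  for (j in seq_len(gc)) for (i in seq_len(gr)) {
    q <- i + (j - 1L) * gr
    patch <- array(vp$patches[index_map[q], ], dim = c(p, p, C))
    for (dc in 0:(p - 1)) for (dr in 0:(p - 1)) {
      sr <- refl1((i - 1L) * s + 1L + dr, H)
      sc <- refl1((j - 1L) * s + 1L + dc, W)
      acc[sr, sc, ] <- acc[sr, sc, ] + patch[dr + 1L, dc + 1L, ]
      cnt[sr, sc] <- cnt[sr, sc] + 1
      cacc[sr, sc] <- cacc[sr, sc] + score_map[q]
    }
  }
  tex <- acc / array(rep(pmax(cnt, 1), C), dim = c(H, W, C))
  cpix <- cacc / pmax(cnt, 1)
  out <- array(0, dim = c(H, W, ncol(fuse_w)))
  for (r in seq_len(H)) for (c in seq_len(W)) {
    vprime <- c(f_cwt[r, c, ], tex[r, c, ])
    y <- as.vector(vprime %*% fuse_w) + fuse_b
    if (use_score) y <- y * cpix[r, c]
    out[r, c, ] <- y
  }
  out
}

## tiny helpers reused across files
tiny_sample <- function(size = 32L, scale = 2L, seed = 1L,
                        ref_seed = seed + 1L) {
  hr <- generate_phantom(phantom_params(size = size, seed = seed))
  ref <- generate_phantom(phantom_params(size = size, seed = ref_seed))
  make_training_sample(crop_to_multiple(hr, scale),
                       crop_to_multiple(ref, scale), scale)
}

tiny_model <- function(channels = 8L, n_hfag = 1L, scale = 2L, seed = 7L,
                       ...) {
  init_daasr(daasr_config(channels = channels, n_hfag = n_hfag,
                          scale = scale, seed = seed, ...))
}
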