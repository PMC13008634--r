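## Central finite-difference checks of the reverse-mode engine on the ops
## the network is built from.

ad <- asNamespace("daasr")

fd_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("matmul, bias, softmax and layernorm gradients match finite differences", {
  set.seed(11)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(6), 3, 2)
  b <- rnorm(2)
  run <- function(av) {
    an <- ad$ad_const(matrix(av, 4, 3))
    out <- ad$ad_softmax_rows(ad$ad_add_bias(ad$ad_matmul(an, B), b))
    loss <- ad$ad_sum(ad$ad_mul(out, out))
    list(val = ad$nval(loss), node = an, root = loss)
  }
  r <- run(A)
  ad$ad_backward(r$root)
  expect_equal(as.vector(r$node$grad),
               fd_grad(function(v) run(v)$val, as.vector(A)),
               tolerance = 1e-6)

  g <- rnorm(3); be <- rnorm(3)
  X <- matrix(rnorm(15), 5, 3)
  runln <- function(xv) {
    xn <- ad$ad_const(matrix(xv, 5, 3))
    out <- ad$ad_layernorm_rows(xn, g, be)
    loss <- ad$ad_mean(ad$ad_mul(out, out))
    list(val = ad$nval(loss), node = xn, root = loss)
  }
  r2 <- runln(X)
  ad$ad_backward(r2$root)
  expect_equal(as.vector(r2$node$grad),
               fd_grad(function(v) runln(v)$val, as.vector(X)),
               tolerance = 1e-6)
})

test_that("strided reflection-padded convolution gradients match finite differences", {
  set.seed(12)
  H <- 6L; W <- 5L; Cin <- 2L; Cout <- 3L
  x <- matrix(rnorm(H * W * Cin), H * W, Cin)
  wm <- matrix(rnorm(9 * Cin * Cout, 0, 0.4), 9 * Cin, Cout)
  bias <- rnorm(Cout)
  for (stride in c(1L, 2L)) {
    run <- function(xv, wv) {
      xn <- ad$ad_const(matrix(xv, H * W, Cin))
      wn <- ad$ad_const(matrix(wv, 9 * Cin, Cout))
      out <- ad$ad_relu(ad$ad_conv2d(xn, wn, bias, H, W, 3L, stride))
      loss <- ad$ad_sum(ad$ad_mul(out, out))
      list(val = ad$nval(loss), xn = xn, wn = wn, root = loss)
    }
    r <- run(x, wm)
    ad$ad_backward(r$root)
    expect_equal(as.vector(r$xn$grad),
                 fd_grad(function(v) run(v, wm)$val, as.vector(x)),
                 tolerance = 1e-5)
    expect_equal(as.vector(r$wn$grad),
                 fd_grad(function(v) run(x, v)$val, as.vector(wm)),
                 tolerance = 1e-5)
  }
})

test_that("batch-norm (training mode), GELU and sigmoid gradients match finite differences", {
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3)
  g <- runif(3, 0.5, 1.5); be <- rnorm(3)
  run <- function(xv) {
    st <- ad$bn_env(list(mean = rep(0, 3), var = rep(1, 3)))
    xn <- ad$ad_const(matrix(xv, 8, 3))
    out <- ad$ad_sigmoid(ad$ad_gelu(
      ad$ad_batchnorm_cols(xn, g, be, st, training = TRUE)))
    loss <- ad$ad_sum(ad$ad_mul(out, out))
    list(val = ad$nval(loss), xn = xn, root = loss)
  }
  r <- run(X)
  ad$ad_backward(r$root)
  expect_equal(as.vector(r$xn$grad),
               fd_grad(function(v) run(v)$val, as.vector(X)),
               tolerance = 1e-5)
})

test_that("patch unfold/fold, pixel shuffle and row-normalization gradients match finite differences", {
  set.seed(14)
  H <- 5L; W <- 4L; C <- 2L
  x <- matrix(rnorm(H * W * C), H * W, C)
  geom <- ad$patch_geom(H, W, 3L, 2L)
  run <- function(xv) {
    xn <- ad$ad_const(matrix(xv, H * W, C))
    up <- ad$ad_unfold(xn, geom)
    fo <- ad$ad_fold_mean(ad$ad_mul(up, up), geom, C)
    loss <- ad$ad_sum(fo)
    list(val = ad$nval(loss), xn = xn, root = loss)
  }
  r <- run(x)
  ad$ad_backward(r$root)
  expect_equal(as.vector(r$xn$grad),
               fd_grad(function(v) run(v)$val, as.vector(x)),
               tolerance = 1e-5)

  xs <- matrix(rnorm(3 * 4 * 8), 12, 8)   # 3x4 grid, 8 = 2 channels * 2^2
  runps <- function(xv) {
    xn <- ad$ad_const(matrix(xv, 12, 8))
    out <- ad$ad_pixel_shuffle(xn, 3L, 4L, 2L)
    loss <- ad$ad_mean(ad$ad_mul(out, out))
    list(val = ad$nval(loss), xn = xn, root = loss)
  }
  rp <- runps(xs)
  ad$ad_backward(rp$root)
  expect_equal(as.vector(rp$xn$grad),
               fd_grad(function(v) runps(v)$val, as.vector(xs)),
               tolerance = 1e-6)

  qm <- matrix(rnorm(12), 4, 3)
  km <- matrix(rnorm(12), 4, 3)
  rununit <- function(v) {
    qn <- ad$ad_const(matrix(v, 4, 3))
    u <- ad$ad_unit_rows(qn)
    d <- ad$ad_rowdot(u, ad$ad_unit_rows(ad$ad_const(km)))
    loss <- ad$ad_sum(ad$ad_mul(d, d))
    list(val = ad$nval(loss), qn = qn, root = loss)
  }
  ru <- rununit(qm)
  ad$ad_backward(ru$root)
  expect_equal(as.vector(ru$qn$grad),
               fd_grad(function(v) rununit(v)$val, as.vector(qm)),
               tolerance = 1e-5)
})
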