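## Phantom generation, bicubic degradation, LR/Ref pair construction and
## dihedral augmentation.

test_that("phantom generation is a pure, seed-sensitive function with distinct tissue regions", {
  p <- phantom_params(size = 64L, seed = 0L)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(64L, 64L))

  ## seed sensitivity: > 1% of pixels differ
  c2 <- generate_phantom(phantom_params(size = 64L, seed = 1L))
  expect_gt(mean(abs(a - c2) > 1e-6), 0.01)

  ## noise-free image: >= 3 sizeable connected regions at the exact
  ## configured levels (label by level sets, 4-connectivity flood fill)
  lv <- p$tissue_levels
  n_regions <- 0L
  for (l in lv) {
    mask <- abs(a - l) < 1e-6
    if (sum(mask) >= 20) n_regions <- n_regions + 1L
  }
  expect_gte(n_regions, 3L)

  ## invalid parameters rejected
  expect_error(phantom_params(size = 16L), "size")
  expect_error(phantom_params(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_params(tissue_levels = c(background = 0.1,
                                                skull = 0.1, csf = 0.3,
                                                gray = 0.5, white = 0.7)),
               "distinct")
})

test_that("noise options perturb the phantom but stay in range", {
  base <- generate_phantom(phantom_params(size = 64L, seed = 5L))
  g <- generate_phantom(phantom_params(size = 64L, seed = 5L,
                                       noise_sigma = 0.05))
  r <- generate_phantom(phantom_params(size = 64L, seed = 5L,
                                       noise_sigma = 0.05,
                                       noise_type = "rician"))
  expect_gt(sd(g - base), 0.01)
  expect_gt(sd(r - base), 0.01)
  expect_false(identical(g, r))
  expect_true(all(g >= 0 & g <= 1) && all(r >= 0 & r <= 1))
})

test_that("bicubic resize preserves constants, the identity, and round-trips smooth images", {
  const <- matrix(0.5, 16, 16)
  expect_lt(max(abs(bicubic_resize(const, 9, 13) - 0.5)), 1e-6)
  img <- generate_phantom(phantom_params(size = 64L, seed = 2L))
  expect_lt(max(abs(bicubic_resize(img, 64, 64) - img)), 1e-7)
  ## smooth low-frequency image survives a down/up round trip
  xs <- (seq_len(64) - 0.5) / 64
  smooth <- outer(sin(2 * pi * xs), cos(2 * pi * xs)) * 0.25 + 0.5
  rt <- bicubic_resize(bicubic_resize(smooth, 32, 32), 64, 64)
  expect_lt(max(abs(rt - smooth)), 0.05)
})

test_that("center cropping to a scale multiple follows the arithmetic", {
  img <- matrix(runif(256 * 256), 256, 256)
  expect_equal(dim(crop_to_multiple(img, 3L)), c(255L, 255L))
  expect_identical(crop_to_multiple(img, 2L), img)
  img2 <- matrix(runif(257 * 255), 257, 255)
  expect_equal(dim(crop_to_multiple(img2, 4L)), c(256L, 252L))
  expect_error(crop_to_multiple(matrix(0.1, 7, 9), 2L), "8x8")
})

test_that("training samples satisfy the shape contract and blur reduces total variation", {
  hr <- generate_phantom(phantom_params(size = 64L, seed = 3L))
  ref <- generate_phantom(phantom_params(size = 64L, seed = 4L))
  sm <- make_training_sample(hr, ref, 2L)
  expect_equal(dim(sm$lr), c(32L, 32L))
  expect_equal(dim(sm$ref_blurred), c(64L, 64L))
  expect_identical(sm$ref, ref)
  expect_error(make_training_sample(hr[1:63, ], ref[1:63, ], 2L), "crop")
  expect_error(make_training_sample(hr, ref[1:32, 1:32], 2L),
               "dimensions")

  cst <- make_training_sample(matrix(0.3, 64, 64), matrix(0.3, 64, 64), 2L)
  expect_lt(max(abs(cst$ref_blurred - 0.3)), 1e-6)

  ## high-frequency checkerboard loses total variation under 4x blur
  ck <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  smc <- make_training_sample(hr, ck, 2L, ref_blur_factor = 4L)
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  expect_lt(tv(smc$ref_blurred), tv(ck))

  ## upsampled LR stays a sane reconstruction of HR
  up <- bicubic_resize(sm$lr, 64, 64)
  expect_gt(psnr(up, sm$hr), 5)
})

test_that("augmentation applies one dihedral transform consistently and the group composes", {
  sm <- tiny_sample(size = 32L, seed = 9L)
  a1 <- augment(sm, seed = 3L)
  a2 <- augment(sm, seed = 3L)
  expect_identical(a1, a2)

  ## same transform on all four images: degrading the augmented HR matches
  ## the augmented LR up to interpolation error
  for (tr in 0:7) {
    at <- augment(sm, transform = tr)
    expect_identical(at$lr, apply_dihedral(sm$lr, tr))
    expect_identical(at$hr, apply_dihedral(sm$hr, tr))
    expect_identical(at$ref, apply_dihedral(sm$ref, tr))
    expect_identical(at$ref_blurred, apply_dihedral(sm$ref_blurred, tr))
  }

  ## involution: horizontal flip twice restores the sample
  expect_identical(augment(augment(sm, transform = 4L), transform = 4L), sm)

  ## 90-degree rotation transposes dimensions of a non-square crop
  hr <- matrix(runif(24 * 16), 24, 16)
  smn <- make_training_sample(hr, hr, 2L)
  rot <- augment(smn, transform = 1L)
  expect_equal(dim(rot$hr), c(16L, 24L))
  expect_equal(dim(rot$lr), c(8L, 12L))

  ## dihedral closure on a labelled image: composing transforms equals some
  ## single transform of the group
  lab <- matrix(seq_len(20), 4, 5)
  for (i in 0:7) for (j in c(0L, 1L, 4L)) {
    comp <- apply_dihedral(apply_dihedral(lab, i), j)
    matches <- vapply(0:7, function(k)
      identical(comp, apply_dihedral(lab, k)), logical(1))
    expect_true(any(matches))
  }
})
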