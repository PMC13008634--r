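## Model assembly: shapes, residual aggregation algebra, sub-pixel head,
## parameter accounting, determinism, checkpointing, gradient audit.

test_that("shallow extraction has the right shape and linearity", {
  set.seed(51)
  model <- tiny_model(channels = 8L)
  img <- matrix(runif(32 * 32), 32, 32)
  fe <- shallow_extract(img, model$params)
  expect_equal(dim(fe), c(32L, 32L, 8L))
  z <- shallow_extract(img, list(shallow_w = model$params$shallow_w * 0,
                                 shallow_b = model$params$shallow_b * 0))
  expect_true(all(z == 0))
  fc <- shallow_extract(matrix(0.7, 16, 16), model$params)
  for (cc in 1:8) expect_lt(diff(range(fc[, , cc])), 1e-10)
})

test_that("residual aggregation follows F_out = F_CWT + F_SAT + F_in, with the stated reduced forms", {
  set.seed(52)
  C <- 4L
  f <- rand_fm(8, 8, C)
  rfe <- rand_fm(8, 8, C); rfb <- rand_fm(8, 8, C)
  cwt_p <- init_cwt_params(C, seed = 1L)
  sat_p <- init_sat_params(C, seed = 2L)

  ## zeroed branch internals: CWT reduces to the identity, SAT to zero, so
  ## the aggregation rule yields exactly 2 * F_in per stage
  z_cwt <- cwt_p
  for (nm in c("w_q", "w_k", "w_v", "mlp_w1", "mlp_w2"))
    z_cwt[[nm]] <- z_cwt[[nm]] * 0
  z_sat <- sat_p
  z_sat$fuse_w <- z_sat$fuse_w * 0
  z_sat$fuse_b <- z_sat$fuse_b * 0
  prm <- list(cwt = z_cwt, sat = z_sat)
  cfg <- daasr_config(channels = C, n_hfag = 1L)
  out <- f
  for (k in 1:3) {
    out_next <- hfag_forward(out, rfe, rfb, prm, cfg)
    expect_equal(out_next, 2 * out, tolerance = 1e-10)
    out <- out_next
  }
  expect_equal(out, (2^3) * f, tolerance = 1e-9)

  ## disabled-branch reductions
  cfg_nosat <- daasr_config(channels = C, n_hfag = 1L, use_sat = FALSE)
  expect_equal(hfag_forward(f, rfe, rfb, list(cwt = z_cwt), cfg_nosat),
               2 * f, tolerance = 1e-10)
  cfg_none <- daasr_config(channels = C, n_hfag = 1L, use_cwt = FALSE,
                           use_sat = FALSE)
  for (k in 1:4)
    expect_equal(hfag_forward(f, rfe, rfb, list(), cfg_none), f)

  ## shape contract with live parameters
  live <- hfag_forward(f, rfe, rfb, list(cwt = cwt_p, sat = sat_p), cfg)
  expect_equal(dim(live), dim(f))
})

test_that("pixel rearrangement follows the index formula and the head respects the skip path", {
  ad <- asNamespace("daasr")
  ## 2 x 2 x 4 tensor, scale 2: enumerate target indices from the formula
  x <- matrix(seq_len(2 * 2 * 4), 4, 4)   # (H*W) x (C*s^2) with C_out = 1
  got <- ad$nval(ad$ad_pixel_shuffle(ad$ad_const(x), 2L, 2L, 2L))
  expected <- matrix(0, 16, 1)
  for (ro in 1:4) for (co in 1:4) {
    ri <- (ro - 1) %/% 2 + 1; ci <- (co - 1) %/% 2 + 1
    dr <- (ro - 1) %% 2; dc <- (co - 1) %% 2
    ch_in <- dr * 2 + dc + 1
    expected[ro + (co - 1) * 4, 1] <- x[ri + (ci - 1) * 2, ch_in]
  }
  expect_equal(got, expected)

  ## shape contract and bicubic-skip identity of the head
  set.seed(53)
  C <- 6L
  hp <- daasr:::init_head_params(C, 4L, seed = 9L)
  f <- rand_fm(16, 16, C)
  img4 <- upsample_head(f, 4L, hp)
  expect_equal(dim(img4), c(64L, 64L))

  lr <- matrix(runif(16 * 16), 16, 16)
  hp0 <- lapply(hp, function(p) p * 0)
  expect_equal(upsample_head(f, 4L, hp0, i_lr = lr),
               bicubic_resize(lr, 64, 64, clip = FALSE), tolerance = 1e-12)
})

test_that("the full forward pass is finite, shape-correct and deterministic in eval mode", {
  sm <- tiny_sample(size = 32L, seed = 61L)
  model <- tiny_model(channels = 8L, n_hfag = 2L)
  fw1 <- daasr_forward(sm$lr, sm$ref, sm$ref_blurred, model)
  fw2 <- daasr_forward(sm$lr, sm$ref, sm$ref_blurred, model)
  for (nm in c("i_sr", "i_cwt", "i_sat")) {
    expect_equal(dim(fw1[[nm]]), c(32L, 32L))
    expect_true(all(is.finite(fw1[[nm]])))
    expect_identical(fw1[[nm]], fw2[[nm]])
  }
  expect_length(fw1$diagnostics$stage_confidence, 2L)

  ## scale-3 path (odd grid) also closes shape-wise
  sm3 <- tiny_sample(size = 33L, scale = 3L, seed = 62L)
  m3 <- tiny_model(channels = 6L, n_hfag = 1L, scale = 3L)
  fw3 <- daasr_forward(sm3$lr, sm3$ref, sm3$ref_blurred, m3)
  expect_equal(dim(fw3$i_sr), dim(sm3$hr))

  ## alternative HR matching grid: match at HR, pool the result back
  mh <- tiny_model(channels = 6L, n_hfag = 1L, sat_grid = "hr")
  fwh <- daasr_forward(sm$lr, sm$ref, sm$ref_blurred, mh)
  expect_equal(dim(fwh$i_sr), c(32L, 32L))
  expect_true(all(is.finite(fwh$i_sr)))
})

test_that("disabling the alignment branch removes exactly the SAT, SFE and auxiliary-head parameters", {
  C <- 8L; n <- 3L
  full <- init_daasr(daasr_config(channels = C, n_hfag = n, scale = 2L))
  nosat <- init_daasr(daasr_config(channels = C, n_hfag = n, scale = 2L,
                                   use_sat = FALSE))
  sat_per_stage <- C * C + (2 * C) * C + C          # w_qprime + fuse conv
  sfe_count <- (9 * C + C) + 3 * (2 * (9 * C * C + C) + 4 * C)
  head_count <- 9 * C * (4 * C) + 4 * C + 9 * C + 1 # scale-2 head
  expect_equal(n_parameters(full) - n_parameters(nosat),
               n * sat_per_stage + sfe_count + head_count)
  expect_lt(n_parameters(nosat), n_parameters(full))
})

test_that("checkpoints round-trip bit-exactly", {
  model <- tiny_model(channels = 6L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(epoch = 3L))
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, model$params)
  expect_identical(ck$model$bn, model$bn)
  expect_identical(ck$model$cfg, model$cfg)
  expect_equal(ck$extra$epoch, 3L)
  unlink(path)
})

test_that("every enabled parameter receives gradient from the total loss", {
  sm <- tiny_sample(size = 32L, seed = 63L)
  model <- tiny_model(channels = 8L, n_hfag = 2L)
  phi <- perceptual_extractor()
  gr <- daasr_gradients(model, sm, loss_weights(), phi, training = TRUE)
  zero <- names(Filter(function(g) is.null(g) || all(g == 0), gr$grads))
  expect_length(zero, 0L)

  ## disabled-branch parameters are absent rather than frozen
  nosat <- tiny_model(channels = 8L, n_hfag = 2L, use_sat = FALSE)
  expect_false(any(grepl("sat|sfe", names(nosat$params))))
  gr2 <- daasr_gradients(nosat, sm, loss_weights(), phi)
  zero2 <- names(Filter(function(g) is.null(g) || all(g == 0), gr2$grads))
  expect_length(zero2, 0L)
})
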