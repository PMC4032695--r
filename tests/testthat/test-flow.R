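test_that("flow_speed matches the elementwise oracle", {
  expect_equal(flow_speed(ff(matrix(0, 4, 4), matrix(0, 4, 4))),
               matrix(0, 4, 4))
  expect_equal(flow_speed(ff(matrix(3, 4, 4), matrix(4, 4, 4))),
               matrix(5, 4, 4))
  set.seed(8)
  u <- matrix(rnorm(64), 8, 8); v <- matrix(rnorm(64), 8, 8)
  expect_lt(max(abs(flow_speed(ff(u, v)) - sqrt(u^2 + v^2))), 1e-12)
})

test_that("estimate_flow: zero-motion fixed point and shape errors", {
  p <- gen_translation_pair(c(48, 48), dx = 0, dy = 0, seed = 2)
  expect_identical(p$frame1, p$frame2)
  fl <- estimate_flow(p$frame1, p$frame2)
  expect_lt(mean(flow_speed(fl$forward)), 0.05)
  expect_error(estimate_flow(p$frame1, matrix(0, 10, 10)), "shape")
})

test_that("estimate_flow recovers a known translation", {
  p <- gen_translation_pair(c(64, 64), dx = 2, dy = 1, seed = 3)
  fl <- estimate_flow(p$frame1, p$frame2)
  epe <- mean(sqrt((fl$forward$u - 2)^2 + (fl$forward$v - 1)^2))
  expect_lt(epe, 0.5)
  # forward/backward consistency residual
  wu <- biomotion:::warp_bilinear(fl$backward$u, fl$forward$u, fl$forward$v)$values
  wv <- biomotion:::warp_bilinear(fl$backward$v, fl$forward$u, fl$forward$v)$values
  res <- sqrt((fl$forward$u + wu)^2 + (fl$forward$v + wv)^2)
  expect_lt(median(res), 0.5)
  # optimized objective does not exceed the zero-flow objective
  z <- matrix(0, 64, 64); one <- matrix(1, 64, 64)
  params <- flow_params()
  e0 <- biomotion:::flow_energy(p$frame1, p$frame2, z, z, z, z, one, one, params)
  e1 <- biomotion:::flow_energy(p$frame1, p$frame2, fl$forward$u, fl$forward$v,
                                fl$backward$u, fl$backward$v, one, one, params)
  expect_lte(e1, e0)
})

test_that("estimate_flow is equivariant to horizontal mirroring", {
  p <- gen_translation_pair(c(48, 48), dx = 2, dy = -1, seed = 13)
  fl <- estimate_flow(p$frame1, p$frame2)
  flm <- estimate_flow(biomotion:::mirror_horizontal(p$frame1),
                       biomotion:::mirror_horizontal(p$frame2))
  du <- mean(abs(flm$forward$u - biomotion:::mirror_horizontal(-fl$forward$u)))
  dv <- mean(abs(flm$forward$v - biomotion:::mirror_horizontal(fl$forward$v)))
  expect_lt(du, 0.2)
  expect_lt(dv, 0.2)
})

test_that("sad_block_flow: exact integer recovery and tie conventions", {
  p <- gen_translation_pair(c(48, 48), dx = 3, dy = -2, seed = 5)
  f2 <- biomotion:::shift_wrap(p$frame1, 3, -2)
  s <- sad_block_flow(p$frame1, f2, block = 8L, search_radius = 4L)
  # exhaustive SAD oracle on one interior block
  block1 <- p$frame1[17:24, 17:24]
  costs <- sapply(-4:4, function(dx) sapply(-4:4, function(dy)
    sum(abs(block1 - f2[17:24 + dy, 17:24 + dx]))))
  best <- unname(which(costs == min(costs), arr.ind = TRUE)[1, ])
  expect_identical(c(best[2] - 5L, best[1] - 5L), c(3L, -2L))
  # all interior blocks report exactly the shift
  expect_true(all(s$u[9:40, 9:40] == 3))
  expect_true(all(s$v[9:40, 9:40] == -2))
  expect_true(all(s$u == round(s$u)))
  # identical frames: all zero
  s0 <- sad_block_flow(p$frame1, p$frame1, 8L, 4L)
  expect_true(all(s0$u == 0) && all(s0$v == 0))
  # zero search radius: zero displacement regardless of content
  sz <- sad_block_flow(p$frame1, f2, 8L, 0L)
  expect_true(all(sz$u == 0) && all(sz$v == 0))
  expect_error(sad_block_flow(p$frame1, f2, block = 100L), "larger")
})

test_that(".flo round trip is exact for float32 payloads", {
  p <- gen_translation_pair(c(20, 30), dx = 2, dy = 1, seed = 9)
  path <- withr::local_tempfile(fileext = ".flo")
  write_flo(p$flow, path)
  back <- read_flo(path)
  expect_identical(back$u, p$flow$u)
  expect_identical(back$v, p$flow$v)
  # non-square shape preserved through the row-major layout
  u <- matrix(seq_len(12) / 7, 3, 4); v <- -u
  write_flo(ff(u, v), path)
  b2 <- read_flo(path)
  expect_equal(b2$u, u, tolerance = 1e-7)
  expect_equal(b2$v, v, tolerance = 1e-7)
})
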