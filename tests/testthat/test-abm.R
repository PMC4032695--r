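test_that("saturate_response: fixed point, monotonicity, bound", {
  z <- matrix(0, 8, 8)
  expect_equal(saturate_response(z, 6), z)
  set.seed(4)
  r1 <- matrix(runif(400, 0, 2), 20, 20)
  r2 <- r1 + matrix(runif(400, 0, 1), 20, 20)
  ms <- mean(c(r1, r2)^2)
  s1 <- saturate_response(r1, 6, mean_square = ms)
  s2 <- saturate_response(r2, 6, mean_square = ms)
  expect_true(all(s2 >= s1))
  # grid-evaluation oracle for the bound
  grid <- matrix(seq(0, 1000, length.out = 1e6), 1000, 1000)
  expect_true(max(saturate_response(grid, 6, mean_square = 1)) <= 6)
  expect_true(max(saturate_response(grid, 2.5, mean_square = 1)) <= 2.5)
})

test_that("local_max_pool recovers displaced placements", {
  d <- test_dictionary()
  # nominal center (24, 24); vertical bar displaced 2 px rightward (the
  # component perpendicular to the bar axis, which pooling can localize)
  b <- gen_bar_images(c(48, 48), orientation = pi / 2, noise_sd = 0,
                      center = c(23, 25), seed = 1)
  stack <- biomotion:::abm_response_stack(b$frames[[1]], d, 6)
  # no perturbation: nominal value unchanged
  p0 <- local_max_pool(stack, d, c(24L, 24L), 5L, 1L, abm_bounds(0L, 0L))
  expect_identical(c(p0$row, p0$col), c(24L, 24L))
  expect_equal(p0$value, stack[[5]][24, 24])
  # exhaustive-search oracle over the perturbation window
  p2 <- local_max_pool(stack, d, c(24L, 24L), 5L, 1L, abm_bounds(2L, 1L))
  vals <- c()
  for (dr in -2:2) for (dc in -2:2) for (dori in -1:1) {
    o <- ((5L - 1L + dori) %% 8L) + 1L
    vals <- c(vals, stack[[o]][24 + dr, 24 + dc])
  }
  expect_equal(p2$value, max(vals))
  expect_identical(p2$col, 26L)  # the displaced column recovered
  expect_gte(p2$value, p0$value)  # pooled >= nominal, always
})

test_that("shared sketch selects the bar orientation and respects inhibition", {
  d <- test_dictionary()
  b <- gen_bar_images(c(48, 48), orientation = pi / 2, n_images = 5,
                      noise_sd = 0.1, seed = 7)
  tpl <- train_shared_sketch(b$frames, 6L, d)
  expect_identical(tpl$elements[[1]]$orientation_index, 5L)  # nearest pi/2
  expect_identical(tpl$n_elements, 6L)
  # selection gains are non-increasing (greedy over a shrinking set)
  expect_true(all(diff(tpl$selection_gains) <= 1e-9))
  # pairwise inhibition: separated in position or beyond the orientation
  # suppression neighborhood
  for (i in seq_len(tpl$n_elements - 1L)) for (j in (i + 1L):tpl$n_elements) {
    ei <- tpl$elements[[i]]; ej <- tpl$elements[[j]]
    dpos <- max(abs(ei$row - ej$row), abs(ei$col - ej$col))
    dori <- min((ei$orientation_index - ej$orientation_index) %% 8L,
                (ej$orientation_index - ei$orientation_index) %% 8L)
    expect_true(dpos > ei$inhibition_radius || dori > 1L)
  }
})

test_that("shared sketch degenerate inputs", {
  d <- build_gabor_dictionary(4L, 1L, 9L)
  b <- gen_bar_images(c(32, 32), noise_sd = 0.05, n_images = 2, seed = 3)
  tpl0 <- train_shared_sketch(b$frames, 0L, d)
  expect_identical(tpl0$n_elements, 0L)
  expect_error(train_shared_sketch(list(), 3L, d), "empty")
  expect_error(train_shared_sketch(list(matrix(0, 8, 8), matrix(0, 9, 9)),
                                   1L, d), "shape")
  # requesting more elements than available placements warns, returns fewer
  expect_warning(
    tpl <- train_shared_sketch(b$frames, 500L, d, inhibition_radius = 16L),
    "selectable")
  expect_lt(tpl$n_elements, 500L)
})

test_that("match_template scores and localization", {
  d <- test_dictionary()
  b <- gen_bar_images(c(48, 48), orientation = pi / 2, n_images = 5,
                      bar_length = 12, noise_sd = 0.1, seed = 7)
  tpl <- train_shared_sketch(b$frames, 6L, d)
  # own training frame beats matched-variance noise (seeded Monte Carlo)
  set.seed(42)
  wins <- 0L
  for (i in 1:20) {
    fr <- b$frames[[(i %% 5) + 1L]]
    noise <- matrix(rnorm(48 * 48, mean(fr), stats::sd(fr)), 48, 48)
    if (match_template(fr, tpl, d)$score >
        match_template(noise, tpl, d)$score) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
  # translated bar: location within perturbation bounds of the (3, 5) shift
  bs <- gen_bar_images(c(48, 48), orientation = pi / 2, bar_length = 12,
                       noise_sd = 0, center = c(23.5 + 3, 23.5 + 5), seed = 1)
  mm <- match_template(bs$frames[[1]], tpl, d)
  expect_lte(abs(mm$location[1] - 3L), tpl$bounds$location)
  expect_lte(abs(mm$location[2] - 5L), tpl$bounds$location)
  # score invariant to additive intensity
  m1 <- match_template(b$frames[[1]], tpl, d)
  m2 <- match_template(b$frames[[1]] + 0.7, tpl, d)
  expect_lt(abs(m1$score - m2$score), 1e-6)
  # empty template: degenerate score 0 at (0, 0)
  empty <- train_shared_sketch(b$frames, 0L, d)
  me <- match_template(b$frames[[1]], empty, d)
  expect_identical(me$score, 0)
  expect_identical(me$location, c(0L, 0L))
  expect_true(me$degenerate)
})

test_that("template serialization round-trips exactly and deterministically", {
  d <- build_gabor_dictionary(4L, 1L, 9L)
  b <- gen_bar_images(c(32, 32), n_images = 3, noise_sd = 0.1, seed = 5)
  tpl <- train_shared_sketch(b$frames, 4L, d)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_template(tpl, p1)
  back <- read_template(p1)
  expect_identical(back$weights, tpl$weights)
  expect_identical(back$log_normalizers, tpl$log_normalizers)
  expect_identical(back$elements, tpl$elements)
  expect_identical(back$frame_shape, tpl$frame_shape)
  write_template(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
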