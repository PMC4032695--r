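test_that("cell_memberships: peaks, degenerate input, and the triangle oracle", {
  div <- flow_division(c(64, 64))
  H <- 64L; W <- 64L
  mk <- function(r, c) {  # single moving pixel at 0-based (r, c)
    u <- matrix(0, H, W); u[r + 1L, c + 1L] <- 1
    ff(u, matrix(0, H, W))
  }
  # pixel at the upper-left cell center: full membership
  cm <- cell_memberships(mk(H / 4, W / 4), div)
  expect_equal(unname(cm$mu["C1"]), 1.0)
  expect_identical(cm$winner, 1L)
  expect_equal(cm$location, c(H / 4, W / 4))
  # all-zero flow: declared degenerate convention
  cm0 <- cell_memberships(ff(matrix(0, H, W), matrix(0, H, W)), div)
  expect_equal(unname(cm0$mu), rep(0.25, 4))
  expect_true(is.na(cm0$winner))
  # seeded sweep against the standalone piecewise-linear oracle
  set.seed(21)
  for (i in 1:50) {
    r <- sample(0:(H - 1L), 1L); cc <- sample(0:(W - 1L), 1L)
    cm <- cell_memberships(mk(r, cc), div)
    expect_lt(max(abs(cm$mu - oracle_cell_mu(r, cc, H, W))), 1e-12)
    expect_true(all(cm$mu >= 0 & cm$mu <= 1))
  }
})

test_that("temporal_update: fixed point, hand-evaluated step, invariants", {
  st <- membership_state(tau = 0.1, beta = 2, beta_prime = 2, N = 3L)
  # Eq fixed point at mu~ = 1: (1 - mu~) = 0
  st1 <- st; st1$mu_tilde["C1"] <- 1; st1$winner <- 1L; st1$k <- 2L
  up <- temporal_update(st1, list(mu = c(C1 = 1, C2 = 0, C3 = 0, C4 = 0),
                                  winner = 1L))
  expect_identical(unname(up$mu_tilde["C1"]), 1)
  # hand evaluation: mu~ = 0.5, k about to become 1, beta = 2 ->
  # eta = 1/(1+2) = 1/3, mu~ <- 0.5 + (1/3)(1 - 0.5) = 2/3
  st2 <- st; st2$mu_tilde["C2"] <- 0.5; st2$winner <- 2L; st2$k <- 0L
  up2 <- temporal_update(st2, list(mu = c(C1 = 0, C2 = 0.9, C3 = 0, C4 = 0),
                                   winner = 2L))
  expect_identical(up2$k, 1L)
  expect_lt(abs(up2$mu_tilde[["C2"]] - (0.5 + (1 / 3) * 0.5)), 1e-12)
  # winner change resets k; cap at N
  up3 <- temporal_update(up2, list(mu = c(C1 = 0, C2 = 0, C3 = 1, C4 = 0),
                                   winner = 3L))
  expect_identical(up3$k, 0L)
  for (i in 1:6) up3 <- temporal_update(up3, list(
    mu = c(C1 = 0, C2 = 0, C3 = 1, C4 = 0), winner = 3L))
  expect_identical(up3$k, 3L)
  # degenerate (no winner) frame leaves the state untouched
  expect_identical(temporal_update(up3, list(mu = rep(0.25, 4),
                                             winner = NA_integer_)), up3)
  # invalid construction
  expect_error(membership_state(beta = 0), "positive")
  expect_error(membership_state(beta_prime = -1), "positive")
})

test_that("temporal_update property sweep keeps invariants under random input", {
  set.seed(31)
  for (rep in 1:25) {
    st <- membership_state(beta = runif(1, 0.5, 4), beta_prime = runif(1, 0.5, 4),
                           N = sample(1:6, 1L))
    for (t in 1:40) {
      mu <- runif(4); names(mu) <- paste0("C", 1:4)
      w <- sample(c(1:4, NA_integer_), 1L, prob = c(rep(0.24, 4), 0.04))
      st <- temporal_update(st, list(mu = mu, winner = w))
      expect_true(all(st$mu_tilde >= 0 & st$mu_tilde <= 1))
      expect_true(st$k >= 0L && st$k <= st$params$N)
    }
  }
  # determinism: identical inputs give identical outputs
  st <- membership_state()
  mu_in <- list(mu = c(C1 = 0.2, C2 = 0.9, C3 = 0.1, C4 = 0.4), winner = 2L)
  expect_identical(temporal_update(st, mu_in), temporal_update(st, mu_in))
})

test_that("limb_scores aggregates by max", {
  st <- membership_state()
  st$mu_tilde <- c(C1 = 1, C2 = 0, C3 = 0, C4 = 0)
  s <- limb_scores(st)
  expect_equal(s$mu_upper, 1); expect_equal(s$mu_lower, 0)
  st$mu_tilde <- c(C1 = 0.2, C2 = 0.7, C3 = 0.4, C4 = 0.1)
  s <- limb_scores(st)
  expect_equal(s$mu_upper, 0.7); expect_equal(s$mu_lower, 0.4)
  st$mu_tilde <- c(C1 = 0.3, C2 = 0.3, C3 = 0.3, C4 = 0.3)
  s <- limb_scores(st, enable_left_right = TRUE)
  expect_equal(s$mu_upper, s$mu_lower)
  expect_equal(s$mu_left, 0.3); expect_equal(s$mu_right, 0.3)
})

test_that("gate_actions selects the dominant group and is never empty", {
  groups <- kth_class_groups()
  g1 <- gate_actions(list(mu_upper = 0.9, mu_lower = 0.1), groups, 0.05)
  expect_setequal(g1, c("boxing", "clapping", "waving"))
  g2 <- gate_actions(list(mu_upper = 0.3, mu_lower = 0.8), groups, 0.05)
  expect_setequal(g2, c("walking", "jogging", "running"))
  g3 <- gate_actions(list(mu_upper = 0.5, mu_lower = 0.5), groups, 0.05)
  expect_setequal(g3, names(groups))
  set.seed(41)
  for (i in 1:100) {
    g <- gate_actions(list(mu_upper = runif(1), mu_lower = runif(1)),
                      groups, runif(1, 0, 0.5))
    expect_gt(length(g), 0L)
  }
})

test_that("persistent upper-half motion drives mu_upper above mu_lower", {
  div <- flow_division(c(64, 64))
  st <- membership_state()
  set.seed(51)
  for (t in 1:6) {
    u <- matrix(0, 64, 64)
    u[sample(1:28, 1L), sample(1:64, 1L)] <- 1 + runif(1)  # upper half only
    st <- temporal_update(st, cell_memberships(ff(u, matrix(0, 64, 64)), div))
  }
  s <- limb_scores(st)
  expect_gt(s$mu_upper, s$mu_lower)
})
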