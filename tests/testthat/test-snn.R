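test_that("normalize_sample satisfies the centering/norm contract", {
  set.seed(6)
  for (i in 1:5) {
    img <- matrix(rnorm(9 * 7, mean = runif(1, -3, 3)), 9, 7)
    v <- normalize_sample(img)
    expect_lt(abs(sum(v)), 1e-10)            # direct summation oracle
    expect_lt(abs(sum(v^2) - 1), 1e-10)
    expect_equal(normalize_sample(v), v, tolerance = 1e-12)  # idempotent
  }
  expect_error(normalize_sample(matrix(2.5, 5, 5)), "constant")
})

test_that("moore_penrose_adjoint: biorthogonality, orthonormal case, rank errors", {
  set.seed(16)
  V <- matrix(rnorm(50 * 4), 50, 4)
  A <- moore_penrose_adjoint(V)
  expect_lt(max(abs(A %*% V - diag(4))), 1e-8)
  Q <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))
  expect_lt(max(abs(moore_penrose_adjoint(Q) - t(Q))), 1e-10)
  expect_error(moore_penrose_adjoint(cbind(V, V[, 1])), "rank-deficient")
})

test_that("mpod_adjoint: reduction, dense-solve oracle, monotone shrinkage", {
  set.seed(26)
  V <- matrix(rnorm(60 * 6), 60, 6)
  # penalty-free, singleton groups: equals Moore-Penrose
  expect_lt(max(abs(mpod_adjoint(V, 0, 0) - moore_penrose_adjoint(V))), 1e-8)
  # independently coded dense-solve oracle
  P1 <- 0.1; P2 <- 0.1
  gs <- c(2L, 2L, 2L)
  G <- t(V) %*% V + P1 * matrix(1, 6, 6) + P2 * diag(6)
  E <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
  oracle <- E %*% solve(G) %*% t(V)
  expect_lt(max(abs(mpod_adjoint(V, P1, P2, gs) - oracle)), 1e-8)
  # increasing P2 shrinks the adjoint norm
  norms <- vapply(c(0.01, 0.1, 0.5, 1, 2), function(p2)
    norm(mpod_adjoint(V, 0, p2), "F"), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(mpod_adjoint(V, 0.1, 0.1, c(2L, 2L)), "sum")
})

test_that("order_parameters: Kronecker delta, linearity, noisy recovery", {
  set.seed(36)
  V <- matrix(rnorm(50 * 4), 50, 4)
  bank <- prototype_bank(V, labels = paste0("c", 1:4))
  op <- order_parameters(V[, 2], bank)
  expect_lt(max(abs(op$eps - c(0, 1, 0, 0))), 1e-8)
  expect_identical(op$label, "c2")
  q1 <- rnorm(50); q2 <- rnorm(50)
  e12 <- order_parameters(2 * q1 - 3 * q2, bank)$eps
  expect_lt(max(abs(e12 - (2 * order_parameters(q1, bank)$eps -
                             3 * order_parameters(q2, bank)$eps))), 1e-10)
  ok <- 0L
  for (i in 1:100) {
    j <- (i %% 4L) + 1L
    q <- V[, j] + rnorm(50, 0, 0.1 * sqrt(sum(V[, j]^2)))
    if (order_parameters(q, bank)$label == paste0("c", j)) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
  expect_error(order_parameters(rnorm(10), bank), "match")
  # self-consistency: every training prototype classified as itself
  for (j in 1:4)
    expect_identical(order_parameters(V[, j], bank)$label, paste0("c", j))
})

test_that("melt: singleton, duplicates, and noise averaging", {
  set.seed(46)
  v <- normalize_sample(matrix(rnorm(64), 8, 8))
  expect_lt(max(abs(melt(list(v)) - v)), 1e-10)
  expect_lt(max(abs(melt(list(v, v, v, v)) - v)), 1e-10)
  base <- normalize_sample(matrix(rnorm(256), 16, 16))
  variants <- lapply(1:5, function(i)
    normalize_sample(base + rnorm(256, 0, 0.4)))
  m <- melt(variants)
  corr_m <- sum(m * base)
  corr_each <- vapply(variants, function(x) sum(x * base), numeric(1))
  expect_gt(corr_m, max(corr_each))
  expect_error(melt(list()), "no samples")
})

test_that("build_action_prototypes: degenerate map, counting, validation", {
  set.seed(56)
  fr <- matrix(rnorm(64), 8, 8)
  tm <- list(act1 = lapply(1:5, function(s) list(fr)))
  ap <- build_action_prototypes(tm)
  expect_lt(max(abs(ap$act1$F - normalize_sample(fr))), 1e-8)
  # full map: 6 actions x (5 snippet + 1 final) prototypes
  full <- lapply(stats::setNames(1:6, paste0("a", 1:6)), function(a)
    lapply(1:5, function(s) lapply(1:2, function(d) matrix(rnorm(64), 8, 8))))
  apf <- build_action_prototypes(full)
  expect_length(apf, 6L)
  counts <- vapply(apf, function(x) length(x$P) + 1L, integer(1))
  expect_true(all(counts == 6L))
  expect_error(build_action_prototypes(list(a = list())), "no snippets")
  expect_error(build_action_prototypes(list(a = list(list()))), "snippet 1")
})

test_that("two synthetic actions with disjoint active regions are recovered", {
  set.seed(66)
  mk <- function(active_rows) function() {
    m <- matrix(rnorm(256, 0, 0.05), 16, 16)
    m[active_rows, ] <- m[active_rows, ] + 1
    m
  }
  gen_a <- mk(2:6); gen_b <- mk(10:14)
  tm <- list(A = lapply(1:5, function(s) lapply(1:3, function(d) gen_a())),
             B = lapply(1:5, function(s) lapply(1:3, function(d) gen_b())))
  ap <- build_action_prototypes(tm)
  cols <- c(ap$A$P, list(ap$A$F), ap$B$P, list(ap$B$F))
  bank <- prototype_bank(do.call(cbind, cols),
                         rep(c("A", "B"), each = 6L),
                         penalty = list(P1 = 0.1, P2 = 0.1))
  hits <- 0L
  for (i in 1:40) {
    truth <- if (i %% 2L == 0L) "A" else "B"
    q <- normalize_sample(if (truth == "A") gen_a() else gen_b())
    if (order_parameters(q, bank)$label == truth) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # >= 90%
})
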