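# Independent oracles used across the suite. These deliberately re-derive
# quantities with the most literal (slow) computation available so they never
# share code paths with the implementation they check.

# O(H*W*K^2) nested-loop zero-padded correlation, anchored at kernel center.
brute_correlate <- function(frame, kern) {
  H <- nrow(frame); W <- ncol(frame)
  k <- nrow(kern); h <- (k - 1L) / 2L
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      rr <- r + a - h - 1L; ccc <- cc + b - h - 1L
      if (rr >= 1L && rr <= H && ccc >= 1L && ccc <= W)
        acc <- acc + kern[a, b] * frame[rr, ccc]
    }
    out[r, cc] <- acc
  }
  out
}

# Direct piecewise-linear triangle evaluation (canonical quadrant geometry:
# peaks at cell centers, zeros at cell edges).
oracle_triangle <- function(x, a, p, b) {
  if (x <= a || x >= b) return(0)
  if (x <= p) (x - a) / (p - a) else (b - x) / (b - p)
}

oracle_cell_mu <- function(y, x, H, W) {
  ml <- oracle_triangle(x, 0, W / 4, W / 2)
  mr <- oracle_triangle(x, W / 2, 3 * W / 4, W)
  mt <- oracle_triangle(y, 0, H / 4, H / 2)
  mb <- oracle_triangle(y, H / 2, 3 * H / 4, H)
  c(C1 = max(ml, mt), C2 = max(mr, mt), C3 = max(ml, mb), C4 = max(mr, mb))
}

# Small default dictionary shared by several tests.
test_dictionary <- function() build_gabor_dictionary(8L, 2L, 17L)

# A flow_field wrapper for raw u/v matrices.
ff <- function(u, v) flow_field(u, v, direction = "forward")
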