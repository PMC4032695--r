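#' Dense optical flow for the motion pathway
#'
#' Bidirectional flow between consecutive frames is estimated by minimizing a
#' three-term objective: a robust (Charbonnier) brightness-constancy data term
#' under Gaussian pre-smoothing, a symmetric coupling term penalizing
#' ||w_fwd(x) + w_bwd(x + w_fwd(x))||, and total-variation-like smoothness,
#' with weights rho (symmetric) and xi (smoothness). Optimization is
#' coarse-to-fine warping with outer/inner fixed-point iterations; the inner
#' linearized system is solved by weighted Jacobi sweeps. Layer visibility
#' masks are an input contract and default to all-ones (full-frame layer).
#'
#' A "compressed" flow is also provided: block matching by sum of absolute
#' differences (L1), integer displacements, deliberately unsmoothed.
#'
#' @name flow
NULL

#' Construct a flow field
#'
#' @param u,v per-pixel horizontal (positive rightward) and vertical (positive
#'   downward) velocities, px/frame.
#' @param mask per-pixel visibility weight in [0, 1]; default all ones.
#' @param direction "forward" (frame1 -> frame2) or "backward".
#' @return a `flow_field` object.
#' @export
flow_field <- function(u, v, mask = NULL, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  if (is.null(mask)) mask <- matrix(1, nrow(u), ncol(u))
  stopifnot(all(dim(mask) == dim(u)), all(mask >= 0), all(mask <= 1))
  structure(list(u = u, v = v, mask = mask, direction = direction),
            class = "flow_field")
}

#' Flow estimation parameters
#'
#' @param rho symmetric (forward/backward coupling) term weight.
#' @param xi smoothness term weight.
#' @param n_levels maximum pyramid depth (downsample factor 0.5 per level).
#' @param n_outer,n_inner outer warping and inner re-weighting iterations.
#' @param n_jacobi Jacobi sweeps per inner iteration.
#' @param presmooth_sigma Gaussian pre-smoothing sigma per pyramid level.
#' @param eps Charbonnier epsilon.
#' @return a `flow_params` object.
#' @export
flow_params <- function(rho = 0.05, xi = 0.03, n_levels = 4L, n_outer = 5L,
                        n_inner = 3L, n_jacobi = 50L, presmooth_sigma = 0.8,
                        eps = 1e-3) {
  stopifnot(rho >= 0, xi >= 0, n_levels >= 1L, n_outer >= 1L, n_inner >= 1L)
  structure(list(rho = rho, xi = xi, n_levels = as.integer(n_levels),
                 n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 n_jacobi = as.integer(n_jacobi),
                 presmooth_sigma = presmooth_sigma, eps = eps),
            class = "flow_params")
}

#' Per-pixel speed map
#'
#' @param field a `flow_field`.
#' @return matrix of sqrt(u^2 + v^2).
#' @export
flow_speed <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  sqrt(field$u^2 + field$v^2)
}

charb <- function(x, eps) sqrt(x^2 + eps^2)

# Central-difference gradients with replicate borders.
grad_x <- function(img) {
  W <- ncol(img)
  (img[, c(2:W, W), drop = FALSE] - img[, c(1, 1:(W - 1)), drop = FALSE]) / 2
}
grad_y <- function(img) {
  H <- nrow(img)
  (img[c(2:H, H), , drop = FALSE] - img[c(1, 1:(H - 1)), , drop = FALSE]) / 2
}

shift_m <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ridx <- clamp(seq_len(H) + dr, 1L, H)
  cidx <- clamp(seq_len(W) + dc, 1L, W)
  m[ridx, cidx, drop = FALSE]
}

# Total objective E = sum_dir [data + rho*symmetric + xi*smooth], Charbonnier
# penalties, masks weighting the data term.
flow_energy <- function(I1, I2, uf, vf, ub, vb, m1, m2, params) {
  eps <- params$eps
  e <- 0
  for (d in 1:2) {
    if (d == 1) { A <- I1; B <- I2; u <- uf; v <- vf; uo <- ub; vo <- vb; m <- m1 }
    else { A <- I2; B <- I1; u <- ub; v <- vb; uo <- uf; vo <- vf; m <- m2 }
    w <- warp_bilinear(B, u, v)
    e <- e + sum(m * w$inside * charb(w$values - A, eps))
    wu <- warp_bilinear(uo, u, v); wv <- warp_bilinear(vo, u, v)
    e <- e + params$rho * sum(w$inside *
                                charb(sqrt((u + wu$values)^2 + (v + wv$values)^2), eps))
    e <- e + params$xi * sum(charb(sqrt(grad_x(u)^2 + grad_y(u)^2 +
                                          grad_x(v)^2 + grad_y(v)^2), eps))
  }
  e
}

# One direction's linearized update at a pyramid level (total-flow form).
# rho_eff lets the caller defer the symmetric coupling until both fields have
# left the zero initialization (the Charbonnier IRLS weight is maximal at zero
# residual and would otherwise pin both fields at zero).
refine_direction <- function(A, B, u, v, uo, vo, m, params,
                             rho_eff = params$rho,
                             n_jacobi = params$n_jacobi) {
  eps <- params$eps
  # Softer epsilons for the IRLS *weights* of the smoothness and coupling
  # terms: the energy itself keeps params$eps, but weight stiffness ~1/eps at
  # zero residual would stall the Jacobi sweeps (and pin the fields at zero
  # for the coupling term).
  eps_c <- 0.05
  eps_s <- 0.05
  w <- warp_bilinear(B, u, v)
  Bw <- w$values
  Ix <- (grad_x(A) + grad_x(Bw)) / 2
  Iy <- (grad_y(A) + grad_y(Bw)) / 2
  It <- Bw - A
  dmask <- m * w$inside
  # symmetric coupling target: U ~ -w_other(x + w(x))
  uc <- -warp_bilinear(uo, u, v)$values
  vc <- -warp_bilinear(vo, u, v)$values
  cmask <- w$inside
  c0 <- It - Ix * u - Iy * v
  U <- u; V <- v
  H <- nrow(A); W <- ncol(A)
  # precomputed clamped neighbor indices (N, S, W, E shifts)
  rN <- c(1L, seq_len(H - 1L)); rS <- c(seq_len(H - 1L) + 1L, H)
  cW <- c(1L, seq_len(W - 1L)); cE <- c(seq_len(W - 1L) + 1L, W)
  for (inner in seq_len(params$n_inner)) {
    r <- c0 + Ix * U + Iy * V
    wd <- dmask / charb(r, eps)
    wc <- rho_eff * cmask / charb(sqrt((U - uc)^2 + (V - vc)^2), eps_c)
    g <- 1 / charb(sqrt(grad_x(U)^2 + grad_y(U)^2 + grad_x(V)^2 + grad_y(V)^2), eps_s)
    wN <- (g + g[rN, ]) / 2
    wS <- (g + g[rS, ]) / 2
    wW <- (g + g[, cW]) / 2
    wE <- (g + g[, cE]) / 2
    wsum <- wN + wS + wW + wE
    # per-pixel 2x2 block (exact block-Jacobi: neighbor sums lagged, the
    # U-V data coupling solved in closed form; diagonally stable since
    # A12^2 < A11*A22 by construction)
    A11 <- wd * Ix^2 + wc + params$xi * wsum + 1e-9
    A22 <- wd * Iy^2 + wc + params$xi * wsum + 1e-9
    A12 <- wd * Ix * Iy
    det <- A11 * A22 - A12^2
    rhsU0 <- -wd * Ix * c0 + wc * uc
    rhsV0 <- -wd * Iy * c0 + wc * vc
    for (sweep in seq_len(n_jacobi)) {
      nbU <- wN * U[rN, ] + wS * U[rS, ] + wW * U[, cW] + wE * U[, cE]
      nbV <- wN * V[rN, ] + wS * V[rS, ] + wW * V[, cW] + wE * V[, cE]
      rhsU <- rhsU0 + params$xi * nbU
      rhsV <- rhsV0 + params$xi * nbV
      U <- (A22 * rhsU - A12 * rhsV) / det
      V <- (A11 * rhsV - A12 * rhsU) / det
    }
    # the brightness linearization is only valid ~1 px from the warp point
    U <- u + clamp(U - u, -1, 1)
    V <- v + clamp(V - v, -1, 1)
  }
  list(u = U, v = V, inside = w$inside)
}

#' Estimate bidirectional dense optical flow
#'
#' @param frame1,frame2 grayscale frames (matrices of equal shape).
#' @param params a [flow_params()] object.
#' @param masks optional list(m1, m2) of per-frame visibility masks in [0, 1];
#'   default full-frame (all ones).
#' @return list(forward, backward) of `flow_field`s; each mask zeroes pixels
#'   whose warped sample fell outside the frame.
#' @export
estimate_flow <- function(frame1, frame2, params = flow_params(), masks = NULL) {
  stopifnot(is.matrix(frame1), is.matrix(frame2))
  if (!all(dim(frame1) == dim(frame2)))
    stop("frames must share one shape", call. = FALSE)
  if (is.null(masks)) masks <- list(m1 = NULL, m2 = NULL)
  H <- nrow(frame1); W <- ncol(frame1)
  m1 <- if (is.null(masks$m1)) matrix(1, H, W) else masks$m1
  m2 <- if (is.null(masks$m2)) matrix(1, H, W) else masks$m2

  # build pyramid (coarsest last)
  pyr <- list(list(I1 = frame1, I2 = frame2, m1 = m1, m2 = m2))
  while (length(pyr) < params$n_levels) {
    top <- pyr[[length(pyr)]]
    h2 <- as.integer(round(nrow(top$I1) / 2)); w2 <- as.integer(round(ncol(top$I1) / 2))
    if (min(h2, w2) < 12L) break
    pyr[[length(pyr) + 1L]] <- list(
      I1 = imresize_bilinear(gaussian_blur(top$I1, 1), h2, w2),
      I2 = imresize_bilinear(gaussian_blur(top$I2, 1), h2, w2),
      m1 = imresize_bilinear(top$m1, h2, w2),
      m2 = imresize_bilinear(top$m2, h2, w2))
  }

  lev <- pyr[[length(pyr)]]
  uf <- matrix(0, nrow(lev$I1), ncol(lev$I1)); vf <- uf; ub <- uf; vb <- uf
  for (li in rev(seq_along(pyr))) {
    lev <- pyr[[li]]
    h <- nrow(lev$I1); w <- ncol(lev$I1)
    if (h != nrow(uf) || w != ncol(uf)) {
      sx <- w / ncol(uf); sy <- h / nrow(uf)
      uf <- imresize_bilinear(uf, h, w) * sx; vf <- imresize_bilinear(vf, h, w) * sy
      ub <- imresize_bilinear(ub, h, w) * sx; vb <- imresize_bilinear(vb, h, w) * sy
    }
    I1 <- gaussian_blur(lev$I1, params$presmooth_sigma)
    I2 <- gaussian_blur(lev$I2, params$presmooth_sigma)
    e_prev <- flow_energy(I1, I2, uf, vf, ub, vb, lev$m1, lev$m2, params)
    # Finer levels start from an upsampled, already-accurate field and only
    # need local correction; the slow-to-converge uniform modes are resolved
    # at the coarse levels, which are cheap. Scale the sweep count down as
    # resolution doubles.
    nj <- max(15L, as.integer(round(params$n_jacobi / 2^(length(pyr) - li))))
    for (outer in seq_len(params$n_outer)) {
      rho_eff <- if (outer == 1L) 0 else params$rho
      rf <- refine_direction(I1, I2, uf, vf, ub, vb, lev$m1, params, rho_eff, nj)
      rb <- refine_direction(I2, I1, ub, vb, rf$u, rf$v, lev$m2, params, rho_eff, nj)
      e_new <- flow_energy(I1, I2, rf$u, rf$v, rb$u, rb$v, lev$m1, lev$m2, params)
      if (e_new > e_prev) break  # keep previous iterate: energy never increases
      uf <- rf$u; vf <- rf$v; ub <- rb$u; vb <- rb$v
      if (e_prev - e_new < 1e-9 * max(1, e_prev)) { e_prev <- e_new; break }
      e_prev <- e_new
    }
  }
  in_f <- warp_bilinear(frame2, uf, vf)$inside
  in_b <- warp_bilinear(frame1, ub, vb)$inside
  list(forward = flow_field(uf, vf, mask = in_f * 1, direction = "forward"),
       backward = flow_field(ub, vb, mask = in_b * 1, direction = "backward"))
}

#' SAD block-matching ("compressed") optical flow
#'
#' Straight matching of each block of `frame1` into `frame2` by minimizing the
#' sum of absolute differences over an integer search window. Ties are broken
#' by the smallest displacement norm, then row-major candidate order. The
#' block displacements are upsampled to per-pixel fields by nearest-block
#' assignment; no smoothing is applied.
#'
#' @param frame1,frame2 equal-shape grayscale frames.
#' @param block block side length in pixels (>= 1).
#' @param search_radius maximum |dx|, |dy| searched (>= 0).
#' @return a forward `flow_field` with piecewise-constant integer u, v.
#' @export
sad_block_flow <- function(frame1, frame2, block = 8L, search_radius = 7L) {
  stopifnot(is.matrix(frame1), all(dim(frame1) == dim(frame2)))
  block <- as.integer(block); search_radius <- as.integer(search_radius)
  if (block < 1L || search_radius < 0L)
    stop("block >= 1 and search_radius >= 0 required", call. = FALSE)
  H <- nrow(frame1); W <- ncol(frame1)
  if (block > min(H, W)) stop("block larger than frame", call. = FALSE)
  nbr <- ceiling(H / block); nbc <- ceiling(W / block)
  brow <- pmin((seq_len(H) - 1L) %/% block, nbr - 1L)
  bcol <- pmin((seq_len(W) - 1L) %/% block, nbc - 1L)
  bid <- matrix(brow, H, W) + nbr * matrix(bcol, H, W, byrow = TRUE)  # 0-based
  bid_v <- as.vector(bid) + 1L
  cand <- expand.grid(dx = -search_radius:search_radius,
                      dy = -search_radius:search_radius)
  cand <- cand[order(cand$dx^2 + cand$dy^2,
                     (cand$dy + search_radius) * (2L * search_radius + 1L) +
                       cand$dx + search_radius), , drop = FALSE]
  BIG <- sum(abs(frame1)) + sum(abs(frame2)) + 1e6
  nblocks <- nbr * nbc
  best_cost <- rep(Inf, nblocks)
  best_dx <- integer(nblocks); best_dy <- integer(nblocks)
  rows <- seq_len(H); cols <- seq_len(W)
  for (i in seq_len(nrow(cand))) {
    dx <- cand$dx[i]; dy <- cand$dy[i]
    r2 <- rows + dy; c2 <- cols + dx
    vr <- r2 >= 1L & r2 <= H; vc <- c2 >= 1L & c2 <= W
    cost <- matrix(BIG, H, W)
    if (any(vr) && any(vc)) {
      cost[vr, vc] <- abs(frame1[vr, vc, drop = FALSE] -
                            frame2[r2[vr], c2[vc], drop = FALSE])
    }
    csum <- rowsum(as.vector(cost), bid_v)[, 1]
    better <- csum < best_cost - 1e-12
    if (any(better)) {
      best_cost[better] <- csum[better]
      best_dx[better] <- dx; best_dy[better] <- dy
    }
  }
  u <- matrix(best_dx[bid_v], H, W)
  v <- matrix(best_dy[bid_v], H, W)
  flow_field(u, v, direction = "forward")
}

#' Read/write Middlebury .flo flow files
#'
#' Standard format: float32 tag 202021.25, int32 width and height, then
#' row-major interleaved (u, v) float32 samples, little-endian.
#'
#' @param field a `flow_field`.
#' @param path file path.
#' @return `write_flo` returns `path` invisibly; `read_flo` a `flow_field`.
#' @export
write_flo <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  H <- nrow(field$u); W <- ncol(field$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4L, endian = "little")
  writeBin(c(as.integer(W), as.integer(H)), con, size = 4L, endian = "little")
  inter <- rbind(as.vector(t(field$u)), as.vector(t(field$v)))
  writeBin(as.numeric(inter), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_flo
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  if (abs(tag - 202021.25) > 1e-3) stop("not a .flo file", call. = FALSE)
  wh <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  W <- wh[1]; H <- wh[2]
  dat <- readBin(con, "numeric", 2L * W * H, size = 4L, endian = "little")
  m <- matrix(dat, nrow = 2L)
  u <- matrix(m[1, ], H, W, byrow = TRUE)
  v <- matrix(m[2, ], H, W, byrow = TRUE)
  flow_field(u, v, direction = "forward")
}
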