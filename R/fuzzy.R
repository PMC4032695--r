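#' Time-dependent fuzzy optical-flow division
#'
#' The flow field is divided into four quadrant cells C1 (upper-left), C2
#' (upper-right), C3 (lower-left), C4 (lower-right), split at row H/2 and
#' column W/2. Triangular membership functions peak at the cell centers (W/4
#' and 3W/4 horizontally, H/4 and 3H/4 vertically) and vanish at the cell
#' edges. Each frame, the location of the maximal flow speed is fuzzified into
#' per-cell memberships; these are accumulated over time with a memory
#' coefficient eta = +1/(k+beta) or -1/(k+beta'), where k counts frames since
#' the winner cell last changed (capped at N). Accumulated memberships
#' aggregate into upper-limb (C1 u C2) and lower-limb (C3 u C4) scores, and a
#' defuzzification rule gates the candidate action classes to the dominant
#' limb group.
#'
#' @name fuzzy
NULL

#' Quadrant division of a frame lattice
#'
#' @param shape c(H, W) frame shape.
#' @return a `flow_division`: cell boundaries and triangle peaks. Cells tile
#'   the frame exactly; pixel (r, c), 0-based, belongs to the upper half iff
#'   r < H/2 and to the left half iff c < W/2.
#' @export
flow_division <- function(shape) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  stopifnot(H >= 2L, W >= 2L)
  structure(list(shape = c(H, W),
                 row_split = H / 2, col_split = W / 2,
                 peaks_x = c(W / 4, 3 * W / 4),
                 peaks_y = c(H / 4, 3 * H / 4)),
            class = "flow_division")
}

# Triangle rising 0 at a, 1 at p, 0 at b; 0 outside [a, b].
triangle_mf <- function(x, a, p, b) {
  ifelse(x > a & x <= p, (x - a) / (p - a),
         ifelse(x > p & x < b, (b - x) / (b - p), 0))
}

#' Per-cell fuzzy memberships of the maximal-velocity location
#'
#' Finds (y*, x*) = argmax of the flow speed (tie-break: smallest row then
#' column; 0-based pixel coordinates), evaluates the four triangular functions
#' over x and y, and aggregates per cell i as
#' mu_Ci = max(mu_x-component, mu_y-component) of that cell's quadrant.
#' An all-zero flow is degenerate: uniform memberships 0.25 and no winner.
#'
#' @param flow a `flow_field`.
#' @param division a matching [flow_division()].
#' @return list(mu = numeric(4) named C1..C4, winner = integer cell id or
#'   NA for the degenerate case, location = c(row, col) 0-based or NA).
#' @export
cell_memberships <- function(flow, division) {
  stopifnot(inherits(flow, "flow_field"), inherits(division, "flow_division"))
  sp <- flow_speed(flow)
  H <- division$shape[1]; W <- division$shape[2]
  stopifnot(nrow(sp) == H, ncol(sp) == W)
  mx <- max(sp)
  if (mx <= 0) {
    return(list(mu = c(C1 = 0.25, C2 = 0.25, C3 = 0.25, C4 = 0.25),
                winner = NA_integer_, location = c(NA_real_, NA_real_)))
  }
  pos <- which(sp == mx, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
  y <- unname(pos[1]) - 1; x <- unname(pos[2]) - 1  # 0-based
  mu_left <- triangle_mf(x, 0, W / 4, W / 2)
  mu_right <- triangle_mf(x, W / 2, 3 * W / 4, W)
  mu_top <- triangle_mf(y, 0, H / 4, H / 2)
  mu_bot <- triangle_mf(y, H / 2, 3 * H / 4, H)
  mu <- c(C1 = max(mu_left, mu_top), C2 = max(mu_right, mu_top),
          C3 = max(mu_left, mu_bot), C4 = max(mu_right, mu_bot))
  upper <- y < H / 2; left <- x < W / 2
  winner <- if (upper && left) 1L else if (upper) 2L
  else if (left) 3L else 4L
  list(mu = mu, winner = winner, location = c(y, x))
}

#' Construct a fuzzy membership state
#'
#' @param tau frame time in seconds (camera parameter).
#' @param beta,beta_prime memory-coefficient adjustment parameters; must be
#'   positive so no denominator k + beta can vanish.
#' @param N cap on k, the count of frames since the winner cell last changed.
#' @return a `membership_state` with all accumulated memberships at 0.
#' @export
membership_state <- function(tau = 0.1, beta = 2, beta_prime = beta, N = 3L) {
  if (beta <= 0 || beta_prime <= 0)
    stop("beta and beta_prime must be positive (k + beta may not vanish)",
         call. = FALSE)
  stopifnot(tau > 0, N >= 0L)
  structure(list(mu_tilde = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0),
                 k = 0L, winner = NA_integer_,
                 params = list(tau = tau, beta = beta,
                               beta_prime = beta_prime, N = as.integer(N))),
            class = "membership_state")
}

#' Temporal membership update with memory coefficient
#'
#' Applies the accumulation rule mu~(t) = mu~(t-tau) + eta(t) (1 - mu~(t-tau))
#' to the winner cell, with eta = +1/(k+beta) while the winner's instantaneous
#' membership confirms (is at least) the stored accumulation, and
#' eta = -1/(k+beta') when it has dropped below it (motion drifting away from
#' that cell's center). The source rule's branch condition is garbled; the
#' opposite reading would keep every accumulated membership at zero forever
#' (see the methods vignette).
#' k increments while the winner cell is unchanged (capped at N) and resets to
#' 0 when it changes. Non-winner cells decay toward zero at rate 1/(k+beta').
#' All memberships stay clamped to [0, 1]. A degenerate (no-winner) input
#' leaves the state's winner unchanged and applies no accumulation.
#'
#' @param state a `membership_state`.
#' @param mu_now output of [cell_memberships()] for the current frame.
#' @return the updated `membership_state`.
#' @export
temporal_update <- function(state, mu_now) {
  stopifnot(inherits(state, "membership_state"))
  p <- state$params
  w <- mu_now$winner
  if (is.na(w)) return(state)  # static frame: no winner flip, no update
  if (!is.na(state$winner) && w == state$winner) {
    k <- min(state$k + 1L, p$N)
  } else {
    k <- 0L
  }
  mu <- state$mu_tilde
  eta <- if (mu_now$mu[w] >= mu[w]) 1 / (k + p$beta) else -1 / (k + p$beta_prime)
  mu[w] <- clamp(mu[w] + eta * (1 - mu[w]), 0, 1)
  decay <- 1 / (k + p$beta_prime)
  for (i in setdiff(1:4, w)) mu[i] <- clamp(mu[i] - decay * mu[i], 0, 1)
  structure(list(mu_tilde = mu, k = k, winner = w, params = p),
            class = "membership_state")
}

#' Limb-level aggregation of accumulated memberships
#'
#' Upper limb = max over the two upper cells, lower limb = max over the two
#' lower cells; optional left/right aggregation over the column pairs.
#'
#' @param state a `membership_state`.
#' @param enable_left_right also return left/right scores (off by default).
#' @return list(mu_upper, mu_lower) and optionally mu_left, mu_right.
#' @export
limb_scores <- function(state, enable_left_right = FALSE) {
  stopifnot(inherits(state, "membership_state"))
  mu <- state$mu_tilde
  out <- list(mu_upper = max(mu["C1"], mu["C2"]),
              mu_lower = max(mu["C3"], mu["C4"]))
  if (enable_left_right) {
    out$mu_left <- max(mu["C1"], mu["C3"])
    out$mu_right <- max(mu["C2"], mu["C4"])
  }
  out
}

#' Gate candidate action classes by dominant limb group
#'
#' The defuzzification rule: when one limb group's accumulated membership
#' dominates the other by more than `margin`, only that group's classes stay
#' eligible for the form pathway; under ambiguity no class is eliminated.
#' The result is never empty.
#'
#' @param scores output of [limb_scores()].
#' @param class_groups named character vector mapping class name to limb group
#'   ("upper" or "lower"); must cover all candidate classes.
#' @param margin dominance margin (>= 0).
#' @return character vector of allowed class names.
#' @export
gate_actions <- function(scores, class_groups, margin = 0.05) {
  stopifnot(margin >= 0, all(class_groups %in% c("upper", "lower")))
  d <- scores$mu_upper - scores$mu_lower
  if (abs(d) > margin) {
    dominant <- if (d > 0) "upper" else "lower"
    allowed <- names(class_groups)[class_groups == dominant]
    if (length(allowed) > 0L) return(allowed)
  }
  names(class_groups)
}
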