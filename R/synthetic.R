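#' Seeded synthetic fixture generators
#'
#' Stand-ins for external benchmark footage: every generator is a pure
#' function of its spec (seed included) and returns a manifest recording all
#' parameters, so fixtures are self-describing and byte-reproducible.
#'
#' Three kinds are provided: oriented anti-aliased bars (exercise template
#' learning), wrapped-translation texture pairs with exact ground-truth flow
#' (exercise flow estimation), and limb-localized blob-actor action sequences
#' (exercise fuzzy gating and the end-to-end pipeline).
#'
#' @name synthetic
NULL

#' Generate noisy oriented-bar images
#'
#' Each image contains one anti-aliased bar (linear intensity falloff over the
#' last half pixel of the bar's half-width/half-length) plus i.i.d. Gaussian
#' noise.
#'
#' @param shape c(H, W) frame shape.
#' @param orientation bar orientation in radians (modulo pi; pi/2 = vertical).
#' @param n_images number of images.
#' @param bar_length,bar_width bar extent in pixels.
#' @param noise_sd i.i.d. Gaussian noise standard deviation.
#' @param center c(row, col) bar center, 0-based; default frame center.
#' @param seed RNG seed.
#' @return list(frames = list of matrices, manifest = list of parameters).
#' @export
gen_bar_images <- function(shape = c(48L, 48L), orientation = pi / 2,
                           n_images = 1L, bar_length = 24, bar_width = 3,
                           noise_sd = 0.1, center = NULL, seed = 1L) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (bar_length > min(H, W) || bar_width > min(H, W))
    stop("bar larger than frame", call. = FALSE)
  if (is.null(center)) center <- c((H - 1) / 2, (W - 1) / 2)
  # 0-based pixel coordinates
  ys <- matrix(seq_len(H) - 1, H, W) - center[1]
  xs <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - center[2]
  d_along <- abs(xs * cos(orientation) + ys * sin(orientation))
  d_across <- abs(-xs * sin(orientation) + ys * cos(orientation))
  profile <- clamp(bar_width / 2 + 0.5 - d_across, 0, 1) *
    clamp(bar_length / 2 + 0.5 - d_along, 0, 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  frames <- lapply(seq_len(n_images), function(i) {
    profile + if (noise_sd > 0) matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    else 0
  })
  list(frames = frames,
       manifest = list(kind = "bars", shape = c(H, W),
                       orientation = orientation, center = center,
                       bar_length = bar_length, bar_width = bar_width,
                       noise_sd = noise_sd, n_images = n_images, seed = seed))
}

#' Generate a wrapped-translation frame pair with exact ground-truth flow
#'
#' A smooth random texture (heavily blurred white noise, rescaled to [0,1])
#' and its toroidal translation by (dx, dy). Because the shift wraps, the
#' ground-truth flow is exactly (dx, dy) at every pixel.
#'
#' @param shape c(H, W).
#' @param dx,dy translation in pixels (positive right/down);
#'   must satisfy |dx|, |dy| < min(H, W) / 4.
#' @param smoothness blur sigma applied to the white-noise texture.
#' @param seed RNG seed.
#' @return list(frame1, frame2, flow = ground-truth flow_field, manifest).
#' @export
gen_translation_pair <- function(shape = c(64L, 64L), dx = 2, dy = 1,
                                 smoothness = 2.5, seed = 1L) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (abs(dx) >= min(H, W) / 4 || abs(dy) >= min(H, W) / 4)
    stop("|dx|, |dy| must be < min(H, W)/4", call. = FALSE)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  tex <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), smoothness)
  tex <- (tex - min(tex)) / max(max(tex) - min(tex), .Machine$double.eps)
  f2 <- shift_wrap(tex, dx, dy)
  gt <- flow_field(u = matrix(dx, H, W), v = matrix(dy, H, W),
                   direction = "forward")
  list(frame1 = tex, frame2 = f2, flow = gt,
       manifest = list(kind = "translate", shape = c(H, W), dx = dx, dy = dy,
                       smoothness = smoothness, seed = seed))
}

# Render an axis-aligned Gaussian blob; coordinates 0-based.
render_blob <- function(H, W, row, col, sr, sc, amp = 1) {
  ys <- matrix(seq_len(H) - 1, H, W)
  xs <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  amp * exp(-((ys - row)^2 / (2 * sr^2) + (xs - col)^2 / (2 * sc^2)))
}

#' Generate a limb-localized synthetic action sequence
#'
#' A blob actor: a static trunk ellipse spanning the frame middle plus one
#' oscillating appendage blob confined to the upper or lower half-frame
#' according to the class's limb group. All inter-frame motion energy is
#' therefore localized to that half. The manifest records per-frame
#' motion-energy centroids computed from absolute frame differences.
#'
#' @param shape c(H, W).
#' @param limb_group "upper" or "lower": which half the appendage moves in.
#' @param n_frames number of frames (>= 6).
#' @param amplitude horizontal oscillation amplitude in pixels.
#' @param period oscillation period in frames.
#' @param noise_sd per-frame Gaussian noise sd.
#' @param clutter_sd static background clutter sd (blurred, shared by frames).
#' @param seed RNG seed.
#' @return list(frames, label = limb_group, manifest).
#' @export
gen_action_sequence <- function(shape = c(64L, 64L), limb_group = c("upper", "lower"),
                                n_frames = 8L, amplitude = 8, period = 8,
                                noise_sd = 0.01, clutter_sd = 0.05, seed = 1L) {
  limb_group <- match.arg(limb_group)
  if (n_frames < 6L) stop("need at least 6 frames", call. = FALSE)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  clutter <- if (clutter_sd > 0)
    gaussian_blur(matrix(stats::rnorm(H * W, 0, clutter_sd), H, W), 2) else 0
  # static trunk: vertical ellipse at mid frame, kept away from the moving half
  trunk <- render_blob(H, W, (H - 1) / 2, (W - 1) / 2, H / 10, W / 14, amp = 0.6)
  base_row <- if (limb_group == "upper") H / 5 else 4 * H / 5
  base_col <- (W - 1) / 2
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    dx <- amplitude * sin(2 * pi * (t - 1) / period)
    app <- render_blob(H, W, base_row, base_col + dx, H / 16, W / 16, amp = 1)
    # hard confinement to the group's half-frame
    if (limb_group == "upper") app[(floor(H / 2) + 1L):H, ] <- 0
    else app[seq_len(floor(H / 2)), ] <- 0
    f <- trunk + app + clutter
    if (noise_sd > 0) f <- f + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    frames[[t]] <- f
  }
  centroids <- t(vapply(seq_len(n_frames - 1L), function(t) {
    d <- abs(frames[[t + 1L]] - frames[[t]])
    s <- sum(d)
    if (s <= 0) return(c(NA_real_, NA_real_))
    c(sum(d * (matrix(seq_len(H), H, W) - 1)) / s,
      sum(d * (matrix(seq_len(W), H, W, byrow = TRUE) - 1)) / s)
  }, numeric(2)))
  list(frames = frames, label = limb_group,
       manifest = list(kind = "action", shape = c(H, W),
                       limb_group = limb_group, n_frames = n_frames,
                       amplitude = amplitude, period = period,
                       noise_sd = noise_sd, clutter_sd = clutter_sd,
                       seed = seed, motion_centroids = centroids))
}

#' Generate a labeled dataset of synthetic action sequences
#'
#' @param n_per_class sequences per class.
#' @param classes named character vector mapping class name to limb group,
#'   e.g. c(boxing = "upper", walking = "lower").
#' @param shape,n_frames,seed passed through; each sequence gets a distinct
#'   deterministic seed derived from `seed`.
#' @param ... further arguments for [gen_action_sequence()].
#' @return list(sequences = list of gen_action_sequence outputs with $class,
#'   manifest).
#' @export
gen_action_dataset <- function(n_per_class = 20L,
                               classes = c(boxing = "upper", walking = "lower"),
                               shape = c(64L, 64L), n_frames = 8L,
                               seed = 1L, ...) {
  sequences <- list()
  i <- 0L
  for (cl in names(classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      s <- gen_action_sequence(shape = shape, limb_group = classes[[cl]],
                               n_frames = n_frames,
                               seed = (seed * 10000L + i) %% 2147483647L, ...)
      s$class <- cl
      sequences[[i]] <- s
    }
  }
  list(sequences = sequences,
       manifest = list(kind = "action_dataset", classes = as.list(classes),
                       n_per_class = n_per_class, n_sequences = i, seed = seed))
}

# Set the RNG reproducibly and return a restorer closure.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
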