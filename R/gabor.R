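#' Gabor wavelet element dictionaries
#'
#' The form pathway rests on an analytic dictionary of oriented, scaled Gabor
#' wavelet pairs (even/cosine and odd/sine phase), emulating V1 simple-cell
#' orientation detectors. Orientations are the n equally spaced angles
#' \{k*pi/n, k = 0..n-1\} (the angle of the bar the element responds to, modulo
#' pi); scales follow a geometric frequency progression
#' omega_i = omega0 / scale_step^(i-1).
#'
#' Every kernel is DC-removed and l2-normalized, so filter responses are
#' invariant to additive intensity shifts; the even and odd kernels of a pair
#' are mutually orthogonal by symmetry.
#'
#' @name gabor
NULL

round_odd <- function(x) {
  k <- max(3L, as.integer(round(x)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Build a single Gabor element pair
#'
#' @param orientation bar orientation in radians (modulo pi).
#' @param omega carrier spatial frequency, radians per pixel.
#' @param size odd kernel side length in pixels.
#' @param gamma envelope aspect ratio; the Gaussian std along the bar is
#'   sigma/gamma, across the bar sigma.
#' @param sigma_factor sigma as a multiple of the carrier wavelength.
#' @return a `gabor_element`: orientation, scale data and the kernel pair.
#' @keywords internal
gabor_element <- function(orientation, omega, size, gamma = 0.5,
                          sigma_factor = 0.56,
                          orientation_index = NA_integer_,
                          scale_index = NA_integer_) {
  stopifnot(size %% 2L == 1L, size >= 5L, omega > 0)
  half <- (size - 1L) / 2L
  xs <- matrix(rep(-half:half, each = size), size, size)   # col offsets
  ys <- matrix(rep(-half:half, times = size), size, size)  # row offsets
  # u: coordinate across the bar (carrier direction); t: along the bar
  u <- -xs * sin(orientation) + ys * cos(orientation)
  tt <- xs * cos(orientation) + ys * sin(orientation)
  lambda <- 2 * pi / omega
  sigma <- sigma_factor * lambda
  env <- exp(-(u^2 + gamma^2 * tt^2) / (2 * sigma^2))
  ke <- env * cos(omega * u)
  ko <- env * sin(omega * u)
  # DC removal then unit l2 norm; ko is antisymmetric so its mean is already ~0
  ke <- ke - mean(ke)
  ko <- ko - mean(ko)
  ke <- ke / sqrt(sum(ke^2))
  ko <- ko / sqrt(sum(ko^2))
  structure(list(orientation = orientation,
                 orientation_index = orientation_index,
                 scale_index = scale_index,
                 omega = omega, size = size,
                 kernel_even = ke, kernel_odd = ko),
            class = "gabor_element")
}

#' Build the Gabor wavelet dictionary
#'
#' Constructs the n_orientations x n_scales bank of even/odd Gabor pairs used
#' by both the orientation detectors and the active basis model.
#'
#' @param n_orientations number of equally spaced orientations (default 8).
#' @param n_scales number of scales (default 2).
#' @param base_size odd kernel side length at the finest scale (default 17);
#'   coarser scales grow proportionally to wavelength.
#' @param omega0 carrier frequency at the finest scale, radians/pixel.
#' @param scale_step geometric step between scale frequencies (default sqrt(2),
#'   i.e. successive scales differ by a factor 2 in area).
#' @param gamma envelope aspect ratio (default 0.5).
#' @return a `gabor_dictionary` with `elements` ordered scale-major then
#'   orientation, length n_orientations * n_scales.
#' @export
#' @examples
#' d <- build_gabor_dictionary(8, 2, 17)
#' length(d$elements)  # 16
build_gabor_dictionary <- function(n_orientations = 8L, n_scales = 2L,
                                   base_size = 17L, omega0 = pi / 2,
                                   scale_step = sqrt(2), gamma = 0.5) {
  n_orientations <- as.integer(n_orientations)
  n_scales <- as.integer(n_scales)
  if (n_orientations < 1L || n_scales < 1L)
    stop("n_orientations and n_scales must be >= 1", call. = FALSE)
  if (base_size %% 2L != 1L || base_size < 5L)
    stop("base_size must be an odd integer >= 5", call. = FALSE)
  orientations <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  elements <- vector("list", n_orientations * n_scales)
  sizes <- integer(n_scales)
  idx <- 1L
  for (s in seq_len(n_scales)) {
    omega <- omega0 / scale_step^(s - 1L)
    size <- round_odd(base_size * scale_step^(s - 1L))
    sizes[s] <- size
    for (o in seq_len(n_orientations)) {
      elements[[idx]] <- gabor_element(orientations[o], omega, size,
                                       gamma = gamma,
                                       orientation_index = o,
                                       scale_index = s)
      idx <- idx + 1L
    }
  }
  structure(list(n_orientations = n_orientations, n_scales = n_scales,
                 orientations = orientations, kernel_sizes = sizes,
                 base_size = as.integer(base_size), omega0 = omega0,
                 scale_step = scale_step, gamma = gamma,
                 elements = elements),
            class = "gabor_dictionary")
}

#' Index into a dictionary by orientation and scale
#' @param dictionary a `gabor_dictionary`.
#' @param orientation_index,scale_index 1-based indices.
#' @return the `gabor_element` at that orientation and scale.
#' @export
dict_element <- function(dictionary, orientation_index, scale_index) {
  dictionary$elements[[(scale_index - 1L) * dictionary$n_orientations +
                         orientation_index]]
}

#' Same-size zero-padded 2-D cross-correlation
#'
#' Anchored at the kernel center: out[r, c] = sum over kernel offsets of
#' kern * frame, with zeros outside the frame lattice (pad-then-crop).
#' Computed by FFT over a linear-convolution-sized zero pad (exact to
#' floating-point rounding; the suite checks it against a nested-loop oracle).
#' @keywords internal
corr2_same <- function(frame, kern) {
  H <- nrow(frame); W <- ncol(frame)
  k <- nrow(kern); h <- (k - 1L) / 2L
  if (H < k || W < k)
    stop("frame smaller than kernel (", k, "x", k, ")", call. = FALSE)
  P1 <- stats::nextn(H + k - 1L, c(2L, 3L, 5L))
  P2 <- stats::nextn(W + k - 1L, c(2L, 3L, 5L))
  A <- matrix(0, P1, P2); A[1:H, 1:W] <- frame
  B <- matrix(0, P1, P2); B[1:k, 1:k] <- kern[k:1, k:1]  # flip: corr = conv
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (P1 * P2)
  conv[(h + 1L):(h + H), (h + 1L):(h + W)]
}

#' Complex-magnitude Gabor response map
#'
#' Correlates a frame with an element's even and odd kernels (zero-padded,
#' cropped back to the frame lattice) and returns the quadrature magnitude
#' sqrt(<I,ke>^2 + <I,ko>^2) at every position.
#'
#' @param frame 2-D numeric matrix (grayscale frame).
#' @param element a `gabor_element`.
#' @return matrix of the frame's shape with the per-position response.
#' @export
gabor_respond <- function(frame, element) {
  stopifnot(is.matrix(frame), inherits(element, "gabor_element"))
  re <- corr2_same(frame, element$kernel_even)
  ro <- corr2_same(frame, element$kernel_odd)
  sqrt(re^2 + ro^2)
}

#' All response maps of a dictionary on one frame
#'
#' @return list indexed like `dictionary$elements` of magnitude response maps.
#' @export
gabor_respond_all <- function(frame, dictionary) {
  stopifnot(inherits(dictionary, "gabor_dictionary"))
  lapply(dictionary$elements, function(el) gabor_respond(frame, el))
}
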