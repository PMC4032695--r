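# Small image-operation helpers shared by the flow and fixture code.
# Frames are plain numeric matrices: rows = y (down), cols = x (right).

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  half <- (length(k) - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  ridx <- pmin(pmax(seq_len(H + 2L * half) - half, 1L), H)
  cidx <- pmin(pmax(seq_len(W + 2L * half) - half, 1L), W)
  pad <- img[ridx, , drop = FALSE]
  out <- matrix(0, H, W)
  for (a in seq_along(k)) out <- out + k[a] * pad[a:(a + H - 1L), , drop = FALSE]
  pad <- out[, cidx, drop = FALSE]
  out2 <- matrix(0, H, W)
  for (a in seq_along(k)) out2 <- out2 + k[a] * pad[, a:(a + W - 1L), drop = FALSE]
  out2
}

# Bilinear resize to (H2, W2); coordinates aligned on pixel centers.
imresize_bilinear <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  if (H2 == H && W2 == W) return(img)
  rs <- if (H2 == 1L) rep((H + 1) / 2, 1L) else (seq_len(H2) - 1) * (H - 1) / (H2 - 1) + 1
  cs <- if (W2 == 1L) rep((W + 1) / 2, 1L) else (seq_len(W2) - 1) * (W - 1) / (W2 - 1) + 1
  r0 <- pmin(floor(rs), H - 1L); c0 <- pmin(floor(cs), W - 1L)
  fr <- rs - r0; fc <- cs - c0
  A <- img[r0, c0, drop = FALSE]; B <- img[r0, c0 + 1L, drop = FALSE]
  C <- img[r0 + 1L, c0, drop = FALSE]; D <- img[r0 + 1L, c0 + 1L, drop = FALSE]
  FR <- matrix(fr, H2, W2); FC <- matrix(fc, H2, W2, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * (1 - FR) * FC + C * FR * (1 - FC) + D * FR * FC
}

# Bilinear sample of img at (rows + v, cols + u); replicate padding.
# Returns list(values, inside) where inside flags samples taken fully
# within the frame (mask weight 1) vs clamped border samples (weight 0).
warp_bilinear <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  R <- matrix(seq_len(H), H, W) + v
  C <- matrix(seq_len(W), H, W, byrow = TRUE) + u
  inside <- (R >= 1) & (R <= H) & (C >= 1) & (C <= W)
  R <- pmin(pmax(R, 1), H); C <- pmin(pmax(C, 1), W)
  r0 <- pmin(floor(R), H - 1L); c0 <- pmin(floor(C), W - 1L)
  fr <- R - r0; fc <- C - c0
  i00 <- (c0 - 1L) * H + r0
  vals <- img[i00] * (1 - fr) * (1 - fc) +
    img[i00 + H] * (1 - fr) * fc +
    img[i00 + 1L] * fr * (1 - fc) +
    img[i00 + H + 1L] * fr * fc
  list(values = matrix(vals, H, W), inside = inside)
}

# Integer or fractional toroidal shift: content moves by (dx right, dy down).
shift_wrap <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  if (dx == round(dx) && dy == round(dy)) {
    ridx <- ((seq_len(H) - 1L - as.integer(round(dy))) %% H) + 1L
    cidx <- ((seq_len(W) - 1L - as.integer(round(dx))) %% W) + 1L
    return(img[ridx, cidx, drop = FALSE])
  }
  R <- matrix(seq_len(H), H, W) - dy
  C <- matrix(seq_len(W), H, W, byrow = TRUE) - dx
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  w <- function(rr, cc) {
    rr <- ((rr - 1L) %% H) + 1L; cc <- ((cc - 1L) %% W) + 1L
    img[cbind(as.vector(rr), as.vector(cc))]
  }
  vals <- w(r0, c0) * (1 - fr) * (1 - fc) + w(r0, c0 + 1L) * (1 - fr) * fc +
    w(r0 + 1L, c0) * fr * (1 - fc) + w(r0 + 1L, c0 + 1L) * fr * fc
  matrix(vals, H, W)
}

# Horizontal mirror (flip columns).
mirror_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Clamp to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
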