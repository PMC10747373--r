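# Internal numerical helpers shared across modules.

# Reflective (mirror, edge not repeated: "reflect" a b c -> b a | a b c | c b)
# padding of a matrix by `k` pixels on every side. k may exceed dim - 1 is not
# supported; callers keep k < min(dim).
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc)
    stop("reflective pad width must be smaller than the image", call. = FALSE)
  ri <- c((k + 1L):2L, 1L:nr, (nr - 1L):(nr - k))
  ci <- c((k + 1L):2L, 1L:nc, (nc - 1L):(nc - k))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1-D kernel along rows then columns, reflective
# boundaries. Kernel must be odd-length.
conv_separable <- function(m, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  if (k == 0L) return(m * kernel)
  p <- pad_reflect(m, k)
  nr <- nrow(m); nc <- ncol(m)
  # along columns (vertical)
  tmp <- matrix(0, nr, nc + 2L * k)
  for (j in seq_along(kernel))
    tmp <- tmp + kernel[j] * p[(j):(j + nr - 1L), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * tmp[, (j):(j + nc - 1L), drop = FALSE]
  out
}

# Gaussian blur with standard deviation sigma_px (pixels), reflective
# boundaries; kernel truncated at 5 sigma and renormalized.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- max(1L, as.integer(ceiling(5 * sigma_px)))
  x <- (-k):k
  kern <- exp(-x^2 / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  conv_separable(m, kern)
}

# Discrete 4-neighbour Laplacian, reflective boundaries.
laplacian4 <- function(m) {
  p <- pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  p[1:nr, 2:(nc + 1L)] + p[3:(nr + 2L), 2:(nc + 1L)] +
    p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 3:(nc + 2L)] - 4 * m
}

# Box (moving-window) sum over a (2r+1)^2 square via summed-area table.
# Input must already be padded so every window is fully defined: for an
# (nr + 2r) x (nc + 2r) input the result is nr x nc.
box_sum <- function(p, r) {
  w <- 2L * r + 1L
  nr <- nrow(p) - 2L * r; nc <- ncol(p) - 2L * r
  s <- apply(p, 2L, cumsum)
  s <- rbind(0, s)
  v <- s[(w + 1L):(w + nr), , drop = FALSE] - s[1:nr, , drop = FALSE]
  s2 <- t(apply(v, 1L, cumsum))
  s2 <- cbind(0, s2)
  s2[, (w + 1L):(w + nc), drop = FALSE] - s2[, 1:nc, drop = FALSE]
}

# Centered DFT frequency axis for n samples at pitch `delta`:
# frequencies in cycles per unit of delta, ascending, DC at position n/2 + 1.
fft_freq_centered <- function(n, delta) {
  (seq_len(n) - 1L - n %/% 2L) / (n * delta)
}

# Shift a 2-D DFT so DC moves to the centre (row/col n/2 + 1).
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr %/% 2L + 1L):nr, 1L:(nr %/% 2L)),
    c((nc %/% 2L + 1L):nc, 1L:(nc %/% 2L)), drop = FALSE]
}

# Mean over y in [0,1] of clamp(a + (b - a) y, 0, 1): exact integral of a
# clamped linear ramp, vectorized over (a, b). Used for sub-pixel
# area-fraction edge rendering.
clamped_linear_mean <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  # integral of clamp(t, 0, 1) dt over [lo, hi], divided by (hi - lo)
  # piecewise: t < 0 contributes 0; 0 <= t <= 1 contributes t; t > 1 -> 1
  t0 <- pmin(pmax(lo, 0), 1); t1 <- pmin(pmax(hi, 0), 1)
  mid <- (t1^2 - t0^2) / 2          # over the linear section
  up  <- pmax(hi - pmax(lo, 1), 0)  # length of the saturated-at-1 section
  out <- (mid + up) / (hi - lo)
  flat <- a == b
  out[flat] <- pmin(pmax(a[flat], 0), 1)
  out
}

# unnormalized sinc with argument x = pi f w: sin(x)/x, value 1 at x = 0.
sinc_pi <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
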