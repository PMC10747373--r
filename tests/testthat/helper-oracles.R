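# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written without reusing package internals.

# Area of the part of the axis-aligned rectangle [x0,x1] x [y0,y1] lying in
# the half-plane a*x + b*y + c >= 0, by Sutherland-Hodgman clipping and the
# shoelace formula.
halfplane_clip_area <- function(x0, x1, y0, y1, a, b, c) {
  poly <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  out <- list()
  n <- length(poly)
  for (i in seq_len(n)) {
    p <- poly[[i]]; q <- poly[[if (i == n) 1L else i + 1L]]
    fp <- a * p[1] + b * p[2] + c
    fq <- a * q[1] + b * q[2] + c
    if (fp >= 0) out[[length(out) + 1L]] <- p
    if ((fp > 0 && fq < 0) || (fp < 0 && fq > 0)) {
      t <- fp / (fp - fq)
      out[[length(out) + 1L]] <- p + t * (q - p)
    }
  }
  if (length(out) < 3L) return(0)
  xs <- vapply(out, `[`, 0, 1); ys <- vapply(out, `[`, 0, 2)
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# Direct-summation edge preservation index: own reflective 3x3 Laplacian,
# explicit loops, straight correlation formula.
epi_oracle <- function(ref, mea, roi) {
  lap <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    refl <- function(i, n) ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      out[r, c] <- m[refl(r - 1L, nr), c] + m[refl(r + 1L, nr), c] +
        m[r, refl(c - 1L, nc)] + m[r, refl(c + 1L, nc)] - 4 * m[r, c]
    }
    out
  }
  sub <- function(m) m[(roi$row0 + 1):(roi$row0 + roi$height),
                       (roi$col0 + 1):(roi$col0 + roi$width)]
  a <- sub(lap(ref)); b <- sub(lap(mea))
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

# Small noisy flat-field raster (Gaussian noise, fixed seed).
noisy_flat <- function(n = 64L, mean = 1000, sd = 10, seed = 1L,
                       pitch = 0.048) {
  withr::with_seed(seed,
    raster_image(matrix(rnorm(n * n, mean, sd), n, n), pitch))
}

# Noiseless tilted-edge raster plus an ROI spanning the edge.
edge_fixture <- function(n = 128L, angle = 2, fluence = 100,
                         pitch = 0.048) {
  sc <- render_scene(scene_spec("edge", fluence = fluence,
                                edge_angle_deg = angle),
                     c(n, n), pitch)
  margin <- as.integer(ceiling(n * tan(angle * pi / 180))) + 10L
  roi <- rect_roi(4L, n %/% 2L - margin - 10L, n - 8L, 2L * (margin + 10L))
  list(img = sc, roi = roi)
}

# closed-form sin(x)/x used by the analytic MTF oracles
sinc_oracle <- function(x) ifelse(x == 0, 1, sin(x) / x)

# Deterministic small random raster.
rand_raster <- function(nr = 8L, nc = nr, seed = 1L, pitch = 0.048) {
  withr::with_seed(seed, raster_image(matrix(runif(nr * nc), nr, nc), pitch))
}
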