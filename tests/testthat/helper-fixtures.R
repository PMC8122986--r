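# Small fixtures shared across the suite: everything generated in code.

tiny_phantom <- function(seed = 1, shape = c(24, 24, 14)) {
  generate_phantom(phantom_spec(shape = shape, n_blobs = 4,
                                texture_scale = 4, noise_sigma = 0.005,
                                seed = seed))
}

# scaled-down study generators: small widths, full structure
tiny_g1_spec <- function(...) {
  generator_spec("rfb_esrgan", n_rrdb = 1, n_rrfdb = 1, base_channels = 8,
                 ...)
}
tiny_g2_spec <- function(...) {
  generator_spec("nesrgan", n_rrdb = 1, base_channels = 8, ...)
}
# training-sized stage-1 spec (RRDB trunk only, the cost-dominant part)
train_g1_spec <- function() {
  generator_spec("rfb_esrgan", n_rrdb = 1, n_rrfdb = 0, base_channels = 8)
}

# independent bicubic reference: direct separable Keys-kernel evaluation by
# double loop, used as the oracle for the matrix-based resize
naive_bicubic <- function(x, out_dim, antialias = TRUE) {
  keys <- function(t) {
    a <- -0.5; at <- abs(t)
    ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
           ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
  }
  res1d <- function(v, n_out) {
    n_in <- length(v)
    scale <- n_in / n_out
    stretch <- if (antialias && scale > 1) scale else 1
    out <- numeric(n_out)
    for (i in seq_len(n_out)) {
      pos <- (i - 0.5) * scale + 0.5
      idx <- floor(pos - 2 * stretch):ceiling(pos + 2 * stretch)
      w <- keys((pos - idx) / stretch)
      keep <- w != 0
      idx <- pmin(pmax(idx[keep], 1), n_in)
      w <- w[keep]
      out[i] <- sum(w * v[idx]) / sum(w)
    }
    out
  }
  y <- apply(x, 2, res1d, n_out = out_dim[1])
  y <- matrix(y, out_dim[1], ncol(x))
  t(apply(y, 1, res1d, n_out = out_dim[2]))
}

# brute-force SSIM: explicit loop over sliding windows
naive_ssim <- function(x, y, size = 7, max_i = 1) {
  c1 <- (0.01 * max_i)^2; c2 <- (0.03 * max_i)^2
  vals <- c()
  for (i in 1:(nrow(x) - size + 1)) for (j in 1:(ncol(x) - size + 1)) {
    wx <- x[i:(i + size - 1), j:(j + size - 1)]
    wy <- y[i:(i + size - 1), j:(j + size - 1)]
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# exhaustive missing-voxel count for an interval-1 tri-planar rebuild:
# a voxel is written by a plane iff its coordinate on that plane's axis is
# one of the kept (odd, 1-based) indices
naive_missing_fraction <- function(shape) {
  n_missing <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3]))
      if (i %% 2 == 0 && j %% 2 == 0 && k %% 2 == 0)
        n_missing <- n_missing + 1L
  n_missing / prod(shape)
}

# central finite difference of f at x (vector argument)
fd_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a), abs(b), 1e-8))
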