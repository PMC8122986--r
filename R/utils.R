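#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Cubic convolution (Keys) kernel
#'
#' The piecewise-cubic interpolation kernel with a = -0.5, the standard
#' "bicubic" kernel. Support is \[-2, 2\].
#'
#' @param x numeric vector of sample offsets.
#' @return kernel weights, same length as `x`.
#' @keywords internal
keys_kernel <- function(x) {
  a <- -0.5
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# 1D resampling matrix (n_out x n_in) for a separable resize from n_in to
# n_out samples. Output sample i (1-based) is placed at input coordinate
# (i - 0.5) * n_in / n_out + 0.5 (half-pixel alignment, the convention used
# by common bicubic resizers). When downscaling with antialias = TRUE the
# kernel is stretched by the scale factor, the usual anti-aliasing treatment.
# Border samples are handled by clamping indices (edge replication) and rows
# are renormalised to sum to 1, so constants are resized to constants exactly.
resize_matrix <- function(n_in, n_out,
                          kernel = c("cubic", "linear", "nearest"),
                          antialias = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(n_in >= 1, n_out >= 1)
  if (n_in == n_out && kernel != "nearest") return(diag(n_in))
  scale <- n_in / n_out
  kwidth <- switch(kernel, cubic = 2, linear = 1, nearest = 0.5)
  stretch <- if (antialias && scale > 1) scale else 1
  support <- kwidth * stretch
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    pos <- (i - 0.5) * scale + 0.5          # centre in input coordinates
    lo <- floor(pos - support)
    hi <- ceiling(pos + support)
    idx <- lo:hi
    d <- (pos - idx) / stretch
    w <- switch(kernel,
      cubic   = keys_kernel(d),
      linear  = pmax(0, 1 - abs(d)),
      nearest = as.numeric(abs(d) <= 0.5)
    )
    if (kernel == "nearest" && sum(w) > 1) w[which(w > 0)[-1]] <- 0
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 1), n_in)   # clamp = replicate borders
    w <- w[keep]
    w <- w / sum(w)
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + w[j]
  }
  M
}

# Apply separable resize matrices A (rows) and B (cols) to a 2D matrix.
resize2d <- function(x, A, B) A %*% x %*% t(B)

#' Resize a 2D image by interpolation
#'
#' @param x numeric matrix.
#' @param out_dim integer pair, output (rows, cols).
#' @param kernel `"cubic"` (default, Keys bicubic), `"linear"` or `"nearest"`.
#' @param antialias stretch the kernel when downscaling (default `TRUE`).
#' @return numeric matrix of dimension `out_dim`.
#' @export
resize_image <- function(x, out_dim, kernel = "cubic", antialias = TRUE) {
  stopifnot(is.matrix(x), length(out_dim) == 2, all(out_dim >= 1))
  A <- resize_matrix(nrow(x), out_dim[1], kernel, antialias)
  B <- resize_matrix(ncol(x), out_dim[2], kernel, antialias)
  resize2d(x, A, B)
}

# Apply a 1D resampling matrix along one axis of a 3D array.
resize_along_axis <- function(vox, M, axis) {
  d <- dim(vox)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  x <- aperm(vox, perm)
  dx <- dim(x)
  y <- M %*% matrix(x, dx[1], dx[2] * dx[3])
  y <- array(y, c(nrow(M), dx[2], dx[3]))
  aperm(y, order(perm))
}

fmt_shape <- function(shape) paste(shape, collapse = "x")
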