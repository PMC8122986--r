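#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_i^2 / MSE)` in decibels; `Inf` when the images are
#' identical. Under the package's intensity convention (per-volume min-max
#' normalization) the dynamic range `max_i` is 1.
#'
#' @param x,y numeric arrays of identical shape.
#' @param max_i dynamic range (default 1; use 255 for 8-bit comparisons).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, max_i = 1) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("shape mismatch")
  if (max_i <= 0) stop("max_i must be > 0")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_i^2 / mse)
}

ssim_window <- function(window = c("uniform", "gaussian"), size = NULL,
                        sigma = 1.5) {
  window <- match.arg(window)
  if (is.null(size)) size <- if (window == "uniform") 7L else 11L
  w <- if (window == "uniform") rep(1, size)
       else exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sigma^2))
  w / sum(w)
}

# banded matrix applying a 1D window at every valid position (n-k+1 x n)
window_matrix <- function(n, w) {
  k <- length(w)
  M <- matrix(0, n - k + 1, n)
  for (i in seq_len(n - k + 1)) M[i, i:(i + k - 1)] <- w
  M
}

#' Structural similarity index
#'
#' Mean over sliding windows of
#' `((2 mu_x mu_y + c1)(2 sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' using local means, variances and covariance; `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` with `L = max_i`, the universal stabilizers.
#'
#' @param x,y numeric matrices of identical shape.
#' @param window `"uniform"` (default, 7x7) or `"gaussian"` (11x11,
#'   sigma 1.5).
#' @param size window side; `NULL` picks the default for the window type.
#' @param max_i dynamic range L (default 1).
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, window = "uniform", size = NULL, max_i = 1) {
  if (!is.matrix(x) || !is.matrix(y) || !identical(dim(x), dim(y)))
    stop("x and y must be matrices of identical shape")
  w <- ssim_window(window, size)
  k <- length(w)
  if (any(dim(x) < k)) stop("window larger than the image")
  c1 <- (0.01 * max_i)^2
  c2 <- (0.03 * max_i)^2
  A <- window_matrix(nrow(x), w)
  B <- window_matrix(ncol(x), w)
  loc <- function(m) A %*% m %*% t(B)
  mx <- loc(x); my <- loc(y)
  vx <- loc(x * x) - mx^2
  vy <- loc(y * y) - my^2
  cxy <- loc(x * y) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Per-plane slicewise volume evaluation
#'
#' Computes each metric on every 2D slice of each requested plane and
#' aggregates to mean and standard deviation, the layout of standard
#' per-plane SR comparison tables. Slices where PSNR is infinite (identical
#' content) are flagged and excluded from the PSNR mean.
#'
#' @param pred,truth `mri_volume`s (or 3D arrays) of identical shape.
#' @param planes subset of `c("sagittal", "coronal", "axial")`.
#' @param metrics subset of `c("psnr", "ssim")`.
#' @param max_i dynamic range (default 1).
#' @param label method name recorded in the report.
#' @return a `metric_report` data.frame with columns `label`, `plane`,
#'   `metric`, `mean`, `sd`, `n_slices`, `n_infinite`.
#' @export
evaluate_volume <- function(pred, truth, planes = PLANES,
                            metrics = c("psnr", "ssim"), max_i = 1,
                            label = "method") {
  pv <- if (inherits(pred, "mri_volume")) pred$voxels else pred
  tv <- if (inherits(truth, "mri_volume")) truth$voxels else truth
  if (!identical(dim(pv), dim(tv))) stop("shape mismatch")
  planes <- match.arg(planes, PLANES, several.ok = TRUE)
  metrics <- match.arg(metrics, c("psnr", "ssim"), several.ok = TRUE)
  rows <- list()
  for (pl in planes) {
    sp <- extract_slices(pv, pl)
    st <- extract_slices(tv, pl)
    for (m in metrics) {
      vals <- vapply(seq_along(sp$slices), function(i) {
        if (m == "psnr") psnr(sp$slices[[i]], st$slices[[i]], max_i)
        else ssim(sp$slices[[i]], st$slices[[i]], max_i = max_i)
      }, numeric(1))
      inf <- !is.finite(vals)
      if (m == "psnr" && any(inf))
        warning(sum(inf), " identical ", pl,
                " slice(s) give infinite PSNR; excluded from the mean")
      use <- vals[is.finite(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, plane = pl, metric = m,
        mean = if (length(use)) mean(use) else Inf,
        sd = if (length(use) > 1) stats::sd(use) else 0,
        n_slices = length(vals), n_infinite = sum(inf),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Per-plane slicewise metrics (mean ± sd):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %-8s %-5s %7.3f ± %.3f  (n = %d)\n",
                x$label[i], x$plane[i], toupper(x$metric[i]),
                x$mean[i], x$sd[i], x$n_slices[i]))
  invisible(x)
}

#' Optional LPIPS plug-in seam
#'
#' Delegates to an externally supplied perceptual scorer (a function of two
#' slices returning one number; lower = more similar). Pretrained perceptual
#' networks are never shipped: without a scorer the metric is skipped with a
#' notice, and a failing scorer is converted into a skip, never a crash.
#'
#' @param pred_slice,truth_slice 2D matrices.
#' @param external_scorer `function(pred, truth) -> numeric(1)`, or `NULL`.
#' @return the scorer's value, or `NA_real_` (with a message) when skipped.
#' @export
lpips_adapter <- function(pred_slice, truth_slice, external_scorer = NULL) {
  if (is.null(external_scorer)) {
    message("LPIPS scorer not supplied; metric skipped")
    return(NA_real_)
  }
  tryCatch(as.numeric(external_scorer(pred_slice, truth_slice)),
           error = function(e) {
             message("LPIPS scorer failed (", conditionMessage(e),
                     "); metric skipped")
             NA_real_
           })
}
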