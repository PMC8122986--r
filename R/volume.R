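#' 3D MRI volume with normalization metadata
#'
#' The unit of reconstruction: a 3D voxel grid in the canonical axis order
#' (x = sagittal index, y = coronal index, z = axial index) with intensities
#' min-max normalized to \[0, 1\] and the raw range kept so that raw
#' intensities can be recovered on write.
#'
#' @param voxels 3D numeric array.
#' @param normalize if `TRUE` (default) min-max normalize to \[0, 1\];
#'   if `FALSE` the array is taken as already normalized.
#' @param norm length-2 numeric, the raw (min, max) of the source data.
#' @return an object of class `mri_volume` with fields `voxels`, `norm`,
#'   `shape`.
#' @export
as_volume <- function(voxels, normalize = TRUE, norm = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array, got ",
         paste(dim(voxels), collapse = "x"))
  if (any(!is.finite(voxels)))
    stop("volume contains non-finite voxels (NaN/Inf)")
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (normalize) {
    rng <- range(voxels)
    if (diff(rng) == 0) {
      warning("constant volume: normalization degenerates to all zeros")
      voxels[] <- 0
    } else {
      voxels <- (voxels - rng[1]) / (rng[2] - rng[1])
    }
    norm <- rng
  } else {
    if (min(voxels) < 0 || max(voxels) > 1)
      stop("normalize = FALSE requires intensities already in [0, 1]")
    if (is.null(norm)) norm <- c(0, 1)
  }
  structure(list(voxels = voxels, norm = as.numeric(norm),
                 shape = dim(voxels)),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume %s> intensity range [%.4g, %.4g], raw [%g, %g]\n",
              fmt_shape(x$shape), min(x$voxels), max(x$voxels),
              x$norm[1], x$norm[2]))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) x$shape

#' Recover raw (pre-normalization) intensities
#' @param vol an `mri_volume`.
#' @return 3D array on the original intensity scale.
#' @export
denormalize <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  vol$voxels * (vol$norm[2] - vol$norm[1]) + vol$norm[1]
}

# Nearest axis permutation/flips taking the NIfTI xform to the canonical
# (sagittal, coronal, axial) voxel order. Works on the rotation part only;
# no resampling.
canonical_perm <- function(affine) {
  R <- affine[1:3, 1:3]
  if (any(!is.finite(R)) || abs(det(R)) < 1e-12)
    return(list(perm = 1:3, flip = rep(FALSE, 3)))
  perm <- integer(3); flip <- logical(3); used <- logical(3)
  for (j in 1:3) {                     # voxel axis j maps to world axis ax
    cand <- abs(R[, j]); cand[used] <- -Inf
    ax <- which.max(cand)
    used[ax] <- TRUE
    perm[ax] <- j
    flip[ax] <- R[ax, j] < 0
  }
  list(perm = perm, flip = flip)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image, permutes axes to the canonical
#' (sagittal, coronal, axial) order using the nearest axis permutation of the
#' image xform, and min-max normalizes intensities to \[0, 1\].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param normalize min-max normalize (default `TRUE`).
#' @return an [as_volume()] `mri_volume`.
#' @export
read_volume <- function(path, normalize = TRUE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D NIfTI image, got ", length(d), " dimensions")
  vox <- array(as.numeric(img), d)
  cp <- tryCatch(canonical_perm(RNifti::xform(img)),
                 error = function(e) list(perm = 1:3, flip = rep(FALSE, 3)))
  if (!identical(cp$perm, 1:3)) vox <- aperm(vox, cp$perm)
  for (ax in which(cp$flip)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- rev(seq_len(dim(vox)[ax]))
    vox <- do.call(`[`, c(list(vox), idx, list(drop = FALSE)))
  }
  if (normalize) return(as_volume(vox, normalize = TRUE))
  # keep stored intensities as-is; only valid for files already on [0, 1]
  if (min(vox) < 0 || max(vox) > 1)
    stop("normalize = FALSE requires stored intensities in [0, 1]; ",
         "this file spans [", min(vox), ", ", max(vox), "]")
  as_volume(vox, normalize = FALSE, norm = c(0, 1))
}

#' Write a volume to NIfTI
#'
#' Raw (denormalized) intensities are written as float32 so that
#' `read_volume(write_volume(v))` recovers `v` to dtype tolerance.
#'
#' @param vol an `mri_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  if (any(!is.finite(vol$voxels))) stop("volume contains non-finite voxels")
  img <- RNifti::asNifti(denormalize(vol), datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Downscale a volume by an integer factor
#'
#' Separable cubic-convolution (Keys, antialiased) resampling along each
#' axis; each dimension becomes `ceiling(dim / factor)`. This simulates the
#' half-resolution acquisition that the two-pass reconstruction takes as
#' input (e.g. 256x256x150 -> 128x128x75 at factor 2).
#'
#' @param vol an `mri_volume`.
#' @param factor integer >= 2.
#' @return downscaled `mri_volume` (intensities re-clipped to \[0, 1\]).
#' @export
downscale_volume <- function(vol, factor = 2) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!is.numeric(factor) || factor < 2)
    stop("`factor` must be >= 2")
  vox <- vol$voxels
  for (ax in 1:3) {
    n_in <- dim(vox)[ax]
    M <- resize_matrix(n_in, ceiling(n_in / factor), "cubic", antialias = TRUE)
    vox <- resize_along_axis(vox, M, ax)
  }
  as_volume(clamp01(vox), normalize = FALSE, norm = vol$norm)
}
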