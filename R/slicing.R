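PLANES <- c("sagittal", "coronal", "axial")

plane_axis <- function(plane) {
  plane <- match.arg(plane, PLANES)
  match(plane, PLANES)
}

# dimensions of a single 2D slice for a plane within a volume shape
slice_dims <- function(shape, plane) shape[-plane_axis(plane)]

new_slice_stack <- function(plane, slices, source_indices, source_shape) {
  plane <- match.arg(plane, PLANES)
  stopifnot(length(slices) == length(source_indices))
  if (length(source_indices) > 1 && any(diff(source_indices) <= 0))
    stop("source_indices must be strictly increasing")
  if (any(source_indices < 1) ||
      any(source_indices > source_shape[plane_axis(plane)]))
    stop("source_indices out of range for the plane axis")
  sd <- vapply(slices, dim, integer(2))
  if (length(slices) && !all(sd[1, ] == sd[1, 1] & sd[2, ] == sd[2, 1]))
    stop("all slices in a stack must share one 2D shape")
  structure(list(plane = plane, slices = slices,
                 source_indices = as.integer(source_indices),
                 source_shape = as.integer(source_shape)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  sd <- if (length(x$slices)) dim(x$slices[[1]]) else c(0, 0)
  cat(sprintf("<slice_stack %s> %d slice(s) of %dx%d from volume %s\n",
              x$plane, length(x$slices), sd[1], sd[2],
              fmt_shape(x$source_shape)))
  invisible(x)
}

#' Extract all 2D slices of a volume on one anatomical plane
#'
#' One slice per index along the plane's axis; source indices are 1-based
#' positions along that axis. `restack(extract_slices(v, p))` recovers `v`
#' exactly for every plane.
#'
#' @param vol an `mri_volume` (or a bare 3D array).
#' @param plane `"sagittal"`, `"coronal"` or `"axial"`.
#' @return a `slice_stack`.
#' @export
extract_slices <- function(vol, plane) {
  vox <- if (inherits(vol, "mri_volume")) vol$voxels else vol
  stopifnot(is.array(vox), length(dim(vox)) == 3)
  ax <- plane_axis(plane)
  n <- dim(vox)[ax]
  slices <- lapply(seq_len(n), function(i) {
    s <- switch(ax, vox[i, , ], vox[, i, ], vox[, , i])
    matrix(s, nrow = dim(vox)[-ax][1])
  })
  new_slice_stack(plane, slices, seq_len(n), dim(vox))
}

#' Restack a full slice stack into a volume array
#'
#' Requires the stack to cover every index of its plane axis.
#'
#' @param stack a `slice_stack` covering all indices of its plane.
#' @return 3D array of shape `stack$source_shape`.
#' @export
restack <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  ax <- plane_axis(stack$plane)
  n <- stack$source_shape[ax]
  if (!identical(stack$source_indices, seq_len(n)))
    stop("restack() needs a full (undecimated) stack")
  vox <- array(0, stack$source_shape)
  for (i in seq_len(n)) {
    s <- stack$slices[[i]]
    switch(ax, vox[i, , ] <- s, vox[, i, ] <- s, vox[, , i] <- s)
  }
  vox
}

#' Decimate a slice stack at a fixed interval
#'
#' Keeps the first slice and then every `(interval + 1)`-th: with the default
#' interval of 1 slice, every other slice survives (odd 1-based positions,
#' i.e. the even 0-based indices), giving `ceiling(n / 2)` slices -- 150
#' axial slices become 75, 256 sagittal become 128.
#'
#' @param stack a `slice_stack`.
#' @param interval number of slices skipped between kept slices (>= 1).
#' @return the decimated `slice_stack` (source indices kept from the volume).
#' @export
decimate <- function(stack, interval = 1) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(stack$slices) == 0) stop("cannot decimate an empty stack")
  if (!is.numeric(interval) || interval < 1) stop("`interval` must be >= 1")
  keep <- seq(1, length(stack$slices), by = interval + 1)
  new_slice_stack(stack$plane, stack$slices[keep],
                  stack$source_indices[keep], stack$source_shape)
}

#' Bicubically degrade a 2D slice
#'
#' Downscales by an integer factor with the antialiased Keys cubic kernel,
#' the standard "bicubic" degradation used to synthesize low-resolution
#' training inputs. Output dimensions are `ceiling(dim / scale)`.
#'
#' @param hr_slice numeric matrix, both dimensions >= `scale`.
#' @param scale integer downscale factor (default 2).
#' @return degraded matrix.
#' @export
degrade_slice <- function(hr_slice, scale = 2) {
  if (!is.matrix(hr_slice)) stop("`hr_slice` must be a 2D matrix")
  if (any(dim(hr_slice) < scale)) stop("slice smaller than the scale factor")
  resize_image(hr_slice, ceiling(dim(hr_slice) / scale),
               kernel = "cubic", antialias = TRUE)
}

#' Build paired LR/HR training patches from a slice stack
#'
#' HR patches of side `lr_size * scale` are tiled over each slice with the
#' given stride; each LR patch is the bicubic degradation of its HR patch,
#' so pairs align exactly at patch borders. Slices smaller than one HR patch
#' are skipped with a warning.
#'
#' @param stack a `slice_stack` of HR slices.
#' @param lr_size LR patch side (default 16, giving 32x32 HR patches).
#' @param scale integer SR factor (default 2).
#' @param stride tiling stride in HR pixels (default `lr_size * scale`,
#'   non-overlapping).
#' @return list of `patch_pair` objects, each with fields `lr`, `hr`,
#'   `origin` (slice id, row, col in HR coordinates) and `scale`.
#' @export
make_patch_pairs <- function(stack, lr_size = 16, scale = 2,
                             stride = lr_size * scale) {
  stopifnot(inherits(stack, "slice_stack"))
  hr_size <- lr_size * scale
  pairs <- list()
  skipped <- 0L
  for (si in seq_along(stack$slices)) {
    s <- stack$slices[[si]]
    if (any(dim(s) < hr_size)) { skipped <- skipped + 1L; next }
    rows <- seq(1, dim(s)[1] - hr_size + 1, by = stride)
    cols <- seq(1, dim(s)[2] - hr_size + 1, by = stride)
    for (r in rows) for (cc in cols) {
      hr <- s[r:(r + hr_size - 1), cc:(cc + hr_size - 1)]
      pairs[[length(pairs) + 1L]] <- structure(
        list(lr = degrade_slice(hr, scale), hr = hr,
             origin = c(slice = stack$source_indices[si], row = r, col = cc),
             scale = scale),
        class = "patch_pair")
    }
  }
  if (skipped > 0)
    warning(skipped, " slice(s) smaller than one ", hr_size, "x", hr_size,
            " patch were skipped")
  pairs
}

#' Deterministically split ids into training and test sets
#'
#' Seeded shuffle then partition, e.g. 581 volumes into 431 training and 150
#' test.
#'
#' @param ids vector of ids.
#' @param train_count number of training ids, strictly between 0 and
#'   `length(ids)`.
#' @param seed shuffle seed (default 42).
#' @return list with `train` and `test`, disjoint, covering `ids`.
#' @export
split_dataset <- function(ids, train_count, seed = 42) {
  n <- length(ids)
  if (!is.numeric(train_count) || train_count <= 0 || train_count >= n)
    stop("`train_count` must satisfy 0 < train_count < length(ids)")
  perm <- with_seed(seed, sample.int(n))
  list(train = ids[perm[seq_len(train_count)]],
       test = ids[perm[(train_count + 1):n]])
}
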