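#' Rebuild a 3D volume from tri-planar slice stacks
#'
#' Writes every slice of every stack at its source index along its plane
#' axis. Voxels written by several planes are merged by the arithmetic mean
#' (order-independent) or by a fixed plane priority. Voxels written by no
#' plane are "missing": left at the sentinel value 0 and flagged in a boolean
#' mask (the mask is authoritative; 0 is also a legal intensity).
#'
#' With full undecimated stacks of one volume the rebuild is the identity;
#' with interval-1 stacks (odd 1-based indices) a voxel is missing iff all
#' three of its coordinates are even, i.e. exactly 1/8 of the voxels when all
#' dimensions are even.
#'
#' @param stacks list of 1-3 `slice_stack`s with distinct planes.
#' @param target_shape integer triple; each stack's slice dimensions must
#'   match it on the stack's plane.
#' @param merge `"mean"` (default) or `"priority"` (axial > coronal >
#'   sagittal: the highest-priority contributing plane wins).
#' @return a `reassembled_volume`: list with `voxels`, `contrib_count`
#'   (0-3 per voxel) and `missing_mask` (`contrib_count == 0`).
#' @export
rebuild <- function(stacks, target_shape, merge = c("mean", "priority")) {
  merge <- match.arg(merge)
  if (inherits(stacks, "slice_stack")) stacks <- list(stacks)
  if (length(stacks) < 1 || length(stacks) > 3)
    stop("`stacks` must hold 1 to 3 slice stacks")
  planes <- vapply(stacks, function(s) s$plane, character(1))
  if (anyDuplicated(planes)) stop("duplicated plane in `stacks`")
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3)

  acc <- array(0, target_shape)    # running sum of contributions
  first <- array(0, target_shape)  # value from the first writing plane
  same <- array(TRUE, target_shape)  # all contributions bitwise equal so far
  cnt <- array(0L, target_shape)
  # priority: axial (3) > coronal (2) > sagittal (1); lower written first
  ord <- order(match(planes, PLANES))
  for (k in ord) {
    st <- stacks[[k]]
    ax <- plane_axis(st$plane)
    want <- target_shape[-ax]
    for (j in seq_along(st$slices)) {
      s <- st$slices[[j]]
      if (!all(dim(s) == want))
        stop(sprintf("slice shape %s does not match target %s on plane %s",
                     fmt_shape(dim(s)), fmt_shape(want), st$plane))
      i <- st$source_indices[j]
      if (i > target_shape[ax])
        stop("source index ", i, " exceeds target extent on plane ", st$plane)
      if (ax == 1) {
        c0 <- cnt[i, , ]; f0 <- first[i, , ]
        acc[i, , ] <- acc[i, , ] + s
        first[i, , ] <- ifelse(c0 == 0L, s, f0)
        same[i, , ] <- same[i, , ] & (c0 == 0L | s == f0)
        cnt[i, , ] <- c0 + 1L
      } else if (ax == 2) {
        c0 <- cnt[, i, ]; f0 <- first[, i, ]
        acc[, i, ] <- acc[, i, ] + s
        first[, i, ] <- ifelse(c0 == 0L, s, f0)
        same[, i, ] <- same[, i, ] & (c0 == 0L | s == f0)
        cnt[, i, ] <- c0 + 1L
      } else {
        c0 <- cnt[, , i]; f0 <- first[, , i]
        acc[, , i] <- acc[, , i] + s
        first[, , i] <- ifelse(c0 == 0L, s, f0)
        same[, , i] <- same[, , i] & (c0 == 0L | s == f0)
        cnt[, , i] <- c0 + 1L
      }
    }
  }
  if (merge == "mean") {
    # mean of contributions, except that agreeing planes keep their exact
    # common value (sum/count perturbs the last bit where three coincide)
    vox <- ifelse(cnt > 0L & same, first,
                  ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0))
  } else {
    # priority merge: planes written in ascending priority, so the
    # highest-priority plane (axial > coronal > sagittal) wins overlaps
    vox <- array(0, target_shape)
    for (k in ord) {
      st <- stacks[[k]]
      ax <- plane_axis(st$plane)
      for (j in seq_along(st$slices)) {
        i <- st$source_indices[j]
        s <- st$slices[[j]]
        switch(ax, vox[i, , ] <- s, vox[, i, ] <- s, vox[, , i] <- s)
      }
    }
  }
  vox <- array(vox, target_shape)
  structure(list(voxels = vox, contrib_count = cnt, missing_mask = cnt == 0L),
            class = "reassembled_volume")
}

#' @export
print.reassembled_volume <- function(x, ...) {
  cat(sprintf("<reassembled_volume %s> missing fraction %.4f\n",
              fmt_shape(dim(x$voxels)), missing_fraction(x)))
  invisible(x)
}

#' Fraction of voxels written by no plane
#' @param rv a `reassembled_volume`.
#' @return ratio in \[0, 1\].
#' @export
missing_fraction <- function(rv) {
  stopifnot(inherits(rv, "reassembled_volume"))
  mean(rv$missing_mask)
}

#' Fill missing voxels by iterative neighbor-mean interpolation
#'
#' The baseline repair: every missing voxel is replaced by the mean of its
#' known face-adjacent neighbors, iterating until no missing voxel remains.
#' Known voxels are never altered. `mode = "slice"` restricts the
#' neighborhood to the 4-connected in-plane neighbors of axial slices
#' (the slice-wise variant of the same repair); `"volume"` (default) uses
#' the full 6-connected 3D neighborhood.
#'
#' @param rv a `reassembled_volume` with at least one known voxel.
#' @param mode `"volume"` or `"slice"`.
#' @return repaired `mri_volume`.
#' @export
interpolation_repair <- function(rv, mode = c("volume", "slice")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rv, "reassembled_volume"))
  if (all(rv$missing_mask)) stop("cannot repair an all-missing volume")
  vox <- rv$voxels
  known <- !rv$missing_mask
  d <- dim(vox)
  axes <- if (mode == "volume") 1:3 else 1:2
  shift_sum <- function(x, ax, by) {
    # x shifted along axis `ax` by +/-1, zero-filled at the border
    out <- array(0, d)
    n <- d[ax]
    if (n < 2) return(out)
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    idx_src <- rep(list(quote(expr = )), 3); idx_src[[ax]] <- src
    idx_dst <- rep(list(quote(expr = )), 3); idx_dst[[ax]] <- dst
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(x), idx_src,
                                                list(drop = FALSE))))))
    out
  }
  while (!all(known)) {
    ks <- array(0, d); vs <- array(0, d)
    kn <- known * 1
    for (ax in axes) for (by in c(1, -1)) {
      ks <- ks + shift_sum(kn, ax, by)
      vs <- vs + shift_sum(vox * kn, ax, by)
    }
    fill <- !known & ks > 0
    if (!any(fill)) stop("repair cannot progress: isolated missing region")
    vox[fill] <- vs[fill] / ks[fill]
    known <- known | fill
  }
  as_volume(vox, normalize = FALSE)
}
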