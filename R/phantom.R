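#' Specification of a synthetic brain phantom
#'
#' Parameters of the synthetic volumes used to exercise the pipeline without
#' real acquisitions: a sum of smooth 3D Gaussian ellipsoids (anatomy-like
#' structure) plus band-limited texture (high-frequency content the
#' super-resolution networks must learn) plus Gaussian acquisition noise,
#' clipped to \[0, 1\].
#'
#' @param shape integer triple, voxel grid size; all entries >= 8. The full
#'   study size is `c(256, 256, 150)`; [toy_phantom_spec()] gives the small
#'   test default `c(64, 64, 38)`, which halves to odd extents the same way
#'   150 does.
#' @param n_blobs number of ellipsoidal structures (default 8).
#' @param texture_scale spatial frequency of the additive band-limited
#'   texture, in coarse cells per axis (default 6; 0 disables texture).
#' @param texture_amp texture amplitude on the \[0, 1\] intensity scale.
#' @param noise_sigma std of additive Gaussian acquisition noise (default
#'   0.01 on the \[0, 1\] scale; 0 disables noise).
#' @param seed RNG seed; identical seeds give bit-identical volumes.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(256, 256, 150), n_blobs = 8,
                         texture_scale = 6, texture_amp = 0.08,
                         noise_sigma = 0.01, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape < 8))
    stop("`shape` must be an integer triple with all entries >= 8")
  if (n_blobs < 0 || texture_scale < 0 || texture_amp < 0 || noise_sigma < 0)
    stop("phantom parameters must be non-negative")
  structure(list(shape = shape, n_blobs = as.integer(n_blobs),
                 texture_scale = texture_scale, texture_amp = texture_amp,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
toy_phantom_spec <- function(shape = c(64, 64, 38), n_blobs = 8,
                             texture_scale = 6, texture_amp = 0.08,
                             noise_sigma = 0.01, seed = 1) {
  phantom_spec(shape, n_blobs, texture_scale, texture_amp, noise_sigma, seed)
}

#' Generate a synthetic brain-like phantom volume
#'
#' Deterministic under `spec$seed`. The volume always has a near-zero
#' background rim; with `n_blobs >= 1` it has structured foreground.
#'
#' @param spec a [phantom_spec()].
#' @return an `mri_volume` of exactly `spec$shape`, intensities in \[0, 1\].
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$shape
  with_seed(spec$seed, {
    vox <- array(0, d)
    gx <- (seq_len(d[1]) - 0.5) / d[1]
    gy <- (seq_len(d[2]) - 0.5) / d[2]
    gz <- (seq_len(d[3]) - 0.5) / d[3]
    if (spec$n_blobs > 0) {
      for (b in seq_len(spec$n_blobs)) {
        ctr <- stats::runif(3, 0.25, 0.75)
        sd3 <- stats::runif(3, 0.06, 0.18)
        amp <- stats::runif(1, 0.35, 0.9)
        fx <- exp(-0.5 * ((gx - ctr[1]) / sd3[1])^2)
        fy <- exp(-0.5 * ((gy - ctr[2]) / sd3[2])^2)
        fz <- exp(-0.5 * ((gz - ctr[3]) / sd3[3])^2)
        vox <- vox + amp * (fx %o% fy %o% fz)
      }
      # head-like envelope: suppress intensity near the grid boundary
      ex <- exp(-((gx - 0.5) / 0.38)^8)
      ey <- exp(-((gy - 0.5) / 0.38)^8)
      ez <- exp(-((gz - 0.5) / 0.42)^8)
      env <- ex %o% ey %o% ez
      vox <- vox * env
      if (spec$texture_scale > 0 && spec$texture_amp > 0) {
        # coarse grid with texture_scale cells along the shortest axis
        cd <- pmax(2L, pmin(d, as.integer(round(spec$texture_scale *
                                                  d / min(d)))))
        coarse <- array(stats::rnorm(prod(cd)), cd)
        for (ax in 1:3) {
          M <- resize_matrix(dim(coarse)[ax], d[ax], "cubic",
                             antialias = FALSE)
          coarse <- resize_along_axis(coarse, M, ax)
        }
        vox <- vox + spec$texture_amp * coarse * env
      }
    }
    if (spec$noise_sigma > 0)
      vox <- vox + stats::rnorm(length(vox), sd = spec$noise_sigma)
    as_volume(clamp01(vox), normalize = FALSE)
  })
}

#' Write a set of phantom volumes with a manifest
#'
#' Generates `n` phantoms with consecutive seeds starting at `spec$seed`,
#' writes each as NIfTI, and writes a JSON manifest of seeds and shapes.
#'
#' @param spec a [phantom_spec()] (its seed is the first of `n`).
#' @param n number of volumes, >= 1.
#' @param out_dir output directory (created if needed).
#' @return character vector of the `n` volume paths; the manifest sits next
#'   to them as `manifest.json`.
#' @export
make_fixture_set <- function(spec, n, out_dir) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec; si$seed <- spec$seed + i - 1L
    vol <- generate_phantom(si)
    paths[i] <- file.path(out_dir, sprintf("phantom_%03d.nii.gz", i))
    write_volume(vol, paths[i])
    rows[[i]] <- list(file = basename(paths[i]), seed = si$seed,
                      shape = si$shape)
  }
  jsonlite::write_json(rows, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths
}
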