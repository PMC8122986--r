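# Architectures: the stage-1 x2 generator (RRDB trunk + residual
# receptive-field dense blocks, NNI/SPC upsampling), the stage-2 same-size
# noise-injected generator (nESRGAN: interpolation sampling instead of
# deconvolution, entry downsampling in feature space), and the shared
# VGG-style relativistic discriminator.

RESIDUAL_SCALE <- 0.2

#' Generator architecture specification
#'
#' @param kind `"rfb_esrgan"` (stage 1, x2) or `"nesrgan"` (stage 2,
#'   same-size restoration with noise injection).
#' @param n_rrdb residual-in-residual dense blocks (default 16).
#' @param n_rrfdb residual receptive-field dense blocks (default 8;
#'   rfb_esrgan only).
#' @param base_channels feature width (default 64).
#' @param growth dense-block growth channels (default `base_channels / 2`).
#' @param scale output/input spatial ratio: 2 for stage 1, 1 for stage 2
#'   (4 = two alternating NNI/SPC stages).
#' @param noise enable per-block noise injection (nesrgan only).
#' @param upsample_mode `"nni_spc_alternating"` (SPC at x2, NNI then SPC at
#'   x4), `"subpixel"`, `"nni"`, `"bilinear_conv"` (interpolation sampling,
#'   the nesrgan default), or `"deconv"` (zero-insertion transposed-
#'   convolution variant, kept only to demonstrate checkerboard artifacts).
#' @return a validated `generator_spec`.
#' @export
generator_spec <- function(kind = c("rfb_esrgan", "nesrgan"),
                           n_rrdb = 16, n_rrfdb = 8, base_channels = 64,
                           growth = max(4L, base_channels %/% 2L),
                           scale = if (kind[1] == "nesrgan") 1 else 2,
                           noise = kind[1] == "nesrgan",
                           upsample_mode = if (kind[1] == "nesrgan")
                             "bilinear_conv" else "nni_spc_alternating") {
  kind <- match.arg(kind)
  if (n_rrdb < 1) stop("n_rrdb must be >= 1")
  if (!scale %in% c(1, 2, 4)) stop("scale must be 1, 2 or 4")
  if (noise && kind != "nesrgan")
    stop("noise injection is only valid for kind = 'nesrgan'")
  if (kind == "nesrgan" && scale != 1)
    stop("nesrgan is a same-size restoration network (scale 1)")
  if (kind == "rfb_esrgan" && scale == 1)
    stop("rfb_esrgan requires scale 2 or 4")
  upsample_mode <- match.arg(upsample_mode,
                             c("nni_spc_alternating", "subpixel", "nni",
                               "bilinear_conv", "deconv"))
  structure(list(kind = kind, n_rrdb = as.integer(n_rrdb),
                 n_rrfdb = if (kind == "rfb_esrgan") as.integer(n_rrfdb)
                           else 0L,
                 base_channels = as.integer(base_channels),
                 growth = as.integer(growth), scale = as.integer(scale),
                 noise = isTRUE(noise), upsample_mode = upsample_mode),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' VGG-style feature widths doubling per block, strides alternating (1, 2),
#' batch normalization, LReLU, ending in two fully connected layers that
#' produce one pre-sigmoid scalar logit per image.
#'
#' @param feature_widths strictly doubling widths (default 64,128,256,512).
#' @param input_size HR patch side; must be a multiple of
#'   `2^length(feature_widths)`.
#' @param fc_width width of the first fully connected layer (default 100).
#' @return a validated `discriminator_spec`.
#' @export
discriminator_spec <- function(feature_widths = c(64, 128, 256, 512),
                               input_size = 32, fc_width = 100) {
  if (length(feature_widths) < 1 ||
      (length(feature_widths) > 1 &&
       any(diff(feature_widths) != feature_widths[-length(feature_widths)])))
    stop("feature_widths must strictly increase by doubling")
  down <- 2^length(feature_widths)
  if (input_size %% down != 0 || input_size < down)
    stop("input_size must be a positive multiple of ", down,
         "; the minimal valid size is ", down)
  structure(list(feature_widths = as.integer(feature_widths),
                 input_size = as.integer(input_size),
                 fc_width = as.integer(fc_width),
                 kernel = 3L, strides = c(1L, 2L)),
            class = "discriminator_spec")
}

# ---- receptive field block -------------------------------------------------

# Multi-branch unit of small and dilated kernels approximating a large
# receptive field: 1x1 | 1x1-3x3 | 1x1-3x3(d3) | 1x1-1x3-3x1-3x3(d5),
# concatenated and fused by 1x1. Residual (scaled 0.2) when in == out.
make_rfb_unit <- function(in_ch, out_ch, init_scale = 0.1) {
  inter <- max(4L, out_ch %/% 4L)
  M <- new_module("rfb")
  M$residual <- in_ch == out_ch
  M$children <- list(
    b1 = list(nn_conv(in_ch, inter, 1, init_scale = init_scale)),
    b2 = list(nn_conv(in_ch, inter, 1, init_scale = init_scale), nn_lrelu(),
              nn_conv(inter, inter, 3, init_scale = init_scale)),
    b3 = list(nn_conv(in_ch, inter, 1, init_scale = init_scale), nn_lrelu(),
              nn_conv(inter, inter, 3, dilation = 3,
                      init_scale = init_scale)),
    b4 = list(nn_conv(in_ch, inter, 1, init_scale = init_scale), nn_lrelu(),
              nn_conv(inter, inter, c(1, 3), init_scale = init_scale),
              nn_lrelu(),
              nn_conv(inter, inter, c(3, 1), init_scale = init_scale),
              nn_lrelu(),
              nn_conv(inter, inter, 3, dilation = 5,
                      init_scale = init_scale)),
    fuse = list(nn_conv(4L * inter, out_ch, 1, init_scale = init_scale)))
  M$inter <- inter
  M$fwd <- function(x, train = FALSE) {
    ys <- lapply(M$children[c("b1", "b2", "b3", "b4")],
                 function(br) seq_fwd(br, x, train))
    f <- seq_fwd(M$children$fuse, cat_channels(ys), train)
    if (M$residual) x + RESIDUAL_SCALE * f else f
  }
  M$bwd <- function(dy) {
    df <- if (M$residual) RESIDUAL_SCALE * dy else dy
    dcat <- seq_bwd(M$children$fuse, df)
    dparts <- split_channels(dcat, rep(M$inter, 4))
    dx <- if (M$residual) dy else 0
    brs <- c("b1", "b2", "b3", "b4")
    for (i in 1:4) dx <- dx + seq_bwd(M$children[[brs[i]]], dparts[[i]])
    dx
  }
  M
}

#' Apply a width-preserving receptive field block
#'
#' Functional surface over the RFB unit: multi-branch aggregation of small
#' kernels, residual-added to the input, width preserved.
#'
#' @param features 3D `(H, W, C)` or 4D `(H, W, C, N)` array.
#' @param block an existing unit from previous calls (to reuse weights);
#'   `NULL` builds a fresh one for `C` channels.
#' @return list with `features` (same shape as input) and `block`.
#' @export
rfb_block <- function(features, block = NULL) {
  x <- as_batch(features)
  if (is.null(block)) block <- make_rfb_unit(dim(x)[4], dim(x)[4])
  if (dim(x)[4] != nrow_in_channels(block))
    stop("feature width ", dim(x)[4], " does not match the block")
  y <- block$fwd(x)
  list(features = match_shape(y, features), block = block)
}

nrow_in_channels <- function(rfb) rfb$children$b1[[1]]$in_ch

# lift a 2D (H, W) or 3D (H, W, C) array to the engine's (H, W, N, C)
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1, 1)
  else if (length(d) == 3) dim(x) <- c(d[1], d[2], 1, d[3])
  x
}
# drop the singleton batch (and channel) dims added by as_batch(), keeping
# the possibly rescaled spatial dims
match_shape <- function(y, template) {
  if (is.matrix(template)) return(matrix(y, dim(y)[1], dim(y)[2]))
  if (length(dim(template)) == 3) dim(y) <- dim(y)[c(1, 2, 4)]
  y
}

# ---- dense blocks ----------------------------------------------------------

# Densely connected block: 5 units, unit i sees the input plus all previous
# unit outputs; the last maps back to C channels; residual-scaled add.
# unit = "conv" (3x3 convolutions, the RRDB interior) or "rfb" (receptive
# field units, the RRFDB interior). Optional noise injection on the fused
# output, before the residual add.
make_dense_block <- function(C, g, unit = c("conv", "rfb"), noise = FALSE) {
  unit <- match.arg(unit)
  mk <- function(ci, co) {
    if (unit == "conv") nn_conv(ci, co, 3, init_scale = 0.1)
    else make_rfb_unit(ci, co)
  }
  M <- new_module(paste0("dense_", unit))
  M$C <- C; M$g <- g
  M$children <- list(
    u1 = mk(C, g), a1 = nn_lrelu(),
    u2 = mk(C + g, g), a2 = nn_lrelu(),
    u3 = mk(C + 2L * g, g), a3 = nn_lrelu(),
    u4 = mk(C + 3L * g, g), a4 = nn_lrelu(),
    u5 = mk(C + 4L * g, C),
    noise = if (noise) nn_noise(C) else NULL)
  M$children <- Filter(Negate(is.null), M$children)
  run_unit <- function(u, x, train) if (inherits(u, "nn_layer"))
    u$fwd(x, train) else u$fwd(x, train)
  M$fwd <- function(x, train = FALSE) {
    ch <- M$children
    f1 <- ch$a1$fwd(run_unit(ch$u1, x, train), train)
    f2 <- ch$a2$fwd(run_unit(ch$u2, cat_channels(list(x, f1)), train), train)
    f3 <- ch$a3$fwd(run_unit(ch$u3, cat_channels(list(x, f1, f2)), train),
                    train)
    f4 <- ch$a4$fwd(run_unit(ch$u4, cat_channels(list(x, f1, f2, f3)), train),
                    train)
    f5 <- run_unit(ch$u5, cat_channels(list(x, f1, f2, f3, f4)), train)
    if (!is.null(ch$noise)) f5 <- ch$noise$fwd(f5, train)
    x + RESIDUAL_SCALE * f5
  }
  M$bwd <- function(dy) {
    ch <- M$children
    C <- M$C; g <- M$g
    df5 <- RESIDUAL_SCALE * dy
    if (!is.null(ch$noise)) df5 <- ch$noise$bwd(df5)
    d5 <- ch$u5$bwd(df5)
    sp <- split_channels(d5, c(C, g, g, g, g))
    dx <- dy + sp[[1]]; d1 <- sp[[2]]; d2 <- sp[[3]]; d3 <- sp[[4]]
    d4 <- sp[[5]]
    s <- split_channels(ch$u4$bwd(ch$a4$bwd(d4)), c(C, g, g, g))
    dx <- dx + s[[1]]; d1 <- d1 + s[[2]]; d2 <- d2 + s[[3]]
    d3 <- d3 + s[[4]]
    s <- split_channels(ch$u3$bwd(ch$a3$bwd(d3)), c(C, g, g))
    dx <- dx + s[[1]]; d1 <- d1 + s[[2]]; d2 <- d2 + s[[3]]
    s <- split_channels(ch$u2$bwd(ch$a2$bwd(d2)), c(C, g))
    dx <- dx + s[[1]]; d1 <- d1 + s[[2]]
    dx + ch$u1$bwd(ch$a1$bwd(d1))
  }
  M
}

# residual-in-residual block: three chained dense blocks, outer residual
make_rir_block <- function(C, g, unit = "conv", noise = FALSE) {
  M <- new_module(if (unit == "conv") "rrdb" else "rrfdb")
  M$children <- list(db1 = make_dense_block(C, g, unit, noise),
                     db2 = make_dense_block(C, g, unit, noise),
                     db3 = make_dense_block(C, g, unit, noise))
  M$fwd <- function(x, train = FALSE) {
    t3 <- M$children$db3$fwd(
      M$children$db2$fwd(M$children$db1$fwd(x, train), train), train)
    x + RESIDUAL_SCALE * t3
  }
  M$bwd <- function(dy) {
    dt <- RESIDUAL_SCALE * dy
    dt <- M$children$db1$bwd(M$children$db2$bwd(M$children$db3$bwd(dt)))
    dy + dt
  }
  M
}

# ---- upsampling stages -----------------------------------------------------

make_up_stage <- function(C, mode) {
  M <- new_module(paste0("up_", mode))
  M$children <- switch(mode,
    subpixel = list(nn_conv(C, 4L * C, 3, init_scale = 0.1),
                    nn_pixel_shuffle(2), nn_lrelu()),
    nni = list(nn_nearest_up2(), nn_conv(C, C, 3, init_scale = 0.1),
               nn_lrelu()),
    bilinear_conv = list(nn_resize(function(hw) 2L * hw, "linear"),
                         nn_conv(C, C, 3, init_scale = 0.1), nn_lrelu()),
    deconv = list(nn_zero_up2(), nn_conv(C, C, 3, init_scale = 0.1),
                  nn_lrelu()),
    stop("unknown upsample stage mode: ", mode))
  M$fwd <- function(x, train = FALSE) seq_fwd(M$children, x, train)
  M$bwd <- function(dy) seq_bwd(M$children, dy)
  M
}

up_stage_modes <- function(spec) {
  if (spec$scale == 1) {
    if (spec$kind != "nesrgan") return(character(0))
    # nesrgan: one x2 tail stage compensating the entry downsampler
    return(if (spec$upsample_mode %in% c("bilinear_conv", "deconv"))
      spec$upsample_mode else "bilinear_conv")
  }
  base <- switch(spec$upsample_mode,
                 nni_spc_alternating = c("nni", "subpixel"),
                 subpixel = c("subpixel", "subpixel"),
                 nni = c("nni", "nni"),
                 bilinear_conv = c("bilinear_conv", "bilinear_conv"),
                 deconv = c("deconv", "deconv"))
  if (spec$scale == 2) base[2] else base   # x2 keeps the SPC (final) stage
}

#' Build and apply an upsampling stage
#'
#' Functional surface: multiplies spatial dimensions by `scale` using the
#' chosen mode. `"nni_spc_alternating"` applies NNI then sub-pixel
#' convolution for scale 4 and the single SPC stage for scale 2;
#' `"bilinear_conv"` is interpolation followed by convolution (never a
#' transposed convolution).
#'
#' @param features 3D or 4D feature array.
#' @param mode see [generator_spec()].
#' @param scale 2 or 4.
#' @param identity_conv initialise each stage's convolution to the identity
#'   (default), so the functional surface is the pure sampling operation;
#'   `FALSE` uses random weights as inside a fresh generator.
#' @return features at `scale` times the spatial resolution.
#' @export
upsampler <- function(features, mode = "nni_spc_alternating", scale = 2,
                      identity_conv = TRUE) {
  if (!scale %in% c(2, 4)) stop("unsupported scale: ", scale)
  x <- as_batch(features)
  sp <- list(scale = scale, kind = "rfb_esrgan", upsample_mode = mode)
  for (m in up_stage_modes(sp)) {
    st <- make_up_stage(dim(x)[4], m)
    if (identity_conv)
      for (L in collect_layers(st))
        if (L$kind == "conv") set_identity_conv(L)
    x <- st$fwd(x)
  }
  match_shape(x, features)
}

# Set a k-odd convolution to the identity: centre tap 1. When out = r^2 * in
# (the sub-pixel stage) every sub-pixel channel of a group replicates its
# input channel, so shuffle reproduces nearest-neighbour sampling.
set_identity_conv <- function(L) {
  kk <- prod(L$k)
  ctr <- (kk + 1) %/% 2
  W <- matrix(0, nrow(L$params$W), ncol(L$params$W))
  rep_out <- L$out_ch %/% L$in_ch
  for (c_in in seq_len(L$in_ch))
    for (j in seq_len(rep_out))
      W[(c_in - 1) * kk + ctr, (c_in - 1) * rep_out + j] <- 1
  L$params$W <- W
  L$params$b[] <- 0
  invisible(L)
}

#' Interpolation-based entry downsampling
#'
#' Halves the spatial dimensions of the feature maps by linear interpolation
#' (odd extents round up, and the tail x2 upsampler restores the exact input
#' size via cropping). This is the head-of-network sampling block that lets
#' the same-size restoration network gather context at half resolution.
#'
#' @param features 3D or 4D feature array.
#' @param scale only 2 is supported.
#' @return features at `ceiling(dim / 2)` spatial size.
#' @export
downsample_entry <- function(features, scale = 2) {
  if (scale != 2) stop("only scale 2 entry downsampling is supported")
  x <- as_batch(features)
  L <- nn_resize(function(hw) as.integer(ceiling(hw / 2)), "linear")
  match_shape(L$fwd(x), features)
}

#' Inject learned-strength Gaussian noise into feature maps
#'
#' One standard-normal noise map per spatial position, shared across
#' channels and scaled by a per-channel strength. With `strength = 0` the
#' injection is a bit-exact no-op.
#'
#' @param features 3D or 4D feature array.
#' @param strength per-channel scale (recycled to the channel count).
#' @param seed optional RNG seed for reproducible noise.
#' @return features with noise added.
#' @export
noise_injection <- function(features, strength = 0, seed = NULL) {
  x <- as_batch(features)
  C <- dim(x)[4]
  L <- nn_noise(C)
  L$params$strength <- rep_len(strength, C)
  L$stochastic <- TRUE
  y <- if (is.null(seed)) L$fwd(x) else with_seed(seed, L$fwd(x))
  match_shape(y, features)
}

# ---- generators ------------------------------------------------------------

#' Build a super-resolution generator
#'
#' `kind = "rfb_esrgan"`: shallow conv, `n_rrdb` RRDBs then `n_rrfdb`
#' residual receptive-field dense blocks, trunk residual, NNI/SPC
#' upsampling, and a zero-initialised output head added to the bicubic
#' upscale of the input -- so a freshly built generator IS bicubic
#' interpolation, and training learns the residual.
#'
#' `kind = "nesrgan"`: same-size restoration; features are downsampled x2 at
#' entry by linear interpolation, pass through noise-injected RRDBs, are
#' upsampled back by interpolation + convolution (no transposed
#' convolution), and the zero-initialised head is added to the input itself.
#'
#' @param spec a [generator_spec()].
#' @param seed weight-initialisation seed.
#' @return an `sr_generator` with `$predict()` (clamped \[0,1\] inference),
#'   `$fwd()` / `$bwd()` (training), `$n_params`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  C <- spec$base_channels; g <- spec$growth
  G <- with_seed(seed, {
    G <- new_module("generator")
    body <- c(
      lapply(seq_len(spec$n_rrdb), function(i)
        make_rir_block(C, g, "conv", noise = spec$noise)),
      lapply(seq_len(spec$n_rrfdb), function(i)
        make_rir_block(C, g, "rfb", noise = FALSE)))
    ups <- lapply(up_stage_modes(spec), function(m) make_up_stage(C, m))
    G$children <- list(
      conv_first = nn_conv(1, C, 3),
      entry_down = if (spec$kind == "nesrgan")
        nn_resize(function(hw) as.integer(ceiling(hw / 2)), "linear")
        else NULL,
      body = body,
      trunk_conv = nn_conv(C, C, 3, init_scale = 0.1),
      ups = ups,
      conv_hr = nn_conv(C, C, 3, init_scale = 0.1),
      act_hr = nn_lrelu(),
      conv_last = nn_conv(C, 1, 3, init_scale = 0),
      skip = if (spec$scale > 1)
        nn_resize(function(hw) spec$scale * hw, "cubic") else NULL)
    G$children <- Filter(Negate(is.null), G$children)
    G
  })
  G$spec <- spec
  G$stochastic <- FALSE   # noise layers live-sample only when enabled

  set_noise_mode <- function(on) {
    for (L in collect_layers(G)) if (L$kind == "noise") L$stochastic <- on
  }

  G$fwd <- function(x, train = FALSE) {
    set_noise_mode(spec$noise && (train || G$stochastic))
    ch <- G$children
    hw <- dim(x)[1:2]
    fea <- ch$conv_first$fwd(x, train)
    if (!is.null(ch$entry_down)) fea <- ch$entry_down$fwd(fea, train)
    b <- fea
    for (blk in ch$body) b <- blk$fwd(b, train)
    fea2 <- fea + ch$trunk_conv$fwd(b, train)
    u <- fea2
    for (st in ch$ups) u <- st$fwd(u, train)
    target_hw <- spec$scale * hw
    G$crop_from <- dim(u)[1:2]
    if (any(dim(u)[1:2] > target_hw))
      u <- u[seq_len(target_hw[1]), seq_len(target_hw[2]), , , drop = FALSE]
    r <- ch$conv_last$fwd(ch$act_hr$fwd(ch$conv_hr$fwd(u, train), train),
                          train)
    sk <- if (!is.null(ch$skip)) ch$skip$fwd(x, train) else x
    sk + r
  }

  G$bwd <- function(dy) {
    ch <- G$children
    dsk <- if (!is.null(ch$skip)) ch$skip$bwd(dy) else dy
    du <- ch$conv_hr$bwd(ch$act_hr$bwd(ch$conv_last$bwd(dy)))
    if (any(G$crop_from > dim(du)[1:2])) {
      full <- array(0, c(G$crop_from, dim(du)[3], dim(du)[4]))
      full[seq_len(dim(du)[1]), seq_len(dim(du)[2]), , ] <- du
      du <- full
    }
    for (st in rev(ch$ups)) du <- st$bwd(du)
    dfea2 <- du
    db <- ch$trunk_conv$bwd(dfea2)
    for (blk in rev(ch$body)) db <- blk$bwd(db)
    dfea <- dfea2 + db
    if (!is.null(ch$entry_down)) dfea <- ch$entry_down$bwd(dfea)
    ch$conv_first$bwd(dfea) + dsk
  }

  G$predict <- function(x, stochastic = FALSE) {
    xb <- as_batch(x)
    old <- G$stochastic; G$stochastic <- stochastic
    on.exit(G$stochastic <- old)
    y <- G$fwd(xb, train = FALSE)
    match_shape(array(clamp01(y), dim(y)), x)
  }

  G$n_params <- n_parameters(G)
  class(G) <- c("sr_generator", class(G))
  G
}

#' @export
print.sr_generator <- function(x, ...) {
  cat(sprintf(
    "<sr_generator %s> scale x%d, %d RRDB + %d RRFDB, %d channels, %s params\n",
    x$spec$kind, x$spec$scale, x$spec$n_rrdb, x$spec$n_rrfdb,
    x$spec$base_channels, format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Does a network contain a transposed-convolution upsampler?
#'
#' Structural check used to assert the anti-checkerboard design: the
#' same-size restoration generator must upsample by interpolation +
#' convolution only.
#'
#' @param net an `sr_generator` or `sr_discriminator`.
#' @return `TRUE` if any zero-insertion (deconvolution) layer is present.
#' @export
uses_transposed_conv <- function(net) {
  any(vapply(collect_layers(net), function(L)
    identical(L$kind, "deconv_zero_up2"), logical(1)))
}

#' Count trainable parameters
#' @param net an `sr_generator` or `sr_discriminator`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) n_parameters(net)

# ---- discriminator ---------------------------------------------------------

#' Build the relativistic discriminator
#'
#' Maps a batch of HR-sized images to one pre-sigmoid scalar logit per image
#' (the "non-transformed" output C(x) of the relativistic-average losses).
#'
#' @param spec a [discriminator_spec()].
#' @param seed weight-initialisation seed.
#' @return an `sr_discriminator` with `$fwd(x, train)` returning a logit
#'   vector and `$bwd(dlogits)` returning input gradients.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1) {
  stopifnot(inherits(spec, "discriminator_spec"))
  D <- with_seed(seed, {
    D <- new_module("discriminator")
    layers <- list(nn_conv(1, spec$feature_widths[1], 3), nn_lrelu())
    prev <- spec$feature_widths[1]
    first <- TRUE
    for (w in spec$feature_widths) {
      if (!first) layers <- c(layers, list(nn_conv(prev, w, 3), nn_bn(w),
                                           nn_lrelu()))
      layers <- c(layers, list(nn_conv(w, w, 3, stride = 2), nn_bn(w),
                               nn_lrelu()))
      prev <- w
      first <- FALSE
    }
    side <- spec$input_size %/% 2^length(spec$feature_widths)
    layers <- c(layers, list(
      nn_flatten(),
      nn_dense(side * side * prev, spec$fc_width, init_scale = 0.5),
      nn_lrelu(),
      nn_dense(spec$fc_width, 1, init_scale = 0.5)))
    D$children <- layers
    D
  })
  D$spec <- spec
  D$fwd <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (!all(dim(x)[1:2] == spec$input_size))
      stop("discriminator expects ", spec$input_size, "x", spec$input_size,
           " inputs; the minimal valid size is ",
           2^length(spec$feature_widths))
    drop(seq_fwd(D$children, x, train))
  }
  D$bwd <- function(dlogits) seq_bwd(D$children, matrix(dlogits, ncol = 1))
  D$n_params <- n_parameters(D)
  class(D) <- c("sr_discriminator", class(D))
  D
}

#' @export
print.sr_discriminator <- function(x, ...) {
  cat(sprintf("<sr_discriminator> input %dx%d, widths %s, %s params\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$feature_widths, collapse = "-"),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load generator checkpoints
#'
#' A checkpoint is the architecture spec plus the flat parameter state, so a
#' generator can be rebuilt exactly.
#'
#' @param gen an `sr_generator`.
#' @param path checkpoint file (RDS).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   rebuilt `sr_generator`.
#' @export
save_checkpoint <- function(gen, path) {
  stopifnot(inherits(gen, "sr_generator"))
  saveRDS(list(spec = gen$spec, state = state_dict(gen)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  gen <- build_generator(ck$spec, seed = 0)
  load_state(gen, ck$state)
  gen
}
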