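# --------------------------------------------------------------------------
# Compact 2D-CNN engine.
#
# Tensors are 4D arrays with dim = c(H, W, N, C) -- channels LAST, so that
# matrix(x, H*W*N, C) is a zero-copy reshape and convolutions need no
# aperm() on the hot path. Every layer is an
# environment with fields:
#   kind    -- layer type string
#   params  -- named list of numeric arrays (may be empty)
#   grads   -- same names, accumulated by backward()
#   fwd(x, train) / bwd(dy) -- forward pass (caches what backward needs)
#                              and backward pass (returns dx)
# Composite modules are environments of class "nn_module" holding children
# and their own fwd/bwd closures. All convolutions are cross-correlations
# (the deep-learning convention). Backward passes are exact analytic
# gradients; tests check them against central finite differences.
# --------------------------------------------------------------------------

new_layer <- function(kind, params = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  class(e) <- "nn_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_module <- function(kind, children = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$children <- children
  class(e) <- "nn_module"
  e
}

# He-style fan-in initialisation, optionally scaled (ESRGAN uses 0.1x MSRA
# for body convolutions); scale = 0 gives exact zero init.
init_weights <- function(n_in, n_out, scale = 1) {
  if (scale == 0) return(matrix(0, n_in, n_out))
  matrix(stats::rnorm(n_in * n_out, sd = scale * sqrt(2 / n_in)), n_in, n_out)
}

# ---- convolution ----------------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = c(3, 3), stride = 1, dilation = 1,
                    pad = NULL, init_scale = 1) {
  if (length(k) == 1) k <- c(k, k)
  if (is.null(pad)) pad <- dilation * (k - 1) %/% 2
  if (length(pad) == 1) pad <- c(pad, pad)
  L <- new_layer("conv", list(
    W = init_weights(prod(k) * in_ch, out_ch, init_scale),
    b = numeric(out_ch)))
  L$k <- k; L$stride <- stride; L$dilation <- dilation; L$pad <- pad
  L$in_ch <- in_ch; L$out_ch <- out_ch

  is_1x1 <- all(k == 1) && stride == 1 && all(pad == 0)

  L$fwd <- function(x, train = FALSE) {
    d <- dim(x)                      # (H, W, N, C)
    stopifnot(d[4] == in_ch)
    if (is_1x1) {                    # pointwise conv: plain matmul
      Xm <- x; dim(Xm) <- c(d[1] * d[2] * d[3], d[4])
      Y <- sweep(Xm %*% L$params$W, 2, L$params$b, `+`)
      dim(Y) <- c(d[1], d[2], d[3], out_ch)
      L$cache <- list(Xm = Xm, din = d)
      return(Y)
    }
    Hp <- d[1] + 2 * pad[1]; Wp <- d[2] + 2 * pad[2]
    xp <- array(0, c(Hp, Wp, d[3], d[4]))
    xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , ] <- x
    Ho <- (Hp - dilation * (k[1] - 1) - 1) %/% stride + 1
    Wo <- (Wp - dilation * (k[2] - 1) - 1) %/% stride + 1
    if (Ho < 1 || Wo < 1) stop("conv input too small for kernel/stride")
    rsel <- 1 + stride * (seq_len(Ho) - 1)
    csel <- 1 + stride * (seq_len(Wo) - 1)
    XA <- array(0, c(Ho * Wo * d[3], prod(k), d[4]))
    o <- 0L
    for (dc in 0:(k[2] - 1)) for (dr in 0:(k[1] - 1)) {
      o <- o + 1L
      XA[, o, ] <- xp[rsel + dr * dilation, csel + dc * dilation, , ,
                      drop = FALSE]
    }
    Xm <- XA; dim(Xm) <- c(Ho * Wo * d[3], prod(k) * d[4])
    Y <- sweep(Xm %*% L$params$W, 2, L$params$b, `+`)
    dim(Y) <- c(Ho, Wo, d[3], out_ch)
    L$cache <- list(Xm = Xm, din = d, Ho = Ho, Wo = Wo,
                    rsel = rsel, csel = csel, Hp = Hp, Wp = Wp)
    Y
  }

  L$bwd <- function(dy) {
    cc <- L$cache
    d <- cc$din
    if (is_1x1) {
      dYm <- dy; dim(dYm) <- c(d[1] * d[2] * d[3], out_ch)
      L$grads$W <- L$grads$W + crossprod(cc$Xm, dYm)
      L$grads$b <- L$grads$b + colSums(dYm)
      dXm <- dYm %*% t(L$params$W)
      dim(dXm) <- d
      return(dXm)
    }
    dYm <- dy; dim(dYm) <- c(cc$Ho * cc$Wo * d[3], out_ch)
    L$grads$W <- L$grads$W + crossprod(cc$Xm, dYm)
    L$grads$b <- L$grads$b + colSums(dYm)
    dXA <- dYm %*% t(L$params$W)
    dim(dXA) <- c(cc$Ho * cc$Wo * d[3], prod(k), d[4])
    dxp <- array(0, c(cc$Hp, cc$Wp, d[3], d[4]))
    o <- 0L
    for (dc in 0:(k[2] - 1)) for (dr in 0:(k[1] - 1)) {
      o <- o + 1L
      rs <- cc$rsel + dr * dilation
      cs <- cc$csel + dc * dilation
      dxp[rs, cs, , ] <- dxp[rs, cs, , , drop = FALSE] +
        array(dXA[, o, ], c(cc$Ho, cc$Wo, d[3], d[4]))
    }
    dxp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , , drop = FALSE]
  }
  L
}

# ---- pointwise / shape layers --------------------------------------------

nn_lrelu <- function(slope = 0.2) {
  L <- new_layer("lrelu")
  L$fwd <- function(x, train = FALSE) {
    fac <- slope + (1 - slope) * (x > 0)   # elementwise multiplier
    L$cache <- fac
    x * fac
  }
  L$bwd <- function(dy) dy * L$cache
  L
}

nn_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  L <- new_layer("bn", list(gamma = rep(1, channels),
                            beta = numeric(channels)))
  L$run_mean <- numeric(channels)
  L$run_var <- rep(1, channels)
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    xc <- x; dim(xc) <- c(d[1] * d[2] * d[3], d[4])
    if (train) {
      mu <- colMeans(xc)
      v <- colMeans(sweep(xc, 2, mu)^2)
      L$run_mean <- momentum * L$run_mean + (1 - momentum) * mu
      L$run_var <- momentum * L$run_var + (1 - momentum) * v
    } else {
      mu <- L$run_mean; v <- L$run_var
    }
    xh <- sweep(sweep(xc, 2, mu), 2, sqrt(v + eps), `/`)
    y <- sweep(sweep(xh, 2, L$params$gamma, `*`), 2, L$params$beta, `+`)
    L$cache <- list(xh = xh, v = v, d = d, train = train)
    dim(y) <- d
    y
  }
  L$bwd <- function(dy) {
    cc <- L$cache; d <- cc$d
    dyc <- dy; dim(dyc) <- c(d[1] * d[2] * d[3], d[4])
    m <- nrow(dyc)
    L$grads$gamma <- L$grads$gamma + colSums(dyc * cc$xh)
    L$grads$beta <- L$grads$beta + colSums(dyc)
    dxh <- sweep(dyc, 2, L$params$gamma, `*`)
    inv <- 1 / sqrt(cc$v + eps)
    if (cc$train) {
      dx <- sweep(dxh - matrix(colMeans(dxh), m, ncol(dxh), byrow = TRUE) -
                    sweep(cc$xh, 2, colMeans(dxh * cc$xh), `*`),
                  2, inv, `*`)
    } else {
      dx <- sweep(dxh, 2, inv, `*`)
    }
    dim(dx) <- d
    dx
  }
  L
}

nn_dense <- function(n_in, n_out, init_scale = 1) {
  L <- new_layer("dense", list(W = init_weights(n_in, n_out, init_scale),
                               b = numeric(n_out)))
  L$fwd <- function(x, train = FALSE) {   # x: matrix (N, n_in)
    L$cache <- x
    sweep(x %*% L$params$W, 2, L$params$b, `+`)
  }
  L$bwd <- function(dy) {
    L$grads$W <- L$grads$W + crossprod(L$cache, dy)
    L$grads$b <- L$grads$b + colSums(dy)
    dy %*% t(L$params$W)
  }
  L
}

# sub-pixel convolution rearrangement (pixel shuffle), scale r:
# (H, W, N, C*r^2) -> (rH, rW, N, C)
nn_pixel_shuffle <- function(r) {
  L <- new_layer("pixel_shuffle")
  L$r <- r
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    stopifnot(d[4] %% (r * r) == 0)
    Co <- d[4] %/% (r * r)
    y <- array(0, c(d[1] * r, d[2] * r, d[3], Co))
    for (a in 0:(r - 1)) for (b in 0:(r - 1)) {
      cin <- (seq_len(Co) - 1) * r * r + a * r + b + 1
      y[seq(a + 1, d[1] * r, by = r), seq(b + 1, d[2] * r, by = r), , ] <-
        x[, , , cin, drop = FALSE]
    }
    L$cache <- d
    y
  }
  L$bwd <- function(dy) {
    d <- L$cache
    Co <- d[4] %/% (r * r)
    dx <- array(0, d)
    for (a in 0:(r - 1)) for (b in 0:(r - 1)) {
      cin <- (seq_len(Co) - 1) * r * r + a * r + b + 1
      dx[, , , cin] <- dy[seq(a + 1, d[1] * r, by = r),
                          seq(b + 1, d[2] * r, by = r), , , drop = FALSE]
    }
    dx
  }
  L
}

# nearest-neighbour x2 upsampling
nn_nearest_up2 <- function() {
  L <- new_layer("nearest_up2")
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x); L$cache <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
      drop = FALSE]
  }
  L$bwd <- function(dy) {
    d <- L$cache
    r1 <- seq(1, 2 * d[1], 2); r2 <- seq(2, 2 * d[1], 2)
    c1 <- seq(1, 2 * d[2], 2); c2 <- seq(2, 2 * d[2], 2)
    dy[r1, c1, , , drop = FALSE] + dy[r1, c2, , , drop = FALSE] +
      dy[r2, c1, , , drop = FALSE] + dy[r2, c2, , , drop = FALSE]
  }
  L
}

# linear interpolation resize in feature space: fixed (non-learned) separable
# matrices; backward is the transposed operator.
nn_resize <- function(out_fn, kernel = "linear") {
  L <- new_layer(paste0("resize_", kernel))
  L$kernel <- kernel
  L$out_fn <- out_fn          # maps input (H, W) to output (H', W')
  L$set_dims <- function(in_hw) {
    out_hw <- L$out_fn(in_hw)
    if (!identical(L$in_hw, in_hw)) {
      L$A <- resize_matrix(in_hw[1], out_hw[1], kernel, antialias = FALSE)
      L$B <- resize_matrix(in_hw[2], out_hw[2], kernel, antialias = FALSE)
      L$in_hw <- in_hw
    }
  }
  apply_AB <- function(x, A, B) {
    d <- dim(x)
    y <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])
    y <- array(y, c(nrow(A), d[2], d[3], d[4]))
    y <- aperm(y, c(2, 1, 3, 4))
    y <- B %*% matrix(y, d[2], nrow(A) * d[3] * d[4])
    y <- array(y, c(nrow(B), nrow(A), d[3], d[4]))
    aperm(y, c(2, 1, 3, 4))
  }
  L$fwd <- function(x, train = FALSE) {
    L$set_dims(dim(x)[1:2])
    apply_AB(x, L$A, L$B)
  }
  L$bwd <- function(dy) apply_AB(dy, t(L$A), t(L$B))
  L
}

# per-channel learned-strength Gaussian noise injection; a single noise map
# per spatial position is shared across channels (the style-based design).
# With strength 0 (the initialisation) the layer is a bit-exact no-op.
nn_noise <- function(channels) {
  L <- new_layer("noise", list(strength = numeric(channels)))
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    if (!isTRUE(L$stochastic)) { L$cache <- NULL; return(x) }
    eps <- stats::rnorm(d[1] * d[2] * d[3])   # one map per spatial position
    L$cache <- eps
    s <- L$params$strength
    y <- x
    for (ch in seq_len(d[4]))
      if (s[ch] != 0) y[, , , ch] <- y[, , , ch] + s[ch] * eps
    y
  }
  L$bwd <- function(dy) {
    if (is.null(L$cache)) return(dy)
    eps <- L$cache
    d <- dim(dy)
    for (ch in seq_len(d[4]))
      L$grads$strength[ch] <- L$grads$strength[ch] +
        sum(dy[, , , ch] * eps)
    dy
  }
  L
}

# flatten (H, W, N, C) -> matrix (N, H*W*C)
nn_flatten <- function() {
  L <- new_layer("flatten")
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x); L$cache <- d
    xs <- aperm(x, c(1, 2, 4, 3))
    t(matrix(xs, d[1] * d[2] * d[4], d[3]))
  }
  L$bwd <- function(dy) {
    d <- L$cache
    aperm(array(t(dy), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  }
  L
}

# zero-insertion upsampling followed by a convolution: the transposed-
# convolution ("deconvolution") upsampler, kept only to demonstrate the
# checkerboard artifact it produces. Flagged so structural checks find it.
nn_zero_up2 <- function() {
  L <- new_layer("deconv_zero_up2")
  L$fwd <- function(x, train = FALSE) {
    d <- dim(x); L$cache <- d
    y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
    y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
    y
  }
  L$bwd <- function(dy) {
    d <- L$cache
    dy[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE]
  }
  L
}

# ---- sequencing / bookkeeping --------------------------------------------

# run children in order; backward in reverse
seq_fwd <- function(children, x, train = FALSE) {
  for (ch in children) x <- ch$fwd(x, train)
  x
}
seq_bwd <- function(children, dy) {
  for (ch in rev(children)) dy <- ch$bwd(dy)
  dy
}

# channel concat helpers: parts is a list of (H, W, N, Ci) arrays; with
# channels last the concat is one contiguous c() in linear memory.
cat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  array(unlist(parts, use.names = FALSE),
        c(d1[1], d1[2], d1[3], sum(cs)))
}
split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cp) {
    sl <- x[, , , at + seq_len(cp), drop = FALSE]
    at <<- at + cp
    sl
  })
}

# collect all leaf layers of a module tree, depth-first, stable order
collect_layers <- function(m) {
  if (inherits(m, "nn_layer")) return(list(m))
  if (inherits(m, "nn_module"))
    return(do.call(c, lapply(m$children, collect_layers)))
  if (is.list(m)) return(do.call(c, lapply(m, collect_layers)))
  list()
}

n_parameters <- function(m) {
  sum(vapply(collect_layers(m),
             function(L) sum(vapply(L$params, length, integer(1))), numeric(1)))
}

zero_grads <- function(m) {
  for (L in collect_layers(m))
    L$grads <- lapply(L$params, function(p) array(0, dim(p) %||% length(p)))
  invisible(m)
}

state_dict <- function(m) lapply(collect_layers(m), function(L) L$params)

load_state <- function(m, state) {
  layers <- collect_layers(m)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    stopifnot(identical(names(layers[[i]]$params), names(state[[i]])))
    layers[[i]]$params <- state[[i]]
  }
  invisible(m)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(m, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_layers(m)
  list(layers = layers, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L,
       m1 = lapply(layers, function(L) lapply(L$params, function(p) p * 0)),
       m2 = lapply(layers, function(L) lapply(L$params, function(p) p * 0)))
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    L <- opt$layers[[i]]
    for (nm in names(L$params)) {
      g <- L$grads[[nm]]
      opt$m1[[i]][[nm]] <- opt$beta1 * opt$m1[[i]][[nm]] + (1 - opt$beta1) * g
      opt$m2[[i]][[nm]] <- opt$beta2 * opt$m2[[i]][[nm]] +
        (1 - opt$beta2) * g^2
      L$params[[nm]] <- L$params[[nm]] -
        opt$lr * (opt$m1[[i]][[nm]] / bc1) /
          (sqrt(opt$m2[[i]][[nm]] / bc2) + opt$eps)
    }
  }
  opt
}
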