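# Engine-level checks: convolution against a direct sliding-window oracle,
# exact analytic gradients, and the shape/permutation layers.

naive_conv <- function(x, W, b, k, stride = 1, dilation = 1, pad) {
  # x: (H, W, C); W: (k1*k2*C, Cout) with offset-fastest column layout
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad[1], d[2] + 2 * pad[2], d[3]))
  xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), ] <- x
  Ho <- (dim(xp)[1] - dilation * (k[1] - 1) - 1) %/% stride + 1
  Wo <- (dim(xp)[2] - dilation * (k[2] - 1) - 1) %/% stride + 1
  out <- array(0, c(Ho, Wo, ncol(W)))
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    patch <- c()
    for (ch in seq_len(d[3])) {
      rows <- (1 + (i - 1) * stride) + dilation * (0:(k[1] - 1))
      cols <- (1 + (j - 1) * stride) + dilation * (0:(k[2] - 1))
      patch <- c(patch, as.vector(xp[rows, cols, ch]))
    }
    out[i, j, ] <- patch %*% W + b
  }
  out
}

test_that("the convolution layer matches a direct sliding-window oracle", {
  set.seed(1)
  cases <- list(list(k = c(3, 3), stride = 1, dilation = 1),
                list(k = c(3, 3), stride = 2, dilation = 1),
                list(k = c(1, 3), stride = 1, dilation = 1),
                list(k = c(3, 3), stride = 1, dilation = 3))
  for (cs in cases) {
    L <- mrisr:::nn_conv(3, 4, k = cs$k, stride = cs$stride,
                         dilation = cs$dilation)
    x <- array(rnorm(10 * 9 * 3), c(10, 9, 1, 3))
    got <- L$fwd(x)
    want <- naive_conv(array(x, c(10, 9, 3)), L$params$W, L$params$b,
                       cs$k, cs$stride, cs$dilation, L$pad)
    expect_lt(max(abs(array(got, dim(got)[c(1, 2, 4)]) - want)), 1e-10,
              label = paste("conv", paste(unlist(cs), collapse = "/")))
  }
})

test_that("layer backward passes are adjoint to their forwards", {
  set.seed(2)
  # linear layers: <L(x), y> == <x, L^T(y)>
  for (mk in list(function() mrisr:::nn_conv(2, 3, 3),
                  function() mrisr:::nn_pixel_shuffle(2),
                  function() mrisr:::nn_nearest_up2(),
                  function() mrisr:::nn_zero_up2(),
                  function() mrisr:::nn_resize(function(hw) 2L * hw,
                                               "linear"))) {
    L <- mk()
    cin <- switch(L$kind, conv = 2L, pixel_shuffle = 4L, 1L)
    x <- array(rnorm(6 * 6 * 2 * cin), c(6, 6, 2, cin))
    if (L$kind == "conv") L$params$b[] <- 0   # adjoint of the linear part
    y <- L$fwd(x)
    dy <- array(rnorm(length(y)), dim(y))
    dx <- L$bwd(dy)
    expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10,
                 label = L$kind)
  }
})

test_that("pixel shuffle rearranges scale^2 channels into space", {
  x <- array(0, c(2, 2, 1, 4))
  x[1, 1, 1, ] <- 1:4
  L <- mrisr:::nn_pixel_shuffle(2)
  y <- L$fwd(x)
  expect_identical(dim(y), c(4L, 4L, 1L, 1L))
  # the 2x2 block at the origin holds channels (1..4) in row-major subpixels
  expect_equal(y[1:2, 1:2, 1, 1], matrix(c(1, 3, 2, 4), 2, 2))
})

test_that("nearest-neighbour upsampling copies each pixel into a 2x2 block", {
  x <- array(0, c(3, 3, 1, 1)); x[2, 2, 1, 1] <- 5
  y <- mrisr:::nn_nearest_up2()$fwd(x)
  expect_identical(dim(y)[1:2], c(6L, 6L))
  expect_true(all(y[3:4, 3:4, 1, 1] == 5))
  expect_equal(sum(y), 4 * 5)
})

test_that("batch normalization gradients match finite differences", {
  set.seed(3)
  L <- mrisr:::nn_bn(3)
  L$params$gamma <- runif(3, 0.5, 1.5)
  L$params$beta <- rnorm(3)
  x <- array(rnorm(4 * 4 * 5 * 3), c(4, 4, 5, 3))
  tgt <- array(rnorm(length(x)), dim(x))
  loss <- function(xv) {
    y <- L$fwd(array(xv, dim(x)), train = TRUE)
    mean((y - tgt)^2)
  }
  y <- L$fwd(x, train = TRUE)
  L$grads$gamma[] <- 0; L$grads$beta[] <- 0
  dx <- L$bwd(2 * (y - tgt) / length(x))
  # spot-check several input coordinates against central differences
  for (ii in sample(length(x), 12)) {
    fd <- fd_grad(function(v) { xs <- as.vector(x); xs[ii] <- v; loss(xs) },
                  as.vector(x)[ii])
    expect_lt(abs(fd - dx[ii]) / max(abs(fd), abs(dx[ii]), 1e-8), 1e-4)
  }
})

test_that("Adam minimises a small least-squares conv problem", {
  set.seed(4)
  L <- mrisr:::nn_conv(1, 1, 3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  target <- array(rnorm(length(x)), dim(x))
  opt <- mrisr:::adam_init(L, lr = 5e-2)
  first <- NA
  for (it in 1:60) {
    y <- L$fwd(x)
    if (it == 1) first <- mean((y - target)^2)
    L$grads$W[] <- 0; L$grads$b[] <- 0
    L$bwd(2 * (y - target) / length(y))
    opt <- mrisr:::adam_step(opt)
  }
  expect_lt(mean((L$fwd(x) - target)^2), first)
})
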