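test_that("generator specs validate their invariants", {
  expect_error(generator_spec("rfb_esrgan", n_rrdb = 0), "n_rrdb")
  expect_error(generator_spec("rfb_esrgan", scale = 3), "scale")
  expect_error(generator_spec("rfb_esrgan", noise = TRUE), "noise")
  expect_error(generator_spec("nesrgan", scale = 2), "same-size")
  sp <- generator_spec("nesrgan")
  expect_true(sp$noise)
  expect_identical(sp$scale, 1L)
  expect_identical(sp$upsample_mode, "bilinear_conv")
})

test_that("the stage-1 generator doubles spatial dimensions", {
  g <- build_generator(tiny_g1_spec(), seed = 1)
  set.seed(1)
  y <- g$predict(matrix(runif(16 * 16), 16, 16))
  expect_identical(dim(y), c(32L, 32L))
  expect_true(all(is.finite(y)))
  expect_true(all(y >= 0 & y <= 1))
  # non-square and odd input sizes follow the same contract
  expect_identical(dim(g$predict(matrix(runif(15 * 9), 15, 9))), c(30L, 18L))
})

test_that("the same-size generator preserves dimensions including odd ones", {
  g <- build_generator(tiny_g2_spec(), seed = 2)
  set.seed(2)
  for (d in list(c(64, 64), c(63, 63), c(17, 31))) {
    y <- g$predict(matrix(runif(prod(d)), d[1], d[2]))
    expect_identical(dim(y), as.integer(d))
  }
})

test_that("zero-initialised generators reduce to their interpolation samplers", {
  set.seed(3)
  x <- matrix(runif(16 * 16), 16, 16)
  g1 <- build_generator(tiny_g1_spec(), seed = 5)
  bic <- pmin(pmax(resize_image(x, c(32, 32), antialias = FALSE), 0), 1)
  expect_lt(max(abs(g1$predict(x) - bic)), 1e-6)
  g2 <- build_generator(tiny_g2_spec(), seed = 6)
  z <- matrix(runif(21 * 19), 21, 19)
  expect_lt(max(abs(g2$predict(z) - z)), 1e-6)
})

test_that("no transposed convolution exists in the restoration generator", {
  g2 <- build_generator(tiny_g2_spec(), seed = 1)
  expect_false(uses_transposed_conv(g2))
  gdec <- build_generator(tiny_g2_spec(upsample_mode = "deconv",
                                       noise = FALSE), seed = 1)
  expect_true(uses_transposed_conv(gdec))
})

test_that("noise injection is a bit-exact no-op at zero strength", {
  set.seed(4)
  f <- array(runif(8 * 8 * 4), c(8, 8, 4))
  expect_identical(noise_injection(f, 0, seed = 11), f)
  n1 <- noise_injection(f, 0.5, seed = 11)
  n2 <- noise_injection(f, 0.5, seed = 11)
  expect_identical(n1, n2)
  expect_gt(max(abs(n1 - f)), 0)
  # deterministic inference: repeated forward passes agree with noise frozen
  g2 <- build_generator(tiny_g2_spec(), seed = 3)
  z <- matrix(runif(16 * 16), 16, 16)
  expect_identical(g2$predict(z), g2$predict(z))
})

test_that("the receptive field block preserves shape and feeds every branch", {
  set.seed(5)
  f <- array(runif(10 * 12 * 8), c(10, 12, 8))
  out <- rfb_block(f)
  expect_identical(dim(out$features), dim(f))
  # residual identity: zero out the fusion conv -> block is the identity
  blk <- out$block
  blk$children$fuse[[1]]$params$W[] <- 0
  blk$children$fuse[[1]]$params$b[] <- 0
  expect_equal(rfb_block(f, blk)$features, f, tolerance = 1e-12)
  # gradient flows into every branch on a random batch
  blk2 <- mrisr:::make_rfb_unit(2L, 2L)
  xb <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- blk2$fwd(xb, train = TRUE)
  blk2$bwd(array(rnorm(length(y)), dim(y)))
  for (br in c("b1", "b2", "b3", "b4")) {
    convs <- Filter(function(L) length(L$params) > 0,
                    mrisr:::collect_layers(blk2$children[[br]]))
    gnorm <- sum(vapply(convs, function(L) sum(abs(L$grads$W)), numeric(1)))
    expect_gt(gnorm, 0, label = br)
  }
  expect_error(rfb_block(array(1, c(8, 8, 4)), blk2), "width")
})

test_that("upsampler stages implement their sampling definitions", {
  cst <- array(0.4, c(6, 6, 3))
  up <- upsampler(cst, "bilinear_conv", 2)
  expect_identical(dim(up), c(12L, 12L, 3L))
  expect_equal(range(up), c(0.4, 0.4))      # constant in, constant out
  # delta impulse through NNI becomes a 2x2 block of the impulse value
  imp <- array(0, c(4, 4, 1)); imp[2, 2, 1] <- 1
  nni <- upsampler(imp, "nni", 2)
  expect_equal(nni[3:4, 3:4, 1], matrix(1, 2, 2))
  expect_equal(sum(nni), 4)
  # x4 alternates NNI and sub-pixel stages
  expect_identical(dim(upsampler(cst, "nni_spc_alternating", 4)),
                   c(24L, 24L, 3L))
  expect_error(upsampler(cst, "nni", 3), "scale")
})

test_that("entry downsampling halves feature maps with odd-size round-up", {
  f <- array(runif(9 * 12 * 2), c(9, 12, 2))
  d <- downsample_entry(f)
  expect_identical(dim(d), c(5L, 6L, 2L))
  expect_error(downsample_entry(f, 4), "scale 2")
})

test_that("the discriminator maps HR batches to one finite logit per image", {
  spec <- discriminator_spec(c(8, 16, 32, 64), input_size = 32,
                             fc_width = 16)
  D <- build_discriminator(spec, seed = 1)
  set.seed(6)
  xb <- array(runif(32 * 32 * 4), c(32, 32, 4, 1))
  lg <- D$fwd(xb)
  expect_length(lg, 4)
  expect_true(all(is.finite(lg)))
  # duplicated inputs give duplicated logits
  xb2 <- xb; xb2[, , 3, ] <- xb[, , 1, ]
  lg2 <- D$fwd(xb2)
  expect_equal(lg2[3], lg2[1], tolerance = 1e-12)
  # all-zero input stays finite
  expect_true(is.finite(D$fwd(array(0, c(32, 32, 1, 1)))))
  # size contract is reported with the minimal valid size
  expect_error(D$fwd(array(0, c(20, 20, 1, 1))), "minimal valid size")
  expect_error(discriminator_spec(c(8, 16, 24), 32), "doubling")
  expect_error(discriminator_spec(c(8, 16), 10), "multiple")
})

test_that("parameter count grows monotonically with trunk depth", {
  n <- vapply(1:3, function(k)
    count_parameters(build_generator(
      generator_spec("nesrgan", n_rrdb = k, base_channels = 8), seed = 1)),
    numeric(1))
  expect_true(all(diff(n) > 0))
})

test_that("checkpoints round-trip a generator exactly", {
  f <- withr::local_tempfile(fileext = ".rds")
  g <- build_generator(tiny_g1_spec(), seed = 9)
  set.seed(7)
  x <- matrix(runif(16 * 16), 16, 16)
  save_checkpoint(g, f)
  g2 <- load_checkpoint(f)
  expect_identical(g2$predict(x), g$predict(x))
  expect_identical(g2$spec, g$spec)
})
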