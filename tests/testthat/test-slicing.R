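test_that("slice extraction and restacking are the identity on every plane", {
  v <- tiny_phantom(seed = 1, shape = c(20, 18, 14))
  for (pl in c("sagittal", "coronal", "axial")) {
    st <- extract_slices(v, pl)
    n_expect <- dim(v)[match(pl, c("sagittal", "coronal", "axial"))]
    expect_length(st$slices, n_expect)
    expect_identical(st$source_indices, seq_len(n_expect))
    expect_identical(restack(st), v$voxels)
  }
  # slice dimensions follow the plane
  st <- extract_slices(v, "sagittal")
  expect_identical(dim(st$slices[[1]]), c(18L, 14L))
  st <- extract_slices(v, "axial")
  expect_identical(dim(st$slices[[1]]), c(20L, 18L))
  expect_error(extract_slices(v, "oblique"))
})

test_that("a single-slice-thick volume yields one slice", {
  v <- as_volume(array(runif(64 * 64), c(64, 64, 1)))
  expect_length(extract_slices(v, "axial")$slices, 1)
})

test_that("interval-1 decimation keeps alternating slices and halves counts", {
  # the study geometry: 150 axial -> 75, 256 sagittal -> 128
  v150 <- as_volume(array(runif(4 * 150), c(2, 2, 150)))
  d <- decimate(extract_slices(v150, "axial"), 1)
  expect_length(d$slices, 75)
  expect_identical(d$source_indices, seq(1L, 149L, 2L))
  v256 <- as_volume(array(runif(256 * 4), c(256, 2, 2)))
  expect_length(decimate(extract_slices(v256, "sagittal"))$slices, 128)
  # union of kept and dropped indices is the original index set
  st <- extract_slices(v150, "axial")
  kept <- decimate(st)$source_indices
  expect_setequal(c(kept, setdiff(seq_len(150), kept)), seq_len(150))
  # an interval so large only the first slice survives
  expect_length(decimate(st, 1000)$slices, 1)
  expect_error(decimate(st, 0), ">= 1")
})

test_that("bicubic slice degradation matches a naive Keys-kernel oracle", {
  set.seed(42)
  checker <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  got <- degrade_slice(checker, 2)
  expect_identical(dim(got), c(16L, 16L))
  expect_lt(max(abs(got - naive_bicubic(checker, c(16, 16)))), 1e-6)
  rnd <- matrix(runif(24 * 18), 24, 18)
  expect_lt(max(abs(degrade_slice(rnd, 2) - naive_bicubic(rnd, c(12, 9)))),
            1e-6)
  # geometry: a 256 x 150 slice halves to 128 x 75
  expect_identical(dim(degrade_slice(matrix(0.5, 256, 150), 2)),
                   c(128L, 75L))
  # constants are preserved exactly
  expect_equal(range(degrade_slice(matrix(0.3, 20, 20), 2)), c(0.3, 0.3))
  expect_error(degrade_slice(array(1, c(4, 4, 2))), "2D")
})

test_that("patch pairing tiles slices into aligned 16/32 LR/HR pairs", {
  v <- as_volume(array(runif(32 * 32 * 3), c(32, 32, 3)))
  st <- extract_slices(v, "axial")
  pairs <- make_patch_pairs(st, lr_size = 16, scale = 2)
  expect_length(pairs, 3)          # one 32x32 tile per slice
  p <- pairs[[1]]
  expect_identical(dim(p$lr), c(16L, 16L))
  expect_identical(dim(p$hr), c(32L, 32L))
  # the HR patch is exactly the slice crop at its origin
  expect_identical(p$hr, st$slices[[1]])
  expect_lt(max(abs(p$lr - degrade_slice(p$hr, 2))), 1e-12)

  v64 <- as_volume(array(runif(64 * 64), c(64, 64, 1)))
  expect_length(make_patch_pairs(extract_slices(v64, "axial")), 4)
  v31 <- as_volume(array(runif(31 * 31), c(31, 31, 1)))
  expect_warning(p0 <- make_patch_pairs(extract_slices(v31, "axial")),
                 "skipped")
  expect_length(p0, 0)
})

test_that("dataset splitting is seeded, disjoint and exactly sized", {
  sp <- split_dataset(seq_len(581), 431, seed = 7)
  expect_length(sp$train, 431)
  expect_length(sp$test, 150)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(581))
  # the second-stage split: 150 volumes -> 120 train, 30 test
  sp2 <- split_dataset(seq_len(150), 120, seed = 7)
  expect_length(sp2$test, 30)
  # determinism and minimal case
  expect_identical(split_dataset(letters, 10, seed = 1),
                   split_dataset(letters, 10, seed = 1))
  expect_length(split_dataset(1:2, 1)$test, 1)
  expect_error(split_dataset(1:5, 5), "train_count")
})
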