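# Generator and discriminator: shape contracts, determinism, upsampling.

test_that("seeded builds are reproducible and forward passes deterministic", {
  gs <- generator_spec(n_views = 16L, view_size = c(8L, 8L), out_slices = 3L,
                       upsample_factor = 4L, base_channels = 6L)
  g1 <- build_generator(gs, 11L)
  g2 <- build_generator(gs, 11L)
  g3 <- build_generator(gs, 12L)
  expect_equal(param_checksum(g1), param_checksum(g2))
  expect_false(param_checksum(g1) == param_checksum(g3))
  expect_equal(param_count(g1), param_count(g2))
  set.seed(5)
  x <- array(runif(8 * 8 * 16 * 2, -1, 1), c(8, 8, 16, 2))
  o1 <- generator_forward(g1, x)
  o2 <- generator_forward(g1, x)
  expect_identical(o1, o2)
  expect_true(all(is.finite(generator_forward(g1, array(0, c(8, 8, 16, 1))))))
  expect_error(generator_forward(g1, array(0, c(8, 8, 9, 1))),
               "does not match")
})

test_that("the published geometry maps 169 views of 16x16 to 208x208x61", {
  gs <- generator_spec(n_views = 169L, view_size = c(16L, 16L),
                       out_slices = 61L, upsample_factor = 13L,
                       base_channels = 4L)
  g <- build_generator(gs, 1L)
  out <- generator_forward(g, array(0.1, c(16, 16, 169, 1)))
  expect_equal(dim(out), c(208L, 208L, 61L, 1L))
})

test_that("even-channel skips concatenate ceiling(C/2) encoder channels", {
  gs <- generator_spec(n_views = 16L, view_size = c(8L, 8L), out_slices = 3L,
                       upsample_factor = 4L, base_channels = 6L)
  g <- build_generator(gs, 1L)
  c1 <- 6L; c3 <- 24L
  # decoder stage-3 conv consumes encoder output plus its even channels
  expect_equal(dim(g$params[["dec3_l1.w"]]$value)[3], c3 + ceiling(c3 / 2))
  expect_equal(dim(g$params[["dec1_l1.w"]]$value)[3], c1 + ceiling(c1 / 2))
  gall <- build_generator(generator_spec(
    n_views = 16L, view_size = c(8L, 8L), out_slices = 3L,
    upsample_factor = 4L, base_channels = 6L,
    skip_channel_rule = "all"), 1L)
  expect_equal(dim(gall$params[["dec3_l1.w"]]$value)[3], 2L * c3)
})

test_that("discriminator scores are in (0, 1), per input, deterministically", {
  ds <- discriminator_spec(in_slices = 4L, n_blocks = 3L, channel_base = 6L)
  d <- build_discriminator(ds, 3L)
  set.seed(6)
  x2 <- array(runif(32 * 32 * 4 * 2, -1, 1), c(32, 32, 4, 2))
  s2 <- as.vector(discriminator_forward(d, x2))
  expect_length(s2, 2L)
  expect_true(all(s2 > 0 & s2 < 1))
  expect_identical(s2, as.vector(discriminator_forward(d, x2)))
  s1 <- as.vector(discriminator_forward(d, x2[, , , 1]))
  expect_length(s1, 1L)
  expect_error(discriminator_forward(d, array(0, c(32, 32, 5, 1))),
               "slice count")
  # channel rule: first block matches slices, then 20 * 2^k (base 20)
  d20 <- build_discriminator(discriminator_spec(in_slices = 7L), 1L)
  expect_equal(d20$widths, c(7L, 40L, 80L, 160L, 320L))
})

test_that("blended upsampling suppresses the checkerboard harmonic", {
  harmonic <- function(mode, seed) {
    gs <- generator_spec(n_views = 16L, view_size = c(8L, 8L),
                         out_slices = 1L, upsample_factor = 4L,
                         base_channels = 6L, upsample_mode = mode)
    g <- build_generator(gs, seed)
    out <- generator_forward(g, array(0.5, c(8, 8, 16, 1)))[, , 1, 1]
    sp <- Mod(stats::fft(out - mean(out)))
    n <- nrow(sp)
    # power at the pixel-shuffle period (frequency n/2 and n/4 lines)
    sp[1 + n / 2, 1] + sp[1, 1 + n / 2] + sp[1 + n / 4, 1] + sp[1, 1 + n / 4]
  }
  seeds <- 1:10
  ps <- sapply(seeds, function(s) harmonic("pixelshuffle", s))
  cb <- sapply(seeds, function(s) harmonic("combined", s))
  expect_lt(mean(cb), mean(ps))
})

test_that("checkpoints round-trip losslessly", {
  gs <- generator_spec(n_views = 16L, view_size = c(8L, 8L), out_slices = 3L,
                       upsample_factor = 4L, base_channels = 6L)
  g <- build_generator(gs, 21L)
  set.seed(7)
  x <- array(runif(8 * 8 * 16), c(8, 8, 16, 1))
  before <- generator_forward(g, x)
  path <- tempfile(fileext = ".rds")
  save_weights(g, path)
  g2 <- load_weights(path)
  expect_identical(generator_forward(g2, x), before)
  expect_equal(param_checksum(g2), param_checksum(g))
})
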