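# Forward model: PSF construction, projection, view decomposition.

test_that("optical_config enforces its invariants", {
  expect_error(optical_config(numerical_aperture = 1.4, medium_index = 1.33),
               "numerical_aperture")
  expect_error(optical_config(z_planes = c(0, 0, 1)), "increasing")
  expect_error(optical_config(kernel_halfwidth = -1L), "kernel_halfwidth")
})

test_that("PSF kernels are non-negative with unit mass per depth and phase", {
  psf <- fix_psf()
  expect_true(all(is.finite(psf$kernels)))
  expect_true(all(psf$kernels >= 0))
  mass <- apply(psf$kernels, c(1, 2, 3), sum)
  expect_true(all(abs(mass - 1) < 1e-6))
})

test_that("zero-defocus kernel mass concentrates under the source lenslet", {
  cfg <- optical_config(pixels_per_lenslet = 4L, z_planes = c(-3, 0, 3),
                        kernel_halfwidth = 2L)
  psf <- build_psf(cfg)
  n <- 4L
  k <- psf$kernels[2, n %/% 2 + 1, n %/% 2 + 1, , ] # central phase at z = 0
  ctr <- cfg$kernel_halfwidth * n + seq_len(n) # source lenslet footprint
  expect_gt(sum(k[ctr, ctr]) / sum(k), 0.9)
})

test_that("wave-optics kernel width grows away from focus", {
  cfg <- optical_config(numerical_aperture = 1.4, medium_index = 1.518,
                        wavelength = 525, pixels_per_lenslet = 3L,
                        sensor_pixel = 0.4, z_planes = c(0, 6),
                        psf_model = "wave_optics", kernel_halfwidth = 3L)
  psf <- build_psf(cfg)
  rms <- function(k) {
    n <- nrow(k)
    x <- seq_len(n) - (n + 1) / 2
    xx <- outer(x, rep(1, n))
    m <- sum(k)
    cx <- sum(k * xx) / m
    sqrt(sum(k * (xx - cx)^2) / m)
  }
  expect_gt(rms(psf$kernels[2, 2, 2, , ]), rms(psf$kernels[1, 2, 2, , ]))
})

test_that("projection is linear and conserves energy", {
  psf <- fix_psf()
  d <- c(64L, 64L, 5L)
  set.seed(21)
  v1 <- array(runif(prod(d)), d)
  v2 <- array(runif(prod(d)), d)
  l1 <- lf_project(v1, psf)$data
  l2 <- lf_project(v2, psf)$data
  lc <- lf_project(2.5 * v1 - 0.7 * v2, psf)$data
  expect_lt(max(abs(lc - (2.5 * l1 - 0.7 * l2))) / max(abs(lc)), 1e-6)
  expect_lt(abs(sum(l1) - sum(v1)) / sum(v1), 1e-5)
  expect_equal(max(abs(lf_project(array(0, d), psf)$data)), 0)
})

test_that("a unit voxel stamps its kernel at the source lenslet", {
  psf <- fix_psf()
  n <- 4L
  khw <- psf$config$kernel_halfwidth
  v <- array(0, c(64, 64, 5))
  r <- 26L; c <- 35L; dz <- 3L # phase (1, 2): (26-1) %% 4, (35-1) %% 4
  v[r, c, dz] <- 1
  lf <- lf_project(v, psf)$data
  i <- (r - 1L) %% n
  j <- (c - 1L) %% n
  rows <- (r - i - khw * n) + seq_len((2 * khw + 1) * n) - 1L
  cols <- (c - j - khw * n) + seq_len((2 * khw + 1) * n) - 1L
  expect_equal(lf[rows, cols], psf$kernels[dz, i + 1, j + 1, , ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("projection is shift-equivariant over one lenslet pitch", {
  psf <- fix_psf()
  v <- array(0, c(64, 64, 5))
  v[30, 30, 2] <- 1
  v2 <- array(0, c(64, 64, 5))
  v2[34, 30, 2] <- 1 # shifted by exactly one pitch (N = 4)
  l1 <- lf_project(v, psf)$data
  l2 <- lf_project(v2, psf)$data
  shifted <- l1[((seq_len(64) - 1 - 4) %% 64) + 1, ] # circular row shift by 4
  expect_equal(l2, shifted, tolerance = 1e-10)
})

test_that("backprojection is the exact adjoint of projection", {
  psf <- fix_psf()
  set.seed(7)
  v <- array(runif(64 * 64 * 5), c(64, 64, 5))
  l <- matrix(runif(64 * 64), 64, 64)
  lhs <- sum(lf_project(v, psf)$data * l)
  rhs <- sum(v * lf_backproject(l, psf)$data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("view decomposition is an exact bijection", {
  set.seed(3)
  lf <- lf_image(matrix(sample(0:255, 52 * 52, TRUE), 52, 52), 4L)
  views <- decompose_views(lf)
  expect_identical(recompose_views(views)$data, lf$data)
  expect_identical(recompose_views(structure(
    list(data = array(0, c(9, 4, 4)), pixels_per_lenslet = 3L),
    class = "lf_views"))$data, matrix(0, 12, 12))
  bad <- views
  bad$data <- bad$data[1:15, , , drop = FALSE]
  expect_error(recompose_views(bad), "inconsistent")
})

test_that("views pick the matching pixel phase of every lenslet", {
  toy <- lf_image(matrix(0:15, 4, 4, byrow = TRUE), 2L)
  views <- decompose_views(toy)
  expect_equal(as.vector(views$data[1, , ]), c(0, 8, 2, 10)) # view (0, 0)
  expect_equal(as.vector(views$data[2, , ]), c(1, 9, 3, 11)) # view (0, 1)
  # single nonzero view recomposes onto one phase only
  vz <- views
  vz$data[] <- 0
  vz$data[2, , ] <- 1
  back <- recompose_views(vz)$data
  nz <- which(back != 0, arr.ind = TRUE)
  expect_true(all((nz[, 1] - 1) %% 2 == 0 & (nz[, 2] - 1) %% 2 == 1))
})

test_that("a 208-pixel light field with N = 13 gives 169 views of 16 x 16", {
  lf <- lf_image(matrix(runif(208 * 208), 208, 208), 13L)
  views <- decompose_views(lf)
  expect_equal(dim(views$data), c(169L, 16L, 16L))
  expect_error(lf_image(matrix(0, 208, 208), 15L), "divisible")
})

test_that("projection rejects mismatched shapes with both named", {
  psf <- fix_psf()
  expect_error(lf_project(array(0, c(64, 64, 4)), psf), "depth count")
  expect_error(lf_project(array(0, c(63, 64, 5)), psf), "divisible")
})
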