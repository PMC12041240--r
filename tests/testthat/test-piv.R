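# Particle localization, matching, optical flow, and velocity scoring.

test_that("particle localization finds isolated beads to sub-voxel accuracy", {
  v <- array(0, c(32, 32, 9))
  v <- lfrecon:::splat_gaussian(v, c(12.4, 20.7, 4.6), c(1.2, 1.2, 0.9))
  det <- localize_particles(lf_volume(v), threshold = 0.3, min_distance = 3)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt(sum((as.numeric(det[1, c("row", "col", "z")]) -
                        c(12.4, 20.7, 4.6))^2)), 0.5)
  expect_equal(nrow(localize_particles(lf_volume(array(0, c(8, 8, 4))))), 0L)
  # two beads separated well beyond min_distance give two detections
  v2 <- lfrecon:::splat_gaussian(v, c(25.2, 8.3, 6.1), c(1.2, 1.2, 0.9))
  det2 <- localize_particles(lf_volume(v2), threshold = 0.3, min_distance = 3)
  expect_equal(nrow(det2), 2L)
})

test_that("position errors follow the Euclidean distance tensor", {
  a <- data.frame(y_um = c(3, 0), x_um = c(4, 5), z_um = c(0, 0))
  b <- data.frame(y_um = c(0, 0), x_um = c(0, 5), z_um = c(0, 0))
  pe <- position_error(a, b)
  expect_equal(sort(pe$errors), c(0, 5)) # 3-4-5 triangle and an exact match
  expect_equal(pe$mean, 2.5)
  same <- position_error(b, b)
  expect_true(all(same$errors == 0))
  gated <- position_error(a, b[1, , drop = FALSE], max_distance = 1)
  expect_equal(gated$n_matched, 0L)
  expect_equal(gated$n_unmatched_ideal, 1L)
})

test_that("optical flow is zero for identical volumes", {
  set.seed(41)
  v <- array(runif(24 * 24 * 8), c(24, 24, 8))
  ff <- optical_flow_3d(v, v)
  expect_true(all(ff$vectors == 0))
  expect_error(optical_flow_3d(v, v[1:10, , ]), "shape mismatch")
})

test_that("optical flow recovers a unit shift within 10%", {
  s <- phantom_spec(shape = c(40L, 40L, 16L), seed = 8L, density_ppm = 0.6,
                    pixels_per_lenslet = 4L, particle_diameter_um = 4,
                    flow = list(kind = "uniform", u = c(0, 0, 0)))
  v1 <- lfrecon:::gauss_blur3(make_particle_pair(s)$frame1$data, c(1, 1, 1))
  v2 <- v1[c(40, 1:39), , ] # circular shift by (1, 0, 0)
  ff <- optical_flow_3d(v1, v2, lambda = 0.02, n_iterations = 250L,
                        pyramid_levels = 1L, presmooth = 1)
  inner <- ff$vectors[8:33, 8:33, 4:13, ]
  w <- array(v1[8:33, 8:33, 4:13], dim(inner))
  mu <- c(sum(inner[, , , 1] * w[, , , 1]), sum(inner[, , , 2] * w[, , , 1]),
          sum(inner[, , , 3] * w[, , , 1])) / sum(w[, , , 1])
  expect_lt(abs(mu[1] - 1), 0.1)
  expect_lt(abs(mu[2]), 0.1)
  expect_lt(abs(mu[3]), 0.1)
})

test_that("optical flow recovers vortex angular speed within 15%", {
  omega <- 0.8 # rad/s; frame_time 0.25 s -> 0.2 rad/frame
  s <- phantom_spec(shape = c(48L, 48L, 48L), seed = 9L, density_ppm = 2,
                    pixels_per_lenslet = 4L, particle_diameter_um = 5,
                    frame_time = 0.25,
                    flow = list(kind = "vortex", omega = omega))
  pp <- make_particle_pair(s)
  ff <- optical_flow_3d(pp$frame1, pp$frame2, lambda = 0.05,
                        n_iterations = 120L, pyramid_levels = 2L,
                        presmooth = 1.5)
  d <- dim(pp$frame1$data)
  ctr <- (d + 1) / 2
  rad <- sqrt((slice.index(array(0, d), 1) - ctr[1])^2 +
                (slice.index(array(0, d), 3) - ctr[3])^2)
  wgt <- lfrecon:::gauss_blur3(pp$frame1$data, c(2, 2, 2)) *
    (rad > 6 & rad < 18) # vortex core annulus, particle-weighted
  om_est <- fit_rotation_rowz(ff, wgt)
  expect_lt(abs(om_est - omega * 0.25) / (omega * 0.25), 0.15)
})

test_that("optical flow commutes with swapping the lateral axes", {
  set.seed(45)
  base <- array(0, c(24, 24, 24))
  for (k in 1:12)
    base <- lfrecon:::splat_gaussian(base, runif(3, 5, 20), c(1.5, 1.5, 1.5))
  shifted <- base[c(24, 1:23), , ]
  f1 <- optical_flow_3d(base, shifted, pyramid_levels = 1L)
  f2 <- optical_flow_3d(aperm(base, c(2, 1, 3)), aperm(shifted, c(2, 1, 3)),
                        pyramid_levels = 1L)
  expect_equal(aperm(f2$vectors[, , , 2], c(2, 1, 3)), f1$vectors[, , , 1],
               tolerance = 1e-8)
  expect_equal(aperm(f2$vectors[, , , 1], c(2, 1, 3)), f1$vectors[, , , 2],
               tolerance = 1e-8)
})

test_that("velocity errors summarize the masked difference magnitudes", {
  d <- c(6L, 5L, 4L)
  t1 <- flow_field(array(1, c(d, 3)))
  est <- t1
  expect_equal(velocity_error(est, t1)$mean, 0)
  est$vectors[, , , 3] <- est$vectors[, , , 3] + 1
  ve <- velocity_error(est, t1)
  expect_equal(ve$mean, 1)
  expect_equal(ve$n, prod(d))
  msk <- array(FALSE, d)
  msk[1:2, 1, 1] <- TRUE
  expect_equal(velocity_error(est, t1, msk)$n, 2L)
  expect_error(velocity_error(est, t1, array(FALSE, d)), "empty mask")
  # unit conversion round trip
  ffu <- flow_convert(flow_field(array(2, c(d, 3)), frame_time = 0.5,
                                 voxel_size = c(2, 2, 2)), "um/s")
  expect_equal(ffu$vectors[1, 1, 1, 1], 2 * 2 / 0.5)
  back <- flow_convert(ffu, "vox/frame")
  expect_equal(back$vectors[1, 1, 1, 1], 2)
})
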