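# Synthetic phantom generators and their ground-truth annotations.

test_that("generators are bit-reproducible under a fixed seed", {
  s <- phantom_spec(shape = c(32L, 32L, 6L), seed = 42L, n_filaments = 4L,
                    diameter_um = 2)
  expect_identical(make_tubulins(s)$data, make_tubulins(s)$data)
  sb <- phantom_spec(shape = c(32L, 32L, 6L), seed = 42L, n_beads = 5L,
                     diameter_um = 1.5, min_separation_um = 4)
  b1 <- make_beads(sb)
  b2 <- make_beads(sb)
  expect_identical(b1$volume$data, b2$volume$data)
  expect_identical(b1$particles, b2$particles)
  sp <- phantom_spec(shape = c(24L, 24L, 8L), seed = 7L,
                     flow = list(kind = "uniform", u = c(1, 0, 2)))
  expect_identical(make_particle_pair(sp)$frame2$data,
                   make_particle_pair(sp)$frame2$data)
})

test_that("tubulin cross-section FWHM tracks the requested diameter", {
  for (diam in c(3, 5)) {
    s <- phantom_spec(shape = c(48L, 48L, 9L), seed = 3L, n_filaments = 1L,
                      diameter_um = diam, wiggle = 0.04)
    v <- make_tubulins(s)$data
    pk <- arrayInd(which.max(v), dim(v))
    # measure across the two lateral axes, keep the sharper one
    w1 <- tryCatch(fwhm_profile(v[, pk[2], pk[3]]), error = function(e) Inf)
    w2 <- tryCatch(fwhm_profile(v[pk[1], , pk[3]]), error = function(e) Inf)
    expect_lt(abs(min(w1, w2) - diam), 1)
  }
})

test_that("tubulin occupancy grows with filament count", {
  occ <- sapply(c(5L, 10L, 20L), function(k) {
    v <- make_tubulins(phantom_spec(shape = c(48L, 48L, 8L), seed = 5L,
                                    n_filaments = k, diameter_um = 2))$data
    mean(v > 0.05)
  })
  expect_true(all(diff(occ) > 0))
})

test_that("bead centroids match the returned ground truth", {
  s <- phantom_spec(shape = c(48L, 48L, 9L), seed = 12L, n_beads = 6L,
                    diameter_um = 2, min_separation_um = 7)
  out <- make_beads(s)
  v <- out$volume$data
  for (b in seq_len(nrow(out$particles))) {
    p <- as.numeric(out$particles[b, c("row", "col", "z")])
    rr <- max(1, round(p[1]) - 3):min(48, round(p[1]) + 3)
    cc <- max(1, round(p[2]) - 3):min(48, round(p[2]) + 3)
    zz <- max(1, round(p[3]) - 3):min(9, round(p[3]) + 3)
    w <- v[rr, cc, zz]
    cen <- c(sum(slice.index(w, 1) * w) / sum(w) + rr[1] - 1,
             sum(slice.index(w, 2) * w) / sum(w) + cc[1] - 1,
             sum(slice.index(w, 3) * w) / sum(w) + zz[1] - 1)
    expect_lt(sqrt(sum((cen - p)^2)), 0.5)
  }
  # pairwise separation honored
  pos <- as.matrix(out$particles[, c("y_um", "x_um", "z_um")])
  dd <- as.matrix(dist(pos))
  expect_true(all(dd[upper.tri(dd)] >= 7))
  # empty request
  e <- make_beads(phantom_spec(shape = c(16L, 16L, 4L), seed = 1L,
                               n_beads = 0L))
  expect_equal(max(e$volume$data), 0)
  expect_equal(nrow(e$particles), 0L)
  # infeasible packing errors out
  expect_error(make_beads(phantom_spec(shape = c(12L, 12L, 4L), seed = 1L,
                                       n_beads = 40L,
                                       min_separation_um = 6)),
               "packing")
})

test_that("background-free neuro volumes are supported on the somata only", {
  s <- phantom_spec(shape = c(40L, 40L, 8L), seed = 4L, n_somas = 4L,
                    soma_radius_um = 4, n_frames = 30L)
  out <- make_neuro_volume(s)
  v <- out$frames[[1]]$data
  expect_true(all(v[out$roi_labels == 0L] == 0))
  expect_true(all(v[out$roi_labels > 0L] > 0))
})

test_that("spike trains render as exponential brightness transients", {
  tau_s <- 1; frame_rate <- 10
  trs <- make_activity_traces(4L, 60L, frame_rate, spike_rate = 0.5,
                              tau_s = tau_s, amplitude = 1, noise_sd = 0,
                              seed = 21L)
  for (tr in trs) {
    tt <- seq_len(60)
    want <- rep(1, 60)
    for (s in tr$spike_frames)
      want[tt >= s] <- want[tt >= s] + exp(-(tt[tt >= s] - s) /
                                             (tau_s * frame_rate))
    expect_equal(tr$values, want, tolerance = 1e-6)
    if (length(tr$spike_frames) == 1L)
      expect_equal(which.max(tr$values), tr$spike_frames)
  }
  # rendered soma brightness equals the trace value on the ROI
  s <- phantom_spec(shape = c(32L, 32L, 6L), seed = 2L, n_somas = 1L,
                    soma_radius_um = 4, n_frames = 20L, spike_rate = 0.5,
                    noise_sd = 0)
  out <- make_neuro_volume(s)
  roi <- sapply(out$frames, function(f) mean(f$data[out$roi_labels == 1L]))
  expect_equal(roi, out$traces[[1]]$values, tolerance = 1e-9)
})

test_that("rendered dF/F0 traces recover the generating dynamics", {
  s <- phantom_spec(shape = c(40L, 40L, 8L), seed = 14L, n_somas = 3L,
                    soma_radius_um = 4, n_frames = 60L, spike_rate = 0.5,
                    noise_sd = 0)
  out <- make_neuro_volume(s)
  roi <- roi_mean_traces(out$frames, out$roi_labels)
  dff <- dff_traces(roi)
  for (k in 1:3) {
    gen <- out$traces[[k]]$values
    expect_gt(cor(dff[, k], (gen - mean(gen)) / mean(gen)), 0.99)
  }
})

test_that("particle pairs follow the seeding density and the flow exactly", {
  # zero flow: identical frames
  s0 <- phantom_spec(shape = c(24L, 24L, 6L), seed = 3L,
                     flow = list(kind = "uniform", u = c(0, 0, 0)))
  p0 <- make_particle_pair(s0)
  expect_identical(p0$frame1$data, p0$frame2$data)
  # uniform flow: exact advection
  su <- phantom_spec(shape = c(24L, 24L, 6L), seed = 3L, frame_time = 0.5,
                     flow = list(kind = "uniform", u = c(2, -1, 3)))
  pu <- make_particle_pair(su)
  expect_equal(pu$particles2$y_um, pu$particles1$y_um + 2 * 0.5)
  expect_equal(pu$particles2$x_um, pu$particles1$x_um - 1 * 0.5)
  expect_equal(pu$particles2$z_um, pu$particles1$z_um + 3 * 0.5)
  expect_error(make_particle_pair(
    phantom_spec(shape = c(24L, 24L, 6L), seed = 1L,
                 flow = list(kind = "swirl"))), "unknown flow")
})

test_that("particle counts follow the particles-per-microlens density", {
  # 0.03 PPM over 100 x 100 lenslets (N = 4): expectation 300
  s <- phantom_spec(shape = c(400L, 400L, 4L), seed = 77L,
                    density_ppm = 0.03, pixels_per_lenslet = 4L,
                    flow = list(kind = "uniform", u = c(0, 0, 0)))
  p <- make_particle_pair(s)
  n <- nrow(p$particles1)
  expect_lt(abs(n - 300), 4 * sqrt(300))
})
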