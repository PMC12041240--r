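# Seeded synthetic phantoms: every generator is a pure function of its spec
# (seed included) and returns machine-readable ground truth alongside the
# rendered volume.

#' Phantom specification
#'
#' Bundles the volume geometry, the RNG seed and class-specific parameters of
#' a synthetic sample. Unrecognized parameters are rejected by the individual
#' generators.
#'
#' @param shape `(H, W, D)` voxel counts.
#' @param voxel_size `(dy, dx, dz)` micrometers per voxel.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param ... class-specific parameters (see [make_tubulins()],
#'   [make_beads()], [make_neuro_volume()], [make_particle_pair()]).
#' @export
phantom_spec <- function(shape = c(64, 64, 5), voxel_size = c(1, 1, 1),
                         seed = 1L, ...) {
  structure(c(list(shape = as.integer(shape), voxel_size = voxel_size,
                   seed = as.integer(seed)), list(...)),
            class = "phantom_spec")
}

spec_par <- function(spec, name, default) {
  if (!is.null(spec[[name]])) spec[[name]] else default
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Separable 3D Gaussian blur via repeated 1-D correlation (zero padding).
gauss_blur3 <- function(x, sigma) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma[min(ax, length(sigma))]
    if (s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    k <- exp(-((-hw):hw)^2 / (2 * s^2))
    k <- k / sum(k)
    x <- aperm(x, c(ax, setdiff(1:3, ax)))
    da <- dim(x)
    dim(x) <- c(da[1], da[2] * da[3])
    x <- blur_cols(x, k)
    dim(x) <- da
    x <- aperm(x, order(c(ax, setdiff(1:3, ax))))
  }
  x
}

blur_cols <- function(m, k) {
  hw <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    off <- t - 1L - hw
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
  }
  out
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Splat a unit Gaussian blob at a continuous voxel position (1-based center
# coordinates), evaluated on the grid. Used for beads and particles.
splat_gaussian <- function(vol, pos, sigma_vox) {
  d <- dim(vol)
  hw <- pmax(1, ceiling(4 * sigma_vox))
  r <- lapply(1:3, function(ax) {
    seq(max(1L, floor(pos[ax] - hw[min(ax, length(hw))])),
        min(d[ax], ceiling(pos[ax] + hw[min(ax, length(hw))])))
  })
  if (any(vapply(r, length, 1L) == 0L)) return(vol)
  g <- lapply(1:3, function(ax) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    exp(-((r[[ax]] - pos[ax])^2) / (2 * s^2))
  })
  blob <- outer(outer(g[[1]], g[[2]]), g[[3]])
  vol[r[[1]], r[[2]], r[[3]]] <- vol[r[[1]], r[[2]], r[[3]]] + blob
  vol
}

#' Filamentous tubulin phantom
#'
#' Smooth random 3D curves (cubic splines through uniformly drawn control
#' points, gently wiggling around a random principal axis) rasterized with a
#' Gaussian cross-section whose FWHM equals the requested diameter.
#' Output intensities are normalized to `[0, 1]`.
#'
#' Spec parameters: `n_filaments` (default 8), `diameter_um` (default 1),
#' `n_control` spline control points (default 5), `wiggle` lateral deviation
#' as a fraction of the volume extent (default 0.12).
#' @param spec a [phantom_spec()].
#' @return an [lf_volume()].
#' @export
make_tubulins <- function(spec) {
  d <- spec$shape
  nf <- spec_par(spec, "n_filaments", 8L)
  diam <- spec_par(spec, "diameter_um", 1)
  ncp <- spec_par(spec, "n_control", 5L)
  wig <- spec_par(spec, "wiggle", 0.12)
  stopifnot(nf >= 0, diam > 0)
  sig_vox <- fwhm_to_sigma(diam) / spec$voxel_size
  if (any(diam / spec$voxel_size > d))
    stop("filament diameter (", diam, " um) exceeds the volume extent")
  vol <- array(0, d)
  if (nf > 0) {
    vol <- with_seed(spec$seed, {
      acc <- array(0, d)
      for (f in seq_len(nf)) {
        ax <- sample(1:2, 1) # principal axis: rows or cols
        tt <- seq(0, 1, length.out = ncp)
        main <- 1 + tt * (d[ax] - 1)
        lat1 <- runif(1, 1, d[3 - ax]) + cumsum(runif(ncp, -1, 1)) *
          wig * d[3 - ax]
        latz <- runif(1, 1, d[3]) + cumsum(runif(ncp, -1, 1)) * wig * d[3]
        ts <- seq(0, 1, length.out = 4L * max(d[1:2]))
        sm <- stats::spline(tt, main, xout = ts)$y
        s1 <- stats::spline(tt, lat1, xout = ts)$y
        sz <- stats::spline(tt, latz, xout = ts)$y
        pr <- if (ax == 1) cbind(sm, s1, sz) else cbind(s1, sm, sz)
        pr[, 1] <- pmin(pmax(pr[, 1], 1), d[1])
        pr[, 2] <- pmin(pmax(pr[, 2], 1), d[2])
        pr[, 3] <- pmin(pmax(pr[, 3], 1), d[3])
        ijk <- round(pr)
        lin <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
        cnt <- table(lin)
        acc[as.integer(names(cnt))] <- acc[as.integer(names(cnt))] + 1
      }
      acc
    })
    vol <- gauss_blur3(vol, pmax(sig_vox, 0.4))
    if (max(vol) > 0) vol <- vol / max(vol)
  }
  lf_volume(vol, spec$voxel_size)
}

#' Bead phantom with ground-truth positions
#'
#' Isolated Gaussian beads at uniformly drawn positions respecting a minimum
#' pairwise separation (rejection sampling). Intensity centroids coincide
#' with the returned positions to sub-voxel accuracy.
#'
#' Spec parameters: `n_beads` (default 10), `diameter_um` (default 0.1),
#' `min_separation_um` (default 0), `margin_vox` border margin (default 3),
#' `positions` optional explicit matrix of `(row, col, z)` voxel coordinates
#' overriding random placement.
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([lf_volume()]) and `particles` (data.frame
#'   with voxel-coordinate columns `row`, `col`, `z` and micrometer columns
#'   `y_um`, `x_um`, `z_um`).
#' @export
make_beads <- function(spec) {
  d <- spec$shape
  nb <- spec_par(spec, "n_beads", 10L)
  diam <- spec_par(spec, "diameter_um", 0.1)
  minsep <- spec_par(spec, "min_separation_um", 0)
  margin <- spec_par(spec, "margin_vox", 3)
  pos_fixed <- spec_par(spec, "positions", NULL)
  stopifnot(nb >= 0, minsep >= 0)
  sig_vox <- pmax(fwhm_to_sigma(diam) / spec$voxel_size, 0.7)
  vol <- array(0, d)
  if (!is.null(pos_fixed)) {
    pos <- as.matrix(pos_fixed)
    nb <- nrow(pos)
  } else if (nb > 0) {
    pos <- with_seed(spec$seed, {
      kept <- matrix(NA_real_, 0, 3)
      tries <- 0L
      while (nrow(kept) < nb) {
        tries <- tries + 1L
        if (tries > 200L * nb)
          stop("bead packing infeasible: ", nrow(kept), " of ", nb,
               " beads placed with min_separation_um = ", minsep)
        m3 <- pmin(margin, (d - 1) / 2 - 0.01) # margin cannot exceed half-extent
        cand <- c(stats::runif(1, 1 + m3[1], d[1] - m3[1]),
                  stats::runif(1, 1 + m3[2], d[2] - m3[2]),
                  stats::runif(1, 1 + m3[3], d[3] - m3[3]))
        if (nrow(kept) > 0) {
          dd <- sqrt(colSums((t(kept) - cand)^2 * spec$voxel_size^2))
          if (any(dd < minsep)) next
        }
        kept <- rbind(kept, cand)
      }
      kept
    })
  } else {
    pos <- matrix(NA_real_, 0, 3)
  }
  if (nb > 0) for (b in seq_len(nrow(pos)))
    vol <- splat_gaussian(vol, pos[b, ], sig_vox)
  if (max(vol) > 0) vol <- vol / max(vol)
  particles <- data.frame(
    row = pos[, 1], col = pos[, 2], z = pos[, 3],
    y_um = (pos[, 1] - 1) * spec$voxel_size[1],
    x_um = (pos[, 2] - 1) * spec$voxel_size[2],
    z_um = (pos[, 3] - 1) * spec$voxel_size[3]
  )
  list(volume = lf_volume(vol, spec$voxel_size), particles = particles)
}

#' Calcium activity traces
#'
#' Poisson spike trains convolved with a single-exponential indicator kernel
#' plus additive Gaussian noise, on a baseline of 1.
#' @param n_neurons number of traces.
#' @param n_frames frames per trace.
#' @param frame_rate Hz (default 10).
#' @param spike_rate expected spikes per second (default 0.2).
#' @param tau_s decay constant in seconds (default 1).
#' @param amplitude fluorescence jump per spike (default 1).
#' @param noise_sd additive noise SD (default 0).
#' @param seed RNG seed.
#' @return list of traces; each has `values`, `frame_rate`, `spike_frames`.
#' @export
make_activity_traces <- function(n_neurons, n_frames, frame_rate = 10,
                                 spike_rate = 0.2, tau_s = 1, amplitude = 1,
                                 noise_sd = 0, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      spikes <- which(stats::runif(n_frames) < spike_rate / frame_rate)
      f <- rep(1, n_frames)
      tt <- seq_len(n_frames)
      for (s in spikes)
        f[tt >= s] <- f[tt >= s] + amplitude * exp(-(tt[tt >= s] - s) /
                                                     (tau_s * frame_rate))
      if (noise_sd > 0) f <- f + stats::rnorm(n_frames, 0, noise_sd)
      list(values = f, frame_rate = frame_rate, spike_frames = spikes)
    })
  })
}

#' Cortical soma phantom with calcium dynamics
#'
#' A simplified stand-in for simulated cortical tissue: ellipsoidal somata
#' whose brightness follows per-neuron calcium traces, with optional neuropil
#' haze and dark vessel tubes.
#'
#' Spec parameters: `n_somas` (default 6), `soma_radius_um` (default 6),
#' `n_frames` (default 40), `frame_rate` Hz (default 10), `neuropil` and
#' `vessels` logical background flags (default FALSE), `spike_rate`, `tau_s`,
#' `noise_sd` forwarded to [make_activity_traces()].
#' @param spec a [phantom_spec()].
#' @return list with `frames` (list of [lf_volume()], one per time point),
#'   `somas` (data.frame of centers/radii), `traces`
#'   (from [make_activity_traces()]), and `roi_labels` (integer array
#'   labelling each soma's voxels).
#' @export
make_neuro_volume <- function(spec) {
  d <- spec$shape
  ns <- spec_par(spec, "n_somas", 6L)
  rad_um <- spec_par(spec, "soma_radius_um", 6)
  n_frames <- spec_par(spec, "n_frames", 40L)
  frame_rate <- spec_par(spec, "frame_rate", 10)
  neuropil <- isTRUE(spec_par(spec, "neuropil", FALSE))
  vessels <- isTRUE(spec_par(spec, "vessels", FALSE))
  stopifnot(ns >= 0)
  rad_vox <- rad_um / spec$voxel_size
  somas <- with_seed(spec$seed, {
    data.frame(
      row = stats::runif(ns, 1 + rad_vox[1], d[1] - rad_vox[1]),
      col = stats::runif(ns, 1 + rad_vox[2], d[2] - rad_vox[2]),
      z = stats::runif(ns, 1 + rad_vox[3] / 2, d[3] - rad_vox[3] / 2),
      radius_um = rad_um * stats::runif(ns, 0.8, 1.2)
    )
  })
  traces <- make_activity_traces(
    ns, n_frames, frame_rate,
    spike_rate = spec_par(spec, "spike_rate", 0.3),
    tau_s = spec_par(spec, "tau_s", 1),
    noise_sd = spec_par(spec, "noise_sd", 0),
    seed = spec$seed + 1L
  )
  # per-soma indicator masks
  grid_r <- slice.index(array(0, d), 1)
  grid_c <- slice.index(array(0, d), 2)
  grid_z <- slice.index(array(0, d), 3)
  roi_labels <- array(0L, d)
  masks <- vector("list", ns)
  for (s in seq_len(ns)) {
    rv <- somas$radius_um[s] / spec$voxel_size
    m <- ((grid_r - somas$row[s]) / rv[1])^2 +
      ((grid_c - somas$col[s]) / rv[2])^2 +
      ((grid_z - somas$z[s]) / rv[3])^2 <= 1
    masks[[s]] <- m
    roi_labels[m] <- s
  }
  background <- array(0, d)
  if (neuropil) {
    background <- background + with_seed(spec$seed + 2L, {
      gauss_blur3(array(stats::runif(prod(d)), d), c(4, 4, 1.5)) * 0.15
    })
  }
  vessel_mask <- array(FALSE, d)
  if (vessels) {
    vessel_mask <- with_seed(spec$seed + 3L, {
      vm <- array(0, d)
      for (k in 1:max(1L, ns %/% 3L)) {
        r0 <- stats::runif(1, 5, d[1] - 5)
        vm[round(r0) + (-1:1), , ] <- 1 # straight vessel tube along cols
      }
      gauss_blur3(vm, c(1, 0.5, 0.5)) > 0.2
    })
  }
  frames <- lapply(seq_len(n_frames), function(t) {
    vol <- background
    for (s in seq_len(ns))
      vol[masks[[s]]] <- vol[masks[[s]]] + traces[[s]]$values[t]
    vol[vessel_mask] <- 0
    lf_volume(vol, spec$voxel_size)
  })
  list(frames = frames, somas = somas, traces = traces,
       roi_labels = roi_labels)
}

#' Analytic flow field factory
#'
#' Velocities in micrometers per second on `(row, col, z)` voxel coordinates.
#' `uniform`: constant `u`; `shear`: lid-driven-cavity-like profile
#' `v_col = rate * (z - z0)`; `vortex`: solid-body rotation at `omega` rad/s
#' about a column-axis line through the domain center (flow in the row-z
#' plane, the axial-resolution stress case).
#' @keywords internal
flow_velocity <- function(flow, pts_um, center_um) {
  kind <- flow$kind
  v <- matrix(0, nrow(pts_um), 3)
  if (kind == "uniform") {
    v[, 1] <- flow$u[1]; v[, 2] <- flow$u[2]; v[, 3] <- flow$u[3]
  } else if (kind == "shear") {
    v[, 2] <- flow$rate * (pts_um[, 3] - center_um[3])
  } else if (kind == "vortex") {
    dr <- pts_um[, 1] - center_um[1]
    dz <- pts_um[, 3] - center_um[3]
    v[, 1] <- -flow$omega * dz
    v[, 3] <- flow$omega * dr
  } else {
    stop("unknown flow descriptor: ", kind)
  }
  v
}

advect_positions <- function(flow, pts_um, center_um, dt) {
  if (flow$kind == "vortex") { # exact rotation, not an Euler step
    th <- flow$omega * dt
    dr <- pts_um[, 1] - center_um[1]
    dz <- pts_um[, 3] - center_um[3]
    out <- pts_um
    out[, 1] <- center_um[1] + cos(th) * dr - sin(th) * dz
    out[, 3] <- center_um[3] + sin(th) * dr + cos(th) * dz
    out
  } else {
    pts_um + flow_velocity(flow, pts_um, center_um) * dt
  }
}

#' Seeded particle field pair under an analytic flow
#'
#' Frame-1 particle count is Poisson with mean `density * lenslet count`
#' (particles-per-microlens seeding); frame-2 positions are the frame-1
#' positions advected by the analytic flow over one frame interval. Both
#' frames are rasterized as Gaussian beads; the instantaneous flow sampled at
#' voxel centers is returned as ground truth.
#'
#' Spec parameters: `density_ppm` (default 0.03), `pixels_per_lenslet`
#' (default 4), `flow` list with `kind` in `uniform|shear|vortex` and its
#' parameters (`u` um/s, `rate` 1/s, `omega` rad/s), `frame_time` seconds
#' (default 0.025), `particle_diameter_um` (default 2 voxels worth).
#' @param spec a [phantom_spec()].
#' @return list with `frame1`, `frame2` ([lf_volume()]), `particles1`,
#'   `particles2` (data.frames), and `flow_field` (see [flow_field()]).
#' @export
make_particle_pair <- function(spec) {
  d <- spec$shape
  dens <- spec_par(spec, "density_ppm", 0.03)
  n <- spec_par(spec, "pixels_per_lenslet", 4L)
  flow <- spec_par(spec, "flow", list(kind = "uniform", u = c(0, 0, 0)))
  dt <- spec_par(spec, "frame_time", 0.025)
  diam <- spec_par(spec, "particle_diameter_um",
                   2 * min(spec$voxel_size[1:2]))
  stopifnot(dens >= 0)
  if (!flow$kind %in% c("uniform", "shear", "vortex"))
    stop("unknown flow descriptor: ", flow$kind)
  n_lenslets <- (d[1] %/% n) * (d[2] %/% n)
  vs <- spec$voxel_size
  extent_um <- (d - 1) * vs
  center_um <- extent_um / 2
  pts <- with_seed(spec$seed, {
    cnt <- stats::rpois(1, dens * n_lenslets)
    cbind(stats::runif(cnt, 0.05, 0.95) * extent_um[1],
          stats::runif(cnt, 0.05, 0.95) * extent_um[2],
          stats::runif(cnt, 0.05, 0.95) * extent_um[3])
  })
  pts2 <- if (nrow(pts)) advect_positions(flow, pts, center_um, dt) else pts
  sig_vox <- pmax(fwhm_to_sigma(diam) / vs, 0.7)
  raster <- function(p) {
    vol <- array(0, d)
    if (nrow(p)) for (b in seq_len(nrow(p)))
      vol <- splat_gaussian(vol, p[b, ] / vs + 1, sig_vox)
    if (max(vol) > 0) vol <- vol / max(vol)
    lf_volume(vol, vs)
  }
  as_df <- function(p) data.frame(y_um = p[, 1], x_um = p[, 2], z_um = p[, 3],
                                  row = p[, 1] / vs[1] + 1,
                                  col = p[, 2] / vs[2] + 1,
                                  z = p[, 3] / vs[3] + 1)
  # ground-truth instantaneous velocity on the voxel grid, in um/s
  grid <- cbind(as.vector(slice.index(array(0, d), 1) - 1) * vs[1],
                as.vector(slice.index(array(0, d), 2) - 1) * vs[2],
                as.vector(slice.index(array(0, d), 3) - 1) * vs[3])
  vel <- flow_velocity(flow, grid, center_um)
  vecs <- array(0, c(d, 3))
  for (k in 1:3) vecs[, , , k] <- array(vel[, k], d)
  list(frame1 = raster(pts), frame2 = raster(pts2),
       particles1 = as_df(pts), particles2 = as_df(pts2),
       flow_field = flow_field(vecs, frame_time = dt, voxel_size = vs,
                               units = "um/s"))
}
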