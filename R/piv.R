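# Particle-velocimetry analysis: 3D particle localization, position-error
# scoring against ground truth, variational 3D optical flow and velocity
# error statistics.

#' Flow field container
#' @param vectors `(H, W, D, 3)` array of velocity components
#'   `(v_row, v_col, v_z)`.
#' @param frame_time seconds between the two frames.
#' @param voxel_size micrometers per voxel.
#' @param units unit label of the stored components (`"um/s"` or
#'   `"vox/frame"`).
#' @export
flow_field <- function(vectors, frame_time = 1, voxel_size = c(1, 1, 1),
                       units = "vox/frame") {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  structure(list(vectors = vectors, frame_time = frame_time,
                 voxel_size = voxel_size, units = units),
            class = "flow_field")
}

#' Convert a flow field between voxels/frame and um/s
#' @param ff a [flow_field()].
#' @param units target units.
#' @export
flow_convert <- function(ff, units = c("um/s", "vox/frame")) {
  units <- match.arg(units)
  if (identical(ff$units, units)) return(ff)
  v <- ff$vectors
  for (k in 1:3) {
    f <- ff$voxel_size[k] / ff$frame_time
    v[, , , k] <- if (units == "um/s") v[, , , k] * f else v[, , , k] / f
  }
  flow_field(v, ff$frame_time, ff$voxel_size, units)
}

#' Localize particles in a reconstructed volume
#'
#' Finds local intensity maxima above a relative threshold, suppresses
#' neighbors within `min_distance`, and refines each detection to the
#' intensity-weighted centroid of its local window.
#'
#' @param volume an [lf_volume()] or `(H, W, D)` array.
#' @param threshold detection level as a fraction of the volume maximum.
#' @param min_distance minimum separation between detections, voxels.
#' @param window centroid-refinement half-width, voxels.
#' @return data.frame with voxel coordinates (`row`, `col`, `z`) and
#'   micrometer coordinates (`y_um`, `x_um`, `z_um`); empty for an empty
#'   volume.
#' @export
localize_particles <- function(volume, threshold = 0.3, min_distance = 3,
                               window = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  v <- as_volume_array(volume)
  vs <- if (inherits(volume, "lf_volume")) volume$voxel_size else c(1, 1, 1)
  d <- dim(v)
  empty <- data.frame(row = numeric(0), col = numeric(0), z = numeric(0),
                      y_um = numeric(0), x_um = numeric(0), z_um = numeric(0))
  if (max(v) <= 0) return(empty)
  if (is.null(window)) window <- ceiling(min_distance)
  lev <- threshold * max(v)
  cand <- which(v >= lev)
  if (!length(cand)) return(empty)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  coords <- arrayInd(cand, d)
  kept <- matrix(numeric(0), 0, 3)
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    if (nrow(kept)) {
      if (any(sqrt(colSums((t(kept) - p)^2)) < min_distance)) next
    }
    # local-maximum check in a 3^3 neighborhood
    rr <- max(1, p[1] - 1):min(d[1], p[1] + 1)
    cc <- max(1, p[2] - 1):min(d[2], p[2] + 1)
    zz <- max(1, p[3] - 1):min(d[3], p[3] + 1)
    if (v[p[1], p[2], p[3]] < max(v[rr, cc, zz])) next
    kept <- rbind(kept, p)
  }
  if (!nrow(kept)) return(empty)
  # centroid refinement
  ref <- t(apply(kept, 1, function(p) {
    rr <- max(1, p[1] - window):min(d[1], p[1] + window)
    cc <- max(1, p[2] - window):min(d[2], p[2] + window)
    zz <- max(1, p[3] - window):min(d[3], p[3] + window)
    w <- v[rr, cc, zz, drop = FALSE]
    w <- pmax(w - lev * 0.5, 0) # background-suppressed weights
    s <- sum(w)
    if (s == 0) return(p)
    c(sum(slice.index(w, 1) * w) / s + rr[1] - 1,
      sum(slice.index(w, 2) * w) / s + cc[1] - 1,
      sum(slice.index(w, 3) * w) / s + zz[1] - 1)
  }))
  data.frame(row = ref[, 1], col = ref[, 2], z = ref[, 3],
             y_um = (ref[, 1] - 1) * vs[1],
             x_um = (ref[, 2] - 1) * vs[2],
             z_um = (ref[, 3] - 1) * vs[3])
}

#' Particle position error against ground truth
#'
#' Greedy nearest-neighbor one-to-one matching (closest pairs first) with an
#' optional gate; reports the Euclidean distance per matched pair and the
#' number of unmatched particles on either side.
#'
#' @param detected,ideal data.frames with coordinate columns (micrometer
#'   columns `y_um`, `x_um`, `z_um` used when present, else `row/col/z`).
#' @param max_distance matching gate in the coordinate units (default Inf).
#' @return list with `errors` (per matched pair), `mean`, `n_matched`,
#'   `n_unmatched_detected`, `n_unmatched_ideal`.
#' @export
position_error <- function(detected, ideal, max_distance = Inf) {
  get_xyz <- function(df) {
    if (all(c("y_um", "x_um", "z_um") %in% names(df)))
      as.matrix(df[, c("y_um", "x_um", "z_um")])
    else as.matrix(df[, c("row", "col", "z")])
  }
  a <- get_xyz(detected)
  b <- get_xyz(ideal)
  if (!nrow(a) || !nrow(b))
    return(list(errors = numeric(0), mean = NA_real_, n_matched = 0L,
                n_unmatched_detected = nrow(a), n_unmatched_ideal = nrow(b)))
  dd <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  dd <- sqrt(pmax(dd, 0))
  errs <- numeric(0)
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  repeat {
    m <- which.min(dd)
    if (!length(m) || !is.finite(dd[m]) || dd[m] > max_distance) break
    ia <- (m - 1) %% nrow(a) + 1
    ib <- (m - 1) %/% nrow(a) + 1
    errs <- c(errs, dd[m])
    used_a[ia] <- TRUE
    used_b[ib] <- TRUE
    dd[ia, ] <- Inf
    dd[, ib] <- Inf
    if (all(used_a) || all(used_b)) break
  }
  list(errors = errs, mean = if (length(errs)) mean(errs) else NA_real_,
       n_matched = length(errs),
       n_unmatched_detected = sum(!used_a),
       n_unmatched_ideal = sum(!used_b))
}

# circular/replicated shift helpers ------------------------------------------

shift3 <- function(x, s) {
  # replicate-padded integer shift of a 3D array by s = (dr, dc, dz)
  d <- dim(x)
  idx <- lapply(1:3, function(ax) pmin(pmax(seq_len(d[ax]) - s[ax], 1), d[ax]))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

grad3 <- function(x) {
  list(gr = (shift3(x, c(-1, 0, 0)) - shift3(x, c(1, 0, 0))) / 2,
       gc = (shift3(x, c(0, -1, 0)) - shift3(x, c(0, 1, 0))) / 2,
       gz = (shift3(x, c(0, 0, -1)) - shift3(x, c(0, 0, 1))) / 2)
}

neighbor_mean3 <- function(x) {
  (shift3(x, c(1, 0, 0)) + shift3(x, c(-1, 0, 0)) +
     shift3(x, c(0, 1, 0)) + shift3(x, c(0, -1, 0)) +
     shift3(x, c(0, 0, 1)) + shift3(x, c(0, 0, -1))) / 6
}

trilinear_warp <- function(x, u, v, w) {
  d <- dim(x)
  gr <- slice.index(x, 1) + u
  gc <- slice.index(x, 2) + v
  gz <- slice.index(x, 3) + w
  gr <- pmin(pmax(gr, 1), d[1])
  gc <- pmin(pmax(gc, 1), d[2])
  gz <- pmin(pmax(gz, 1), d[3])
  r0 <- pmin(floor(gr), d[1] - 1L); c0 <- pmin(floor(gc), d[2] - 1L)
  z0 <- pmin(floor(gz), d[3] - 1L)
  if (d[1] == 1L) r0[] <- 1L
  if (d[2] == 1L) c0[] <- 1L
  if (d[3] == 1L) z0[] <- 1L
  fr <- gr - r0; fc <- gc - c0; fz <- gz - z0
  at <- function(r, c, z) x[cbind(as.vector(r), as.vector(c), as.vector(z))]
  r1 <- pmin(r0 + 1L, d[1]); c1 <- pmin(c0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  out <- (1 - fr) * (1 - fc) * (1 - fz) * array(at(r0, c0, z0), d) +
    fr * (1 - fc) * (1 - fz) * array(at(r1, c0, z0), d) +
    (1 - fr) * fc * (1 - fz) * array(at(r0, c1, z0), d) +
    (1 - fr) * (1 - fc) * fz * array(at(r0, c0, z1), d) +
    fr * fc * (1 - fz) * array(at(r1, c1, z0), d) +
    fr * (1 - fc) * fz * array(at(r1, c0, z1), d) +
    (1 - fr) * fc * fz * array(at(r0, c1, z1), d) +
    fr * fc * fz * array(at(r1, c1, z1), d)
  out
}

downsample2_3d <- function(x) {
  d <- dim(x)
  dn <- pmax(d %/% 2L, 1L)
  x <- gauss_blur3(x, c(1, 1, 1) * 0.8)
  x[pmin(seq_len(dn[1]) * 2L - 1L, d[1]),
    pmin(seq_len(dn[2]) * 2L - 1L, d[2]),
    pmin(seq_len(dn[3]) * 2L - 1L, d[3]), drop = FALSE]
}

#' Variational 3D optical flow (Horn-Schunck with coarse-to-fine warping)
#'
#' Minimizes the linearized brightness-constancy data term plus a quadratic
#' smoothness penalty, by Jacobi fixed-point iteration, on a Gaussian
#' pyramid with warping between levels.
#'
#' @param vol1,vol2 same-shape volumes (arrays or [lf_volume()]).
#' @param lambda smoothness weight (default 0.1); larger = smoother flow.
#' @param n_iterations fixed-point iterations per pyramid level.
#' @param pyramid_levels number of dyadic pyramid levels.
#' @param presmooth Gaussian pre-smoothing sigma in voxels.
#' @return a [flow_field()] in voxels/frame.
#' @export
optical_flow_3d <- function(vol1, vol2, lambda = 0.1, n_iterations = 80L,
                            pyramid_levels = 2L, presmooth = 1) {
  a <- as_volume_array(vol1)
  b <- as_volume_array(vol2)
  if (!identical(dim(a), dim(b))) stop("optical_flow_3d: shape mismatch")
  vs <- if (inherits(vol1, "lf_volume")) vol1$voxel_size else c(1, 1, 1)
  if (presmooth > 0) {
    a <- gauss_blur3(a, rep(presmooth, 3))
    b <- gauss_blur3(b, rep(presmooth, 3))
  }
  if (max(abs(a - b)) == 0) {
    vecs <- array(0, c(dim(a), 3))
    return(flow_field(vecs, voxel_size = vs))
  }
  pyr_a <- list(a); pyr_b <- list(b)
  for (l in seq_len(pyramid_levels - 1L)) {
    if (min(dim(pyr_a[[l]])[1:2]) < 12L) break
    pyr_a[[l + 1L]] <- downsample2_3d(pyr_a[[l]])
    pyr_b[[l + 1L]] <- downsample2_3d(pyr_b[[l]])
  }
  nl <- length(pyr_a)
  u <- v <- w <- array(0, dim(pyr_a[[nl]]))
  for (l in rev(seq_len(nl))) {
    al <- pyr_a[[l]]; bl <- pyr_b[[l]]
    if (!identical(dim(u), dim(al))) {
      # upsample flow to this level (components scale with the grid)
      u <- resize3(u, dim(al)) * dim(al)[1] / dim(pyr_a[[l + 1L]])[1]
      v <- resize3(v, dim(al)) * dim(al)[2] / dim(pyr_a[[l + 1L]])[2]
      w <- resize3(w, dim(al)) * dim(al)[3] / dim(pyr_a[[l + 1L]])[3]
    }
    for (warp in 1:2) { # incremental estimation with re-warping
      bw <- trilinear_warp(bl, u, v, w)
      g <- grad3((al + bw) / 2)
      it_img <- bw - al
      denom <- lambda + g$gr^2 + g$gc^2 + g$gz^2
      du <- dv <- dw <- array(0, dim(al))
      for (it in seq_len(n_iterations)) {
        ubar <- neighbor_mean3(du); vbar <- neighbor_mean3(dv)
        wbar <- neighbor_mean3(dw)
        # classic Horn-Schunck fixed-point update on the increment
        cmn <- (g$gr * ubar + g$gc * vbar + g$gz * wbar + it_img) / denom
        du <- ubar - g$gr * cmn
        dv <- vbar - g$gc * cmn
        dw <- wbar - g$gz * cmn
      }
      u <- u + du; v <- v + dv; w <- w + dw
    }
  }
  vecs <- array(0, c(dim(a), 3))
  vecs[, , , 1] <- u; vecs[, , , 2] <- v; vecs[, , , 3] <- w
  flow_field(vecs, voxel_size = vs)
}

resize3 <- function(x, dnew) {
  d <- dim(x)
  arr <- array(0, dnew)
  gr <- (slice.index(arr, 1) - 0.5) * d[1] / dnew[1] + 0.5
  gc <- (slice.index(arr, 2) - 0.5) * d[2] / dnew[2] + 0.5
  gz <- (slice.index(arr, 3) - 0.5) * d[3] / dnew[3] + 0.5
  src <- function(g, ax) pmin(pmax(g, 1), d[ax])
  r <- src(gr, 1); c <- src(gc, 2); z <- src(gz, 3)
  r0 <- pmin(floor(r), max(d[1] - 1L, 1L)); c0 <- pmin(floor(c), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L))
  fr <- r - r0; fc <- c - c0; fz <- z - z0
  r1 <- pmin(r0 + 1L, d[1]); c1 <- pmin(c0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(rr, cc, zz) array(x[cbind(as.vector(rr), as.vector(cc),
                                           as.vector(zz))], dnew)
  (1 - fr) * (1 - fc) * (1 - fz) * at(r0, c0, z0) +
    fr * (1 - fc) * (1 - fz) * at(r1, c0, z0) +
    (1 - fr) * fc * (1 - fz) * at(r0, c1, z0) +
    (1 - fr) * (1 - fc) * fz * at(r0, c0, z1) +
    fr * fc * (1 - fz) * at(r1, c1, z0) +
    fr * (1 - fc) * fz * at(r1, c0, z1) +
    (1 - fr) * fc * fz * at(r0, c1, z1) +
    fr * fc * fz * at(r1, c1, z1)
}

#' Velocity error statistics
#'
#' Per-voxel magnitude of the vector difference between an estimated and a
#' ground-truth flow over a mask, with mean and standard error.
#' @param est,truth same-shape [flow_field()]s (auto-converted to matching
#'   units).
#' @param mask logical array selecting scored voxels (default all).
#' @return list with `errors` (vector over masked voxels), `mean`, `stderr`,
#'   `n`, `units`.
#' @export
velocity_error <- function(est, truth, mask = NULL) {
  if (!identical(dim(est$vectors), dim(truth$vectors)))
    stop("velocity_error: shape mismatch")
  tr <- flow_convert(truth, if (est$units == "um/s") "um/s" else "vox/frame")
  diff2 <- (est$vectors[, , , 1] - tr$vectors[, , , 1])^2 +
    (est$vectors[, , , 2] - tr$vectors[, , , 2])^2 +
    (est$vectors[, , , 3] - tr$vectors[, , , 3])^2
  if (is.null(mask)) mask <- array(TRUE, dim(diff2))
  if (!any(mask)) stop("velocity_error: empty mask")
  errs <- sqrt(diff2[mask])
  list(errors = errs, mean = mean(errs),
       stderr = stats::sd(errs) / sqrt(length(errs)), n = length(errs),
       units = est$units)
}

#' Solid-body rotation fit to a flow field
#'
#' Weighted least-squares angular speed (rad per flow time unit) of rotation
#' in the row-z plane about the domain center; used to score vortex
#' recovery.
#' @param ff a [flow_field()] in voxels/frame.
#' @param weights non-negative weight array (e.g. particle intensity);
#'   default uniform.
#' @export
fit_rotation_rowz <- function(ff, weights = NULL) {
  d <- dim(ff$vectors)[1:3]
  ctr <- (d + 1) / 2
  dr <- slice.index(array(0, d), 1) - ctr[1]
  dz <- slice.index(array(0, d), 3) - ctr[3]
  vr <- ff$vectors[, , , 1]
  vz <- ff$vectors[, , , 3]
  if (is.null(weights)) weights <- array(1, d)
  # v = omega x r in the row-z plane: vr = -omega dz, vz = omega dr
  num <- sum(weights * (vz * dr - vr * dz))
  den <- sum(weights * (dr^2 + dz^2))
  num / max(den, 1e-12)
}
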