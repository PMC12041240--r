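# Non-learning reconstruction baselines: synthetic-aperture (shift-and-add)
# refocusing and Richardson-Lucy light-field deconvolution built on the
# forward projector and its adjoint.

#' Classical reconstruction parameters
#' @param depths refocus planes in micrometers (refocusing) — defaults to the
#'   configured z planes when omitted.
#' @param n_iterations Richardson-Lucy iteration cap (default 30).
#' @param stop_tolerance relative-change early-stop threshold (default 1e-6).
#' @param upscale return refocused planes upsampled from view resolution to
#'   sensor resolution (default TRUE).
#' @export
recon_params <- function(depths = NULL, n_iterations = 30L,
                         stop_tolerance = 1e-6, upscale = TRUE) {
  if (!is.null(depths) && !length(depths)) stop("depths must be non-empty")
  stopifnot(n_iterations >= 1)
  structure(list(depths = depths, n_iterations = as.integer(n_iterations),
                 stop_tolerance = stop_tolerance, upscale = isTRUE(upscale)),
            class = "recon_params")
}

# Shift a matrix by a continuous (dy, dx) offset with bilinear interpolation
# and edge clamping.
shift_bilinear <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(seq_len(h) - dy, 1), h)
  xs <- pmin(pmax(seq_len(w) - dx, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  if (h == 1L) y0 <- rep(1L, h)
  if (w == 1L) x0 <- rep(1L, w)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' Synthetic-aperture refocusing
#'
#' For every requested depth, shifts each sub-aperture view against its
#' depth-dependent disparity (the geometry's [disparity_slope()] times the
#' view's offset from the central view) and averages; at the native focal
#' plane all shifts vanish and the result is the plain view mean. The stack
#' is ordered like `params$depths` and, by default, upsampled to sensor
#' resolution.
#'
#' @param lf an [lf_image()].
#' @param cfg the [optical_config()] of the acquisition.
#' @param params a [recon_params()]; `depths` defaults to `cfg$z_planes`.
#' @return an [lf_volume()] of refocused planes.
#' @export
refocus <- function(lf, cfg, params = recon_params()) {
  stopifnot(inherits(lf, "lf_image"))
  depths <- if (is.null(params$depths)) cfg$z_planes else params$depths
  if (!length(depths)) stop("no refocus depths requested")
  n <- cfg$pixels_per_lenslet
  views <- decompose_views(lf)
  vh <- dim(views$data)[2]
  vw <- dim(views$data)[3]
  c0 <- (n - 1) / 2
  slope <- disparity_slope(cfg) # sensor px / um / view unit
  wap <- view_aperture(n)
  planes <- array(0, c(vh, vw, length(depths)))
  for (di in seq_along(depths)) {
    z <- depths[di]
    acc <- matrix(0, vh, vw)
    wsum <- 0
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      wv <- wap[i + 1, j + 1]
      if (wv == 0) next
      # view-space displacement of a depth-z feature, in view pixels
      dy <- slope * z * (i - c0) / n
      dx <- slope * z * (j - c0) / n
      acc <- acc + wv * shift_bilinear(views$data[i * n + j + 1, , ], -dy, -dx)
      wsum <- wsum + wv
    }
    planes[, , di] <- acc / wsum
  }
  if (params$upscale && n > 1L) {
    t4 <- planes
    dim(t4) <- c(vh, vw, 1L, length(depths))
    t4 <- ag_resize_bicubic(t4, vh * n, vw * n)
    dim(t4) <- c(vh * n, vw * n, length(depths))
    planes <- t4
  }
  lf_volume(planes)
}

#' Richardson-Lucy light-field deconvolution
#'
#' Multiplicative updates `V <- V * Pt(lf / P(V))` with `P` the forward
#' projector and `Pt` its exact adjoint, from a uniform positive start.
#' Non-negativity is preserved at every iteration; the update stops after
#' `n_iterations` or when the relative volume change falls below
#' `stop_tolerance`.
#'
#' @param lf an [lf_image()] whose geometry matches `psf`.
#' @param psf a [build_psf()] bank.
#' @param params a [recon_params()].
#' @param trace_divergence also return the per-iteration Kullback-Leibler
#'   data-fit divergence between `lf` and `P(V_k)`.
#' @return an [lf_volume()]; with `trace_divergence`, a list with `volume`
#'   and `divergence`.
#' @export
lfd_deconvolve <- function(lf, psf, params = recon_params(),
                           trace_divergence = FALSE) {
  stopifnot(inherits(lf, "lf_image"))
  n <- psf$config$pixels_per_lenslet
  if (lf$pixels_per_lenslet != n)
    stop("light-field N (", lf$pixels_per_lenslet, ") does not match PSF N (",
         n, ")")
  eps <- 1e-12
  l <- pmax(lf$data, 0)
  d_n <- dim(psf$kernels)[1]
  v <- array(mean(l) + eps, c(nrow(l), ncol(l), d_n))
  # flat-field normalization of the adjoint (Pt of ones)
  norm <- as_volume_array(lf_backproject(matrix(1, nrow(l), ncol(l)), psf))
  norm <- pmax(norm, eps)
  div <- numeric(0)
  for (it in seq_len(params$n_iterations)) {
    fwd <- pmax(lf_project(v, psf)$data, 0)
    if (trace_divergence) {
      m <- fwd > eps & l > eps
      div <- c(div, sum(l[m] * log(l[m] / fwd[m])) - sum(l) + sum(fwd))
    }
    ratio <- l / pmax(fwd, eps)
    upd <- as_volume_array(lf_backproject(ratio, psf)) / norm
    v_new <- v * pmax(upd, 0)
    rel <- sum(abs(v_new - v)) / max(sum(abs(v)), eps)
    v <- v_new
    if (rel < params$stop_tolerance) break
  }
  out <- lf_volume(v)
  if (trace_divergence) list(volume = out, divergence = div) else out
}
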