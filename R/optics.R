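# Light-field optics: acquisition geometry, PSF banks, forward projection
# and sub-aperture view decomposition.
#
# Conventions (fixed so that roundtrips are exact):
#  * depth index 1 corresponds to z_planes[1]; z in micrometers, sample-referred
#  * a lenslet covers N x N sensor pixels; the (i, j) "phase" of a pixel is its
#    0-based (row, col) position inside its lenslet
#  * views are ordered row-major over (i, j): view index v = i * N + j + 1
#  * volumes are (H, W, D) arrays, slice k at z_planes[k]; light fields are
#    (H, W) matrices at sensor resolution, sample-referred

#' Optical configuration of a light-field acquisition
#'
#' Describes the geometry and the point-spread-function model used to map a
#' 3D sample volume onto a 2D light-field sensor image.
#'
#' @param magnification objective magnification (dimensionless; metadata).
#' @param numerical_aperture objective NA; must be < `medium_index`.
#' @param wavelength emission wavelength in nm.
#' @param medium_index refractive index of the immersion/sample medium.
#' @param lenslet_pitch microlens pitch in micrometers, sample-referred.
#' @param pixels_per_lenslet integer N: sensor pixels per lenslet per axis.
#' @param sensor_pixel sensor pixel size in micrometers, sample-referred.
#'   Defaults to `lenslet_pitch / pixels_per_lenslet`.
#' @param z_planes strictly increasing depths (micrometers) of volume slices.
#' @param psf_model `"gaussian_defocus"` (fast parametric surrogate with
#'   parallax) or `"wave_optics"` (scalar-diffraction Fresnel model).
#' @param kernel_halfwidth PSF support half-width in lenslet pitches.
#' @param psf_sigma_px in-focus per-view Gaussian width (sensor pixels) for
#'   the surrogate model.
#' @param psf_oversample sub-pixel sampling factor for the wave-optics model.
#' @return an object of class `optical_config`.
#' @export
optical_config <- function(magnification = 40,
                           numerical_aperture = 0.95,
                           wavelength = 525,
                           medium_index = 1.33,
                           lenslet_pitch = NULL,
                           pixels_per_lenslet = 4L,
                           sensor_pixel = 1,
                           z_planes = seq(-8, 8, by = 4),
                           psf_model = c("gaussian_defocus", "wave_optics"),
                           kernel_halfwidth = 2L,
                           psf_sigma_px = 0.7,
                           psf_oversample = 4L) {
  psf_model <- match.arg(psf_model)
  n <- as.integer(pixels_per_lenslet)
  if (is.null(lenslet_pitch)) lenslet_pitch <- sensor_pixel * n
  cfg <- structure(list(
    magnification = magnification,
    numerical_aperture = numerical_aperture,
    wavelength = wavelength,
    medium_index = medium_index,
    lenslet_pitch = lenslet_pitch,
    pixels_per_lenslet = n,
    sensor_pixel = sensor_pixel,
    z_planes = as.numeric(z_planes),
    psf_model = psf_model,
    kernel_halfwidth = as.integer(kernel_halfwidth),
    psf_sigma_px = psf_sigma_px,
    psf_oversample = as.integer(psf_oversample)
  ), class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  if (cfg$numerical_aperture >= cfg$medium_index)
    stop("invalid optics: numerical_aperture (", cfg$numerical_aperture,
         ") must be smaller than medium_index (", cfg$medium_index, ")")
  if (cfg$pixels_per_lenslet < 1L) stop("pixels_per_lenslet must be >= 1")
  if (length(cfg$z_planes) < 1L || is.unsorted(cfg$z_planes, strictly = TRUE))
    stop("z_planes must be a strictly increasing depth list")
  if (cfg$kernel_halfwidth < 0L) stop("kernel_halfwidth must be >= 0")
  invisible(cfg)
}

# Maximum marginal-ray tangent in the sample medium.
tan_theta_max <- function(cfg) {
  na <- cfg$numerical_aperture
  na / sqrt(cfg$medium_index^2 - na^2)
}

#' Depth disparity slope of the configured geometry
#'
#' Sensor-pixel displacement per micrometer of defocus per unit of view index
#' offset from the central view. This single slope links the PSF parallax
#' structure, refocusing shifts, and depth localization.
#' @param cfg an [optical_config()].
#' @return slope in sensor pixels per micrometer per view-index unit.
#' @export
disparity_slope <- function(cfg) {
  n <- cfg$pixels_per_lenslet
  if (n == 1L) return(0)
  tan_theta_max(cfg) / (((n - 1) / 2) * cfg$sensor_pixel)
}

# Aperture window over view phases: which (i, j) carry light.
view_aperture <- function(n) {
  c0 <- (n - 1) / 2
  w <- outer(0:(n - 1), 0:(n - 1), function(i, j)
    as.numeric(sqrt((i - c0)^2 + (j - c0)^2) <= n / 2))
  if (sum(w) == 0) w[] <- 1
  w
}

#' Build a light-field PSF kernel bank
#'
#' Computes the per-depth, per-source-phase sensor response of a point
#' source. Kernels are indexed `(depth, phase_i, phase_j, row, col)` with
#' spatial offsets covering `2*kernel_halfwidth + 1` lenslet pitches; each
#' `(depth, phase)` kernel is normalized to unit mass so that forward
#' projection conserves total intensity.
#'
#' @param cfg an [optical_config()].
#' @return an object of class `lightfield_psf` with elements `kernels`
#'   (5-D array) and `config`.
#' @export
build_psf <- function(cfg) {
  validate_optical_config(cfg)
  n <- cfg$pixels_per_lenslet
  khw <- cfg$kernel_halfwidth
  k_px <- (2L * khw + 1L) * n
  d_n <- length(cfg$z_planes)
  kernels <- array(0, c(d_n, n, n, k_px, k_px))
  if (cfg$psf_model == "gaussian_defocus") {
    kernels <- psf_gaussian_defocus(cfg, kernels)
  } else {
    kernels <- psf_wave_optics(cfg, kernels)
  }
  # per-(depth, phase) unit mass
  for (d in seq_len(d_n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(kernels[d, i, j, , ])
    if (s > 0) kernels[d, i, j, , ] <- kernels[d, i, j, , ] / s
  }
  psf <- structure(list(kernels = kernels, config = cfg),
                   class = "lightfield_psf")
  attr(psf, "fft_cache") <- new.env(parent = emptyenv())
  psf
}

# Parametric surrogate: each view (u, v) sees the point displaced by the
# depth-dependent disparity; its energy is partitioned over lenslet cells by
# an integrated Gaussian (so at focus all light stays under the source
# lenslet), and views are weighted by an aperture window. Parallax across
# views carries the defocus information.
psf_gaussian_defocus <- function(cfg, kernels) {
  n <- cfg$pixels_per_lenslet
  khw <- cfg$kernel_halfwidth
  k_px <- (2L * khw + 1L) * n
  c0 <- (n - 1) / 2
  slope <- disparity_slope(cfg) * cfg$sensor_pixel # px per um per view unit
  wap <- view_aperture(n)
  sig <- cfg$psf_sigma_px
  # lenslet cells of the kernel support, in sensor px relative to the source
  # lenslet origin: cell q covers [q * n, (q + 1) * n)
  cells <- (-khw):khw
  lo <- cells * n
  for (d in seq_along(cfg$z_planes)) {
    z <- cfg$z_planes[d]
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      acc <- matrix(0, k_px, k_px)
      for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
        if (wap[u + 1, v + 1] == 0) next
        cr <- i + 0.5 + slope * z * (u - c0)
        cc <- j + 0.5 + slope * z * (v - c0)
        mr <- stats::pnorm(lo + n, cr, sig) - stats::pnorm(lo, cr, sig)
        mc <- stats::pnorm(lo + n, cc, sig) - stats::pnorm(lo, cc, sig)
        m <- outer(mr, mc)
        s <- sum(m)
        if (s > 0) {
          ridx <- (seq_along(cells) - 1L) * n + u + 1L
          cidx <- (seq_along(cells) - 1L) * n + v + 1L
          acc[ridx, cidx] <- acc[ridx, cidx] + wap[u + 1, v + 1] * m / s
        }
      }
      kernels[d, i + 1, j + 1, , ] <- acc
    }
  }
  kernels
}

# Scalar-diffraction model: defocused pupil field at the native image plane,
# lenslet phase mask, Fresnel propagation to the sensor, intensity binning.
# All lengths sample-referred; wavelength in the medium.
psf_wave_optics <- function(cfg, kernels) {
  n <- cfg$pixels_per_lenslet
  khw <- cfg$kernel_halfwidth
  k_px <- (2L * khw + 1L) * n
  o <- cfg$psf_oversample
  g <- k_px * o
  dx <- cfg$sensor_pixel / o
  lam <- cfg$wavelength * 1e-3 / cfg$medium_index # um, in medium
  na_freq <- cfg$numerical_aperture / (cfg$wavelength * 1e-3) # cycles/um
  f_ml <- cfg$lenslet_pitch / (2 * tan_theta_max(cfg))
  idx <- 0:(g - 1)
  idx[idx > g / 2] <- idx[idx > g / 2] - g
  nu <- idx / (g * dx)
  nu2 <- outer(nu^2, nu^2, "+")
  pupil <- (nu2 <= na_freq^2) * 1
  kz <- sqrt(pmax(1 / lam^2 - nu2, 0))
  # centered spatial raster (after fftshift): x_m = (m - g/2) * dx,
  # source lenslet center at x = 0
  xs_grid <- (seq_len(g) - 1 - g / 2) * dx
  pitch <- cfg$lenslet_pitch
  xrel <- xs_grid - round(xs_grid / pitch) * pitch
  lens_phase <- outer(xrel^2, xrel^2, "+")
  t_ml <- exp(-1i * pi / (lam * f_ml) * lens_phase)
  prop <- exp(-1i * pi * lam * f_ml * nu2)
  for (d in seq_along(cfg$z_planes)) {
    z <- cfg$z_planes[d]
    defoc <- pupil * exp(2i * pi * z * kz)
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      # source offset from the lenslet center
      sx <- (i + 0.5 - n / 2) * cfg$sensor_pixel
      sy <- (j + 0.5 - n / 2) * cfg$sensor_pixel
      shift <- exp(-2i * pi * outer(nu * sx, nu * sy, "+"))
      u_img <- fftshift2(stats::fft(defoc * shift, inverse = TRUE))
      u_ml <- u_img * t_ml
      u_sen <- stats::fft(stats::fft(u_ml) * prop, inverse = TRUE) / length(u_ml)
      inten <- Mod(u_sen)^2
      # bin o x o sub-samples into sensor pixels
      dim(inten) <- c(o, k_px, o, k_px)
      kernels[d, i + 1, j + 1, , ] <- apply(inten, c(2, 4), sum)
    }
  }
  kernels
}

fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((h %/% 2 + 1):h, 1:(h %/% 2)), c((w %/% 2 + 1):w, 1:(w %/% 2))]
}

# ---- containers -------------------------------------------------------------

#' Construct a sample volume
#' @param data non-negative numeric array `(H, W, D)`; slice k sits at the
#'   k-th configured depth plane.
#' @param voxel_size `(dy, dx, dz)` in micrometers.
#' @return object of class `lf_volume`.
#' @export
lf_volume <- function(data, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, voxel_size = voxel_size), class = "lf_volume")
}

#' Construct a light-field image
#' @param data numeric matrix `(H, W)`; both dimensions must be divisible by
#'   `pixels_per_lenslet`.
#' @param pixels_per_lenslet integer N.
#' @export
lf_image <- function(data, pixels_per_lenslet) {
  n <- as.integer(pixels_per_lenslet)
  if (!is.matrix(data)) stop("light-field data must be a matrix")
  if (nrow(data) %% n != 0L || ncol(data) %% n != 0L)
    stop("light-field dimensions (", nrow(data), " x ", ncol(data),
         ") must be divisible by pixels_per_lenslet = ", n)
  structure(list(data = data, pixels_per_lenslet = n), class = "lf_image")
}

as_volume_array <- function(v) if (inherits(v, "lf_volume")) v$data else v

#' Project a volume to a light-field image
#'
#' Applies the linear forward model: every voxel, according to its depth and
#' its sub-lenslet phase, stamps its PSF kernel at its lenslet position.
#' Convolution is circular (periodic boundary), which makes the operator
#' exactly energy conserving and shift equivariant over one lenslet pitch.
#'
#' @param volume an [lf_volume()] (or `(H, W, D)` array) with `D` matching the
#'   PSF depth count and lateral size divisible by N.
#' @param psf a [build_psf()] bank.
#' @return an [lf_image()].
#' @export
lf_project <- function(volume, psf) {
  v <- as_volume_array(volume)
  cfg <- psf$config
  n <- cfg$pixels_per_lenslet
  dims <- dim(v)
  if (dims[3] != dim(psf$kernels)[1])
    stop("volume depth count (", dims[3], ") does not match PSF depth count (",
         dim(psf$kernels)[1], ")")
  if (dims[1] %% n != 0L || dims[2] %% n != 0L)
    stop("volume lateral size (", dims[1], " x ", dims[2],
         ") must be divisible by N = ", n)
  kf <- psf_kernel_ffts(psf, dims[1], dims[2])
  acc <- matrix(0 + 0i, dims[1], dims[2])
  for (d in seq_len(dims[3])) for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- matrix(0, dims[1], dims[2])
    ridx <- seq(i, dims[1], by = n)
    cidx <- seq(j, dims[2], by = n)
    sub <- v[ridx, cidx, d]
    if (all(sub == 0)) next
    s[ridx, cidx] <- sub
    acc <- acc + stats::fft(s) * kf[[d]][[i]][[j]]
  }
  out <- Re(stats::fft(acc, inverse = TRUE)) / (dims[1] * dims[2])
  lf_image(out, n)
}

#' Adjoint of the forward projection
#'
#' Backprojects a light-field image into the volume domain; exact adjoint of
#' [lf_project()] (used by Richardson-Lucy deconvolution).
#' @param lf an [lf_image()] or matrix.
#' @param psf a [build_psf()] bank.
#' @return an [lf_volume()].
#' @export
lf_backproject <- function(lf, psf) {
  l <- if (inherits(lf, "lf_image")) lf$data else lf
  cfg <- psf$config
  n <- cfg$pixels_per_lenslet
  d_n <- dim(psf$kernels)[1]
  kf <- psf_kernel_ffts(psf, nrow(l), ncol(l))
  lf_f <- stats::fft(l)
  out <- array(0, c(nrow(l), ncol(l), d_n))
  for (d in seq_len(d_n)) {
    plane <- matrix(0, nrow(l), ncol(l))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      corr <- Re(stats::fft(lf_f * Conj(kf[[d]][[i]][[j]]), inverse = TRUE)) /
        length(l)
      ridx <- seq(i, nrow(l), by = n)
      cidx <- seq(j, ncol(l), by = n)
      plane[ridx, cidx] <- corr[ridx, cidx]
    }
    out[, , d] <- plane
  }
  lf_volume(out) # adjoint output is signed in general
}

# FFTs of kernels embedded in an (H, W) frame with shifts expressed relative
# to the source pixel. Cached on the psf object keyed by frame size.
psf_kernel_ffts <- function(psf, h, w) {
  key <- paste0("kf_", h, "x", w)
  cache <- attr(psf, "fft_cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    # attr<- on a local copy would be lost; stash in the kernels' environment
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  cfg <- psf$config
  n <- cfg$pixels_per_lenslet
  khw <- cfg$kernel_halfwidth
  k_px <- (2L * khw + 1L) * n
  d_n <- dim(psf$kernels)[1]
  base_off <- -(khw * n) # kernel index 1 offset from the lenslet origin
  out <- vector("list", d_n)
  for (d in seq_len(d_n)) {
    out[[d]] <- vector("list", n)
    for (i in seq_len(n)) {
      out[[d]][[i]] <- vector("list", n)
      for (j in seq_len(n)) {
        img <- matrix(0, h, w)
        # shift relative to the source pixel = offset - phase
        rpos <- ((base_off + seq_len(k_px) - 1L - (i - 1L)) %% h) + 1L
        cpos <- ((base_off + seq_len(k_px) - 1L - (j - 1L)) %% w) + 1L
        if (k_px <= h && k_px <= w) {
          img[rpos, cpos] <- img[rpos, cpos] + psf$kernels[d, i, j, , ]
        } else { # kernel support wraps onto itself: accumulate entry-wise
          for (a in seq_len(k_px)) for (b in seq_len(k_px))
            img[rpos[a], cpos[b]] <- img[rpos[a], cpos[b]] +
              psf$kernels[d, i, j, a, b]
        }
        out[[d]][[i]][[j]] <- stats::fft(img)
      }
    }
  }
  cache[[key]] <- out
  out
}

# ---- view decomposition -----------------------------------------------------

#' Decompose a light field into sub-aperture views
#'
#' View `(i, j)` (0-based, row-major order) collects pixel phase `(i, j)` of
#' every lenslet, preserving lenslet raster order. Exact inverse:
#' [recompose_views()].
#' @param lf an [lf_image()].
#' @return object of class `lf_views`: `data` is `(N^2, H/N, W/N)`.
#' @export
decompose_views <- function(lf) {
  stopifnot(inherits(lf, "lf_image"))
  n <- lf$pixels_per_lenslet
  h <- nrow(lf$data) %/% n
  w <- ncol(lf$data) %/% n
  x <- lf$data
  dim(x) <- c(n, h, n, w)
  x <- aperm(x, c(1, 3, 2, 4)) # (i, j, h, w)
  dim(x) <- c(n * n, h, w)
  # reorder so view index v = i * N + j (row-major over (i, j))
  ord <- as.vector(t(matrix(seq_len(n * n), n, n)))
  structure(list(data = x[ord, , , drop = FALSE], pixels_per_lenslet = n),
            class = "lf_views")
}

#' Recompose sub-aperture views into a light field
#' @param views an `lf_views` object from [decompose_views()].
#' @return an [lf_image()]; bit-exact inverse of the decomposition.
#' @export
recompose_views <- function(views) {
  stopifnot(inherits(views, "lf_views"))
  n <- views$pixels_per_lenslet
  d <- dim(views$data)
  if (d[1] != n * n)
    stop("view count (", d[1], ") inconsistent with N^2 = ", n * n)
  ord <- as.vector(t(matrix(seq_len(n * n), n, n)))
  x <- views$data[order(ord), , , drop = FALSE] # undo row-major reorder
  dim(x) <- c(n, n, d[2], d[3])
  x <- aperm(x, c(1, 3, 2, 4))
  dim(x) <- c(n * d[2], n * d[3])
  lf_image(x, n)
}

# Views as an (h, w, N^2, B=1) tensor for the network.
views_to_tensor <- function(views) {
  d <- dim(views$data)
  x <- aperm(views$data, c(2, 3, 1))
  dim(x) <- c(d[2], d[3], d[1], 1L)
  x
}
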