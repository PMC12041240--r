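# Quantitative evaluation: image-fidelity metrics, resolution estimators and
# calcium-trace extraction.

#' Metric configuration
#'
#' @param max_i dynamic-range parameter MAX_I / R of the compared data
#'   (255 for 8-bit data, 1 for unit-normalized floats). `NULL` infers 1 when
#'   the inputs fit in [0, 1] (or [-1, 1]) and 255 otherwise.
#' @param ssim_mode `"global"` evaluates one set of image-wide statistics
#'   (the printed closed form); `"windowed"` averages a sliding
#'   Gaussian-window SSIM map.
#' @param lpips perceptual-distance settings from [lpips_config()].
#' @param psnr_cap sentinel PSNR (dB) reported for identical images.
#' @export
metric_config <- function(max_i = NULL, ssim_mode = c("global", "windowed"),
                          lpips = lpips_config(), psnr_cap = 99) {
  structure(list(max_i = max_i, ssim_mode = match.arg(ssim_mode),
                 lpips = lpips, psnr_cap = psnr_cap),
            class = "metric_config")
}

#' Perceptual feature-distance configuration
#'
#' A small convolutional feature stack compares images in feature space, per
#' layer: unit-normalize channels at every pixel, take the layer-weighted
#' squared difference, average over positions, and sum over layers. The
#' default backbone is a seeded random stack, which is deterministic and
#' self-contained; its absolute values are not comparable across backbones.
#'
#' @param backbone `"fixed_random"` (seeded random convolutions) or a
#'   user-supplied function `(image) -> list of feature tensors`.
#' @param channels channel widths of the random stack.
#' @param layer_weights per-layer weights `w_l` (recycled).
#' @param seed RNG seed for the random backbone.
#' @export
lpips_config <- function(backbone = "fixed_random", channels = c(8, 16, 16),
                         layer_weights = 1, seed = 7L) {
  structure(list(backbone = backbone, channels = channels,
                 layer_weights = layer_weights, seed = as.integer(seed)),
            class = "lpips_config")
}

infer_max_i <- function(x, y) {
  hi <- max(abs(range(x)), abs(range(y)))
  if (hi <= 1 + 1e-9) 1 else 255
}

#' Image-fidelity metric suite
#'
#' Computes PSNR, SSIM, MS-SSIM, perceptual feature distance (LPIPS-style),
#' MSE and the Pearson correlation between a reconstruction and its ground
#' truth. PSNR of identical inputs is reported as the configured cap with
#' `psnr_capped = TRUE` rather than infinity.
#'
#' @param x ground truth (matrix or 3-D array).
#' @param y reconstruction, same shape.
#' @param cfg a [metric_config()].
#' @return object of class `metric_report`: a list with `psnr`, `ssim`,
#'   `msssim`, `lpips`, `mse`, `pearson`, `psnr_capped`, `max_i`.
#' @export
compute_metrics <- function(x, y, cfg = metric_config()) {
  x <- nval(x); y <- nval(y)
  if (!identical(dim(x), dim(y)))
    stop("compute_metrics: shape mismatch (",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(y), collapse = "x"), ")")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("compute_metrics: inputs must be finite")
  max_i <- if (is.null(cfg$max_i)) infer_max_i(x, y) else cfg$max_i
  mse <- mean((y - x)^2)
  capped <- mse == 0
  psnr <- if (capped) cfg$psnr_cap else
    min(10 * log10(max_i^2 / mse), cfg$psnr_cap)
  if (stats::sd(as.vector(x)) == 0 || stats::sd(as.vector(y)) == 0)
    stop("pearson correlation undefined for constant input")
  rep <- structure(list(
    psnr = psnr,
    ssim = ssim_global(x, y, max_i, mode = cfg$ssim_mode),
    msssim = msssim_auto(x, y, max_i),
    lpips = lpips_distance(x, y, cfg$lpips),
    mse = mse,
    pearson = stats::cor(as.vector(x), as.vector(y)),
    psnr_capped = capped,
    max_i = max_i
  ), class = "metric_report")
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "psnr: %.4f dB%s | ssim: %.4f | ms-ssim: %.4f | lpips: %.3e | mse: %.3e | pearson: %.4f\n",
    x$psnr, if (x$psnr_capped) " (capped)" else "", x$ssim, x$msssim,
    x$lpips, x$mse, x$pearson))
  invisible(x)
}

# SSIM from one set of image-wide statistics (population moments), with
# C1 = (0.01 R)^2 and C2 = (0.03 R)^2; optional sliding-window variant.
ssim_global <- function(x, y, max_i, mode = "global") {
  c1 <- (0.01 * max_i)^2
  c2 <- (0.03 * max_i)^2
  if (mode == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  } else {
    k <- gauss_kernel1d(11L, 1.5)
    xt <- as_tensor4(x); yt <- as_tensor4(y)
    mu_x <- .cpp_sepconv2d(xt, k); mu_y <- .cpp_sepconv2d(yt, k)
    xx <- .cpp_sepconv2d(xt * xt, k); yy <- .cpp_sepconv2d(yt * yt, k)
    xy <- .cpp_sepconv2d(xt * yt, k)
    vx <- pmax(xx - mu_x^2, 0); vy <- pmax(yy - mu_y^2, 0)
    cxy <- xy - mu_x * mu_y
    mean(((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
           ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2)))
  }
}

# MS-SSIM with the scale count (and, for tiny images, the window) adapted to
# the image size.
msssim_auto <- function(x, y, max_i) {
  side <- min(dim(x)[1], dim(x)[2])
  win <- min(11L, side - (side + 1L) %% 2L) # odd, no larger than the image
  sigma <- 1.5 * win / 11
  m <- max(1L, min(5L, floor(log2(side / win)) + 1L))
  msssim(x, y, loss_config(msssim_levels = m, data_range = max_i,
                           msssim_window = win, msssim_sigma = sigma))
}

# ---- perceptual feature distance -------------------------------------------

lpips_weights <- function(cfg, in_ch = 1L) {
  with_seed(cfg$seed, {
    ws <- list()
    cin <- in_ch
    for (l in seq_along(cfg$channels)) {
      cout <- cfg$channels[l]
      ws[[l]] <- list(
        w = array(stats::rnorm(3 * 3 * cin * cout, sd = sqrt(2 / (9 * cin))),
                  c(3, 3, cin, cout)),
        b = rep(0, cout))
      cin <- cout
    }
    ws
  })
}

lpips_features <- function(x, ws) {
  t <- as_tensor4(x)
  d <- dim(t)
  if (d[3] > 1L || d[4] > 1L) { # treat slices independently as batch
    dim(t) <- c(d[1], d[2], 1L, d[3] * d[4])
  }
  feats <- list()
  for (l in seq_along(ws)) {
    t <- .cpp_conv2d_fwd(t, ws[[l]]$w, ws[[l]]$b, 1L, 2L)
    t <- t * (t > 0)
    feats[[l]] <- t
  }
  feats
}

#' Perceptual feature distance between two images
#'
#' Layer-weighted squared distance between channel-normalized feature maps;
#' a pseudometric: non-negative, symmetric, and zero on identical inputs.
#' @param x,y same-shape images or stacks.
#' @param cfg an [lpips_config()].
#' @return non-negative scalar.
#' @export
lpips_distance <- function(x, y, cfg = lpips_config()) {
  if (!identical(dim(x), dim(y))) stop("lpips: shape mismatch")
  if (is.function(cfg$backbone)) {
    fx <- cfg$backbone(x)
    fy <- cfg$backbone(y)
  } else {
    ws <- lpips_weights(cfg)
    fx <- lpips_features(x, ws)
    fy <- lpips_features(y, ws)
  }
  wl <- rep(cfg$layer_weights, length.out = length(fx))
  total <- 0
  for (l in seq_along(fx)) {
    a <- unit_normalize_channels(fx[[l]])
    b <- unit_normalize_channels(fy[[l]])
    d <- dim(a)
    total <- total + wl[l] * sum((a - b)^2) / (d[1] * d[2] * d[4])
  }
  total
}

unit_normalize_channels <- function(t) {
  nrm <- sqrt(apply(t^2, c(1, 2, 4), sum)) + 1e-10
  sweep_channels(t, nrm)
}

sweep_channels <- function(t, nrm) {
  d <- dim(t)
  out <- aperm(t, c(1, 2, 4, 3))
  dim(out) <- c(d[1] * d[2] * d[4], d[3])
  out <- out / as.vector(nrm)
  dim(out) <- c(d[1], d[2], d[4], d[3])
  aperm(out, c(1, 2, 4, 3))
}

# ---- resolution estimators --------------------------------------------------

#' Decorrelation-based resolution estimate
#'
#' Correlates the image spectrum with radially masked versions of its
#' phase-normalized spectrum while sweeping a series of Gaussian high-pass
#' filters from weak to strong; the cut-off frequency `k_c` is the largest
#' refined correlation-peak position across the series, normalized so that
#' Nyquist = 1.
#'
#' @param image non-constant 2-D matrix.
#' @param n_filters number of high-pass strengths (default 10).
#' @param n_radii radial sampling of the decorrelation curves.
#' @return `k_c` in `[0, 1]`.
#' @export
decorrelation_kc <- function(image, n_filters = 10L, n_radii = 60L) {
  if (!is.matrix(image)) stop("decorrelation_kc expects a 2-D matrix")
  if (max(image) == min(image)) stop("constant image: cut-off undefined")
  h <- nrow(image); w <- ncol(image)
  win <- outer(hann(h), hann(w))
  img0 <- (image - mean(image)) * win
  fr <- function(n) {
    i <- 0:(n - 1)
    i[i > n / 2] <- i[i > n / 2] - n
    i / (n / 2) # normalized so Nyquist = 1
  }
  kr <- sqrt(outer(fr(h)^2, fr(w)^2, "+"))
  rs <- seq(0.02, 1, length.out = n_radii)
  sigmas <- exp(seq(log(max(h, w) / 2), log(0.5), length.out = n_filters))
  peak_of <- function(img) {
    a <- Mod(stats::fft(img))
    a[1, 1] <- 0
    ord <- order(as.vector(kr))
    csum <- cumsum(as.vector(a)[ord])
    ccnt <- seq_along(ord)
    tot2 <- sum(a^2)
    krs <- as.vector(kr)[ord]
    idx <- findInterval(rs, krs)
    ok <- idx > 0
    dvals <- rep(0, length(rs))
    dvals[ok] <- csum[idx[ok]] / sqrt(tot2 * ccnt[idx[ok]])
    p <- which.max(dvals)
    # rightmost index within a whisker of the max (plateau handling)
    near <- which(dvals >= dvals[p] * (1 - 1e-3))
    p <- max(near)
    # parabolic refinement on the original peak
    if (p > 1 && p < length(rs)) {
      y1 <- dvals[p - 1]; y2 <- dvals[p]; y3 <- dvals[p + 1]
      den <- y1 - 2 * y2 + y3
      off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      off <- max(min(off, 0.5), -0.5)
      rs[p] + off * (rs[2] - rs[1])
    } else rs[p]
  }
  peaks <- peak_of(img0)
  for (s in sigmas) {
    hp <- img0 - gauss_blur2(img0, s)
    if (max(abs(hp)) < 1e-14) next
    peaks <- c(peaks, peak_of(hp))
  }
  min(max(peaks), 1)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

gauss_blur2 <- function(m, sigma) {
  hw <- max(1L, min(ceiling(3 * sigma), floor((min(dim(m)) - 1) / 2)))
  k <- exp(-((-hw):hw)^2 / (2 * sigma^2))
  k <- k / sum(k)
  t4 <- m
  dim(t4) <- c(dim(m), 1L, 1L)
  out <- .cpp_sepconv2d(t4, k)
  dim(out) <- dim(m)
  out
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated width at half of `max - baseline`, where the baseline
#' is the profile minimum. The profile must attain its maximum strictly
#' inside the support and cross the half level on both sides.
#' @param profile numeric vector.
#' @param sample_spacing physical distance between samples.
#' @return width in the units of `sample_spacing`.
#' @export
fwhm_profile <- function(profile, sample_spacing = 1) {
  n <- length(profile)
  p <- which.max(profile)
  if (p == 1L || p == n || profile[p] <= max(profile[1], profile[n]))
    stop("profile has no interior maximum above its boundary values")
  base <- min(profile)
  half <- base + (profile[p] - base) / 2
  li <- p
  while (li > 1L && profile[li] > half) li <- li - 1L
  if (profile[li] > half) stop("no half-maximum crossing on the left")
  xl <- li + (half - profile[li]) / (profile[li + 1] - profile[li])
  ri <- p
  while (ri < n && profile[ri] > half) ri <- ri + 1L
  if (profile[ri] > half) stop("no half-maximum crossing on the right")
  xr <- ri - 1 + (profile[ri - 1] - half) / (profile[ri - 1] - profile[ri])
  (xr - xl) * sample_spacing
}

#' Fractional fluorescence change traces
#'
#' For each neuron, `dF/F0 = (F - F0) / F0` with the baseline `F0` taken as
#' the time average of that neuron's ROI-mean fluorescence.
#' @param roi_means numeric vector (one neuron) or matrix
#'   `(frames x neurons)` of per-frame ROI mean fluorescence.
#' @return same shape as the input; each trace has exact zero mean.
#' @export
dff_traces <- function(roi_means) {
  m <- as.matrix(roi_means)
  if (any(!is.finite(m))) stop("fluorescence values must be finite")
  f0 <- colMeans(m)
  if (any(f0 == 0)) stop("zero baseline F0: dF/F0 undefined")
  out <- sweep(sweep(m, 2, f0, "-"), 2, f0, "/")
  if (is.vector(roi_means)) out <- as.vector(out)
  out
}

#' ROI mean fluorescence from a labelled movie
#'
#' Convenience extractor pairing [make_neuro_volume()] output with
#' [dff_traces()]: averages each labelled ROI over every frame.
#' @param frames list of volumes (or arrays), one per time point.
#' @param roi_labels integer array of the same shape; 0 = background.
#' @return matrix `(frames x neurons)`.
#' @export
roi_mean_traces <- function(frames, roi_labels) {
  ids <- sort(setdiff(unique(as.vector(roi_labels)), 0L))
  out <- matrix(0, length(frames), length(ids))
  for (t in seq_along(frames)) {
    v <- as_volume_array(frames[[t]])
    for (k in seq_along(ids)) out[t, k] <- mean(v[roi_labels == ids[k]])
  }
  colnames(out) <- paste0("neuron", ids)
  out
}
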