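# Composite training objective: reverse-Huber (BerHu) pixel term, multi-scale
# structural similarity, and the adversarial term, plus the (-1, 1) min-max
# normalization applied to every training pair.
#
# All loss functions accept plain arrays or autodiff nodes; with an active
# tape they contribute gradients, otherwise they are ordinary computations.

#' Loss configuration
#'
#' Weights and constants of the composite generator objective
#' `alpha * BerHu + beta * (1 - MS-SSIM) + gamma * BCE(D(G(x)), 1)`.
#'
#' @param alpha BerHu weight (default 3).
#' @param beta MS-SSIM loss weight (default 1).
#' @param gamma adversarial weight (default 0.5).
#' @param berhu_c BerHu branch threshold c (default 0.1).
#' @param msssim_levels number of dyadic scales M (default 5).
#' @param msssim_weights per-scale exponents; defaults to the published
#'   five-scale constants, truncated and renormalized when `msssim_levels < 5`.
#'   Used for the luminance exponent at the coarsest scale and for both the
#'   contrast and structure exponents at every scale.
#' @param msssim_k `(K1, K2)` stabilization constants: `C1 = (K1 R)^2`,
#'   `C2 = (K2 R)^2`, `C3 = C2 / 2` with `R` the dynamic range.
#' @param msssim_window window size of the local-statistics Gaussian
#'   (default 11).
#' @param msssim_sigma Gaussian window SD in pixels (default 1.5).
#' @param data_range dynamic range R of the compared images (default 2:
#'   data normalized to (-1, 1)).
#' @export
loss_config <- function(alpha = 3, beta = 1, gamma = 0.5, berhu_c = 0.1,
                        msssim_levels = 5L,
                        msssim_weights = NULL,
                        msssim_k = c(0.01, 0.03),
                        msssim_window = 11L, msssim_sigma = 1.5,
                        data_range = 2) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, berhu_c > 0, msssim_levels >= 1)
  if (is.null(msssim_weights)) {
    w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
    msssim_weights <- w5[seq_len(min(msssim_levels, 5L))]
    msssim_weights <- msssim_weights / sum(msssim_weights)
    if (msssim_levels > 5L)
      msssim_weights <- rep(msssim_weights, length.out = msssim_levels)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, berhu_c = berhu_c,
                 msssim_levels = as.integer(msssim_levels),
                 msssim_weights = msssim_weights, msssim_k = msssim_k,
                 msssim_window = as.integer(msssim_window),
                 msssim_sigma = msssim_sigma, data_range = data_range),
            class = "loss_config")
}

#' Reverse Huber (BerHu) loss
#'
#' Sum over elements of `|d|` where `|d| <= c` and `(d^2 + c^2) / (2c)` where
#' `|d| > c`, with `d = pred - target`. Both branches meet at `c`, so the
#' penalty is continuous; it is L1 near zero and scaled-quadratic in the
#' tails.
#' @param pred,target same-shape arrays (or autodiff nodes).
#' @param c branch threshold (> 0).
#' @return scalar (node when recording).
#' @export
berhu <- function(pred, target, c = 0.1) {
  stopifnot(c > 0)
  pv <- nval(pred); tv <- nval(target)
  if (!identical(dim(pv), dim(tv)) || length(pv) != length(tv))
    stop("berhu: shape mismatch (", paste(dim(pv), collapse = "x"), " vs ",
         paste(dim(tv), collapse = "x"), ")")
  ag_berhu_sum(pred, target, c)
}

gauss_kernel1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# ensure a (H, W, C, B) tensor; images come in as matrices or (H, W, D)
as_tensor4 <- function(x) {
  v <- nval(x)
  d <- dim(v)
  if (is.null(d)) stop("expected an array input")
  nd <- switch(as.character(length(d)),
               "2" = c(d, 1L, 1L),
               "3" = c(d[1], d[2], 1L, d[3]), # slices treated as batch
               "4" = d,
               stop("unsupported array rank: ", length(d)))
  if (is_node(x)) ag_reshape(x, nd) else {
    dim(v) <- nd
    v
  }
}

# SSIM component maps at one scale from windowed local statistics.
ssim_components <- function(x, y, k1d, c1, c2, c3) {
  mu_x <- ag_sepblur(x, k1d)
  mu_y <- ag_sepblur(y, k1d)
  xx <- ag_sepblur(ag_mul(x, x), k1d)
  yy <- ag_sepblur(ag_mul(y, y), k1d)
  xy <- ag_sepblur(ag_mul(x, y), k1d)
  var_x <- ag_clamp_min(ag_sub(xx, ag_mul(mu_x, mu_x)), 0)
  var_y <- ag_clamp_min(ag_sub(yy, ag_mul(mu_y, mu_y)), 0)
  cov_xy <- ag_sub(xy, ag_mul(mu_x, mu_y))
  sd_x <- ag_pow(ag_add(var_x, 1e-12), 0.5)
  sd_y <- ag_pow(ag_add(var_y, 1e-12), 0.5)
  lum <- ag_div(ag_add(ag_scale(ag_mul(mu_x, mu_y), 2), c1),
                ag_add(ag_add(ag_mul(mu_x, mu_x), ag_mul(mu_y, mu_y)), c1))
  con <- ag_div(ag_add(ag_scale(ag_mul(sd_x, sd_y), 2), c2),
                ag_add(ag_add(var_x, var_y), c2))
  str <- ag_div(ag_add(cov_xy, c3), ag_add(ag_mul(sd_x, sd_y), c3))
  list(lum = lum, con = con, str = str)
}

#' Multi-scale structural similarity
#'
#' Product over `M` dyadic scales of contrast and structure factors with the
#' luminance factor at the coarsest scale; local statistics from a Gaussian
#' window. 3-D stacks are evaluated per slice and averaged. Returns a value
#' in `[0, 1]` for well-behaved inputs; the training loss is `1 - msssim`.
#'
#' @param pred,target same-shape arrays (2-D images or 3-D stacks), or nodes.
#' @param cfg a [loss_config()].
#' @return scalar similarity (node when recording).
#' @export
msssim <- function(pred, target, cfg = loss_config()) {
  pv <- nval(pred); tv <- nval(target)
  if (!identical(dim(pv), dim(tv)))
    stop("msssim: shape mismatch")
  m <- cfg$msssim_levels
  d <- dim(pv)
  min_side <- min(d[1], d[2])
  if (min_side < cfg$msssim_window * 2^(m - 1))
    stop("image side ", min_side, " too small for ", m,
         " dyadic scales with window ", cfg$msssim_window,
         "; reduce msssim_levels")
  r <- cfg$data_range
  c1 <- (cfg$msssim_k[1] * r)^2
  c2 <- (cfg$msssim_k[2] * r)^2
  c3 <- c2 / 2
  k1d <- gauss_kernel1d(cfg$msssim_window, cfg$msssim_sigma)
  x <- as_tensor4(pred)
  y <- as_tensor4(target)
  total <- NULL
  for (j in seq_len(m)) {
    comp <- ssim_components(x, y, k1d, c1, c2, c3)
    w <- cfg$msssim_weights[j]
    cs <- ag_mul(ag_pow(ag_clamp_min(ag_mean(comp$con), 1e-6), w),
                 ag_pow(ag_clamp_min(ag_mean(comp$str), 1e-6), w))
    total <- if (is.null(total)) cs else ag_mul(total, cs)
    if (j == m) {
      lum <- ag_pow(ag_clamp_min(ag_mean(comp$lum), 1e-6), w)
      total <- ag_mul(total, lum)
    } else {
      x <- ag_avgpool2(x)
      y <- ag_avgpool2(y)
    }
  }
  total
}

#' @rdname msssim
#' @export
msssim_loss <- function(pred, target, cfg = loss_config()) {
  ag_sub(1, msssim(pred, target, cfg))
}

#' Adversarial objectives from discriminator scores
#'
#' The discriminator objective (to be maximized) is
#' `0.5 * log(1 - D(G(x))) + 0.5 * log(D(y))`; its supremum is 0 when the
#' discriminator is perfect. The generator minimizes the non-saturating
#' binary cross-entropy toward the "real" label, `-log D(G(x))`.
#' Scores at exactly 0 or 1 are clamped to `[eps, 1 - eps]`.
#'
#' @param d_real,d_fake discriminator scores in (0, 1) (arrays or nodes).
#' @param eps numerical clamp inside logarithms (default 1e-7).
#' @return list with `d_objective` and `g_bce` (means over the batch).
#' @export
adversarial_losses <- function(d_real, d_fake, eps = 1e-7) {
  clip <- function(s) ag_clamp_min(ag_sub(1, ag_clamp_min(ag_sub(1, s), eps)),
                                   eps) # clamp to [eps, 1-eps]
  dr <- clip(d_real)
  df <- clip(d_fake)
  d_obj <- ag_add(ag_scale(ag_mean(ag_log(ag_sub(1, df))), 0.5),
                  ag_scale(ag_mean(ag_log(dr)), 0.5))
  g_bce <- ag_scale(ag_mean(ag_log(df)), -1)
  list(d_objective = d_obj, g_bce = g_bce)
}

#' Total generator loss
#'
#' `alpha * BerHu + beta * (1 - MS-SSIM) + gamma * BCE(d_fake, 1)` with the
#' weights of `cfg`.
#' @param pred,target prediction and ground-truth volumes (arrays or nodes).
#' @param d_fake discriminator score(s) for the prediction.
#' @param cfg a [loss_config()].
#' @return list with `total`, `berhu`, `msssim_loss`, `g_bce` (scalars or
#'   nodes).
#' @export
total_generator_loss <- function(pred, target, d_fake, cfg = loss_config()) {
  lb <- berhu(pred, target, cfg$berhu_c)
  lm <- msssim_loss(pred, target, cfg)
  la <- adversarial_losses(d_fake, d_fake)$g_bce # g side only needs d_fake
  total <- ag_add(ag_add(ag_scale(lb, cfg$alpha), ag_scale(lm, cfg$beta)),
                  ag_scale(la, cfg$gamma))
  list(total = total, berhu = lb, msssim_loss = lm, g_bce = la)
}

#' Min-max normalization to (-1, 1)
#'
#' `2 * (x - min) / (max - min) - 1`; every training image and volume is
#' normalized this way before entering the network. Affine-invariant for
#' positive rescalings.
#' @param x numeric array with `max(x) > min(x)`.
#' @return array with range exactly `[-1, 1]`.
#' @export
normalize_unit <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("normalize_unit: degenerate input (constant or non-finite)")
  2 * (x - lo) / (hi - lo) - 1
}
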