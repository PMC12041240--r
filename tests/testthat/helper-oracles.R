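# Independent brute-force oracle implementations of the printed formulas.
# These deliberately share no code with the package: statistics are computed
# by explicit shift-and-add window sums and plain elementwise arithmetic.

oracle_berhu <- function(pred, target, c) {
  d <- as.vector(pred) - as.vector(target)
  s <- 0
  for (v in d) {
    s <- s + if (abs(v) <= c) abs(v) else (v^2 + c^2) / (2 * c)
  }
  s
}

# Gaussian-window local mean by explicit accumulation over window offsets
# (zero padding), matching a separable same-size blur.
oracle_blur <- function(m, win = 11L, sigma = 1.5) {
  hw <- (win - 1L) %/% 2L
  x <- seq(-hw, hw)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2 * hw, w + 2 * hw)
  pad[hw + seq_len(h), hw + seq_len(w)] <- m
  out <- matrix(0, h, w)
  for (a in seq_along(k)) for (b in seq_along(k)) {
    out <- out + k[a] * k[b] *
      pad[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
  }
  out
}

oracle_msssim <- function(x, y, levels, weights, max_i = 2,
                          win = 11L, sigma = 1.5) {
  c1 <- (0.01 * max_i)^2
  c2 <- (0.03 * max_i)^2
  c3 <- c2 / 2
  total <- 1
  for (j in seq_len(levels)) {
    mx <- oracle_blur(x, win, sigma)
    my <- oracle_blur(y, win, sigma)
    vx <- pmax(oracle_blur(x * x, win, sigma) - mx^2, 0)
    vy <- pmax(oracle_blur(y * y, win, sigma) - my^2, 0)
    cxy <- oracle_blur(x * y, win, sigma) - mx * my
    sx <- sqrt(vx + 1e-12)
    sy <- sqrt(vy + 1e-12)
    con <- mean((2 * sx * sy + c2) / (vx + vy + c2))
    str <- mean((cxy + c3) / (sx * sy + c3))
    total <- total * max(con, 1e-6)^weights[j] * max(str, 1e-6)^weights[j]
    if (j == levels) {
      lum <- mean((2 * mx * my + c1) / (mx^2 + my^2 + c1))
      total <- total * max(lum, 1e-6)^weights[j]
    } else {
      he <- nrow(x) - nrow(x) %% 2L
      we <- ncol(x) - ncol(x) %% 2L
      ds <- function(m) (m[seq(1, he, 2), seq(1, we, 2)] +
                           m[seq(2, he, 2), seq(1, we, 2)] +
                           m[seq(1, he, 2), seq(2, we, 2)] +
                           m[seq(2, he, 2), seq(2, we, 2)]) / 4
      x <- ds(x)
      y <- ds(y)
    }
  }
  total
}

oracle_psnr <- function(x, y, max_i) 10 * log10(max_i^2 / mean((y - x)^2))

oracle_ssim_global <- function(x, y, r) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + (0.01 * r)^2) * (2 * cxy + (0.03 * r)^2)) /
    ((mx^2 + my^2 + (0.01 * r)^2) * (vx + vy + (0.03 * r)^2))
}

oracle_pearson <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

# Brightness calibration used when scoring reconstructions whose intensity
# scale is arbitrary: least-squares affine map onto the reference.
affine_calibrate <- function(v, ref) {
  v <- as.vector(v); r <- as.vector(ref)
  a <- stats::cov(v, r) / max(stats::var(v), 1e-12)
  out <- a * v + (mean(r) - a * mean(v))
  array(out, dim(ref))
}
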