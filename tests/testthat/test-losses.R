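# Composite objective: BerHu, MS-SSIM, adversarial terms, normalization.

test_that("berhu reproduces both branch closed forms and is continuous", {
  expect_equal(nval(berhu(array(0.05, c(1, 1)), array(0, c(1, 1)), 0.1)),
               0.05)
  expect_equal(nval(berhu(array(0.3, c(1, 1)), array(0, c(1, 1)), 0.1)),
               (0.3^2 + 0.1^2) / (2 * 0.1)) # = 0.5
  # both branches meet at |d| = c
  eps <- 1e-9
  lo <- nval(berhu(array(0.1 - eps, c(1, 1)), array(0, c(1, 1)), 0.1))
  hi <- nval(berhu(array(0.1 + eps, c(1, 1)), array(0, c(1, 1)), 0.1))
  expect_lt(abs(hi - lo), 1e-6)
  x <- array(runif(24), c(4, 6))
  expect_equal(nval(berhu(x, x, 0.1)), 0)
  expect_error(berhu(x, x[1:3, ], 0.1), "shape mismatch")
})

test_that("berhu agrees with a brute-force evaluation on random pairs", {
  set.seed(11)
  for (k in 1:20) {
    a <- array(rnorm(60, sd = 0.3), c(5, 4, 3))
    b <- array(rnorm(60, sd = 0.3), c(5, 4, 3))
    expect_lt(abs(nval(berhu(a, b, 0.1)) - oracle_berhu(a, b, 0.1)), 1e-6)
  }
  # symmetric in the sign of the difference, non-negative
  a <- array(rnorm(60), c(5, 4, 3)); b <- array(rnorm(60), c(5, 4, 3))
  expect_equal(nval(berhu(a, b, 0.2)), nval(berhu(b, a, 0.2)))
  expect_gt(nval(berhu(a, b, 0.2)), 0)
})

test_that("msssim matches the independent windowed-statistics oracle", {
  set.seed(5)
  cfg <- loss_config(msssim_levels = 3L, data_range = 2)
  for (k in 1:20) {
    x <- matrix(runif(64 * 64), 64, 64)
    y <- 0.6 * x + 0.4 * matrix(runif(64 * 64), 64, 64)
    got <- nval(msssim(x, y, cfg))
    want <- oracle_msssim(x, y, 3L, cfg$msssim_weights, max_i = 2)
    expect_lt(abs(got - want), 1e-6)
  }
})

test_that("msssim is a bounded symmetric similarity", {
  set.seed(6)
  cfg <- loss_config(msssim_levels = 2L, data_range = 1)
  x <- matrix(runif(48 * 48), 48, 48)
  y <- matrix(runif(48 * 48), 48, 48)
  expect_equal(nval(msssim(x, x, cfg)), 1)
  expect_lt(nval(msssim(x, y, cfg)), 1) # independent noise vs structure
  expect_gte(nval(msssim(x, y, cfg)), 0)
  expect_equal(nval(msssim(x, y, cfg)), nval(msssim(y, x, cfg)))
  expect_equal(nval(msssim_loss(x, x, cfg)), 0)
  expect_error(msssim(matrix(0, 8, 8), matrix(0, 8, 8),
                      loss_config(msssim_levels = 4L)), "msssim_levels")
})

test_that("adversarial objectives take their closed-form values", {
  out <- adversarial_losses(0.5, 0.5)
  expect_equal(nval(out$d_objective), log(0.5), tolerance = 1e-12)
  expect_equal(nval(out$g_bce), -log(0.5), tolerance = 1e-12)
  # perfect discriminator approaches the supremum 0
  near <- adversarial_losses(1 - 1e-9, 1e-9)
  expect_gt(nval(near$d_objective), -1e-4)
  expect_lt(nval(near$d_objective), 0)
  # generator optimum as the fake score approaches 1
  expect_lt(nval(adversarial_losses(0.5, 1 - 1e-9)$g_bce), 1e-4)
  # exact 0/1 scores are clamped, not infinite
  expect_true(is.finite(nval(adversarial_losses(1, 0)$d_objective)))
})

test_that("total generator loss is the configured weighted sum", {
  cfg <- loss_config(alpha = 3, beta = 1, gamma = 0.5, msssim_levels = 2L)
  set.seed(8)
  x <- matrix(runif(48 * 48), 48, 48)
  out <- total_generator_loss(x, x, 0.5, cfg)
  # identical pred/target: only the adversarial term remains
  expect_equal(nval(out$total), cfg$gamma * nval(out$g_bce))
  expect_equal(nval(out$berhu), 0)
  expect_equal(nval(out$msssim_loss), 0)
  zero <- total_generator_loss(x, x, 0.5,
                               loss_config(alpha = 0, beta = 0, gamma = 0,
                                           msssim_levels = 2L))
  expect_equal(nval(zero$total), 0)
  # weighted-sum contract on arbitrary component values
  y <- matrix(runif(48 * 48), 48, 48)
  o2 <- total_generator_loss(x, y, 0.3, cfg)
  expect_equal(nval(o2$total),
               3 * nval(o2$berhu) + nval(o2$msssim_loss) + 0.5 * nval(o2$g_bce))
})

test_that("normalize_unit maps onto [-1, 1] and is affine invariant", {
  expect_equal(normalize_unit(c(2, 3, 4)), c(-1, 0, 1))
  set.seed(9)
  x <- array(rnorm(100), c(10, 10))
  y <- normalize_unit(x)
  expect_equal(min(y), -1)
  expect_equal(max(y), 1)
  expect_equal(normalize_unit(3.7 * x + 11), y)
  expect_error(normalize_unit(rep(1, 5)), "degenerate")
})

test_that("the composite loss descends under gradient steps on a toy fit", {
  # one-parameter generator: pred = theta * template; minimize the total loss
  set.seed(10)
  template <- matrix(runif(48 * 48), 48, 48)
  target <- 0.8 * template
  cfg <- loss_config(msssim_levels = 2L, data_range = 1)
  theta <- lfrecon:::ag_param(0.1)
  losses <- numeric(30)
  for (it in 1:30) {
    lfrecon:::ag_start()
    predm <- lfrecon:::ag_mul(lfrecon:::ag_leaf(template), theta)
    lb <- berhu(predm, lfrecon:::ag_leaf(target), 0.1)
    lm <- msssim_loss(predm, lfrecon:::ag_leaf(target), cfg)
    total <- lfrecon:::ag_add(lfrecon:::ag_scale(lb, 1 / length(target)),
                              lm)
    lfrecon:::ag_zero_grad(list(theta))
    lfrecon:::ag_backward(total)
    lfrecon:::ag_stop()
    losses[it] <- nval(total)
    theta$value <- theta$value - 0.02 * theta$grad
  }
  expect_lt(losses[30], losses[1])
  expect_equal(as.numeric(theta$value), 0.8, tolerance = 0.1)
})
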