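# Alternating optimization, schedules, prediction, and data splits.

test_that("the learning-rate schedule decays by 0.95 every 5 epochs", {
  cfg <- train_config()
  expect_equal(scheduled_lr(1e-6, 0L, cfg), 1e-6)
  expect_equal(scheduled_lr(1e-6, 4L, cfg), 1e-6)
  expect_equal(scheduled_lr(1e-6, 5L, cfg), 0.95e-6)
  expect_equal(scheduled_lr(1e-6, 10L, cfg), 1e-6 * 0.95^2) # 9.025e-7
  expect_equal(scheduled_lr(1e-7, 10L, cfg), 1e-7 * 0.95^2)
})

test_that("each player is frozen during the other's update", {
  gs <- generator_spec(n_views = 16L, view_size = c(4L, 4L), out_slices = 3L,
                       upsample_factor = 4L, base_channels = 4L)
  ds <- discriminator_spec(in_slices = 3L, n_blocks = 2L, channel_base = 4L)
  gen <- build_generator(gs, 1L)
  dis <- build_discriminator(ds, 2L)
  set.seed(3)
  x <- array(runif(4 * 4 * 16 * 2, -1, 1), c(4, 4, 16, 2))
  y <- array(runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  # discriminator step on a detached fake: generator untouched
  g_before <- param_checksum(gen)
  fake <- nval(generator_forward(gen, x, training = TRUE))
  lfrecon:::ag_start()
  adv <- adversarial_losses(discriminator_forward(dis, lfrecon:::ag_leaf(y)),
                            discriminator_forward(dis,
                                                  lfrecon:::ag_leaf(fake)))
  lfrecon:::ag_zero_grad(dis$params)
  lfrecon:::ag_backward(lfrecon:::ag_scale(adv$d_objective, -1))
  lfrecon:::ag_stop()
  lfrecon:::adamw_step(dis$params, 1e-3, c(0.9, 0.999), 0)
  expect_equal(param_checksum(gen), g_before)
  # generator step with the critic in the graph: critic values untouched
  d_before <- param_checksum(dis)
  lfrecon:::ag_start()
  pred <- generator_forward(gen, lfrecon:::ag_leaf(x), training = TRUE)
  score <- discriminator_forward(dis, pred)
  tot <- total_generator_loss(pred, lfrecon:::ag_leaf(y), score,
                              loss_config(msssim_levels = 1L))
  lfrecon:::ag_zero_grad(gen$params)
  lfrecon:::ag_zero_grad(dis$params)
  lfrecon:::ag_backward(tot$total)
  lfrecon:::ag_stop()
  lfrecon:::adamw_step(gen$params, 1e-3, c(0.9, 0.999), 0)
  expect_equal(param_checksum(dis), d_before)
  expect_false(param_checksum(gen) == g_before)
})

test_that("training is deterministic and fully logged", {
  pairs <- lapply(31:34, fix_bead_pair)
  gs <- generator_spec(n_views = 16L, view_size = c(16L, 16L),
                       out_slices = 5L, upsample_factor = 4L,
                       base_channels = 4L)
  ds <- discriminator_spec(in_slices = 5L, n_blocks = 2L, channel_base = 4L)
  tc <- train_config(lr_generator = 1e-3, lr_discriminator = 1e-4,
                     epochs = 100L, batch_size = 2L, seed = 9L)
  lc <- loss_config(msssim_levels = 2L)
  f1 <- train_gan(pairs, gs, ds, lc, tc, max_steps = 6L)
  f2 <- train_gan(pairs, gs, ds, lc, tc, max_steps = 6L)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 6L)
  expect_true(all(c("loss_total", "loss_berhu", "loss_msssim", "loss_adv",
                    "d_objective", "lr_generator", "lr_discriminator",
                    "epoch") %in% names(f1$history)))
  expect_equal(param_checksum(f1$generator), param_checksum(f2$generator))
  # prediction is repeatable and checkpoints restore it exactly
  held <- fix_heldout()
  p1 <- predict_volume(f1$generator, held$lf)
  p2 <- predict_volume(f1$generator, held$lf)
  expect_identical(p1$data, p2$data)
  path <- tempfile(fileext = ".rds")
  save_weights(f1$generator, path)
  expect_identical(predict_volume(load_weights(path), held$lf)$data, p1$data)
  # geometry mismatch is rejected
  expect_error(predict_volume(f1$generator,
                              lf_image(matrix(0, 30, 30), 5L)),
               "does not match")
})

test_that("k-fold splits cover all items disjointly", {
  sp <- kfold_split(2000L, 5L, seed = 1L)
  expect_length(sp, 5L)
  for (f in sp) {
    expect_length(f$train, 1600L)
    expect_length(f$validation, 400L)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  vals <- sort(unlist(lapply(sp, `[[`, "validation")))
  expect_equal(vals, 1:2000)
  # n = k gives leave-one-out
  loo <- kfold_split(5L, 5L, seed = 2L)
  expect_true(all(vapply(loo, function(f) length(f$validation), 1L) == 1L))
  expect_equal(sort(unlist(lapply(loo, `[[`, "validation"))), 1:5)
  expect_error(kfold_split(3L, 5L), "exceeds")
})
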