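# Alternating GAN optimization with AdamW, the staircase learning-rate decay
# and full per-step loss bookkeeping, plus prediction and k-fold utilities.

#' Training configuration
#'
#' Defaults follow the published recipe: AdamW with betas (0.9, 0.999) and
#' weight decay 1e-2, generator / discriminator learning rates 1e-6 / 1e-7,
#' both decayed by 0.95 every 5 epochs, batch size 2.
#'
#' @param lr_generator,lr_discriminator base learning rates.
#' @param adam_betas `(beta1, beta2)`.
#' @param weight_decay decoupled weight decay.
#' @param lr_decay_factor multiplicative decay (default 0.95).
#' @param lr_decay_every epochs between decays (default 5).
#' @param batch_size samples per step (default 2).
#' @param epochs training epochs.
#' @param seed RNG seed controlling shuffling (training is fully
#'   deterministic under a fixed seed).
#' @param checkpoint_every epochs between retained parameter snapshots.
#' @param d_steps_per_g discriminator updates per generator update.
#' @param normalize_pairs min-max normalize every view stack and target
#'   volume to (-1, 1) before use (default TRUE).
#' @export
train_config <- function(lr_generator = 1e-6, lr_discriminator = 1e-7,
                         adam_betas = c(0.9, 0.999), weight_decay = 1e-2,
                         lr_decay_factor = 0.95, lr_decay_every = 5L,
                         batch_size = 2L, epochs = 10L, seed = 1L,
                         checkpoint_every = 5L, d_steps_per_g = 1L,
                         normalize_pairs = TRUE) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, batch_size >= 1)
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 adam_betas = adam_betas, weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 d_steps_per_g = as.integer(d_steps_per_g),
                 normalize_pairs = isTRUE(normalize_pairs)),
            class = "train_config")
}

#' Scheduled learning rate
#'
#' Staircase decay: `lr0 * factor^(floor(epoch / every))` with `epoch`
#' counted from 0.
#' @param lr0 base rate.
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @export
scheduled_lr <- function(lr0, epoch, cfg) {
  lr0 * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

adamw_step <- function(params, lr, betas, wd, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    p$t <- p$t + 1L
    p$m <- betas[1] * p$m + (1 - betas[1]) * g
    p$v <- betas[2] * p$v + (1 - betas[2]) * g * g
    mhat <- p$m / (1 - betas[1]^p$t)
    vhat <- p$v / (1 - betas[2]^p$t)
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + wd * p$value)
  }
  invisible(NULL)
}

batch_tensor <- function(items) {
  d <- dim(items[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(items)))
  for (i in seq_along(items)) out[, , , i] <- items[[i]]
  out
}

#' Train the reconstruction GAN
#'
#' Alternating optimization: each step first updates the discriminator toward
#' labelling real volumes 1 and generated volumes 0 (generator frozen), then
#' updates the generator on the composite BerHu + MS-SSIM + adversarial
#' objective (discriminator frozen). All loss terms, learning rates, and the
#' epoch index are recorded per step.
#'
#' @param pairs list of training pairs; each is a list with `views` (an
#'   `lf_views` or `(h, w, n_views)` array) and `volume` (an [lf_volume()] or
#'   `(H, W, D)` array).
#' @param gspec,dspec architecture specs ([generator_spec()],
#'   [discriminator_spec()]).
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param max_steps optional hard cap on optimization steps (for scaled-down
#'   runs); `NULL` runs `epochs` full epochs.
#' @return list with `generator`, `discriminator`, `history` (data.frame of
#'   per-step records) and `checkpoints`.
#' @export
train_gan <- function(pairs, gspec, dspec, loss_cfg = loss_config(),
                      train_cfg = train_config(), max_steps = NULL) {
  if (!length(pairs)) stop("no training pairs")
  prep <- lapply(pairs, function(p) {
    v <- if (inherits(p$views, "lf_views")) views_to_tensor(p$views) else {
      a <- p$views
      if (length(dim(a)) == 3L) { # (n_views, h, w) raster order
        a <- aperm(a, c(2, 3, 1))
        dim(a) <- c(dim(a), 1L)
      }
      a
    }
    y <- as_volume_array(p$volume)
    dim(y) <- c(dim(y)[1:3], 1L)
    if (train_cfg$normalize_pairs) {
      v <- normalize_unit(v)
      y <- normalize_unit(y)
    }
    list(x = v, y = y)
  })
  dx <- dim(prep[[1]]$x)
  dy <- dim(prep[[1]]$y)
  for (p in prep) {
    if (!identical(dim(p$x), dx) || !identical(dim(p$y), dy))
      stop("shape drift across training pairs")
  }
  gen <- build_generator(gspec, train_cfg$seed)
  dis <- build_discriminator(dspec, train_cfg$seed + 1L)
  gp <- gen$params
  dp <- dis$params
  hist <- list()
  checkpoints <- list()
  step <- 0L
  abort <- FALSE
  with_seed(train_cfg$seed + 2L, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      if (abort) break
      lr_g <- scheduled_lr(train_cfg$lr_generator, epoch, train_cfg)
      lr_d <- scheduled_lr(train_cfg$lr_discriminator, epoch, train_cfg)
      ord <- sample(length(prep))
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      for (bidx in batches) {
        x <- batch_tensor(lapply(prep[bidx], `[[`, "x"))
        y <- batch_tensor(lapply(prep[bidx], `[[`, "y"))
        # --- discriminator step(s): generator frozen (detached fake) ---
        fake_det <- nval(generator_forward(gen, x, training = TRUE))
        d_obj_val <- NA_real_
        for (k in seq_len(train_cfg$d_steps_per_g)) {
          ag_start()
          d_real <- discriminator_forward(dis, ag_leaf(y))
          d_fake <- discriminator_forward(dis, ag_leaf(fake_det))
          adv <- adversarial_losses(d_real, d_fake)
          d_loss <- ag_scale(adv$d_objective, -1) # maximize the objective
          ag_zero_grad(dp)
          ag_backward(d_loss)
          ag_stop()
          adamw_step(dp, lr_d, train_cfg$adam_betas, train_cfg$weight_decay)
          d_obj_val <- nval(adv$d_objective)
        }
        # --- generator step: discriminator frozen -----------------------
        ag_start()
        xg <- ag_leaf(x)
        pred <- generator_forward(gen, xg, training = TRUE)
        d_fake2 <- discriminator_forward(dis, pred)
        lb <- berhu(pred, ag_leaf(y), loss_cfg$berhu_c)
        lm <- msssim_loss(pred, ag_leaf(y), loss_cfg)
        la <- adversarial_losses(d_fake2, d_fake2)$g_bce
        total <- ag_add(ag_add(ag_scale(lb, loss_cfg$alpha),
                               ag_scale(lm, loss_cfg$beta)),
                        ag_scale(la, loss_cfg$gamma))
        ag_zero_grad(gp)
        ag_zero_grad(dp) # discard spillover grads into the frozen critic
        ag_backward(total)
        ag_stop()
        total_v <- nval(total)
        if (!is.finite(total_v)) {
          warning("non-finite generator loss at step ", step + 1L,
                  "; aborting with last checkpoint")
          abort <- TRUE
          break
        }
        adamw_step(gp, lr_g, train_cfg$adam_betas, train_cfg$weight_decay)
        ag_zero_grad(dp)
        step <- step + 1L
        hist[[step]] <- data.frame(
          step = step, epoch = epoch,
          loss_total = total_v, loss_berhu = nval(lb),
          loss_msssim = nval(lm), loss_adv = nval(la),
          d_objective = d_obj_val, lr_generator = lr_g,
          lr_discriminator = lr_d)
        if (!is.null(max_steps) && step >= max_steps) break
      }
      if ((epoch + 1L) %% train_cfg$checkpoint_every == 0L || abort) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(epoch = epoch, g = lapply(gp, function(p) p$value),
               d = lapply(dp, function(p) p$value))
      }
      if (!is.null(max_steps) && step >= max_steps) break
    }
  })
  list(generator = gen, discriminator = dis,
       history = do.call(rbind, hist), checkpoints = checkpoints,
       train_cfg = train_cfg, loss_cfg = loss_cfg)
}

#' Reconstruct a volume from a light field with a trained generator
#'
#' Decomposes the light field into sub-aperture views, min-max normalizes
#' them to (-1, 1), runs the generator in eval mode and maps the output back
#' to `[0, 1]`. Repeated calls are bit-identical.
#'
#' @param gen a trained `lf_generator`.
#' @param lf an [lf_image()].
#' @return an [lf_volume()].
#' @export
predict_volume <- function(gen, lf) {
  stopifnot(inherits(lf, "lf_image"))
  spec <- gen$spec
  n <- as.integer(round(sqrt(spec$n_views)))
  if (lf$pixels_per_lenslet != n)
    stop("light-field N (", lf$pixels_per_lenslet,
         ") does not match generator N (", n, ")")
  views <- decompose_views(lf)
  x <- normalize_unit(views_to_tensor(views))
  out <- nval(generator_forward(gen, x, training = FALSE))
  v <- out[, , , 1]
  lf_volume((v + 1) / 2)
}

#' k-fold cross-validation split
#'
#' Shuffles the items once, cuts them into k near-equal disjoint folds, and
#' returns one train / validation round per fold.
#' @param n_items number of items (or a vector whose length is used).
#' @param k number of folds (>= 2).
#' @param seed shuffling seed.
#' @return list of `k` lists with integer index vectors `train` and
#'   `validation`.
#' @export
kfold_split <- function(n_items, k, seed = 1L) {
  n <- if (length(n_items) > 1L) length(n_items) else as.integer(n_items)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of items (", n, ")")
  ord <- with_seed(seed, sample(n))
  fold_id <- sort(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    val <- ord[fold_id == f]
    list(train = sort(setdiff(ord, val)), validation = sort(val))
  })
}
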