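# The reconstruction GAN: an encoder-decoder generator mapping sub-aperture
# view stacks to depth stacks, and a convolutional discriminator scoring
# volumes in (0, 1). Both are built on the package's autodiff engine; forward
# passes are deterministic in eval mode.

#' Generator architecture specification
#'
#' @param n_views number of sub-aperture views (N^2).
#' @param view_size `(h, w)` of each view.
#' @param out_slices number of output depth slices D.
#' @param upsample_factor lateral upsampling factor N; the output is
#'   `(h * N, w * N, D)`.
#' @param base_channels encoder width of the first stage (doubled per stage).
#' @param convs_per_block convolution + normalization + rectifier layers per
#'   encoder/decoder block (default 1).
#' @param skip_layers encoder stages whose outputs are concatenated onto the
#'   matching decoder stage inputs (default `c(1, 3)`).
#' @param skip_channel_rule `"even_channels"` concatenates the even-indexed
#'   channels of the encoder stage; `"all"` concatenates the full stage.
#' @param upsample_mode `"combined"` blends a bicubic-interpolation path and
#'   a sub-pixel (pixel-shuffle) convolution path equally, suppressing
#'   checkerboard harmonics; `"pixelshuffle"` and `"bicubic"` select a single
#'   path.
#' @export
generator_spec <- function(n_views, view_size, out_slices, upsample_factor,
                           base_channels = 16L,
                           convs_per_block = 1L,
                           skip_layers = c(1L, 3L),
                           skip_channel_rule = c("even_channels", "all"),
                           upsample_mode = c("combined", "pixelshuffle",
                                             "bicubic"),
                           out_activation = c("linear", "tanh")) {
  skip_channel_rule <- match.arg(skip_channel_rule)
  upsample_mode <- match.arg(upsample_mode)
  out_activation <- match.arg(out_activation)
  if (round(sqrt(n_views))^2 != n_views)
    stop("n_views must be a square number (N^2)")
  if (!all(skip_layers %in% 1:3))
    stop("skip_layers must be a subset of encoder stages 1..3")
  structure(list(n_views = as.integer(n_views),
                 view_size = as.integer(view_size),
                 out_slices = as.integer(out_slices),
                 upsample_factor = as.integer(upsample_factor),
                 base_channels = as.integer(base_channels),
                 convs_per_block = as.integer(convs_per_block),
                 skip_layers = as.integer(skip_layers),
                 skip_channel_rule = skip_channel_rule,
                 upsample_mode = upsample_mode,
                 out_activation = out_activation),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Five convolutional blocks of two layers each (second layer stride 2); the
#' first block is as wide as the volume slice count, later blocks follow the
#' `20 * 2^k` channel rule (k = 1 at the second block). Global average
#' pooling feeds two dense (1x1 convolution) layers of 20 hidden units and a
#' sigmoid output in (0, 1).
#'
#' @param in_slices volume slice count D (also the first block width).
#' @param n_blocks number of convolutional blocks (default 5).
#' @param channel_base base of the channel rule (default 20).
#' @param dense_units hidden units of the first dense layer (default 20).
#' @export
discriminator_spec <- function(in_slices, n_blocks = 5L, channel_base = 20L,
                               dense_units = 20L) {
  structure(list(in_slices = as.integer(in_slices),
                 n_blocks = as.integer(n_blocks),
                 channel_base = as.integer(channel_base),
                 dense_units = as.integer(dense_units)),
            class = "discriminator_spec")
}

# Greedy pixel-shuffle factorization of the upsample factor: extract factors
# of 2 and 3, then extra factors of 2 while the running product stays <= N;
# any remainder is covered by an exact bicubic resize.
`%||%` <- function(a, b) if (is.null(a)) b else a

shuffle_factors <- function(n) {
  fs <- integer(0)
  r <- n
  while (r %% 2L == 0L) { fs <- c(fs, 2L); r <- r %/% 2L }
  while (r %% 3L == 0L) { fs <- c(fs, 3L); r <- r %/% 3L }
  if (r > 1L) while (prod(c(fs, 2L)) <= n) fs <- c(fs, 2L)
  fs
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv <- function(model, name, k, cin, cout) {
  model$params[[paste0(name, ".w")]] <- ag_param(he_init(k, cin, cout))
  model$params[[paste0(name, ".b")]] <- ag_param(rep(0, cout))
  model
}

new_bn <- function(model, name, c) {
  model$params[[paste0(name, ".gamma")]] <- ag_param(rep(1, c))
  model$params[[paste0(name, ".beta")]] <- ag_param(rep(0, c))
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, c)
  st$running_var <- rep(1, c)
  model$bn[[name]] <- st
  model
}

conv_fwd <- function(model, name, x, pad = 1L, stride = 1L) {
  ag_conv2d(x, model$params[[paste0(name, ".w")]],
            model$params[[paste0(name, ".b")]], pad, stride)
}

bn_fwd <- function(model, name, x, training) {
  ag_batchnorm(x, model$params[[paste0(name, ".gamma")]],
               model$params[[paste0(name, ".beta")]],
               model$bn[[name]], training = training)
}

skip_channels <- function(spec, c_enc) {
  if (spec$skip_channel_rule == "even_channels") length(seq(1L, c_enc, by = 2L))
  else c_enc
}

#' Build a generator
#'
#' Encoder of three convolutional blocks (3x3 kernels, batch normalization,
#' rectifier), a mirrored decoder with skip concatenation of the selected
#' encoder channels at stages 1 and 3, and an upsampling head combining
#' bicubic interpolation with sub-pixel convolution to reach the exact
#' factor-N output size.
#'
#' @param spec a [generator_spec()].
#' @param seed parameter initialization seed; identical seeds give identical
#'   parameters.
#' @return an object of class `lf_generator` (parameters, normalization
#'   state, spec, seed).
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  c1 <- spec$base_channels
  c2 <- 2L * c1
  c3 <- 4L * c1
  model <- list(params = list(), bn = list(), spec = spec,
                seed = as.integer(seed))
  nb <- max(1L, spec$convs_per_block %||% 2L)
  new_block <- function(model, name, cin, cout) {
    for (l in seq_len(nb)) {
      model <- new_conv(model, paste0(name, "_l", l), 3L,
                        if (l == 1L) cin else cout, cout)
      model <- new_bn(model, paste0(name, "_l", l, "_bn"), cout)
    }
    model
  }
  with_seed(seed, {
    model <- new_block(model, "enc1", spec$n_views, c1)
    model <- new_block(model, "enc2", c1, c2)
    model <- new_block(model, "enc3", c2, c3)
    dec3_in <- c3 + if (3L %in% spec$skip_layers) skip_channels(spec, c3) else 0L
    model <- new_block(model, "dec3", dec3_in, c2)
    model <- new_block(model, "dec2", c2, c1)
    dec1_in <- c1 + if (1L %in% spec$skip_layers) skip_channels(spec, c1) else 0L
    model <- new_block(model, "dec1", dec1_in, c1)
    fs <- shuffle_factors(spec$upsample_factor)
    for (s in seq_along(fs))
      model <- new_conv(model, paste0("ps", s), 3L, c1, c1 * fs[s]^2)
    model <- new_conv(model, "bicubic_conv", 3L, c1, c1)
    model <- new_conv(model, "head", 3L, c1, spec$out_slices)
  })
  model$shuffle_factors <- shuffle_factors(spec$upsample_factor)
  class(model) <- "lf_generator"
  model
}

#' Generator forward pass
#'
#' @param model an `lf_generator`.
#' @param views an `lf_views` object or an `(h, w, n_views, batch)` tensor
#'   (values expected normalized to (-1, 1)).
#' @param training use batch statistics and update running moments (TRUE
#'   during optimization); FALSE gives deterministic eval behavior.
#' @return `(h*N, w*N, D, batch)` tensor (autodiff node when recording).
#' @export
generator_forward <- function(model, views, training = FALSE) {
  spec <- model$spec
  if (inherits(views, "lf_views")) views <- views_to_tensor(views)
  d <- dim(nval(views))
  if (length(d) != 4L || d[3] != spec$n_views ||
      d[1] != spec$view_size[1] || d[2] != spec$view_size[2])
    stop("view stack shape (", paste(d, collapse = "x"),
         ") does not match generator spec (",
         spec$view_size[1], "x", spec$view_size[2], "x", spec$n_views, "xB)")
  nb <- max(1L, spec$convs_per_block %||% 2L)
  block_fwd <- function(name, x) {
    for (l in seq_len(nb)) {
      nm <- paste0(name, "_l", l)
      x <- ag_relu(bn_fwd(model, paste0(nm, "_bn"),
                          conv_fwd(model, nm, x), training))
    }
    x
  }
  e1 <- block_fwd("enc1", views)
  e2 <- block_fwd("enc2", e1)
  e3 <- block_fwd("enc3", e2)
  x <- e3
  if (3L %in% spec$skip_layers)
    x <- ag_concat_c(x, take_skip(spec, e3))
  x <- block_fwd("dec3", x)
  x <- block_fwd("dec2", x)
  if (1L %in% spec$skip_layers)
    x <- ag_concat_c(x, take_skip(spec, e1))
  x <- block_fwd("dec1", x)
  h_out <- d[1] * spec$upsample_factor
  w_out <- d[2] * spec$upsample_factor
  up <- NULL
  if (spec$upsample_mode %in% c("combined", "pixelshuffle")) {
    ps <- x
    for (s in seq_along(model$shuffle_factors)) {
      ps <- ag_pixel_shuffle(conv_fwd(model, paste0("ps", s), ps),
                             model$shuffle_factors[s])
    }
    dps <- dim(nval(ps))
    if (dps[1] != h_out || dps[2] != w_out)
      ps <- ag_resize_bicubic(ps, h_out, w_out)
    up <- ps
  }
  if (spec$upsample_mode %in% c("combined", "bicubic")) {
    bc <- conv_fwd(model, "bicubic_conv", ag_resize_bicubic(x, h_out, w_out))
    up <- if (is.null(up)) bc else ag_scale(ag_add(up, bc), 0.5)
  }
  out <- conv_fwd(model, "head", ag_relu(up))
  if ((spec$out_activation %||% "linear") == "tanh") out <- ag_tanh(out)
  out
}

take_skip <- function(spec, enc_out) {
  c_enc <- dim(nval(enc_out))[3]
  idx <- if (spec$skip_channel_rule == "even_channels")
    seq(1L, c_enc, by = 2L) else seq_len(c_enc)
  ag_take_c(enc_out, idx)
}

#' Build a discriminator
#' @param spec a [discriminator_spec()].
#' @param seed initialization seed.
#' @return an object of class `lf_discriminator`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  model <- list(params = list(), bn = list(), spec = spec,
                seed = as.integer(seed))
  widths <- c(spec$in_slices,
              spec$channel_base * 2^seq_len(max(spec$n_blocks - 1L, 0L)))
  with_seed(seed, {
    cin <- spec$in_slices
    for (b in seq_len(spec$n_blocks)) {
      cout <- widths[b]
      model <- new_conv(model, paste0("b", b, "c1"), 3L, cin, cout)
      model <- new_conv(model, paste0("b", b, "c2"), 3L, cout, cout)
      cin <- cout
    }
    model <- new_conv(model, "dense1", 1L, cin, spec$dense_units)
    model <- new_conv(model, "dense2", 1L, spec$dense_units, 1L)
  })
  model$widths <- widths
  class(model) <- "lf_discriminator"
  model
}

#' Discriminator forward pass
#'
#' @param model an `lf_discriminator`.
#' @param volume `(H, W, D)` array or `(H, W, D, B)` tensor/node (depth
#'   slices are the input channels).
#' @return vector of `B` scores, each strictly inside (0, 1) (node when
#'   recording).
#' @export
discriminator_forward <- function(model, volume) {
  spec <- model$spec
  x <- volume
  dv <- dim(nval(x))
  if (length(dv) == 3L) x <- if (is_node(x)) ag_reshape(x, c(dv, 1L)) else
    array(nval(x), c(dv, 1L))
  dv <- dim(nval(x))
  if (dv[3] != spec$in_slices)
    stop("volume slice count (", dv[3], ") does not match discriminator (",
         spec$in_slices, ")")
  for (b in seq_len(spec$n_blocks)) {
    x <- ag_relu(conv_fwd(model, paste0("b", b, "c1"), x))
    x <- ag_relu(conv_fwd(model, paste0("b", b, "c2"), x, stride = 2L))
  }
  x <- ag_gap(x)
  x <- ag_relu(conv_fwd(model, "dense1", x, pad = 0L))
  x <- ag_sigmoid(conv_fwd(model, "dense2", x, pad = 0L))
  b <- dim(nval(x))[4]
  ag_reshape(x, b)
}

#' Model parameter checksum
#'
#' Deterministic fingerprint of all parameter values; equal for identically
#' seeded builds.
#' @param model generator or discriminator.
#' @return numeric scalar.
#' @export
param_checksum <- function(model) {
  s <- 0
  for (nm in sort(names(model$params))) {
    v <- model$params[[nm]]$value
    s <- s + sum(v * seq_along(v) %% 97)
  }
  s
}

#' Number of trainable parameters
#' @param model generator or discriminator.
#' @export
param_count <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Save / load model weights
#'
#' Checkpoints embed the architecture spec, creation seed, parameter values,
#' and batch-normalization running statistics; loading restores a model whose
#' predictions are bit-identical to the saved one.
#' @param model generator or discriminator.
#' @param path file path.
#' @export
save_weights <- function(model, path) {
  obj <- list(
    format_version = 1L,
    class = class(model),
    spec = model$spec,
    seed = model$seed,
    values = lapply(model$params, function(p) p$value),
    bn = lapply(model$bn, function(st)
      list(running_mean = st$running_mean, running_var = st$running_var))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- readRDS(path)
  model <- if (obj$class[1] == "lf_generator")
    build_generator(obj$spec, obj$seed) else build_discriminator(obj$spec,
                                                                 obj$seed)
  for (nm in names(obj$values)) model$params[[nm]]$value <- obj$values[[nm]]
  for (nm in names(obj$bn)) {
    model$bn[[nm]]$running_mean <- obj$bn[[nm]]$running_mean
    model$bn[[nm]]$running_var <- obj$bn[[nm]]$running_var
  }
  model
}
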