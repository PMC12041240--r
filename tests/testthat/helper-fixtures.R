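# Shared fixtures, memoized so expensive objects (PSF banks, the toy
# training run) are built once per test session.

.fixtures <- new.env(parent = emptyenv())

# value extractor for possibly-recorded loss outputs
nval <- lfrecon:::nval

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_optics <- function() memo("optics", {
  optical_config(pixels_per_lenslet = 4L, sensor_pixel = 1,
                 z_planes = seq(-6, 6, length.out = 5),
                 kernel_halfwidth = 2L)
})

fix_psf <- function() memo("psf", build_psf(fix_optics()))

fix_bead_pair <- function(seed) {
  memo(paste0("pair", seed), {
    ph <- make_beads(phantom_spec(shape = c(64L, 64L, 5L), seed = seed,
                                  n_beads = 5L, diameter_um = 2.5,
                                  min_separation_um = 8))
    lf <- lf_project(ph$volume, fix_psf())
    list(views = decompose_views(lf), volume = ph$volume, lf = lf,
         particles = ph$particles)
  })
}

# The scaled-down end-to-end training run: 8 bead-phantom pairs, 16x16
# views, 5 depth slices, 200 alternating steps, fixed seed. Learning rates
# are raised to toy scale so a short run can move the network.
fix_toy_fit <- function() memo("toy_fit", {
  pairs <- lapply(11:18, fix_bead_pair)
  gspec <- generator_spec(n_views = 16L, view_size = c(16L, 16L),
                          out_slices = 5L, upsample_factor = 4L,
                          base_channels = 16L)
  dspec <- discriminator_spec(in_slices = 5L, n_blocks = 3L,
                              channel_base = 8L)
  train_gan(pairs, gspec, dspec, loss_config(msssim_levels = 2L),
            train_config(lr_generator = 1e-2, lr_discriminator = 1e-3,
                         epochs = 1000L, batch_size = 2L, seed = 5L,
                         lr_decay_every = 1000L),
            max_steps = 200L)
})

fix_heldout <- function() fix_bead_pair(99L)
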