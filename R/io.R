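# TIFF volume / light-field I/O, PSF and checkpoint containers, and the
# nested run configuration with validation.
#
# Integer images go through the tiff package; 32-bit float data is written
# with a minimal uncompressed baseline-TIFF writer (SampleFormat = IEEE
# float), because the installed TIFF bindings only write integer samples.
# Reading always goes through the tiff package, which handles both.

write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL) # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset placeholder: data is laid out [header][page data+IFD]...
  offset_pos <- 4L
  writeBin(8L, con, size = 4, endian = "little")
  pos <- 8L
  n_pages <- length(pages)
  for (p in seq_len(n_pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    nbytes <- 4L * h * w
    data_off <- pos
    writeBin(as.vector(t(m)), con, size = 4, endian = "little")
    pos <- pos + nbytes
    ifd_off <- pos
    n_tags <- 10L
    writeBin(n_tags, con, size = 2, endian = "little")
    tag <- function(id, type, count, value) {
      writeBin(as.integer(id), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    tag(256, 4, 1, w)            # ImageWidth
    tag(257, 4, 1, h)            # ImageLength
    tag(258, 3, 1, 32)           # BitsPerSample
    tag(259, 3, 1, 1)            # Compression: none
    tag(262, 3, 1, 1)            # Photometric: BlackIsZero
    tag(273, 4, 1, data_off)     # StripOffsets
    tag(277, 3, 1, 1)            # SamplesPerPixel
    tag(278, 4, 1, h)            # RowsPerStrip
    tag(279, 4, 1, nbytes)       # StripByteCounts
    tag(339, 3, 1, 3)            # SampleFormat: IEEE float
    ifd_end <- pos + 2L + n_tags * 12L + 4L
    next_ifd <- if (p < n_pages) {
      nxt <- pages[[p + 1L]]
      ifd_end + 4L * nrow(nxt) * ncol(nxt) # next IFD sits after its data
    } else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    pos <- ifd_end
  }
  # fix the first IFD offset (points at the IFD of page 1, after its data)
  seek(con, offset_pos, rw = "write")
  first_ifd <- 8L + 4L * nrow(pages[[1]]) * ncol(pages[[1]])
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  invisible(path)
}

write_tiff_pages <- function(pages, path, dtype) {
  if (dtype == "float32") return(write_float_tiff(pages, path))
  bits <- if (dtype == "uint8") 8L else 16L
  rng <- range(unlist(lapply(pages, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("integer TIFF output requires data in [0, 1]; got range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  tiff::writeTIFF(if (length(pages) == 1L) pages[[1]] else pages, path,
                  bits.per.sample = bits)
  invisible(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("failed to read TIFF ", path, ": ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  fmt <- attr(pages[[1]], "sample.format")
  max_i <- if (!is.null(fmt) && identical(fmt, "float")) 1
  else if (!is.null(bits) && bits == 8) 255
  else if (!is.null(bits) && bits == 16) 65535
  else 1
  list(pages = pages, bits = bits, max_i = max_i)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else NULL
}

#' Read / write volumes and light fields as TIFF
#'
#' Volumes are stored depth-major (one page per z slice), light fields as a
#' single page. 8/16-bit integer data is scaled to `[0, 1]` on read with the
#' dynamic range recorded in the report metadata; 32-bit float data round
#' trips exactly. Voxel size and lenslet geometry travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param volume an [lf_volume()].
#' @param path TIFF file path.
#' @param dtype `"float32"`, `"uint16"` or `"uint8"`.
#' @return `read_volume` returns an [lf_volume()] with attribute `max_i`;
#'   `write_volume` returns the path.
#' @export
write_volume <- function(volume, path, dtype = "float32") {
  v <- as_volume_array(volume)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  write_tiff_pages(pages, path, dtype)
  write_sidecar(path, list(kind = "volume",
                           voxel_size = if (inherits(volume, "lf_volume"))
                             volume$voxel_size else c(1, 1, 1),
                           dtype = dtype))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  d <- dim(r$pages[[1]])
  v <- array(0, c(d[1], d[2], length(r$pages)))
  for (k in seq_along(r$pages)) v[, , k] <- r$pages[[k]]
  out <- lf_volume(v, if (!is.null(meta$voxel_size)) meta$voxel_size
                   else c(1, 1, 1))
  attr(out, "max_i") <- r$max_i
  out
}

#' @rdname write_volume
#' @param lf an [lf_image()].
#' @export
write_lightfield <- function(lf, path, dtype = "float32") {
  stopifnot(inherits(lf, "lf_image"))
  write_tiff_pages(list(lf$data), path, dtype)
  write_sidecar(path, list(kind = "lightfield",
                           pixels_per_lenslet = lf$pixels_per_lenslet,
                           dtype = dtype))
  invisible(path)
}

#' @rdname write_volume
#' @param pixels_per_lenslet N, when the sidecar is absent.
#' @export
read_lightfield <- function(path, pixels_per_lenslet = NULL) {
  r <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  n <- if (!is.null(meta$pixels_per_lenslet)) meta$pixels_per_lenslet
  else pixels_per_lenslet
  if (is.null(n))
    stop("pixels_per_lenslet unknown: no sidecar next to ", path,
         " and none supplied")
  out <- lf_image(r$pages[[1]], n)
  attr(out, "max_i") <- r$max_i
  out
}

#' Save / load a PSF kernel bank
#'
#' Single-container serialization embedding the kernels and the optical
#' configuration that produced them.
#' @param psf a [build_psf()] bank.
#' @param path destination file.
#' @export
save_psf <- function(psf, path) {
  saveRDS(list(format_version = 1L, kernels = psf$kernels,
               config = unclass(psf$config)), path)
  invisible(path)
}

#' @rdname save_psf
#' @export
load_psf <- function(path) {
  obj <- readRDS(path)
  psf <- structure(list(kernels = obj$kernels,
                        config = structure(obj$config,
                                           class = "optical_config")),
                   class = "lightfield_psf")
  attr(psf, "fft_cache") <- new.env(parent = emptyenv())
  psf
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The nested configuration tree covering optics, phantom, model, loss,
#' training, reconstruction, metric and flow parameters, with the published
#' hyperparameters as defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    optics = list(magnification = 40, numerical_aperture = 0.95,
                  wavelength = 525, medium_index = 1.33,
                  pixels_per_lenslet = 4L, sensor_pixel = 1,
                  z_planes = seq(-8, 8, by = 4),
                  psf_model = "gaussian_defocus", kernel_halfwidth = 2L,
                  psf_sigma_px = 0.6, psf_oversample = 4L),
    phantom = list(type = "beads", shape = c(64L, 64L, 5L),
                   voxel_size = c(1, 1, 1), n_beads = 6L, n_filaments = 8L,
                   diameter_um = 2, min_separation_um = 6,
                   density_ppm = 0.03, frame_time = 0.025),
    generator = list(base_channels = 16L, convs_per_block = 1L,
                     skip_layers = c(1L, 3L),
                     skip_channel_rule = "even_channels",
                     upsample_mode = "combined"),
    discriminator = list(n_blocks = 5L, channel_base = 20L,
                         dense_units = 20L),
    loss = list(alpha = 3, beta = 1, gamma = 0.5, berhu_c = 0.1,
                msssim_levels = 3L, msssim_window = 11L, msssim_sigma = 1.5),
    train = list(lr_generator = 1e-6, lr_discriminator = 1e-7,
                 adam_betas = c(0.9, 0.999), weight_decay = 1e-2,
                 lr_decay_factor = 0.95, lr_decay_every = 5L,
                 batch_size = 2L, epochs = 10L, checkpoint_every = 5L),
    recon = list(n_iterations = 30L, stop_tolerance = 1e-6),
    metrics = list(max_i = NULL, ssim_mode = "global"),
    piv = list(lambda = 0.1, n_iterations = 80L, pyramid_levels = 2L,
               threshold = 0.3, min_distance = 3)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration section ", key, " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  with(cfg$train, {
    if (lr_generator <= 0 || lr_discriminator <= 0)
      stop("learning rates must be positive")
    if (batch_size < 1) stop("batch_size must be >= 1")
  })
  with(cfg$loss, {
    if (alpha < 0 || beta < 0 || gamma < 0) stop("loss weights must be >= 0")
    if (berhu_c <= 0) stop("berhu_c must be > 0")
  })
  if (cfg$optics$numerical_aperture >= cfg$optics$medium_index)
    stop("optics: numerical_aperture must be below medium_index")
  invisible(cfg)
}

#' Load / save a run configuration
#'
#' YAML files are merged over [default_run_config()]; unknown keys are
#' rejected with the offending path, and basic invariants are validated. An
#' empty file yields the full default configuration.
#' @param path YAML file.
#' @export
load_config <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("no such config file: ", path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg configuration list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic configuration fingerprint
#'
#' A stable hash of the serialized configuration, embedded in every artifact
#' a run writes.
#' @param cfg configuration list.
#' @export
config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
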