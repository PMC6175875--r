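#' Dose-symmetric tilt scheme
#'
#' Builds the acquisition-ordered angle list of a dose-symmetric scheme
#' (group size 1): `0, +i, -i, -2i, +2i, +3i, -3i, ...` for increment `i`,
#' covering `[tilt_min, tilt_max]`. The default reproduces a +/-60 degree
#' series with 3 degree increments (41 tilts).
#'
#' @param tilt_min,tilt_max tilt range in degrees, within `[-90, 90]`.
#' @param increment tilt increment in degrees.
#' @param dose_per_tilt electron exposure per tilt, e-/A^2.
#' @return A `tilt_scheme` object with `angles` (acquisition order) and
#'   `dose_per_tilt`.
#' @export
tilt_scheme <- function(tilt_min = -60, tilt_max = 60, increment = 3,
                        dose_per_tilt = 140 / 41) {
  if (tilt_min < -90 || tilt_max > 90 || tilt_min >= tilt_max)
    stop("tilt range must satisfy -90 <= tilt_min < tilt_max <= 90",
         call. = FALSE)
  n_side <- floor(min(-tilt_min, tilt_max) / increment)
  angles <- 0
  for (g in seq_len(n_side)) {
    a <- g * increment
    angles <- if (g %% 2 == 1) c(angles, a, -a) else c(angles, -a, a)
  }
  structure(list(angles = angles, dose_per_tilt = dose_per_tilt,
                 increment = increment),
            class = "tilt_scheme")
}

#' Per-tilt acquisition metadata
#'
#' @param scheme a [tilt_scheme()].
#' @param defocus defocus in micrometres (constant across the series).
#' @return Tibble with `order` (acquisition index), `angle`, `defocus` and
#'   `accumulated_dose` (dose received up to and including each tilt).
#' @export
tilt_metadata <- function(scheme, defocus = 2.5) {
  tibble::tibble(
    order = seq_along(scheme$angles),
    angle = scheme$angles,
    defocus = defocus,
    accumulated_dose = seq_along(scheme$angles) * scheme$dose_per_tilt
  )
}

#' @rdname tilt_metadata
#' @param meta metadata tibble.
#' @param path file path.
#' @export
write_tilt_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' @rdname tilt_metadata
#' @export
read_tilt_metadata <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("order", "angle", "defocus", "accumulated_dose")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("tilt metadata missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

#' Noise model for the simulator
#'
#' White Gaussian detector/shot noise scaled so that the signal-to-noise
#' power ratio within the band below `band_limit` matches `target_snr`.
#'
#' @param target_snr signal/noise power ratio (> 0).
#' @param rng_seed integer seed.
#' @param band_limit band edge in 1/Angstrom within which the SNR is
#'   defined; default half-Nyquist at 4 A voxels.
#' @return A `noise_model` object.
#' @export
noise_model <- function(target_snr = 0.1, rng_seed = 1, band_limit = 1 / 16) {
  if (target_snr <= 0) stop("target_snr must be > 0", call. = FALSE)
  structure(list(target_snr = target_snr, rng_seed = as.integer(rng_seed),
                 band_limit = band_limit),
            class = "noise_model")
}

#' Project a volume at a tilt angle
#'
#' Line integral along the beam (z) after rotating the specimen about the
#' y (tilt) axis.
#'
#' @param map a [density_map()].
#' @param angle_deg tilt angle in degrees.
#' @return Matrix `nx x ny`.
#' @export
project_tilt <- function(map, angle_deg) {
  cpp_tilt_project(as.numeric(map$data), as.integer(dim(map$data)), angle_deg)
}

band_power <- function(image, pixel_size, band_limit) {
  s <- freq_grid_2d(dim(image), pixel_size)
  f <- stats::fft(image)
  sel <- s <= band_limit & s > 0
  mean(Mod(f[sel])^2) / length(image)
}

#' Simulate a tilt series from a phantom
#'
#' For each angle of the scheme (acquisition order): rotate the phantom
#' about the y tilt axis, project along the beam, apply the CTF with a
#' Gaussian envelope, and add white Gaussian noise scaled to the model's
#' target in-band SNR. Defocus is constant within the series, drawn
#' uniformly from `defocus_range` with the noise seed.
#'
#' @param phantom a [density_map()].
#' @param scheme a [tilt_scheme()].
#' @param ctf a [ctf_params()]; its `defocus` is overwritten by the draw
#'   unless `defocus_range` is `NULL`.
#' @param noise a [noise_model()], or `NULL` for noise-free images.
#' @param defocus_range length-2 range in micrometres, or `NULL` to keep
#'   `ctf$defocus`.
#' @param envelope_B Gaussian envelope B-factor in A^2 collapsing detector
#'   and optical envelopes.
#' @param signal_phantom optional [density_map()] whose projections define
#'   the signal power the SNR target refers to. For decorated tubes this
#'   should be the coat-only phantom: the membrane carries two orders of
#'   magnitude more in-band power than the coat, so tying the noise floor
#'   to the total would leave the structure under study with no stated
#'   relation to the SNR. Default: the phantom itself.
#' @return List with `images` (`nx * ny * ntilt`, acquisition order),
#'   `meta` (see [tilt_metadata()]) and `pixel_size`.
#' @export
simulate_tilt_series <- function(phantom, scheme, ctf = NULL, noise = NULL,
                                 defocus_range = c(1.5, 3.5),
                                 envelope_B = 150, signal_phantom = NULL) {
  stopifnot(is_density_map(phantom))
  if (length(scheme$angles) == 0) stop("empty tilt scheme", call. = FALSE)
  d <- dim(phantom$data)
  seed <- if (is.null(noise)) 1L else noise$rng_seed
  with_seed(seed, {
    defocus <- if (is.null(defocus_range)) {
      if (is.null(ctf)) NA_real_ else ctf$defocus
    } else stats::runif(1, defocus_range[1], defocus_range[2])
    if (!is.null(ctf)) ctf$defocus <- defocus
    nt <- length(scheme$angles)
    images <- array(0, c(d[1], d[2], nt))
    for (t in seq_len(nt)) {
      img <- project_tilt(phantom, scheme$angles[t])
      sig_img <- if (is.null(signal_phantom)) img else
        project_tilt(signal_phantom, scheme$angles[t])
      if (!is.null(ctf)) {
        ctf_t <- ctf
        ctf_t$voxel_size <- phantom$voxel_size
        img <- apply_ctf(img, ctf_t, envelope_B)
        if (!is.null(signal_phantom))
          sig_img <- apply_ctf(sig_img, ctf_t, envelope_B)
        else sig_img <- img
      }
      if (!is.null(noise)) {
        sig_p <- band_power(sig_img, phantom$voxel_size, noise$band_limit)
        sigma <- sqrt(sig_p / noise$target_snr)
        img <- img + matrix(stats::rnorm(length(img), 0, sigma),
                            nrow(img), ncol(img))
      }
      images[, , t] <- img
    }
    list(images = images, meta = tilt_metadata(scheme, defocus),
         pixel_size = phantom$voxel_size)
  })
}
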