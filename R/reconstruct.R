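#' Critical-exposure dose filter specification
#'
#' Frequency-dependent exposure filtering: Fourier amplitudes of an image
#' that has accumulated dose `d` are attenuated by
#' `q(k, d) = exp(-d / (2 Nc(k)))` with the critical-exposure curve
#' `Nc(k) = a k^b + c` (`k` in 1/Angstrom, `Nc` in e-/A^2). The default
#' coefficients are the published critical-exposure fit (0.245, -1.665,
#' 2.81).
#'
#' @param a,b,c curve coefficients.
#' @param dose_increment_per_tilt nominal accumulated dose per tilt, e-/A^2.
#' @return A `dose_filter_spec` object.
#' @export
dose_filter_spec <- function(a = 0.245, b = -1.665, c = 2.81,
                             dose_increment_per_tilt = 2.5) {
  structure(list(a = a, b = b, c = c,
                 dose_increment_per_tilt = dose_increment_per_tilt),
            class = "dose_filter_spec")
}

critical_exposure <- function(spec, k) {
  nc <- spec$a * k^spec$b + spec$c   # k = 0 gives Inf -> q = 1 (DC untouched)
  nc
}

dose_attenuation <- function(spec, k, d) {
  exp(-d / (2 * critical_exposure(spec, k)))
}

#' Exposure-filter a tilt image
#'
#' @param image 2D matrix.
#' @param accumulated_dose dose received by this tilt, e-/A^2 (>= 0).
#' @param spec a [dose_filter_spec()].
#' @param pixel_size Angstrom per pixel.
#' @return Filtered image.
#' @export
dose_filter <- function(image, accumulated_dose, spec = dose_filter_spec(),
                        pixel_size = 1) {
  stopifnot(accumulated_dose >= 0)
  if (accumulated_dose == 0) return(image)
  k <- freq_grid_2d(dim(image), pixel_size)
  q <- dose_attenuation(spec, k, accumulated_dose)
  Re(stats::fft(stats::fft(image) * q, inverse = TRUE)) / length(image)
}

#' CTF-correct a tilt image by phase flipping
#'
#' Multiplies Fourier components by the sign of the CTF at the tilt's
#' nominal defocus (`mode = "phase_flip"`), restoring a consistent contrast
#' sign across Thon zones. Applying the flip twice returns the original
#' image (multiplication by a fixed +/-1 pattern). `mode = "none"` is the
#' identity.
#'
#' @param image 2D matrix.
#' @param ctf a [ctf_params()] carrying the tilt's defocus and pixel size.
#' @param mode `"phase_flip"` or `"none"`.
#' @return Corrected image.
#' @export
ctf_correct_tilt <- function(image, ctf, mode = c("phase_flip", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(image)
  s <- freq_grid_2d(dim(image), ctf$voxel_size)
  h <- ctf_1d(ctf, s)
  sgn <- ifelse(h >= 0, 1, -1)
  Re(stats::fft(stats::fft(image) * sgn, inverse = TRUE)) / length(image)
}

# r-weighting of one projection: |kx| ramp along the axis perpendicular to
# the tilt axis, with an optional Hann rolloff above 0.9 Nyquist.
ramp_filter_image <- function(image, rolloff = TRUE) {
  nx <- nrow(image)
  kx <- abs(fft_freq(nx))              # cycles/pixel, Nyquist 0.5
  w <- kx
  if (rolloff) {
    k0 <- 0.9 * 0.5
    hi <- kx > k0
    w[hi] <- kx[hi] * 0.5 * (1 + cos(pi * (kx[hi] - k0) / (0.5 - k0)))
  }
  f <- stats::mvfft(image)
  Re(stats::mvfft(f * w, inverse = TRUE)) / nx
}

#' Weighted back-projection
#'
#' Reconstructs a tomogram from a tilt series: each projection is
#' r-weighted (ramp filter along the axis perpendicular to the y tilt axis)
#' and smeared back along its beam direction with linear interpolation.
#'
#' @param images `nx * ny * ntilt` array, or a simulation result list from
#'   [simulate_tilt_series()].
#' @param angles tilt angles in degrees (ignored when `images` carries
#'   metadata).
#' @param shape output dimensions; `shape[1:2]` must match the projection
#'   size.
#' @param pixel_size Angstrom per pixel of the projections.
#' @param rolloff apply a Hann rolloff above 0.9 Nyquist to the ramp (set
#'   `FALSE` for a pure ramp).
#' @return A [density_map()].
#' @export
wbp_reconstruct <- function(images, angles = NULL, shape, pixel_size = NULL,
                            rolloff = TRUE) {
  if (is.list(images)) {
    angles <- images$meta$angle
    pixel_size <- images$pixel_size
    images <- images$images
  }
  d <- dim(images)
  if (length(d) != 3L) stop("images must be nx x ny x ntilt", call. = FALSE)
  if (length(angles) != d[3])
    stop("need one tilt angle per image", call. = FALSE)
  if (shape[1] != d[1] || shape[2] != d[2])
    stop(sprintf("output shape %dx%d incompatible with projection size %dx%d",
                 shape[1], shape[2], d[1], d[2]), call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- 1
  filtered <- array(0, d)
  for (t in seq_len(d[3]))
    filtered[, , t] <- ramp_filter_image(images[, , t], rolloff)
  vol <- cpp_backproject(as.numeric(filtered), as.integer(d),
                         as.numeric(angles), as.integer(shape))
  # normalization to the inverse-Radon scale
  vol <- vol * pi / (2 * d[3])
  density_map(array(vol, shape), voxel_size = pixel_size)
}

#' Full reconstruction of a simulated tilt series
#'
#' Convenience wrapper: optional exposure filtering (per-tilt accumulated
#' dose from the metadata), optional phase-flip CTF correction at the
#' series' nominal defocus, then weighted back-projection.
#'
#' @param sim result of [simulate_tilt_series()].
#' @param shape output tomogram dimensions.
#' @param ctf a [ctf_params()] template (defocus taken from metadata), or
#'   `NULL` to skip CTF correction.
#' @param dose_spec a [dose_filter_spec()], or `NULL` to skip exposure
#'   filtering.
#' @param rolloff see [wbp_reconstruct()].
#' @return A [density_map()].
#' @export
reconstruct_tomogram <- function(sim, shape, ctf = NULL, dose_spec = NULL,
                                 rolloff = TRUE) {
  images <- sim$images
  for (t in seq_len(dim(images)[3])) {
    img <- images[, , t]
    if (!is.null(dose_spec))
      img <- dose_filter(img, sim$meta$accumulated_dose[t], dose_spec,
                         sim$pixel_size)
    if (!is.null(ctf)) {
      ctf_t <- ctf
      ctf_t$defocus <- sim$meta$defocus[t]
      ctf_t$voxel_size <- sim$pixel_size
      img <- ctf_correct_tilt(img, ctf_t, "phase_flip")
    }
    images[, , t] <- img
  }
  wbp_reconstruct(images, sim$meta$angle, shape, sim$pixel_size, rolloff)
}

#' SIRT-like smoothing filter
#'
#' The iteration-count-equivalent low-pass applied to a weighted
#' back-projection to emulate `n` iterations of SIRT for picking and
#' inspection volumes: radial gain
#' `g_n(k) = (1 - (1 - mu k/k_nyq)^n) / (n mu k/k_nyq)`, which is 1 at DC,
#' bounded by 1 everywhere, and smooths monotonically with `n`.
#'
#' @param map a [density_map()].
#' @param iterations SIRT iteration count the filter emulates (default 50).
#' @param mu relaxation constant of the emulated iteration.
#' @return Filtered [density_map()].
#' @export
sirt_like_filter <- function(map, iterations = 50, mu = 0.1) {
  stopifnot(is_density_map(map), iterations >= 1)
  d <- dim(map$data)
  k <- freq_grid(d, map$voxel_size)
  knyq <- 1 / (2 * map$voxel_size)
  x <- mu * pmin(k / knyq, 1)
  g <- array(1, d)
  pos <- x > 0
  g[pos] <- (1 - (1 - x[pos])^iterations) / (iterations * x[pos])
  out <- Re(ifftn(fftn(map$data) * g))
  as_map_like(out, map)
}
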