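#' Contrast transfer function parameters
#'
#' @param voltage accelerating voltage in kV.
#' @param spherical_aberration Cs in mm.
#' @param amplitude_contrast fraction in `[0, 1]`.
#' @param defocus defocus in micrometres, underfocus positive.
#' @param voxel_size pixel size in Angstrom.
#' @return A `ctf_params` object.
#' @export
ctf_params <- function(voltage = 300, spherical_aberration = 2.7,
                       amplitude_contrast = 0.07, defocus = 2.5,
                       voxel_size = 1.327) {
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must be in [0, 1]", call. = FALSE)
  if (voltage <= 0) stop("voltage must be positive", call. = FALSE)
  structure(list(voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 defocus = defocus, voxel_size = voxel_size),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv accelerating voltage in kV.
#' @return Wavelength in Angstrom (1.969 pm at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  # h / sqrt(2 m e V (1 + eV / (2 m c^2))), in Angstrom
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' 1D contrast transfer function
#'
#' Weak-phase-object CTF,
#' `CTF(s) = -sqrt(1 - w^2) sin(chi) - w cos(chi)` with phase aberration
#' `chi(s) = pi lambda df s^2 - (pi/2) Cs lambda^3 s^4` (underfocus
#' positive).
#'
#' @param ctf a [ctf_params()].
#' @param s spatial frequency in 1/Angstrom (vector ok, `s >= 0`).
#' @return CTF amplitude at each `s`; `-w` at `s = 0`.
#' @export
ctf_1d <- function(ctf, s) {
  lambda <- electron_wavelength(ctf$voltage)
  df_A <- ctf$defocus * 1e4           # um -> A
  cs_A <- ctf$spherical_aberration * 1e7  # mm -> A
  chi <- pi * lambda * df_A * s^2 - (pi / 2) * cs_A * lambda^3 * s^4
  w <- ctf$amplitude_contrast
  -sqrt(1 - w^2) * sin(chi) - w * cos(chi)
}

# CTF evaluated on the (unshifted) 2D frequency grid of an image.
ctf_image <- function(ctf, dims) {
  s <- freq_grid_2d(dims, ctf$voxel_size)
  matrix(ctf_1d(ctf, as.numeric(s)), dims[1], dims[2])
}

# Apply the CTF (optionally with a Gaussian envelope, B in A^2) to an image.
apply_ctf <- function(image, ctf, envelope_B = 0) {
  s <- freq_grid_2d(dim(image), ctf$voxel_size)
  h <- ctf_1d(ctf, s)
  if (envelope_B > 0) h <- h * exp(-envelope_B * s^2 / 4)
  Re(stats::fft(stats::fft(image) * h, inverse = TRUE)) / length(image)
}
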