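# Fourier-domain helpers shared by the simulator, reconstruction, alignment
# and postprocessing. All frequency grids are in the unshifted FFT layout
# (DC at index [1,1,1]); spatial frequency s is in 1/Angstrom.

fft_freq <- function(n) {
  # cycles per sample, matching the layout of stats::fft
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / n
}

#' @noRd
freq_grid <- function(dims, voxel_size = 1) {
  fx <- fft_freq(dims[1]) / voxel_size
  fy <- fft_freq(dims[2]) / voxel_size
  fz <- fft_freq(dims[3]) / voxel_size
  sq <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  sqrt(sq)
}

freq_grid_2d <- function(dims, pixel_size = 1) {
  fx <- fft_freq(dims[1]) / pixel_size
  fy <- fft_freq(dims[2]) / pixel_size
  sqrt(outer(fx^2, fy^2, `+`))
}

fftshift3 <- function(x) {
  d <- dim(x)
  sh <- lapply(d, function(n) {
    c(seq(floor(n / 2) + 1, n), seq_len(floor(n / 2)))
  })
  x[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  sh <- lapply(d, function(n) {
    c(seq(ceiling(n / 2) + 1, n), seq_len(ceiling(n / 2)))
  })
  x[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
}

fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Soft low-pass transfer function: 1 below the cutoff, cosine rolloff over
# `edge_frac` of the cutoff frequency, 0 above.
lowpass_transfer <- function(s, cutoff_A, edge_frac = 0.1) {
  if (!is.finite(cutoff_A) || cutoff_A <= 0) return(array(1, dim(s)))
  s0 <- 1 / cutoff_A
  w <- edge_frac * s0
  h <- array(0, dim(s))
  h[s <= s0] <- 1
  if (w > 0) {
    ramp <- s > s0 & s < s0 + w
    h[ramp] <- 0.5 * (1 + cos(pi * (s[ramp] - s0) / w))
  }
  h
}

#' Low-pass filter a density map
#'
#' Applies a soft (cosine-edged) low-pass at the given resolution.
#'
#' @param map a [density_map()] or 3D array.
#' @param cutoff_A resolution cutoff in Angstrom; `Inf` is a no-op.
#' @param voxel_size required when `map` is a bare array.
#' @param edge_frac width of the cosine edge as a fraction of the cutoff
#'   frequency.
#' @return Same type as `map`.
#' @export
lowpass_map <- function(map, cutoff_A, voxel_size = NULL, edge_frac = 0.1) {
  arr <- if (is_density_map(map)) map$data else map
  vs <- if (is_density_map(map)) map$voxel_size else voxel_size
  if (is.null(vs)) stop("voxel_size required for a bare array", call. = FALSE)
  if (!is.finite(cutoff_A)) return(map)
  s <- freq_grid(dim(arr), vs)
  out <- Re(ifftn(fftn(arr) * lowpass_transfer(s, cutoff_A, edge_frac)))
  if (is_density_map(map)) as_map_like(out, map) else out
}

# Radial shell index (1-based) for every Fourier voxel, shell width of one
# Fourier voxel along the fastest-varying axis of the box.
shell_index <- function(dims, voxel_size = 1) {
  s <- freq_grid(dims, voxel_size)
  d_s <- 1 / (dims[1] * voxel_size)
  pmin(as.integer(round(s / d_s)) + 1L, as.integer(floor(dims[1] / 2)) + 1L)
}
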