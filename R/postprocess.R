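#' Fourier shell correlation
#'
#' Per-shell correlation between two maps:
#' `FSC(shell) = Re sum(F_A conj(F_B)) / sqrt(sum |F_A|^2 sum |F_B|^2)`,
#' shell width one Fourier voxel.
#'
#' @param mapA,mapB [density_map()]s of identical shape and voxel size.
#' @param variant label stored on the curve (`"unmasked"`, `"masked"`,
#'   `"phase_randomized"`, `"corrected"`).
#' @return An `fsc_curve`: a tibble with `shell`, `freq` (1/Angstrom),
#'   `fsc` and `n_terms`, carrying `voxel_size` and `variant` attributes.
#' @export
fsc <- function(mapA, mapB, variant = "unmasked") {
  stopifnot(is_density_map(mapA), is_density_map(mapB))
  if (!all(dim(mapA$data) == dim(mapB$data)))
    stop("maps have mismatched shapes", call. = FALSE)
  d <- dim(mapA$data)
  vs <- mapA$voxel_size
  fa <- fftn(mapA$data); fb <- fftn(mapB$data)
  sh <- shell_index(d, vs)
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2; pb <- Mod(fb)^2
  ns <- max(sh)
  t_num <- vapply(split(num, sh), sum, numeric(1))
  t_pa <- vapply(split(pa, sh), sum, numeric(1))
  t_pb <- vapply(split(pb, sh), sum, numeric(1))
  t_n <- vapply(split(num, sh), length, numeric(1))
  shell <- as.integer(names(t_num))
  d_s <- 1 / (d[1] * vs)
  curve <- tibble::tibble(
    shell = shell,
    freq = (shell - 1) * d_s,
    fsc = ifelse(t_pa * t_pb > 0, t_num / sqrt(t_pa * t_pb), 0),
    n_terms = as.integer(t_n)
  )
  curve <- curve[order(curve$shell), ]
  structure(curve, class = c("fsc_curve", class(curve)),
            voxel_size = vs, variant = variant)
}

#' Resolution at an FSC threshold
#'
#' First crossing of the curve below the threshold, linearly interpolated
#' between shells. If the curve never crosses, the Nyquist resolution is
#' returned with `crossed = FALSE`.
#'
#' @param curve an [fsc()] curve.
#' @param threshold FSC threshold in `(0, 1)` (0.143 gold-standard, 0.5
#'   conservative).
#' @return List with `resolution` (Angstrom), `freq` (1/Angstrom) and
#'   `crossed`.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(threshold > 0, threshold < 1)
  vs <- attr(curve, "voxel_size")
  f <- curve$freq[curve$shell > 1]
  v <- curve$fsc[curve$shell > 1]
  below <- which(v < threshold)
  nyq <- 1 / (2 * vs)
  if (length(below) == 0)
    return(list(resolution = 1 / nyq, freq = nyq, crossed = FALSE))
  i <- below[1]
  if (i == 1)
    return(list(resolution = 1 / max(f[1], 1e-12), freq = f[1],
                crossed = TRUE))
  # interpolate between shells i-1 (above) and i (below)
  f0 <- f[i - 1]; f1 <- f[i]; v0 <- v[i - 1]; v1 <- v[i]
  fc <- f0 + (v0 - threshold) / max(v0 - v1, 1e-12) * (f1 - f0)
  list(resolution = 1 / fc, freq = fc, crossed = TRUE)
}

phase_randomize <- function(map, freq_min, seed = 1) {
  d <- dim(map$data)
  s <- freq_grid(d, map$voxel_size)
  f <- fftn(map$data)
  sel <- s > freq_min
  # draw Hermitian-symmetric random phases (phases of a real noise field)
  # so amplitudes are preserved exactly and the result stays real
  g <- with_seed(seed, fftn(array(stats::rnorm(prod(d)), d)))
  f[sel] <- Mod(f[sel]) * exp(1i * Arg(g[sel]))
  out <- Re(ifftn(f))
  as_map_like(out, map)
}

#' Mask-corrected FSC
#'
#' Computes the masked FSC and removes mask-induced correlation by phase
#' randomization: above `randomization_freq`, the corrected curve is
#' `(FSC_masked - FSC_rand) / (1 - FSC_rand)` where `FSC_rand` is the
#' masked FSC of the phase-randomized half maps; below it, the corrected
#' curve equals the masked one. Phase randomization preserves per-shell
#' amplitude spectra exactly.
#'
#' @param mapA,mapB half maps.
#' @param mask soft real-space mask with values in `[0, 1]`
#'   ([density_map()] or array).
#' @param randomization_freq frequency (1/Angstrom) above which phases are
#'   randomized; default: where the masked FSC first drops below 0.8.
#' @param seed seed for the phase randomization.
#' @return Tibble with `shell`, `freq` and the `unmasked`, `masked`,
#'   `randomized`, `corrected` curves; class `fsc_table`.
#' @export
mask_corrected_fsc <- function(mapA, mapB, mask, randomization_freq = NULL,
                               seed = 1) {
  m <- if (is_density_map(mask)) mask$data else mask
  if (min(m) < 0 || max(m) > 1)
    stop("mask values must lie in [0, 1]", call. = FALSE)
  unmasked <- fsc(mapA, mapB, variant = "unmasked")
  am <- as_map_like(mapA$data * m, mapA)
  bm <- as_map_like(mapB$data * m, mapB)
  masked <- fsc(am, bm, variant = "masked")
  if (is.null(randomization_freq)) {
    idx <- which(masked$fsc < 0.8 & masked$shell > 1)
    randomization_freq <- if (length(idx) == 0)
      0.5 * 1 / (2 * mapA$voxel_size) else masked$freq[idx[1]]
  }
  ar <- phase_randomize(mapA, randomization_freq, seed)
  br <- phase_randomize(mapB, randomization_freq, seed + 1)
  arm <- as_map_like(ar$data * m, mapA)
  brm <- as_map_like(br$data * m, mapB)
  rand <- fsc(arm, brm, variant = "phase_randomized")
  corrected <- masked$fsc
  hi <- masked$freq > randomization_freq
  corrected[hi] <- (masked$fsc[hi] - rand$fsc[hi]) /
    pmax(1 - rand$fsc[hi], 1e-6)
  out <- tibble::tibble(shell = masked$shell, freq = masked$freq,
                        unmasked = unmasked$fsc, masked = masked$fsc,
                        randomized = rand$fsc, corrected = corrected)
  structure(out, class = c("fsc_table", class(out)),
            voxel_size = mapA$voxel_size,
            randomization_freq = randomization_freq)
}

#' Corrected curve of a mask-corrected FSC table
#'
#' @param tab an `fsc_table` from [mask_corrected_fsc()].
#' @return An `fsc_curve` usable with [resolution_at()].
#' @export
corrected_curve <- function(tab) {
  curve <- tibble::tibble(shell = tab$shell, freq = tab$freq,
                          fsc = tab$corrected,
                          n_terms = NA_integer_)
  structure(curve, class = c("fsc_curve", class(curve)),
            voxel_size = attr(tab, "voxel_size"), variant = "corrected")
}

#' Sharpening specification
#'
#' @param bfactor B-factor in Angstrom^2; negative sharpens.
#' @param final_lowpass final low-pass in Angstrom (>= 2 voxel).
#' @return A `sharpen_spec` object.
#' @export
sharpen_spec <- function(bfactor = -350, final_lowpass = 8) {
  structure(list(bfactor = bfactor, final_lowpass = final_lowpass),
            class = "sharpen_spec")
}

#' Sharpen and low-pass filter a map
#'
#' Multiplies Fourier amplitudes by `exp(-B s^2 / 4)` and applies a
#' cosine-edged low-pass at `final_lowpass`.
#'
#' @param map a [density_map()].
#' @param spec a [sharpen_spec()].
#' @return Sharpened [density_map()].
#' @export
sharpen_and_filter <- function(map, spec = sharpen_spec()) {
  stopifnot(is_density_map(map))
  if (spec$final_lowpass < 2 * map$voxel_size)
    stop("final_lowpass below Nyquist", call. = FALSE)
  d <- dim(map$data)
  s <- freq_grid(d, map$voxel_size)
  h <- exp(-spec$bfactor * s^2 / 4) * lowpass_transfer(s, spec$final_lowpass)
  out <- Re(ifftn(fftn(map$data) * h))
  as_map_like(out, map)
}

hann_window3 <- function(n) {
  w1 <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
  outer(outer(w1, w1), w1)
}

#' Local resolution filtering
#'
#' Estimates resolution in overlapping soft-windowed cubic blocks from the
#' two half maps (windowed FSC at `threshold`), interpolates the per-block
#' frequency cutoff to every voxel, and blends band-passed versions of the
#' map so each voxel is filtered at its local resolution.
#'
#' @param map the combined map to filter.
#' @param halfA,halfB half maps used for the local FSC.
#' @param window block size in voxels (default 24; must not exceed the
#'   map).
#' @param stride block stride in voxels (default `window / 2`).
#' @param threshold local FSC threshold.
#' @return List with `map` (locally filtered [density_map()]) and `blocks`
#'   (tibble of block centers and local resolutions).
#' @export
local_filter <- function(map, halfA, halfB, window = 24, stride = NULL,
                         threshold = 0.143) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  if (any(window > d)) stop("window larger than map", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, window %/% 2L)
  vs <- map$voxel_size
  win <- hann_window3(window)
  starts <- function(n) {
    s <- seq(1, max(1, n - window + 1), by = stride)
    if (s[length(s)] != n - window + 1) s <- c(s, n - window + 1)
    unique(s)
  }
  sx <- starts(d[1]); sy <- starts(d[2]); sz <- starts(d[3])
  blocks <- tidyr::expand_grid(x0 = sx, y0 = sy, z0 = sz)
  freqs <- purrr::pmap_dbl(blocks, function(x0, y0, z0) {
    ia <- halfA$data[x0:(x0 + window - 1), y0:(y0 + window - 1),
                     z0:(z0 + window - 1)] * win
    ib <- halfB$data[x0:(x0 + window - 1), y0:(y0 + window - 1),
                     z0:(z0 + window - 1)] * win
    cv <- fsc(density_map(ia, vs), density_map(ib, vs))
    resolution_at(cv, threshold)$freq
  })
  blocks$freq <- freqs
  blocks$resolution <- 1 / freqs
  cx <- sx + (window - 1) / 2; cy <- sy + (window - 1) / 2
  cz <- sz + (window - 1) / 2
  # per-voxel cutoff field by separable linear interpolation of the block grid
  interp1 <- function(centers, n) {
    xs <- seq_len(n)
    lo <- findInterval(xs, centers, all.inside = TRUE)
    hi <- lo + 1
    f <- (xs - centers[lo]) / pmax(centers[hi] - centers[lo], 1e-9)
    f <- pmin(pmax(f, 0), 1)
    list(lo = lo, hi = hi, f = f)
  }
  gx <- interp1(cx, d[1]); gy <- interp1(cy, d[2]); gz <- interp1(cz, d[3])
  fgrid <- array(freqs, c(length(sx), length(sy), length(sz)))
  cutoff <- array(0, d)
  for (k in seq_len(d[3])) {
    w <- list(c(gz$lo[k], 1 - gz$f[k]), c(gz$hi[k], gz$f[k]))
    plane <- matrix(0, d[1], d[2])
    for (p in w) {
      kz <- p[1]; wz <- p[2]
      if (wz == 0) next
      m00 <- fgrid[gx$lo, gy$lo, kz] * (1 - gx$f) * rep(1 - gy$f, each = d[1])
      m10 <- fgrid[gx$hi, gy$lo, kz] * gx$f * rep(1 - gy$f, each = d[1])
      m01 <- fgrid[gx$lo, gy$hi, kz] * (1 - gx$f) * rep(gy$f, each = d[1])
      m11 <- fgrid[gx$hi, gy$hi, kz] * gx$f * rep(gy$f, each = d[1])
      plane <- plane + wz * (m00 + m10 + m01 + m11)
    }
    cutoff[, , k] <- plane
  }
  # blend band-passed maps at the distinct block cutoffs
  levels <- sort(unique(round(freqs, 6)))
  banded <- purrr::map(levels, function(fq) {
    lowpass_map(map, 1 / fq)$data
  })
  out <- array(0, d)
  if (length(levels) == 1) {
    out <- banded[[1]]
  } else {
    li <- findInterval(cutoff, levels, all.inside = TRUE)
    f <- (cutoff - levels[li]) / pmax(levels[li + 1] - levels[li], 1e-12)
    f <- pmin(pmax(f, 0), 1)
    for (lv in seq_along(levels)) {
      wl <- (li == lv) * (1 - f) + (li == lv - 1) * {
        if (lv >= 2) f else 0
      }
      out <- out + wl * banded[[lv]]
    }
  }
  list(map = as_map_like(out, map),
       blocks = tibble::as_tibble(blocks))
}

#' Back-plot an average into tomogram space
#'
#' Pastes a rotated copy of the average at every particle pose
#' (max-compositing), visualizing the recovered lattice.
#'
#' @param table refined particle tibble.
#' @param avg the average [density_map()].
#' @param tomo_shape output dimensions in voxels.
#' @return A [density_map()] of shape `tomo_shape`.
#' @export
backplot <- function(table, avg, tomo_shape) {
  stopifnot(is_density_map(avg))
  vol <- array(0, tomo_shape)
  kd <- dim(avg$data)
  for (i in seq_len(nrow(table))) {
    rinv <- t(euler_matrix(euler(table$phi[i], table$theta[i],
                                 table$psi[i])))
    cpp_stamp_kernel(vol, as.integer(tomo_shape), as.numeric(avg$data),
                     as.integer(kd), as.numeric(t(rinv)),
                     c(table$x[i], table$y[i], table$z[i]), 1.0, TRUE)
  }
  density_map(vol, voxel_size = avg$voxel_size)
}

#' Lattice statistics of a refined particle set
#'
#' Nearest-neighbour distances, a helical (rise, twist) fit from unwrapped
#' cylindrical coordinates around the tube axis, and lattice completeness
#' against the expected site count.
#'
#' @param table refined particles of one tube.
#' @param tube the [tube_model()] providing the axis.
#' @param voxel_size Angstrom per voxel.
#' @param expected_sites expected lattice site count (for completeness),
#'   or `NULL`.
#' @return List with `n`, `nn_dist` (Angstrom vector), `rise`, `twist`
#'   (degrees; `NA` when fewer than 4 particles), `completeness`.
#' @export
lattice_stats <- function(table, tube, voxel_size, expected_sites = NULL) {
  n <- nrow(table)
  xyz <- cbind(table$x, table$y, table$z) * voxel_size
  nn <- if (n >= 2) {
    dmat <- as.matrix(stats::dist(xyz))
    diag(dmat) <- Inf
    apply(dmat, 1, min)
  } else numeric(0)
  if (n < 4) {
    return(list(n = n, nn_dist = nn, rise = NA_real_, twist = NA_real_,
                completeness = if (is.null(expected_sites)) NA_real_
                               else n / expected_sites))
  }
  # cylindrical coordinates about the (resampled) tube axis
  ax <- resample_axis(tube, 0.5)
  pts <- ax$axis_points * voxel_size
  tang <- axis_tangents(pts)
  arc <- polyline_arclength(pts)
  s <- numeric(n); theta <- numeric(n)
  for (i in seq_len(n)) {
    dd <- rowSums((pts - matrix(xyz[i, ], nrow(pts), 3, byrow = TRUE))^2)
    j <- which.min(dd)
    s[i] <- arc[j]
    fr <- perp_frame(tang[j, ])
    v <- xyz[i, ] - pts[j, ]
    theta[i] <- atan2(sum(v * fr$n2), sum(v * fr$n1)) * 180 / pi
  }
  ord <- order(s)
  s <- s[ord]; theta <- theta[ord]
  rise0 <- stats::median(diff(s))
  k <- round((s - s[1]) / max(rise0, 1e-9))
  # unwrap azimuth against the running fit
  dtheta <- wrap180(diff(theta))
  theta_un <- cumsum(c(theta[1], dtheta))
  fit_s <- stats::lm(s ~ k)
  fit_t <- stats::lm(theta_un ~ k)
  completeness <- if (is.null(expected_sites)) NA_real_
                  else n / expected_sites
  list(n = n, nn_dist = nn,
       rise = unname(stats::coef(fit_s)[2]),
       twist = unname(stats::coef(fit_t)[2]),
       completeness = completeness)
}
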