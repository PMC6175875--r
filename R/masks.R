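#' Missing-wedge specification
#'
#' @param tilt_min,tilt_max tilt range in degrees,
#'   `-90 <= tilt_min < tilt_max <= 90`.
#' @return A `wedge_spec` object.
#' @export
wedge_spec <- function(tilt_min = -60, tilt_max = 60) {
  if (!(tilt_min >= -90 && tilt_min < tilt_max && tilt_max <= 90))
    stop("need -90 <= tilt_min < tilt_max <= 90", call. = FALSE)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max),
            class = "wedge_spec")
}

#' Binary missing-wedge Fourier mask
#'
#' For a single y tilt axis, a Fourier component `(kx, ky, kz)` is sampled
#' when some tilt in `[tilt_min, tilt_max]` had its central plane pass
#' through it, i.e. when `atan(-kz / kx)` lies within the tilt range. The
#' mask is Hermitian-symmetric; `ky` plays no role.
#'
#' @param spec a [wedge_spec()].
#' @param shape volume dimensions.
#' @param shifted return the mask in centered (`fftshift`) layout instead
#'   of the native FFT layout.
#' @return Numeric 0/1 array of dimension `shape`.
#' @export
wedge_mask <- function(spec, shape, shifted = FALSE) {
  stopifnot(inherits(spec, "wedge_spec"))
  kx <- fft_freq(shape[1])
  kz <- fft_freq(shape[3])
  # plane-normal tilt angle of each (kx, kz); points on the ky axis are
  # sampled by every tilt
  ang <- outer(kx, kz, function(x, z) {
    a <- atan2(-z * sign(x), abs(x)) * 180 / pi
    a[x == 0 & z != 0] <- 90
    a[x == 0 & z == 0] <- 0
    a
  })
  sel <- ang >= spec$tilt_min & ang <= spec$tilt_max
  # handle the +-90 column for asymmetric ranges reaching -90
  sel[outer(kx == 0, kz != 0) & spec$tilt_min <= -90] <- TRUE
  m <- aperm(array(rep(sel, shape[2]), c(shape[1], shape[3], shape[2])),
             c(1, 3, 2))
  out <- array(as.numeric(m), shape)
  if (shifted) fftshift3(out) else out
}

#' Soft saddle mask for alignment
#'
#' A box-wide soft mask for tube-surface particles, realized as a soft
#' cylindrical band in the reference frame: the tube axis runs along y at
#' `z = -axis_dist` below the box center, and the mask keeps radii between
#' `inner_radius` and `outer_radius` (Angstrom from that axis) — the coat
#' shell — with a cosine edge, excluding most of the membrane below and
#' disordered material above.
#'
#' @param box box size in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param axis_dist distance from the box center down to the tube axis,
#'   Angstrom (coat radius: tube radius + surface offset).
#' @param inner_radius,outer_radius band radii in Angstrom.
#' @param soft_edge cosine edge width in voxels (>= 1).
#' @param central_radius optional radius (Angstrom) of a soft sphere about
#'   the box center intersected with the band, confining the mask to the
#'   central coat subunit.
#' @return A [density_map()] with values in `[0, 1]`.
#' @export
saddle_mask <- function(box, voxel_size, axis_dist, inner_radius,
                        outer_radius, soft_edge = 5,
                        central_radius = NULL) {
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("need 0 < inner_radius < outer_radius", call. = FALSE)
  if (soft_edge < 1) stop("soft_edge must be >= 1", call. = FALSE)
  co <- (seq_len(box) - 1 - box / 2) * voxel_size
  gx <- rep(co, times = box * box)
  gz <- rep(co, each = box * box)
  r <- sqrt(gx^2 + (gz + axis_dist)^2)  # distance to the tube axis, A
  w <- soft_edge * voxel_size
  band <- function(d) {
    v <- numeric(length(d))
    core <- d >= inner_radius & d <= outer_radius
    v[core] <- 1
    lo <- d < inner_radius & d > inner_radius - w
    v[lo] <- 0.5 * (1 + cos(pi * (inner_radius - d[lo]) / w))
    hi <- d > outer_radius & d < outer_radius + w
    v[hi] <- 0.5 * (1 + cos(pi * (d[hi] - outer_radius) / w))
    v
  }
  m <- band(r)
  if (!is.null(central_radius)) {
    # optionally focus the band on the central subunit: a soft sphere
    # about the box center confines scoring to one coat unit, which pins
    # oversampled seeds onto lattice sites instead of the smeared shell
    gy <- rep(rep(co, each = box), times = box)
    rc <- sqrt(gx^2 + gy^2 + gz^2)
    sph <- numeric(length(rc))
    sph[rc <= central_radius] <- 1
    edge <- rc > central_radius & rc < central_radius + w
    sph[edge] <- 0.5 * (1 + cos(pi * (rc[edge] - central_radius) / w))
    m <- m * sph
  }
  density_map(array(m, c(box, box, box)), voxel_size = voxel_size)
}

#' Default saddle-mask parameters for a tube
#'
#' Places the band over the coat shell: inner edge just above the membrane
#' outer leaflet, outer edge past the coat lobes.
#'
#' @param tube_radius membrane midplane radius in Angstrom.
#' @param surface_offset radial offset of the coat layer, Angstrom.
#' @return List with `axis_dist`, `inner_radius`, `outer_radius`,
#'   `soft_edge` for [saddle_mask()] / [run_refinement()].
#' @export
default_mask_spec <- function(tube_radius = 120, surface_offset = 40) {
  # the inner edge sits at the coat-centre radius so that even the soft
  # ramp stays clear of the membrane: any leaflet leakage into the band
  # correlates identically for every particle and drowns the motif term
  list(axis_dist = tube_radius + surface_offset,
       inner_radius = tube_radius + surface_offset,
       outer_radius = tube_radius + 85,
       soft_edge_A = 16, central_radius = 32)
}

#' Smear a reference along the tube axis
#'
#' Averages the map over translations along `axis_direction` across one
#' lattice period (a boxcar convolution), producing a featureless membrane
#' plus coat tube usable as an unbiased starting reference.
#'
#' @param avg a [density_map()].
#' @param axis_direction unit vector of the tube axis in the box frame
#'   (default y, the in-plane convention of the picker).
#' @param period_A boxcar full width in Angstrom (one lattice period).
#' @return Smeared [density_map()].
#' @export
smear_reference <- function(avg, axis_direction = c(0, 1, 0), period_A = 28) {
  stopifnot(is_density_map(avg))
  u <- axis_direction / sqrt(sum(axis_direction^2))
  d <- dim(avg$data)
  fx <- fft_freq(d[1]) / avg$voxel_size
  fy <- fft_freq(d[2]) / avg$voxel_size
  fz <- fft_freq(d[3]) / avg$voxel_size
  ku <- outer(outer(fx * u[1], fy * u[2], `+`), fz * u[3], `+`)
  arg <- pi * period_A * ku
  transfer <- ifelse(abs(arg) < 1e-12, 1, sin(arg) / arg)
  out <- Re(ifftn(fftn(avg$data) * transfer))
  as_map_like(out, avg)
}
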