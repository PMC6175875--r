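#' Helical lattice parameters
#'
#' Geometry of the synthetic coat lattice wrapped around a membrane tube:
#' subunit `k` sits at axial offset `k * rise` and azimuth `k * twist`.
#'
#' @param rise Angstrom per subunit along the tube axis (> 0).
#' @param twist degrees per subunit about the axis.
#' @param tube_radius radius of the membrane midplane in Angstrom.
#' @param n_units number of subunits (>= 1).
#' @param jitter_sd positional noise sd in Angstrom (>= 0).
#' @param angle_jitter_sd orientational noise sd in degrees (>= 0).
#' @return A `lattice_params` object.
#' @export
lattice_params <- function(rise = 28, twist = 24, tube_radius = 120,
                           n_units = 60, jitter_sd = 0, angle_jitter_sd = 0) {
  if (rise <= 0) stop("rise must be > 0", call. = FALSE)
  if (tube_radius <= 0) stop("tube_radius must be > 0", call. = FALSE)
  if (n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  if (jitter_sd < 0 || angle_jitter_sd < 0)
    stop("jitter sds must be >= 0", call. = FALSE)
  structure(list(rise = rise, twist = twist, tube_radius = tube_radius,
                 n_units = as.integer(n_units), jitter_sd = jitter_sd,
                 angle_jitter_sd = angle_jitter_sd),
            class = "lattice_params")
}

#' Build a ground-truth helical lattice on a tube
#'
#' Places `n_units` coat subunits on the tube surface at the coat radius
#' (`tube_radius + surface_offset`), assigning each an orientation whose z
#' axis is the outward membrane normal and whose in-plane direction follows
#' the tube axis (times `direction_flag`). Positional and angular jitter are
#' applied with the given seed.
#'
#' @param lp a [lattice_params()].
#' @param tube a [tube_model()] (axis in voxel coordinates).
#' @param voxel_size Angstrom per voxel, to convert the Angstrom lattice
#'   onto the voxel grid.
#' @param seed RNG seed for the jitter.
#' @param surface_offset radial offset of the coat layer off the membrane
#'   midplane, Angstrom.
#' @param azimuth0 azimuth of the first subunit, degrees.
#' @return A ground-truth particle tibble (see [particle_table()]).
#' @export
build_lattice <- function(lp, tube, voxel_size, seed = 1,
                          surface_offset = 40, azimuth0 = 0) {
  stopifnot(inherits(lp, "lattice_params"), is_tube_model(tube))
  ax <- resample_axis(tube, step = 0.5)
  arclen_A <- polyline_arclength(ax$axis_points) * voxel_size
  total_A <- arclen_A[length(arclen_A)]
  needed <- (lp$n_units - 1) * lp$rise
  if (needed > total_A)
    stop(sprintf(
      "lattice of %d units (%.0f A) exceeds tube length %.0f A; max n_units = %d",
      lp$n_units, needed, total_A, floor(total_A / lp$rise) + 1), call. = FALSE)
  tang <- axis_tangents(ax$axis_points)
  r_coat_vox <- (lp$tube_radius + surface_offset) / voxel_size

  with_seed(seed, {
    rows <- purrr::map(seq_len(lp$n_units) - 1L, function(k) {
      s_k <- k * lp$rise
      i <- findInterval(s_k, arclen_A, all.inside = TRUE)
      f <- (s_k - arclen_A[i]) / max(arclen_A[i + 1] - arclen_A[i], 1e-12)
      cen <- (1 - f) * ax$axis_points[i, ] + f * ax$axis_points[i + 1, ]
      tg <- (1 - f) * tang[i, ] + f * tang[i + 1, ]
      tg <- tg / sqrt(sum(tg^2))
      fr <- perp_frame(tg)
      az <- (azimuth0 + k * lp$twist) * pi / 180
      normal <- cos(az) * fr$n1 + sin(az) * fr$n2
      pos <- cen + r_coat_vox * normal
      if (lp$jitter_sd > 0)
        pos <- pos + stats::rnorm(3, 0, lp$jitter_sd / voxel_size)
      e <- frame_to_euler(normal, tube$direction_flag * tg)
      if (lp$angle_jitter_sd > 0) {
        de <- euler(stats::rnorm(1, 0, lp$angle_jitter_sd),
                    abs(stats::rnorm(1, 0, lp$angle_jitter_sd)),
                    stats::rnorm(1, 0, lp$angle_jitter_sd))
        e <- euler_compose(e, de)
      }
      list(pos = pos, e = e)
    })
    tab <- particle_table(lp$n_units)
    tab$tube_id <- tube$tube_id
    tab$x <- vapply(rows, function(r) r$pos[1], numeric(1))
    tab$y <- vapply(rows, function(r) r$pos[2], numeric(1))
    tab$z <- vapply(rows, function(r) r$pos[3], numeric(1))
    set_euler_cols(tab, purrr::map(rows, "e"))
  })
}

gauss3 <- function(dx, dy, dz, sx, sy = sx, sz = sx) {
  exp(-0.5 * ((dx / sx)^2 + (dy / sy)^2 + (dz / sz)^2))
}

#' Synthetic coat motif
#'
#' A fixed asymmetric multi-lobe density kernel standing in for one coat
#' subunit: three globular lobes arranged like a trimer footprint above the
#' membrane, plus a small elongated lobe on the membrane-proximal side
#' mimicking an inserted amphipathic helix. The kernel frame has +z pointing
#' away from the membrane and y along the tube axis; it has no rotational
#' symmetry, so particle orientations are fully recoverable.
#'
#' @param box kernel box size in voxels (even).
#' @param voxel_size Angstrom per voxel.
#' @return A [density_map()] of the kernel.
#' @export
coat_motif <- function(box = 24, voxel_size = 4) {
  cen <- box / 2
  co <- (seq_len(box) - 1 - cen) * voxel_size  # A, relative to box center
  gx <- rep(co, times = box * box)
  gy <- rep(rep(co, each = box), times = box)
  gz <- rep(co, each = box * box)
  # lobe table: x, y, z (A), sigma (A), weight; offsets chosen to break all
  # in-plane and flip symmetries
  d <- gauss3(gx - 0,  gy - 0,  gz - 8, 7) * 1.0 +
       gauss3(gx - 11, gy - 5,  gz - 4, 6.5) * 0.85 +
       gauss3(gx + 9,  gy - 7,  gz - 2, 6) * 0.9 +
       gauss3(gx - 2,  gy + 9,  gz + 14, 3.5, 9, 3.5) * 0.7  # helix lobe
  density_map(array(d, c(box, box, box)), voxel_size = voxel_size)
}

#' Render a phantom tomogram from ground truth
#'
#' Density = membrane bilayer shell (two concentric Gaussian shells 35 A
#' apart around the tube midplane radius) + the [coat_motif()] stamped at
#' every particle pose.
#'
#' @param truth ground-truth particle tibble.
#' @param tube a [tube_model()].
#' @param map_shape integer length-3 tomogram dimensions in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param motif kernel [density_map()]; default [coat_motif()] at this voxel
#'   size.
#' @param membrane logical, include the bilayer shell.
#' @param bilayer_sep leaflet separation in Angstrom.
#' @param leaflet_sd Gaussian sd of each leaflet in Angstrom.
#' @param membrane_weight peak leaflet density relative to motif lobes.
#' @return A [density_map()] phantom tomogram.
#' @export
render_phantom <- function(truth, tube, map_shape, voxel_size,
                           motif = NULL, membrane = TRUE,
                           bilayer_sep = 35, leaflet_sd = 7,
                           membrane_weight = 0.8) {
  if (is.null(motif)) motif <- coat_motif(voxel_size = voxel_size)
  kd <- dim(motif$data)
  if (any(kd > map_shape))
    stop("motif kernel larger than the tomogram box", call. = FALSE)
  vol <- numeric(prod(map_shape))
  if (membrane) {
    dist_vox <- cpp_polyline_distance(as.integer(map_shape),
                                      t(tube$axis_points))
    d_A <- dist_vox * voxel_size
    r <- tube$radius
    vol <- membrane_weight *
      (exp(-0.5 * ((d_A - (r - bilayer_sep / 2)) / leaflet_sd)^2) +
       exp(-0.5 * ((d_A - (r + bilayer_sep / 2)) / leaflet_sd)^2))
  }
  vol <- array(vol, map_shape)
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      rinv <- t(euler_matrix(euler(truth$phi[i], truth$theta[i], truth$psi[i])))
      cpp_stamp_kernel(vol, as.integer(map_shape),
                       as.numeric(motif$data), as.integer(kd),
                       as.numeric(t(rinv)),
                       c(truth$x[i], truth$y[i], truth$z[i]),
                       1.0, FALSE)
    }
  }
  density_map(vol, voxel_size = voxel_size)
}
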