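#' Picking grid
#'
#' Spacing of the oversampled seed lattice on a tube surface.
#'
#' @param axial_spacing seed spacing along the tube axis, Angstrom.
#' @param azimuthal_spacing seed spacing around the tube (arc length),
#'   Angstrom.
#' @param surface_offset radial shift of the seeds off the membrane
#'   midplane toward the coat layer, Angstrom.
#' @return A `picking_grid` object.
#' @export
picking_grid <- function(axial_spacing = 14, azimuthal_spacing = 32,
                         surface_offset = 40) {
  if (axial_spacing <= 0 || azimuthal_spacing <= 0)
    stop("spacings must be > 0", call. = FALSE)
  structure(list(axial_spacing = axial_spacing,
                 azimuthal_spacing = azimuthal_spacing,
                 surface_offset = surface_offset),
            class = "picking_grid")
}

#' Oversample seeds on a tube surface
#'
#' Resamples the tube axis to uniform arc length and places seeds on rings
#' around it at the coat radius (`radius + surface_offset`). Each seed's
#' orientation maps the reference z axis onto the outward surface normal
#' (so `phi` carries the tube azimuth) with the in-plane direction
#' initialized from the local axis tangent. Seeds falling outside the
#' tomogram are dropped with a message.
#'
#' @param tube a [tube_model()].
#' @param grid a [picking_grid()].
#' @param voxel_size Angstrom per voxel.
#' @param tomo_dims optional tomogram dimensions for bounds filtering.
#' @param tomo_id identifier stamped on the seeds.
#' @return A particle tibble of seeds.
#' @export
oversample_surface <- function(tube, grid, voxel_size, tomo_dims = NULL,
                               tomo_id = "tomo1") {
  stopifnot(is_tube_model(tube), inherits(grid, "picking_grid"))
  ax <- resample_axis(tube, step = grid$axial_spacing / voxel_size)
  pts <- ax$axis_points
  tang <- axis_tangents(pts)
  r_A <- tube$radius + grid$surface_offset
  r_vox <- r_A / voxel_size
  n_azim <- max(1L, as.integer(round(2 * pi * r_A / grid$azimuthal_spacing)))
  az <- seq(0, 2 * pi, length.out = n_azim + 1)[seq_len(n_azim)]

  rows <- purrr::map(seq_len(nrow(pts)), function(i) {
    fr <- perp_frame(tang[i, ])
    purrr::map(az, function(a) {
      normal <- cos(a) * fr$n1 + sin(a) * fr$n2
      pos <- pts[i, ] + r_vox * normal
      e <- frame_to_euler(normal, tube$direction_flag * tang[i, ])
      list(pos = pos, e = e)
    })
  }) |> purrr::flatten()

  tab <- particle_table(length(rows))
  tab$tomo_id <- tomo_id
  tab$tube_id <- tube$tube_id
  tab$x <- vapply(rows, function(r) r$pos[1], numeric(1))
  tab$y <- vapply(rows, function(r) r$pos[2], numeric(1))
  tab$z <- vapply(rows, function(r) r$pos[3], numeric(1))
  tab <- set_euler_cols(tab, purrr::map(rows, "e"))
  if (!is.null(tomo_dims)) {
    inside <- tab$x >= 0 & tab$x <= tomo_dims[1] - 1 &
              tab$y >= 0 & tab$y <= tomo_dims[2] - 1 &
              tab$z >= 0 & tab$z <= tomo_dims[3] - 1
    if (any(!inside))
      message(sum(!inside), " seed(s) outside the tomogram dropped")
    tab <- tab[inside, , drop = FALSE]
  }
  tab
}

#' Extract subvolumes around particles
#'
#' Cuts a cubic box centred (with sub-voxel interpolation) on each particle
#' position. Particles whose box would extend beyond the tomogram are
#' skipped and flagged in the returned `kept` vector.
#'
#' @param tomo a [density_map()].
#' @param table particle tibble.
#' @param box box size in voxels (even).
#' @return List with `stack` (list of [density_map()] subvolumes), `kept`
#'   (logical flag per input row) and `table` (the kept rows).
#' @export
extract_subvolumes <- function(tomo, table, box) {
  stopifnot(is_density_map(tomo))
  if (box %% 2 != 0) stop("box must be even", call. = FALSE)
  d <- dim(tomo$data)
  if (any(box > d)) stop("box larger than tomogram", call. = FALSE)
  half <- box / 2
  kept <- table$x - half >= -0.5 & table$x + half <= d[1] - 0.5 &
          table$y - half >= -0.5 & table$y + half <= d[2] - 0.5 &
          table$z - half >= -0.5 & table$z + half <= d[3] - 0.5
  stack <- purrr::map(which(kept), function(i) {
    v <- cpp_extract_box(as.numeric(tomo$data), as.integer(d),
                         c(table$x[i], table$y[i], table$z[i]),
                         as.integer(box), 0)
    density_map(array(v, c(box, box, box)), voxel_size = tomo$voxel_size)
  })
  list(stack = stack, kept = kept, table = table[kept, , drop = FALSE])
}
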