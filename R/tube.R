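#' Tube model
#'
#' A membrane tube described by its axis (an ordered polyline of 0-based
#' voxel coordinates) and radius in Angstrom. `direction_flag` records the
#' agreed lattice direction along the axis (+1 or -1) and is flipped by the
#' per-tube directionality fix during curation.
#'
#' @param axis_points numeric matrix `n x 3` (n >= 2), voxel coordinates.
#' @param radius tube radius in Angstrom (> 0), measured to the membrane
#'   midplane.
#' @param tube_id identifier.
#' @param direction_flag `+1` or `-1`.
#' @return A `tube_model` object.
#' @export
tube_model <- function(axis_points, radius, tube_id = "tube1",
                       direction_flag = 1L) {
  axis_points <- as.matrix(axis_points)
  if (nrow(axis_points) < 2L || ncol(axis_points) != 3L)
    stop("axis_points must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (!direction_flag %in% c(-1L, 1L))
    stop("direction_flag must be +1 or -1", call. = FALSE)
  structure(list(axis_points = unname(axis_points), radius = as.numeric(radius),
                 tube_id = tube_id, direction_flag = as.integer(direction_flag)),
            class = "tube_model")
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf("<tube_model> '%s': %d axis points, radius %.1f A, direction %+d\n",
              x$tube_id, nrow(x$axis_points), x$radius, x$direction_flag))
  invisible(x)
}

is_tube_model <- function(x) inherits(x, "tube_model")

polyline_arclength <- function(pts) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a tube axis to uniform arc length
#'
#' Linear interpolation of the axis polyline at evenly spaced arc lengths;
#' step in voxel units.
#'
#' @param tube a [tube_model()].
#' @param step arc-length step in voxels.
#' @return A new [tube_model()] with a uniformly sampled axis.
#' @export
resample_axis <- function(tube, step) {
  pts <- tube$axis_points
  s <- polyline_arclength(pts)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate axis", call. = FALSE)
  si <- seq(0, total, by = step)
  if (si[length(si)] < total) si <- c(si, total)
  newpts <- vapply(1:3, function(dd) stats::approx(s, pts[, dd], xout = si)$y,
                   numeric(length(si)))
  tube_model(newpts, tube$radius, tube$tube_id, tube$direction_flag)
}

# Unit tangent vectors at each axis point (central differences).
axis_tangents <- function(pts) {
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tang / sqrt(rowSums(tang^2))
}

# Stable frame (normal/binormal pair) perpendicular to a tangent.
perp_frame <- function(tangent) {
  up <- if (abs(tangent[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- up - sum(up * tangent) * tangent
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(tangent[2] * n1[3] - tangent[3] * n1[2],
          tangent[3] * n1[1] - tangent[1] * n1[3],
          tangent[1] * n1[2] - tangent[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

# Orientation whose z-axis is the outward surface normal and whose in-plane
# angle tracks the local tube axis: the reference z maps onto `normal` and
# the reference y onto the tube tangent (projected on the tangent plane).
frame_to_euler <- function(normal, tangent) {
  z <- normal / sqrt(sum(normal^2))
  y <- tangent - sum(tangent * z) * z
  y <- y / sqrt(sum(y^2))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  matrix_euler(cbind(x, y, z))
}

#' Read / write tube models
#'
#' TSV with columns `tube_id`, `radius`, `direction_flag`, `x`, `y`, `z`
#' (one row per axis point, grouped by tube).
#'
#' @param tubes list of [tube_model()] objects.
#' @param path file path.
#' @return A list of tubes for the reader; `path` invisibly for the writer.
#' @export
write_tubes <- function(tubes, path) {
  rows <- purrr::map_dfr(tubes, function(tb) {
    tibble::tibble(tube_id = tb$tube_id, radius = tb$radius,
                   direction_flag = tb$direction_flag,
                   x = tb$axis_points[, 1], y = tb$axis_points[, 2],
                   z = tb$axis_points[, 3])
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tubes
#' @export
read_tubes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("tube_id", "radius", "direction_flag", "x", "y", "z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("tube table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab |>
    dplyr::group_split(.data$tube_id) |>
    purrr::map(function(g) {
      tube_model(cbind(g$x, g$y, g$z), g$radius[1], as.character(g$tube_id[1]),
                 g$direction_flag[1])
    })
}
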