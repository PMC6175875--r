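#' Euler triplets (intrinsic ZYZ)
#'
#' Orientations are parameterized pipeline-wide as intrinsic ZYZ Euler angles
#' in degrees: `phi` about z, `theta` about the new y, `psi` about the new z.
#' The rotation matrix `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)` rotates the
#' reference frame into the particle frame. Triplets are stored normalized to
#' `phi, psi` in `[-180, 180)` and `theta` in `[0, 180]`.
#'
#' @param phi,theta,psi angles in degrees.
#' @return A named numeric vector of class `euler` with components
#'   `phi`, `theta`, `psi`.
#' @export
euler <- function(phi = 0, theta = 0, psi = 0) {
  e <- c(phi = as.numeric(phi), theta = as.numeric(theta), psi = as.numeric(psi))
  if (any(!is.finite(e))) stop("euler angles must be finite", call. = FALSE)
  euler_normalize(structure(e, class = "euler"))
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

euler_normalize <- function(e) {
  phi <- e[["phi"]]; theta <- wrap180(e[["theta"]]); psi <- e[["psi"]]
  if (theta < 0) { # flip into [0, 180] using the ZYZ identity
    theta <- -theta
    phi <- phi + 180
    psi <- psi + 180
  }
  structure(c(phi = wrap180(phi), theta = theta, psi = wrap180(psi)),
            class = "euler")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix of an Euler triplet
#'
#' @param e an [euler()] triplet.
#' @return 3x3 rotation matrix `Rz(phi) Ry(theta) Rz(psi)`.
#' @export
euler_matrix <- function(e) {
  rot_z(e[["phi"]]) %*% rot_y(e[["theta"]]) %*% rot_z(e[["psi"]])
}

#' Euler triplet of a rotation matrix
#'
#' Inverse of [euler_matrix()]; at gimbal lock (`theta` 0 or 180) the
#' in-plane angle is assigned to `psi` and `phi` is set to 0.
#'
#' @param m 3x3 rotation matrix.
#' @return An [euler()] triplet.
#' @export
matrix_euler <- function(m) {
  ct <- max(-1, min(1, m[3, 3]))
  theta <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    # lock: theta 0 -> R == Rz(phi+psi); theta 180 -> R == Ry(180) Rz(psi-phi).
    psi <- if (ct > 0) atan2(m[2, 1], m[1, 1]) * 180 / pi
           else        atan2(m[2, 1], -m[1, 1]) * 180 / pi
    return(euler(0, theta, psi))
  }
  phi <- atan2(m[2, 3], m[1, 3]) * 180 / pi
  psi <- atan2(m[3, 2], -m[3, 1]) * 180 / pi
  euler(phi, theta, psi)
}

#' Compose and invert Euler triplets
#'
#' `euler_compose(e1, e2)` is the triplet of `R(e1) %*% R(e2)` — apply `e2`
#' first, then `e1`, both intrinsic ZYZ. `euler_inverse(e)` satisfies
#' `euler_compose(e, euler_inverse(e)) == euler(0, 0, 0)` within tolerance.
#'
#' @param e1,e2,e [euler()] triplets.
#' @return An [euler()] triplet.
#' @export
euler_compose <- function(e1, e2) {
  matrix_euler(euler_matrix(e1) %*% euler_matrix(e2))
}

#' @rdname euler_compose
#' @export
euler_inverse <- function(e) {
  euler(-e[["psi"]], -e[["theta"]], -e[["phi"]])
}

#' Angular distance between two orientations
#'
#' Geodesic rotation angle (degrees) between the rotations encoded by two
#' triplets; 0 means identical orientation.
#'
#' @param e1,e2 [euler()] triplets.
#' @return Angle in degrees in `[0, 180]`.
#' @export
euler_distance <- function(e1, e2) {
  r <- euler_matrix(e1) %*% t(euler_matrix(e2))
  acos(max(-1, min(1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}

is_multiple_90 <- function(deg, tol = 1e-9) {
  abs(deg / 90 - round(deg / 90)) < tol
}

#' Rotate a density map
#'
#' Rotates `map` by the rotation of `e` about the grid center
#' (voxel `dim/2`): `out(x) = in(R^{-1} (x - c) + c)`. Trilinear
#' interpolation, except that rotations whose matrix is an exact signed
#' permutation (all angles multiples of 90 degrees) dispatch to index
#' remapping and are exact.
#'
#' @param map a [density_map()] (or bare 3D array).
#' @param e an [euler()] triplet.
#' @param fill value used outside the input grid.
#' @return Same type as `map`.
#' @export
rotate_volume <- function(map, e, fill = 0) {
  arr <- if (is_density_map(map)) map$data else map
  d <- dim(arr)
  r <- euler_matrix(e)
  rinv <- t(r)
  if (all(is_multiple_90(c(e[["phi"]], e[["theta"]], e[["psi"]])))) {
    out <- rotate_exact90(arr, round(rinv))
  } else {
    cen <- d / 2
    out <- cpp_affine_resample(as.numeric(arr), as.integer(d),
                               as.numeric(t(rinv)), c(0, 0, 0),
                               cen, cen, fill)
    out <- array(out, d)
  }
  if (is_density_map(map)) as_map_like(out, map) else out
}

# Exact rotation for signed-permutation matrices via index remapping about
# the voxel-grid center c = dim/2 (so even grids map onto themselves).
rotate_exact90 <- function(arr, rinv) {
  d <- dim(arr)
  idx <- lapply(d, function(n) seq_len(n) - 1 - n / 2)
  out <- array(0, d)
  # source index for output (i,j,k): s = rinv %*% (x - c) + c
  gi <- rep(idx[[1]], times = d[2] * d[3])
  gj <- rep(rep(idx[[2]], each = d[1]), times = d[3])
  gk <- rep(idx[[3]], each = d[1] * d[2])
  sx <- rinv[1, 1] * gi + rinv[1, 2] * gj + rinv[1, 3] * gk + d[1] / 2
  sy <- rinv[2, 1] * gi + rinv[2, 2] * gj + rinv[2, 3] * gk + d[2] / 2
  sz <- rinv[3, 1] * gi + rinv[3, 2] * gj + rinv[3, 3] * gk + d[3] / 2
  ok <- sx >= 0 & sx <= d[1] - 1 & sy >= 0 & sy <= d[2] - 1 &
        sz >= 0 & sz <= d[3] - 1
  lin <- sx + d[1] * (sy + d[2] * sz) + 1
  out[ok] <- arr[lin[ok]]
  out
}

#' Translate a density map by a sub-voxel shift
#'
#' `out(x) = in(x - shift)` with trilinear interpolation; `shift` in voxels.
#'
#' @param map a [density_map()] or 3D array.
#' @param shift numeric length-3 shift in voxels.
#' @return Same type as `map`.
#' @export
shift_volume <- function(map, shift) {
  arr <- if (is_density_map(map)) map$data else map
  d <- dim(arr)
  cen <- d / 2
  out <- cpp_affine_resample(as.numeric(arr), as.integer(d),
                             as.numeric(diag(3)), -as.numeric(shift),
                             cen, cen, 0)
  out <- array(out, d)
  if (is_density_map(map)) as_map_like(out, map) else out
}
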