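#' Refinement round parameters
#'
#' One stage of the coarse-to-fine schedule: binning factor, resolution
#' limit, angular sampling and shift limit, mirroring the conventional
#' progression from binned/low-pass/coarse to unbinned/fine.
#'
#' @param binning integer binning factor (>= 1).
#' @param lowpass resolution limit in Angstrom (>= 2 * voxel * binning).
#' @param angular_step angular sampling in degrees.
#' @param cone_range half-angle of the orientation cone searched around the
#'   current orientation, degrees.
#' @param inplane_range half-range of the in-plane scan, degrees.
#' @param shift_limit maximum shift in Angstrom.
#' @param iterations alignment iterations in this round (>= 1).
#' @param box optional unbinned box-size override (voxels) for this round;
#'   coarse rounds can use a smaller window than the final box.
#' @param radial_limit maximum shift component along the particle's surface
#'   normal, Angstrom (`Inf` to disable); tube-surface particles stay on
#'   the coat layer while sliding freely along it.
#' @return A `refinement_round` object.
#' @export
refinement_round <- function(binning, lowpass, angular_step, cone_range,
                             inplane_range, shift_limit, iterations = 1,
                             box = NULL, radial_limit = 12) {
  if (binning < 1) stop("binning must be >= 1", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  structure(list(binning = as.integer(binning), lowpass = lowpass,
                 angular_step = angular_step, cone_range = cone_range,
                 inplane_range = inplane_range, shift_limit = shift_limit,
                 iterations = as.integer(iterations),
                 box = if (is.null(box)) NULL else as.integer(box),
                 radial_limit = radial_limit),
            class = "refinement_round")
}

#' Default desk-scale refinement schedule
#'
#' Three rounds mirroring the usual coarse-to-fine shape at 4 A voxels and
#' a 48-voxel box. The coarse round runs at 8 A voxels (binned 2x) — the
#' same physical scale as a binned-8x stage on ~1.3 A detector pixels —
#' with a 34 A low-pass, 32 A shifts in a reduced 32-voxel window and the
#' orientations held at their membrane-normal priors (translational
#' convergence onto lattice sites; searching orientations against the
#' still-forming reference only lets them random-walk in noise); the
#' middle round opens a 6 degree cone at 3 degree sampling; the final
#' unbinned round samples 1 degree with 7 A shifts and a low-pass floored
#' at 7.4 A (between rounds the low-pass additionally obeys the half-set
#' FSC 0.5 rule, see [run_refinement()]).
#'
#' @return List of [refinement_round()] objects.
#' @export
default_schedule <- function() {
  list(
    refinement_round(binning = 2, lowpass = 34, angular_step = 7,
                     cone_range = 0, inplane_range = 0, shift_limit = 32,
                     iterations = 6, box = 32),
    refinement_round(binning = 2, lowpass = 17, angular_step = 3,
                     cone_range = 6, inplane_range = 6, shift_limit = 16,
                     iterations = 3),
    refinement_round(binning = 1, lowpass = 7.4, angular_step = 1,
                     cone_range = 2, inplane_range = 1, shift_limit = 7,
                     iterations = 1)
  )
}

band_mask <- function(dims, voxel_size, lowpass, wedge = NULL) {
  s <- freq_grid(dims, voxel_size)
  smax <- if (is.finite(lowpass) && lowpass > 0) 1 / lowpass else Inf
  b <- s <= smax & s > 0   # DC excluded from all correlations
  if (!is.null(wedge)) b <- b & (wedge > 0.5)
  b
}

#' Missing-wedge constrained cross-correlation
#'
#' Normalized cross-correlation computed only over the Fourier components
#' sampled in both volumes' wedges and below the low-pass band, after
#' real-space masking. With `shift_limit > 0` the correlation is maximized
#' over translations within the limit and the best shift is returned.
#'
#' @param sub,ref [density_map()]s (or arrays) of identical shape.
#' @param wedge_sub,wedge_ref binary Fourier masks (native FFT layout) or
#'   `NULL` for full coverage.
#' @param mask real-space mask ([density_map()] or array) applied to both,
#'   or `NULL`.
#' @param lowpass resolution band limit in Angstrom (`Inf` for none).
#' @param shift_limit maximum shift in Angstrom (0: correlation at zero
#'   shift only).
#' @param voxel_size required if `sub` is a bare array.
#' @return List with `cc` (in `[-1, 1]`) and `shift` (voxels, length 3).
#' @export
constrained_cc <- function(sub, ref, wedge_sub = NULL, wedge_ref = NULL,
                           mask = NULL, lowpass = Inf, shift_limit = 0,
                           voxel_size = NULL) {
  a <- if (is_density_map(sub)) sub$data else sub
  b <- if (is_density_map(ref)) ref$data else ref
  vs <- if (is_density_map(sub)) sub$voxel_size else voxel_size
  if (is.null(vs)) stop("voxel_size required for bare arrays", call. = FALSE)
  if (!all(dim(a) == dim(b))) stop("sub and ref shapes differ", call. = FALSE)
  m <- if (is.null(mask)) NULL else if (is_density_map(mask)) mask$data else mask
  if (!is.null(m)) {
    # subtract the in-mask mean before masking: otherwise the mask's own
    # shape acts as shared signal and featureless volumes correlate
    # spuriously with any reference (mask-induced correlation)
    a <- (a - sum(a * m) / sum(m)) * m
    b <- (b - sum(b * m) / sum(m)) * m
  }
  band <- band_mask(dim(a), vs, lowpass, wedge_sub)
  if (!is.null(wedge_ref)) band <- band & (wedge_ref > 0.5)
  if (!any(band)) stop("empty wedge overlap", call. = FALSE)
  fa <- fftn(a); fb <- fftn(b)
  prep <- list(fa = fa, band = band,
               norm_a = sqrt(sum(Mod(fa[band])^2)), dims = dim(a), vs = vs)
  cc_against(prep, fb, shift_limit_vox = if (shift_limit > 0)
    shift_limit / vs else 0)
}

# Core of the constrained correlation: `prep` carries the subvolume side.
# `radial_dir`/`radial_limit_vox` optionally restrict the component of the
# shift along a direction (used to keep tube-surface particles from
# sliding off the coat layer radially).
cc_against <- function(prep, fb, shift_limit_vox = 0, radial_dir = NULL,
                       radial_limit_vox = Inf) {
  band <- prep$band
  norm_b <- sqrt(sum(Mod(fb[band])^2))
  denom <- prep$norm_a * norm_b
  if (denom == 0) return(list(cc = 0, shift = c(0, 0, 0)))
  prod <- array(0 + 0i, prep$dims)
  prod[band] <- prep$fa[band] * Conj(fb[band])
  if (shift_limit_vox <= 0) {
    cc <- Re(sum(prod)) / denom
    return(list(cc = cc, shift = c(0, 0, 0)))
  }
  ccmap <- Re(stats::fft(prod, inverse = TRUE)) / denom
  d <- prep$dims
  lim <- shift_limit_vox
  ix <- shift_indices(d[1], lim); iy <- shift_indices(d[2], lim)
  iz <- shift_indices(d[3], lim)
  sub_map <- ccmap[ix$idx, iy$idx, iz$idx, drop = FALSE]
  ok <- outer(outer(ix$off^2, iy$off^2, `+`), iz$off^2, `+`) <= lim^2
  if (!is.null(radial_dir) && is.finite(radial_limit_vox)) {
    rad <- outer(outer(ix$off * radial_dir[1], iy$off * radial_dir[2], `+`),
                 iz$off * radial_dir[3], `+`)
    ok <- ok & abs(rad) <= radial_limit_vox
  }
  sub_map[!ok] <- -Inf
  best <- arrayInd(which.max(sub_map), dim(sub_map))
  shift <- c(ix$off[best[1]], iy$off[best[2]], iz$off[best[3]])
  list(cc = sub_map[best[1], best[2], best[3]], shift = shift)
}

shift_indices <- function(n, lim) {
  k <- min(floor(lim), floor(n / 2) - 1)
  off <- c(0:k, if (k >= 1) -(k:1))
  idx <- ifelse(off >= 0, off + 1, n + off + 1)
  list(idx = idx, off = off)
}

# Cone + in-plane orientation grid around the identity, as euler offsets.
orientation_grid <- function(cone_range, inplane_range, step) {
  deltas <- list()
  thetas <- if (cone_range > 0) seq(0, cone_range, by = step) else 0
  psis <- if (inplane_range > 0)
    seq(-inplane_range, inplane_range, by = step) else 0
  for (th in thetas) {
    azs <- if (th == 0) 0 else {
      naz <- max(1L, ceiling(360 * sin(th * pi / 180) / step))
      seq(0, 360, length.out = naz + 1)[seq_len(naz)]
    }
    for (az in azs) for (ps in psis)
      deltas[[length(deltas) + 1L]] <- euler(az, th, ps - az)
  }
  deltas
}

#' Angular search around a seed orientation
#'
#' Scores every orientation on a cone/in-plane grid around `seed_euler` by
#' rotating the reference to it and evaluating the missing-wedge
#' constrained correlation with shifts. Ties break to the lowest grid
#' index, making the search deterministic.
#'
#' @param sub particle subvolume ([density_map()]).
#' @param ref reference in the canonical frame ([density_map()]).
#' @param seed_euler current orientation ([euler()]).
#' @param round a [refinement_round()] (its `angular_step`, `cone_range`,
#'   `inplane_range`, `shift_limit` and `lowpass` are used).
#' @param wedge_sub Fourier wedge mask of the subvolume (native layout).
#' @param mask real-space mask in the canonical reference frame, rotated to
#'   the seed orientation internally; or `NULL`.
#' @return List with `euler`, `cc`, `shift` (voxels).
#' @export
angular_search <- function(sub, ref, seed_euler, round, wedge_sub = NULL,
                           mask = NULL) {
  stopifnot(is_density_map(sub), is_density_map(ref))
  vs <- sub$voxel_size
  m_rot <- if (is.null(mask)) NULL else rotate_volume(mask, seed_euler)$data
  m_sum <- if (is.null(m_rot)) 0 else sum(m_rot)
  a <- sub$data
  if (!is.null(m_rot)) a <- (a - sum(a * m_rot) / m_sum) * m_rot
  band <- band_mask(dim(a), vs, round$lowpass, wedge_sub)
  if (!any(band)) stop("empty wedge overlap", call. = FALSE)
  fa <- fftn(a)
  prep <- list(fa = fa, band = band,
               norm_a = sqrt(sum(Mod(fa[band])^2)), dims = dim(a), vs = vs)
  lim_vox <- round$shift_limit / vs
  radial_limit <- if (is.null(round$radial_limit)) Inf else round$radial_limit
  radial_dir <- as.numeric(euler_matrix(seed_euler)[, 3])
  deltas <- orientation_grid(round$cone_range, round$inplane_range,
                             round$angular_step)
  best <- list(cc = -Inf, shift = c(0, 0, 0), euler = seed_euler)
  for (dl in deltas) {
    trial <- euler_compose(seed_euler, dl)
    b <- rotate_volume(ref$data, trial)
    if (!is.null(m_rot)) b <- (b - sum(b * m_rot) / m_sum) * m_rot
    res <- cc_against(prep, fftn(b), lim_vox, radial_dir,
                      radial_limit / vs)
    if (res$cc > best$cc) best <- list(cc = res$cc, shift = res$shift,
                                       euler = trial)
  }
  best
}

#' Remove converged duplicates
#'
#' Greedy suppression in descending `cc`: the best particle is kept and all
#' others within `min_separation` of a kept particle are dropped. With
#' distinct `cc` values the result does not depend on row order.
#'
#' @param table particle tibble with refined positions and `cc`.
#' @param min_separation minimum allowed separation in Angstrom.
#' @param voxel_size Angstrom per voxel (positions are in voxels).
#' @return The surviving rows.
#' @export
remove_duplicates <- function(table, min_separation, voxel_size = 1) {
  validate_particles(table)
  if (min_separation <= 0 || nrow(table) < 2) return(table)
  xyz <- cbind(table$x, table$y, table$z) * voxel_size
  sc <- table$cc
  sc[is.na(sc)] <- -Inf
  keep <- cpp_greedy_suppress(xyz, sc, min_separation)
  table[keep, , drop = FALSE]
}

#' Fix per-tube lattice directionality
#'
#' Computes a per-tube average and compares it to the global reference
#' under the identity and under a 180 degree in-plane flip; if the flip
#' correlates better, 180 degrees is added to the in-plane angle of every
#' particle in that tube.
#'
#' @param table particle tibble.
#' @param per_tube_avgs named list of per-tube average [density_map()]s
#'   (names = tube ids).
#' @param global_ref the global reference [density_map()].
#' @param mask optional real-space mask.
#' @param lowpass band limit in Angstrom for the comparison.
#' @return List with `table` (in-plane angles adjusted) and `flipped`
#'   (character vector of flipped tube ids).
#' @export
fix_tube_directionality <- function(table, per_tube_avgs, global_ref,
                                    mask = NULL, lowpass = 30) {
  validate_particles(table)
  flip_e <- euler(0, 0, 180)
  ref_flipped <- rotate_volume(global_ref, flip_e)
  flipped <- character(0)
  for (tid in names(per_tube_avgs)) {
    avg <- per_tube_avgs[[tid]]
    cc_id <- constrained_cc(avg, global_ref, mask = mask,
                            lowpass = lowpass)$cc
    cc_fl <- constrained_cc(avg, ref_flipped, mask = mask,
                            lowpass = lowpass)$cc
    if (cc_fl > cc_id) flipped <- c(flipped, tid)
  }
  if (length(flipped) > 0) {
    sel <- table$tube_id %in% flipped
    table$psi[sel] <- wrap180(table$psi[sel] + 180)
  }
  list(table = table, flipped = flipped)
}

#' Azimuth-dependent CC weighting
#'
#' The missing wedge biases raw correlation scores as a function of a
#' particle's azimuth `phi` around the tube. Per tube, a polynomial is fit
#' to `cc` against `phi` and scores are reweighted by the ratio of the fit
#' mean to the fitted value, flattening the azimuthal trend while
#' preserving the CC scale. Tubes with fewer than `degree + 2` particles
#' are skipped with a warning.
#'
#' @param table particle tibble with `cc` and the predictor column filled.
#' @param degree polynomial degree (default 4).
#' @param eps floor applied to the fitted value before division, as a
#'   fraction of the fit mean.
#' @param predictor column holding the azimuthal angle; `"phi"` by
#'   default. For tubes whose axis is not the beam axis the wedge
#'   orientation is predicted by the azimuth about the tube axis rather
#'   than by a single Euler angle; the pipeline stores it as `tube_phi`.
#' @return The table with `cc_weighted` filled.
#' @export
cc_phi_weight <- function(table, degree = 4, eps = 0.05,
                          predictor = "phi") {
  validate_particles(table)
  if (!predictor %in% names(table))
    stop("predictor column '", predictor, "' not found", call. = FALSE)
  out <- table |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::group_modify(function(g, key) {
      # the wedge-orientation bias is invariant under a 180-degree azimuth
      # flip, so the polynomial is fit on the folded angle (one period)
      x <- ((g[[predictor]] + 90) %% 180) - 90
      if (nrow(g) < degree + 2 || length(unique(x)) < degree + 2) {
        warning(sprintf(
          "tube '%s': too few particles (or unique angles) for degree %d, weighting skipped",
          key$tube_id, degree), call. = FALSE)
        g$cc_weighted <- g$cc
        return(g)
      }
      fit <- stats::lm(g$cc ~ stats::poly(x, degree))
      pred <- unname(stats::fitted(fit))
      mu <- mean(pred)
      g$cc_weighted <- unname(g$cc * mu / pmax(pred, eps * abs(mu)))
      g
    }) |>
    dplyr::ungroup()
  out[, union(names(table), "cc_weighted")]
}

#' Threshold curated particles
#'
#' @param table particle tibble with `cc_weighted` filled.
#' @param mode `"percentile_cc_weighted"` (drop the lowest `value`
#'   percent) or `"absolute"` (keep `cc_weighted >= value`).
#' @param value percentile in `[0, 100]` or an absolute score.
#' @return The surviving rows; an error if nothing survives.
#' @export
threshold_particles <- function(table,
                                mode = c("percentile_cc_weighted", "absolute"),
                                value) {
  mode <- match.arg(mode)
  validate_particles(table)
  sc <- table$cc_weighted
  cut <- if (mode == "percentile_cc_weighted")
    stats::quantile(sc, value / 100, na.rm = TRUE, names = FALSE)
  else value
  keep <- !is.na(sc) & sc >= cut
  if (!any(keep))
    stop("threshold removed all particles", call. = FALSE)
  message(sum(!keep), " particle(s) removed by ", mode, " threshold")
  table[keep, , drop = FALSE]
}

# ---- averaging ------------------------------------------------------------

normalize_volume <- function(arr) {
  mu <- mean(arr); s <- stats::sd(arr)
  if (s == 0) arr - mu else (arr - mu) / s
}

#' Wedge-compensated particle average
#'
#' Sums subvolumes rotated into the canonical frame together with their
#' rotated wedge masks, and divides in Fourier space by the accumulated
#' wedge occupancy with a Wiener floor — per-particle missing-wedge
#' compensation.
#'
#' @param tomo tomogram [density_map()] (at the binning the table's
#'   coordinates refer to; positions are divided by `binning`).
#' @param table particle tibble.
#' @param box box size in voxels at this binning.
#' @param wedge a [wedge_spec()] or `NULL` (full coverage).
#' @param binning binning factor relating table coordinates to `tomo`.
#' @param wiener Wiener floor as a fraction of the maximum accumulated
#'   weight.
#' @return List with `map` (the average), `weight` (accumulated Fourier
#'   occupancy, native layout) and `n`.
#' @export
average_particles <- function(tomo, table, box, wedge = NULL, binning = 1,
                              wiener = 0.05) {
  stopifnot(is_density_map(tomo))
  d <- dim(tomo$data)
  fsum <- array(0 + 0i, c(box, box, box))
  wsum <- array(0, c(box, box, box))
  wedge_cent <- if (is.null(wedge)) NULL else
    wedge_mask(wedge, c(box, box, box), shifted = TRUE)
  n_used <- 0L
  for (i in seq_len(nrow(table))) {
    pos <- c(table$x[i], table$y[i], table$z[i]) / binning
    half <- box / 2
    if (any(pos - half < -0.5) ||
        any(pos + half > d - 0.5)) next
    v <- cpp_extract_box(as.numeric(tomo$data), as.integer(d), pos,
                         as.integer(box), 0)
    v <- normalize_volume(array(v, c(box, box, box)))
    inv <- euler_inverse(euler(table$phi[i], table$theta[i], table$psi[i]))
    fsum <- fsum + fftn(rotate_volume(v, inv))
    wsum <- wsum + if (is.null(wedge_cent)) 1 else
      rotate_volume(wedge_cent, inv)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no particles inside the tomogram", call. = FALSE)
  w_native <- if (is.null(wedge_cent)) array(n_used, c(box, box, box))
              else ifftshift3(wsum)
  floor_w <- wiener * max(w_native)
  avg <- Re(ifftn(fsum / pmax(w_native, floor_w)))
  list(map = density_map(avg, voxel_size = tomo$voxel_size),
       weight = w_native, n = n_used)
}

#' Combine half-set averages with Fourier weighting
#'
#' `combined = (F_A + F_B) / (W_A + W_B + eps)` in Fourier space, where the
#' weights are the per-half accumulated Fourier occupancy (wedge and, when
#' tracked, CTF amplitude) from the averaging bookkeeping.
#'
#' @param avgA,avgB half-average [density_map()]s.
#' @param weightA,weightB accumulated weight volumes (native FFT layout);
#'   `NULL` means unit weight.
#' @param wiener small additive constant (absolute).
#' @return Combined [density_map()].
#' @export
combine_halves <- function(avgA, avgB, weightA = NULL, weightB = NULL,
                           wiener = 1e-6) {
  stopifnot(is_density_map(avgA), is_density_map(avgB))
  if (!all(dim(avgA$data) == dim(avgB$data)))
    stop("half maps have mismatched shapes", call. = FALSE)
  d <- dim(avgA$data)
  wa <- if (is.null(weightA)) array(1, d) else weightA
  wb <- if (is.null(weightB)) array(1, d) else weightB
  fa <- fftn(avgA$data)
  fb <- fftn(avgB$data)
  out <- Re(ifftn((fa + fb) / (wa + wb + wiener)))
  as_map_like(out, avgA)
}
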