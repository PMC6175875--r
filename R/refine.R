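# Iterative alignment engine: one round on one particle set with one
# reference, and the half-set refinement driver on top of it.

# One alignment round (possibly several iterations) of `table` against a
# reference built from (or passed into) the round. Positions are in
# full-scale voxels; work happens at round$binning.
# Lattice-phase gauge fixing: a reference built from the particles it
# aligns can place the coat motif anywhere in the box; re-centering its
# masked center of mass after every rebuild pins particle positions onto
# the density maxima instead of an arbitrary common offset.
recenter_reference <- function(ref, mask = NULL, max_shift_vox = 2) {
  w <- ref$data
  if (!is.null(mask)) w <- w * mask$data
  w <- pmax(w, 0)
  if (sum(w) <= 0) return(ref)
  d <- dim(w)
  com <- c(sum(w * rep(seq_len(d[1]) - 1, times = d[2] * d[3])),
           sum(w * rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])),
           sum(w * rep(seq_len(d[3]) - 1, each = d[1] * d[2]))) / sum(w)
  off <- com - d / 2
  # only the tangential (x) and axial (y) lattice phases are gauge
  # freedoms; the radial (z) coordinate is fixed by the tube surface and
  # the mask band is radially asymmetric, so z is never recentered
  off[3] <- 0
  off <- pmin(pmax(off, -max_shift_vox), max_shift_vox)
  if (max(abs(off)) < 0.05) return(ref)
  shift_volume(ref, -off)
}

# Mean density in a small ball (~12 A) around each particle's current
# position; a reference-independent measure of sitting on a coat subunit.
central_density <- function(tomo_b, table_b, vs_b, radius_A = 12) {
  d0 <- dim(tomo_b$data)
  r_ball <- max(2, round(radius_A / vs_b))
  bx <- 2L * r_ball + 2L
  co <- seq_len(bx) - 1 - bx / 2
  cball <- array(sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`)) <= r_ball,
                 c(bx, bx, bx))
  vapply(seq_len(nrow(table_b)), function(i) {
    p <- c(table_b$x[i], table_b$y[i], table_b$z[i])
    if (any(p - bx / 2 < -0.5) || any(p + bx / 2 > d0 - 0.5)) return(NA_real_)
    v <- cpp_extract_box(as.numeric(tomo_b$data), as.integer(d0), p, bx, 0)
    mean(array(v, c(bx, bx, bx))[cball])
  }, numeric(1))
}

# Project an orientation onto the tube-surface manifold at a position:
# z axis = outward normal there, in-plane angle preserved from `current`.
surface_project_euler <- function(current, pos, pts, tang, direction_flag) {
  dd <- rowSums((pts - matrix(pos, nrow(pts), 3, byrow = TRUE))^2)
  j <- which.min(dd)
  v <- pos - pts[j, ]
  v <- v - sum(v * tang[j, ]) * tang[j, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(current)
  geo <- frame_to_euler(v / nv, direction_flag * tang[j, ])
  delta <- euler_matrix(euler_inverse(geo)) %*% euler_matrix(current)
  psi_off <- atan2(delta[2, 1], delta[1, 1]) * 180 / pi
  euler_compose(geo, euler(0, 0, psi_off))
}

align_round <- function(tomo, table, round, wedge = NULL, mask_spec = NULL,
                        box = 48, ref = NULL, smear_period = NULL,
                        update_reference = TRUE, center_reference = TRUE,
                        ref_top_frac = 1, final_rescore = FALSE,
                        tube = NULL, verbose = FALSE) {
  stopifnot(is_density_map(tomo))
  b <- round$binning
  tomo_b <- bin_map(tomo, b)
  box_b <- as.integer((if (is.null(round$box)) box else round$box) / b)
  vs_b <- tomo_b$voxel_size
  wedge_native <- if (is.null(wedge)) NULL else
    wedge_mask(wedge, rep(box_b, 3))
  mask <- NULL; mask_center <- NULL
  if (!is.null(mask_spec)) {
    # the mask edge is physical (Angstrom); convert to this round's voxels
    edge_vox <- if (!is.null(mask_spec$soft_edge_A))
      max(1, mask_spec$soft_edge_A / vs_b)
    else mask_spec$soft_edge
    mask <- saddle_mask(box_b, vs_b, mask_spec$axis_dist,
                        mask_spec$inner_radius, mask_spec$outer_radius,
                        edge_vox, mask_spec$central_radius)
    # gauge fixing always needs the central-subunit region: the full-band
    # center of mass barely responds to the motif position, so centering
    # against it lets the lattice phase drift over iterations
    cr <- if (is.null(mask_spec$central_radius)) 32
          else mask_spec$central_radius
    mask_center <- saddle_mask(box_b, vs_b, mask_spec$axis_dist,
                               mask_spec$inner_radius,
                               mask_spec$outer_radius, edge_vox, cr)
  }
  table_b <- table
  table_b$x <- table$x / b; table_b$y <- table$y / b; table_b$z <- table$z / b
  axis_b <- NULL
  if (!is.null(tube)) {
    # orientations stay constrained to the tube surface: positions carry
    # the azimuth far more precisely than per-particle angular matching
    ax <- resample_axis(tube, 1)
    axis_b <- list(pts = ax$axis_points / b,
                   tang = axis_tangents(ax$axis_points),
                   dir = tube$direction_flag)
  }
  if (is.null(ref)) {
    ref <- average_particles(tomo_b, table, box_b, wedge, binning = b)$map
    if (!is.null(smear_period))
      ref <- smear_reference(ref, c(0, 1, 0), smear_period)
  } else if (identical(ref, "subvolume")) {
    # reference-free bootstrap: one raw subvolume (the particle closest to
    # the tomogram centre), unrotated into the canonical frame; its lattice
    # neighbourhood nucleates the common lattice phase, which the
    # re-centering step then pins to the density maxima
    d0 <- dim(tomo_b$data)
    # choose the seed with the strongest density in a small central ball:
    # a seed sitting on a coat subunit, so the bootstrap reference has a
    # motif at its center rather than empty space between lattice sites
    central <- central_density(tomo_b, table_b, vs_b)
    central[is.na(central)] <- -Inf
    mid <- which.max(central)
    v <- cpp_extract_box(as.numeric(tomo_b$data), as.integer(d0),
                         c(table_b$x[mid], table_b$y[mid], table_b$z[mid]),
                         as.integer(box_b), 0)
    sub0 <- density_map(normalize_volume(array(v, rep(box_b, 3))),
                        voxel_size = vs_b)
    e0 <- euler_inverse(euler(table_b$phi[mid], table_b$theta[mid],
                              table_b$psi[mid]))
    ref <- rotate_volume(sub0, e0)
  }
  cc_hist <- numeric(0)
  weight <- NULL
  for (it in seq_len(round$iterations)) {
    ref_f <- lowpass_map(ref, round$lowpass)
    d <- dim(tomo_b$data)
    for (i in seq_len(nrow(table_b))) {
      pos <- c(table_b$x[i], table_b$y[i], table_b$z[i])
      half <- box_b / 2
      if (any(pos - half < -0.5) || any(pos + half > d - 0.5)) next
      v <- cpp_extract_box(as.numeric(tomo_b$data), as.integer(d), pos,
                           box_b, 0)
      sub <- density_map(normalize_volume(array(v, rep(box_b, 3))),
                         voxel_size = vs_b)
      res <- angular_search(sub, ref_f,
                            euler(table_b$phi[i], table_b$theta[i],
                                  table_b$psi[i]),
                            round, wedge_native, mask)
      table_b$x[i] <- table_b$x[i] + res$shift[1]
      table_b$y[i] <- table_b$y[i] + res$shift[2]
      table_b$z[i] <- table_b$z[i] + res$shift[3]
      e_new <- res$euler
      if (!is.null(axis_b))
        e_new <- surface_project_euler(
          e_new, c(table_b$x[i], table_b$y[i], table_b$z[i]),
          axis_b$pts, axis_b$tang, axis_b$dir)
      table_b$phi[i] <- e_new[["phi"]]
      table_b$theta[i] <- e_new[["theta"]]
      table_b$psi[i] <- e_new[["psi"]]
      table_b$cc[i] <- res$cc
    }
    cc_hist <- c(cc_hist, mean(table_b$cc, na.rm = TRUE))
    if (verbose)
      message(sprintf("  bin %d iteration %d: mean cc %.4f", b, it,
                      cc_hist[length(cc_hist)]))
    full <- table_b
    full$x <- table_b$x * b; full$y <- table_b$y * b; full$z <- table_b$z * b
    if (update_reference || it == round$iterations) {
      # seeded growth: rebuild the reference only from particles that have
      # real density at their box center. The score is independent of the
      # current reference, so particles resting on featureless patches of
      # the coat shell (which correlate well with any smooth reference)
      # cannot capture the average and erase the lattice.
      rebuild <- full
      if (ref_top_frac < 1) {
        cdens <- central_density(tomo_b, table_b, vs_b)
        cut <- stats::quantile(cdens, 1 - ref_top_frac, na.rm = TRUE)
        sel <- !is.na(cdens) & cdens >= cut
        if (sum(sel) >= 3) rebuild <- full[sel, , drop = FALSE]
      }
      acc <- average_particles(tomo_b, rebuild, box_b, wedge, binning = b)
      ref <- acc$map
      weight <- acc$weight
      if (center_reference)
        ref <- recenter_reference(ref, if (is.null(mask_center)) mask
                                        else mask_center)
    }
  }
  if (final_rescore) {
    # re-score every particle against the final reference so the scores
    # used for curation reflect the same (lattice-featured) reference
    ref_f <- lowpass_map(ref, round$lowpass)
    score_round <- round
    score_round$cone_range <- 0; score_round$inplane_range <- 0
    score_round$shift_limit <- 0
    d <- dim(tomo_b$data)
    for (i in seq_len(nrow(table_b))) {
      pos <- c(table_b$x[i], table_b$y[i], table_b$z[i])
      half <- box_b / 2
      if (any(pos - half < -0.5) || any(pos + half > d - 0.5)) next
      v <- cpp_extract_box(as.numeric(tomo_b$data), as.integer(d), pos,
                           box_b, 0)
      sub <- density_map(normalize_volume(array(v, rep(box_b, 3))),
                         voxel_size = vs_b)
      table_b$cc[i] <- angular_search(sub, ref_f,
                                      euler(table_b$phi[i], table_b$theta[i],
                                            table_b$psi[i]),
                                      score_round, wedge_native, mask)$cc
    }
  }
  out <- table_b
  out$x <- table_b$x * b; out$y <- table_b$y * b; out$z <- table_b$z * b
  list(table = out, ref = ref, weight = weight, cc_history = cc_hist)
}

# Azimuth of each particle about the tube axis, degrees in [-180, 180) —
# the wedge-orientation predictor used for CC weighting.
tube_azimuth <- function(table, tube) {
  ax <- resample_axis(tube, 1)
  pts <- ax$axis_points
  tang <- axis_tangents(pts)
  vapply(seq_len(nrow(table)), function(i) {
    p <- c(table$x[i], table$y[i], table$z[i])
    dd <- rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2)
    j <- which.min(dd)
    fr <- perp_frame(tang[j, ])
    v <- p - pts[j, ]
    atan2(sum(v * fr$n2), sum(v * fr$n1)) * 180 / pi
  }, numeric(1))
}

#' Independent half-set refinement
#'
#' Runs the coarse-to-fine schedule separately on half sets A and B, which
#' never share references. Per round and half, all particles are aligned by
#' constrained-correlation angular search and the half average rebuilt with
#' per-particle wedge compensation. Between rounds the next low-pass is
#' floored at the current half-vs-half FSC 0.5 crossing, so no half is ever
#' aligned against frequencies the data do not support. Refinement aborts
#' if the mean correlation of a half decreases three rounds running.
#'
#' @param tomo tomogram [density_map()] (unbinned).
#' @param table curated particle tibble; unassigned particles are split
#'   into halves (stratified by tube) with `seed`.
#' @param schedule list of [refinement_round()]s (e.g.
#'   [default_schedule()]).
#' @param box unbinned box size in voxels.
#' @param wedge a [wedge_spec()] or `NULL`.
#' @param mask_spec saddle-mask parameters: list with `axis_dist`,
#'   `inner_radius`, `outer_radius`, `soft_edge` (see [saddle_mask()]), or
#'   `NULL`.
#' @param seed RNG seed for the half split.
#' @param inter_round_percentile percentage of lowest-scoring particles
#'   dropped from each half between rounds (0 disables).
#' @param tube optional [tube_model()]; when given, orientations are
#'   projected back onto the tube-surface manifold after every update
#'   (normal from the refined position, refined in-plane angle kept).
#' @param verbose log per-iteration mean correlations.
#' @return List with `tableA`, `tableB`, `avgA`, `avgB`, `weightA`,
#'   `weightB`, `fsc` (final half-vs-half [fsc()] curve), `table` (both
#'   halves combined) and `cc_history`.
#' @export
run_refinement <- function(tomo, table, schedule = default_schedule(),
                           box = 48, wedge = wedge_spec(), mask_spec = NULL,
                           seed = 1, inter_round_percentile = 0,
                           tube = NULL, verbose = FALSE) {
  validate_particles(table)
  if (all(table$half_set == "unassigned"))
    table <- split_half_sets(table, seed)
  halves <- list(A = table[table$half_set == "A", , drop = FALSE],
                 B = table[table$half_set == "B", , drop = FALSE])
  refs <- list(A = NULL, B = NULL)
  weights <- list(A = NULL, B = NULL)
  cc_hist <- list(A = numeric(0), B = numeric(0))
  lowpass_fsc <- -Inf   # set after round 1 by the FSC 0.5 rule
  fsc_curve <- NULL
  for (r in seq_along(schedule)) {
    round <- schedule[[r]]
    round$lowpass <- max(round$lowpass, lowpass_fsc,
                         2 * tomo$voxel_size * round$binning)
    if (verbose)
      message(sprintf("round %d: bin %d, low-pass %.1f A", r, round$binning,
                      round$lowpass))
    # refinement scores over the full saddle band: the lattice neighbours
    # in the box rotate rigidly with the particle and their long lever arm
    # sharpens the angular discrimination; the central-sphere confinement
    # is only needed while seeds are still converging positionally
    mask_spec_r <- mask_spec
    if (!is.null(mask_spec_r)) mask_spec_r$central_radius <- NULL
    for (h in c("A", "B")) {
      res <- align_round(tomo, halves[[h]], round, wedge, mask_spec_r, box,
                         ref = NULL, ref_top_frac = 0.5,
                         final_rescore = inter_round_percentile > 0,
                         tube = tube, verbose = verbose)
      halves[[h]] <- res$table
      refs[[h]] <- res$ref
      weights[[h]] <- res$weight
      # round-level mean cc; correlations are only comparable within one
      # low-pass band, so the divergence check uses end-of-round values
      cc_hist[[h]] <- c(cc_hist[[h]], utils::tail(res$cc_history, 1))
      hist_r <- cc_hist[[h]]
      if (length(hist_r) >= 4 &&
          all(diff(utils::tail(hist_r, 4)) < -1e-4))
        stop(sprintf("half %s: mean cc decreasing 3 rounds running; aborting",
                     h), call. = FALSE)
    }
    fsc_curve <- fsc(refs$A, refs$B)
    lowpass_fsc <- resolution_at(fsc_curve, 0.5)$resolution
    if (inter_round_percentile > 0 && r < length(schedule)) {
      # shed the weakest particles before the next (more expensive) round;
      # scores from this round's final reference separate cleanly
      for (h in c("A", "B")) {
        tab_h <- halves[[h]]
        tab_h$cc_weighted <- tab_h$cc
        halves[[h]] <- suppressMessages(
          threshold_particles(tab_h, "percentile_cc_weighted",
                              inter_round_percentile))
      }
    }
  }
  combined <- dplyr::bind_rows(halves$A, halves$B)
  list(tableA = halves$A, tableB = halves$B,
       avgA = refs$A, avgB = refs$B,
       weightA = weights$A, weightB = weights$B,
       fsc = fsc_curve, table = combined, cc_history = cc_hist)
}

#' End-to-end tube alignment pipeline
#'
#' The full desk-scale flow on one tomogram: oversampled surface seeding,
#' a coarse alignment of all seeds against a smeared (featureless) starting
#' reference, duplicate suppression, optional azimuthal CC weighting and
#' thresholding, half-set split and independent refinement through the
#' remaining schedule rounds, and the final weighted combination of the
#' half averages.
#'
#' @param tomo tomogram [density_map()].
#' @param tube a [tube_model()].
#' @param grid a [picking_grid()].
#' @param schedule full schedule; round 1 is the coarse stage run before
#'   curation, later rounds refine the halves.
#' @param box unbinned box size in voxels.
#' @param wedge a [wedge_spec()].
#' @param mask_spec saddle-mask parameter list (see [run_refinement()]);
#'   `NULL` disables masking.
#' @param min_separation duplicate-suppression distance in Angstrom.
#' @param smear_period smear width of the starting reference in Angstrom.
#' @param cc_weight apply [cc_phi_weight()] before thresholding.
#' @param threshold_percentile percentile of `cc_weighted` dropped after
#'   curation (0 keeps everything).
#' @param inter_round_percentile passed to [run_refinement()]; percentage
#'   of lowest-scoring particles dropped per half between rounds.
#' @param seed RNG seed (half split).
#' @param verbose log progress.
#' @return The [run_refinement()] result, plus `seeds` (initial seed
#'   count), `curated` (post-curation table) and `combined_map`.
#' @export
align_tube_pipeline <- function(tomo, tube, grid = picking_grid(),
                                schedule = default_schedule(), box = 48,
                                wedge = wedge_spec(), mask_spec = NULL,
                                min_separation = 40, smear_period = 28,
                                cc_weight = TRUE, threshold_percentile = 70,
                                inter_round_percentile = 40,
                                seed = 1, verbose = FALSE) {
  seeds <- oversample_surface(tube, grid, tomo$voxel_size, dim(tomo$data))
  if (verbose) message(nrow(seeds), " seeds placed")
  coarse <- align_round(tomo, seeds, schedule[[1]], wedge, mask_spec, box,
                        ref = "subvolume", ref_top_frac = 0.3,
                        final_rescore = TRUE, verbose = verbose)
  curated <- remove_duplicates(coarse$table, min_separation, tomo$voxel_size)
  if (verbose) message(nrow(curated), " particles after duplicate removal")
  if (cc_weight) {
    curated$tube_phi <- tube_azimuth(curated, tube)
    curated <- suppressWarnings(cc_phi_weight(curated,
                                              predictor = "tube_phi"))
    if (threshold_percentile > 0)
      curated <- suppressMessages(
        threshold_particles(curated, "percentile_cc_weighted",
                            threshold_percentile))
  }
  res <- run_refinement(tomo, curated, schedule[-1], box, wedge, mask_spec,
                        seed = seed,
                        inter_round_percentile = inter_round_percentile,
                        tube = tube, verbose = verbose)
  res$seeds <- nrow(seeds)
  res$curated <- curated
  res$combined_map <- combine_halves(res$avgA, res$avgB, res$weightA,
                                     res$weightB)
  res
}
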