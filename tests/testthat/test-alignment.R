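test_that("the wedge mask covers the stated angular measure and symmetry", {
  expect_true(all(wedge_mask(wedge_spec(-90, 90), c(16, 16, 16)) == 1))
  d <- c(64, 64, 64)
  wm <- wedge_mask(wedge_spec(-60, 60), d)
  # excluded fraction of in-plane angles is 1/3 (angular measure, sampled
  # on a ring in the xz plane)
  th <- seq(0, 2 * pi, length.out = 1441)[-1441]
  kx <- round(20 * cos(th)); kz <- round(20 * sin(th))
  excl <- 1 - mean(wm[cbind((kx %% 64) + 1, 33, (kz %% 64) + 1)])
  expect_equal(excl, 1 / 3, tolerance = 0.05)
  # Hermitian symmetry: mask(k) == mask(-k)
  set.seed(1)
  for (t in 1:100) {
    i <- sample(0:63, 3)
    j <- (-i) %% 64
    expect_identical(wm[i[1] + 1, i[2] + 1, i[3] + 1],
                     wm[j[1] + 1, j[2] + 1, j[3] + 1])
  }
  expect_error(wedge_spec(-95, 60), "-90")
})

test_that("constrained CC is exact on identity and recovers integer shifts", {
  ref <- coat_motif(32, 4)
  r <- constrained_cc(ref, ref)
  expect_equal(r$cc, 1, tolerance = 1e-6)
  expect_identical(r$shift, c(0, 0, 0))
  sub <- shift_volume(ref, c(3, -2, 1))
  r2 <- constrained_cc(sub, ref, shift_limit = 40, voxel_size = 4)
  expect_equal(r2$shift, c(3, -2, 1))
  expect_error(constrained_cc(ref, coat_motif(16, 4)), "shapes differ")
  expect_error(constrained_cc(ref, ref, lowpass = 1e6), "empty wedge")
})

test_that("constrained CC equals the brute-force masked real-space correlation", {
  # independent oracle: band-filter both volumes in Fourier space, then
  # correlate the real-space voxel series directly
  set.seed(20)
  wm <- wedge_mask(wedge_spec(-60, 60), c(32, 32, 32))
  msk <- saddle_mask(32, 4, 144, 148, 200, 3)
  for (i in 1:20) {
    a <- array(rnorm(32^3), c(32, 32, 32))
    b <- array(rnorm(32^3), c(32, 32, 32))
    got <- constrained_cc(density_map(a, 4), density_map(b, 4),
                          wedge_sub = wm, mask = msk, lowpass = 12)$cc
    band <- tubesta:::band_mask(c(32, 32, 32), 4, 12, wm)
    am <- (a - sum(a * msk$data) / sum(msk$data)) * msk$data
    bm <- (b - sum(b * msk$data) / sum(msk$data)) * msk$data
    af <- stats::fft(am) * band
    bf <- stats::fft(bm) * band
    ar <- Re(stats::fft(af, inverse = TRUE)) / length(af)
    br <- Re(stats::fft(bf, inverse = TRUE)) / length(bf)
    oracle <- sum(ar * br) / sqrt(sum(ar^2) * sum(br^2))
    expect_lt(abs(got - oracle), 1e-6)
  }
})

test_that("wedge-constrained correlation ignores the missing wedge", {
  ref <- coat_motif(32, 4)
  wm <- wedge_mask(wedge_spec(-60, 60), c(32, 32, 32))
  fsub <- stats::fft(ref$data) * wm
  subw <- density_map(Re(stats::fft(fsub, inverse = TRUE)) / length(fsub),
                      voxel_size = 4)
  expect_equal(constrained_cc(subw, ref, wedge_sub = wm)$cc, 1,
               tolerance = 1e-6)
  expect_lt(constrained_cc(subw, ref)$cc, 0.9)
})

test_that("the null distribution of the constrained CC is tight", {
  # white noise against an independent reference: |cc| < 3 / sqrt(N_eff)
  # in 99% of draws
  d <- c(32, 32, 32)
  wm <- wedge_mask(wedge_spec(-60, 60), d)
  band <- tubesta:::band_mask(d, 4, 10, wm)
  n_eff <- sum(band)
  set.seed(99)
  ref <- density_map(array(rnorm(prod(d)), d), 4)
  ccs <- replicate(50, {
    sub <- density_map(array(rnorm(prod(d)), d), 4)
    constrained_cc(sub, ref, wedge_sub = wm, lowpass = 10)$cc
  })
  expect_gte(mean(abs(ccs) < 3 / sqrt(n_eff)), 0.98)
})

test_that("angular search recovers grid-representable rotations exactly", {
  ref <- coat_motif(32, 4)
  rnd <- refinement_round(1, 16, 7, 14, 14, 0, 1)
  seed_e <- euler(20, 70, -40)
  grid_deltas <- tubesta:::orientation_grid(14, 14, 7)
  for (delta in grid_deltas[c(1, 10, 25)]) {
    true_e <- euler_compose(seed_e, delta)
    sub <- rotate_volume(ref, true_e)
    res <- angular_search(sub, ref, seed_e, rnd)
    expect_lt(euler_distance(res$euler, true_e), 1e-3)
    expect_gt(res$cc, 0.99)
  }
  # zero ranges reduce to the constrained CC at the seed orientation
  rnd0 <- refinement_round(1, 16, 7, 0, 0, 0, 1)
  sub <- rotate_volume(ref, seed_e)
  res0 <- angular_search(sub, ref, seed_e, rnd0)
  expect_equal(res0$cc,
               constrained_cc(sub, rotate_volume(ref, seed_e),
                              lowpass = 16)$cc,
               tolerance = 1e-9)
  # the search can only improve on the seed orientation
  sub2 <- rotate_volume(ref, euler_compose(seed_e, euler(0, 5, 3)))
  rnd2 <- refinement_round(1, 16, 7, 14, 14, 0, 1)
  res2 <- angular_search(sub2, ref, seed_e, rnd2)
  cc_seed <- angular_search(sub2, ref, seed_e, rnd0)$cc
  expect_gte(res2$cc, cc_seed)
})

test_that("smearing produces translational symmetry and kills the fundamental", {
  # translation-invariant input is unchanged
  d <- c(24, 24, 24)
  arr <- array(rep(matrix(rnorm(576), 24, 24), each = 1), d)
  inv <- aperm(array(rep(matrix(rnorm(576), 24, 24), 24), c(24, 24, 24)),
               c(1, 3, 2))  # constant along y
  m <- density_map(inv, voxel_size = 4)
  sm <- smear_reference(m, c(0, 1, 0), period_A = 28)
  expect_equal(sm$data, m$data, tolerance = 1e-9)
  # delta -> uniform line segment along the axis
  dl <- array(0, d); dl[13, 13, 13] <- 1
  sm2 <- smear_reference(density_map(dl, 4), c(0, 1, 0), period_A = 32)
  line <- sm2$data[13, , 13]
  expect_gt(sum(line > 0.05), 6)  # spread over ~8 voxels (32 A / 4 A)
  # a period-commensurate boxcar nulls the lattice fundamental
  y <- (0:23) * 4
  lattice_wave <- array(rep(sin(2 * pi * y / 32), each = 24), d)
  sm3 <- smear_reference(density_map(lattice_wave, 4), c(0, 1, 0),
                         period_A = 32)
  core <- 5:20
  expect_lt(stats::var(as.numeric(sm3$data[core, core, core])),
            0.05 * stats::var(as.numeric(lattice_wave[core, core, core])))
})

test_that("duplicate removal matches brute-force survivor sets", {
  brute <- function(tab, min_sep, vs) {
    ord <- order(-tab$cc)
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (j in kept) {
        dd <- sqrt((tab$x[i] - tab$x[j])^2 + (tab$y[i] - tab$y[j])^2 +
                   (tab$z[i] - tab$z[j])^2) * vs
        if (dd < min_sep) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, i)
    }
    sort(kept)
  }
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    tab <- particle_table(n)
    tab$x <- runif(n, 0, 30); tab$y <- runif(n, 0, 30)
    tab$z <- runif(n, 0, 30)
    tab$cc <- sample(seq(0.1, 0.99, length.out = n))  # distinct scores
    min_sep <- runif(1, 5, 40)
    got <- remove_duplicates(tab, min_sep, voxel_size = 1)
    expect_identical(sort(match(paste(got$x, got$y), paste(tab$x, tab$y))),
                     brute(tab, min_sep, 1))
    # row order never matters with distinct scores
    perm <- sample(n)
    got2 <- remove_duplicates(tab[perm, ], min_sep, voxel_size = 1)
    expect_setequal(got2$x, got$x)
  }
  # two coincident records: the better one survives
  tab <- particle_table(2)
  tab$cc <- c(0.8, 0.6)
  out <- remove_duplicates(tab, 10, 1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$cc, 0.8)
  # min_separation 0 is a no-op
  expect_identical(nrow(remove_duplicates(tab, 0, 1)), 2L)
})

test_that("converged seed grids collapse onto the true sites", {
  # 16 seeds all converged near 2 true sites 40 A apart
  tab <- particle_table(16)
  site <- rep(c(0, 40), each = 8)
  set.seed(4)
  tab$x <- site + rnorm(16, 0, 1); tab$y <- rnorm(16, 0, 1)
  tab$z <- rnorm(16, 0, 1)
  tab$cc <- seq(0.5, 0.95, length.out = 16)
  out <- remove_duplicates(tab, 30, voxel_size = 1)
  expect_identical(nrow(out), 2L)
  expect_setequal(round(out$x / 40), c(0, 1))
})

test_that("directionality fixing flips exactly the reversed tubes", {
  ref <- coat_motif(32, 4)
  flipped_ref <- rotate_volume(ref, euler(0, 0, 180))
  tubes <- sprintf("tube%d", 1:8)
  reversed <- c("tube2", "tube5", "tube7")
  avgs <- stats::setNames(lapply(tubes, function(t) {
    if (t %in% reversed) flipped_ref else ref
  }), tubes)
  tab <- particle_table(16)
  tab$tube_id <- rep(tubes, each = 2)
  tab$psi <- 10
  res <- fix_tube_directionality(tab, avgs, ref)
  expect_setequal(res$flipped, reversed)
  expect_true(all(res$table$psi[res$table$tube_id %in% reversed] == -170))
  expect_true(all(res$table$psi[!res$table$tube_id %in% reversed] == 10))
  # idempotent: flipped tubes now match, nothing flips again
  avgs2 <- stats::setNames(rep(list(ref), 8), tubes)
  res2 <- fix_tube_directionality(res$table, avgs2, ref)
  expect_length(res2$flipped, 0)
  expect_identical(res2$table, res$table)
})

test_that("azimuthal CC weighting flattens a planted cos(2 phi) bias", {
  set.seed(8)
  n <- 500
  tab <- particle_table(n)
  tab$phi <- runif(n, -180, 180)
  phi_r <- tab$phi * pi / 180
  tab$cc <- 0.5 + 0.1 * cos(2 * phi_r) + rnorm(n, 0, 0.01)
  before <- abs(stats::cor(tab$cc, cos(2 * phi_r)))
  expect_gt(before, 0.9)
  out <- cc_phi_weight(tab, degree = 4)
  after <- abs(stats::cor(out$cc_weighted, cos(2 * phi_r)))
  expect_lt(after, 0.1)
  # weighting preserves the per-tube mean within 1%
  expect_equal(mean(out$cc_weighted), mean(tab$cc), tolerance = 0.01)
  # constant cc is untouched
  tab2 <- particle_table(50)
  tab2$phi <- runif(50, -180, 180); tab2$cc <- 0.7
  out2 <- cc_phi_weight(tab2, degree = 4)
  expect_equal(out2$cc_weighted, rep(0.7, 50), tolerance = 1e-9)
  # a 3-particle tube is skipped with a warning
  tab3 <- particle_table(3)
  tab3$phi <- c(-10, 20, 50); tab3$cc <- c(0.5, 0.6, 0.7)
  expect_warning(out3 <- cc_phi_weight(tab3, degree = 4), "skipped")
  expect_equal(out3$cc_weighted, out3$cc)
})

test_that("thresholding removes planted outliers and guards degenerate cuts", {
  set.seed(12)
  n <- 200
  tab <- particle_table(n)
  tab$cc_weighted <- rnorm(n, 0.7, 0.02)
  out_idx <- sample(n, 10)
  tab$cc_weighted[out_idx] <- 0.7 - 5 * 0.02 - abs(rnorm(10, 0.05, 0.01))
  kept <- suppressMessages(
    threshold_particles(tab, "percentile_cc_weighted", 25))
  expect_equal(nrow(kept), 150)
  expect_false(any(out_idx %in% match(kept$cc_weighted, tab$cc_weighted)))
  # percentile 0 keeps everything
  expect_equal(
    nrow(suppressMessages(threshold_particles(tab, "percentile_cc_weighted",
                                              0))), n)
  expect_error(
    suppressMessages(threshold_particles(tab, "absolute", 2)), "removed all")
})

test_that("half combination honours the Fourier weighting identities", {
  a <- random_map(16, seed = 1)
  b <- random_map(16, seed = 2)
  # unit weights: plain mean
  comb <- combine_halves(a, b)
  expect_equal(comb$data, (a$data + b$data) / 2, tolerance = 1e-5)
  # zero-weighted empty half drops out
  zero <- density_map(array(0, c(16, 16, 16)), a$voxel_size)
  w0 <- array(0, c(16, 16, 16)); w1 <- array(1, c(16, 16, 16))
  comb2 <- combine_halves(a, zero, w1, w0)
  expect_lt(max(abs(comb2$data - a$data)), 1e-5)
  expect_error(combine_halves(a, random_map(8)), "mismatched")
  # restoration: with |CTF| < 1 weights the combined spectrum exceeds the
  # naive mean's
  s <- tubesta:::freq_grid(c(16, 16, 16), 4)
  ctf_amp <- array(abs(ctf_1d(ctf_params(voxel_size = 4), s)), c(16, 16, 16))
  comb3 <- combine_halves(a, b, ctf_amp, ctf_amp, wiener = 1e-3)
  f3 <- Mod(stats::fft(comb3$data))
  fm <- Mod(stats::fft((a$data + b$data) / 2))
  low_ctf <- ctf_amp < 0.9 & ctf_amp > 0.05
  expect_gt(mean(f3[low_ctf] >= fm[low_ctf] * 0.999), 0.95)
})

test_that("wedge-compensated averaging recovers an isolated particle view", {
  # a taller box so the 48-voxel boxes of bottom-azimuth particles fit
  tb <- tube_model(rbind(c(100, 24, 70), c(100, 176, 70)), radius = 120)
  lp <- lattice_params(rise = 28, twist = 24, tube_radius = 120,
                       n_units = 12)
  truth <- build_lattice(lp, tb, 4, seed = 1)
  ph <- render_phantom(truth, tb, c(200, 200, 140), 4)
  avg <- average_particles(ph, truth, box = 48, wedge = NULL)
  expect_gte(avg$n, nrow(truth) - 1L)
  # oracle: a single-particle render extracted and unrotated
  one <- truth[6, , drop = FALSE]
  ph1 <- render_phantom(one, tb, c(200, 200, 140), 4)
  sub1 <- extract_subvolumes(ph1, one, 48)$stack[[1]]
  oracle <- rotate_volume(sub1, euler_inverse(euler(one$phi, one$theta,
                                                    one$psi)))
  # compare within the central subunit: away from it the average contains
  # the neighbour lattice that the single-particle oracle lacks
  ms <- default_mask_spec()
  msk <- saddle_mask(48, 4, ms$axis_dist, ms$inner_radius, ms$outer_radius,
                     4, central_radius = 32)
  cc <- constrained_cc(avg$map, oracle, mask = msk, lowpass = 16)$cc
  expect_gt(cc, 0.95)
})
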