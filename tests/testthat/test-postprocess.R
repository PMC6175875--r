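test_that("FSC identities: self-correlation, null bound, lowpass transition", {
  a <- random_map(32, seed = 1)
  # self-FSC is 1 in every populated shell
  cv <- fsc(a, a)
  expect_lt(max(abs(cv$fsc - 1)), 1e-9)
  # independent white noise: |FSC| < 3/sqrt(n_shell) in ~99% of shells
  set.seed(5)
  hits <- 0; total <- 0
  for (i in 1:20) {
    m1 <- density_map(array(rnorm(64^3), c(64, 64, 64)), 4)
    m2 <- density_map(array(rnorm(64^3), c(64, 64, 64)), 4)
    cvn <- fsc(m1, m2)
    sel <- cvn$shell > 2
    hits <- hits + sum(abs(cvn$fsc[sel]) < 3 / sqrt(cvn$n_terms[sel]))
    total <- total + sum(sel)
  }
  expect_gt(hits / total, 0.97)
  # map vs its low-passed copy: 1 below the cutoff, ~0 above
  b <- lowpass_map(a, 16, edge_frac = 0)
  cvl <- fsc(a, b)
  s0 <- 1 / 16
  expect_lt(max(abs(cvl$fsc[cvl$freq < s0 * 0.9 & cvl$shell > 1] - 1)), 1e-6)
  expect_lt(max(abs(cvl$fsc[cvl$freq > s0 * 1.2])), 0.05)
  expect_error(fsc(a, random_map(16)), "mismatched")
})

test_that("resolution_at interpolates crossings and is monotone in threshold", {
  a <- random_map(32, seed = 2)
  curve <- fsc(a, a)
  # no crossing: Nyquist with a flag
  r <- resolution_at(curve, 0.143)
  expect_false(r$crossed)
  expect_equal(r$resolution, 2 * a$voxel_size)
  # constructed crossing: replace the curve values
  curve$fsc <- 1 - curve$freq / max(curve$freq)
  r143 <- resolution_at(curve, 0.143)
  r50 <- resolution_at(curve, 0.5)
  expect_true(r143$crossed)
  expect_gte(r50$resolution, r143$resolution)
  # the crossing frequency solves the linear model within half a shell
  f_star <- (1 - 0.143) * max(curve$freq)
  expect_lt(abs(r143$freq - f_star), 0.5 / (32 * 4))
})

test_that("phase randomization preserves per-shell amplitude spectra", {
  a <- random_map(32, seed = 3)
  ar <- tubesta:::phase_randomize(a, freq_min = 0.02, seed = 7)
  sh <- tubesta:::shell_index(dim(a$data), a$voxel_size)
  pa <- tapply(Mod(stats::fft(a$data))^2, sh, sum)
  pr <- tapply(Mod(stats::fft(ar$data))^2, sh, sum)
  expect_equal(as.numeric(pr), as.numeric(pa), tolerance = 1e-9)
})

test_that("mask correction removes mask-induced FSC inflation", {
  set.seed(9)
  d <- c(48, 48, 48)
  signal <- lowpass_map(density_map(array(rnorm(prod(d)), d), 4), 16)$data
  mk <- array(0, d)
  mk[17:32, 17:32, 17:32] <- 1
  mk <- lowpass_map(mk, 40, voxel_size = 4)  # soft edges
  mk <- pmin(pmax(mk, 0), 1)
  # shared noise inflates the high-frequency FSC; a tight mask makes it
  # worse by correlating the halves through the mask edges
  shared <- array(rnorm(prod(d)), d)
  a <- density_map(signal + 0.7 * shared + 0.7 * array(rnorm(prod(d)), d), 4)
  b <- density_map(signal + 0.7 * shared + 0.7 * array(rnorm(prod(d)), d), 4)
  tab <- mask_corrected_fsc(a, b, mk, randomization_freq = 0.04)
  hi <- tab$freq > 0.06
  expect_lt(mean(tab$corrected[hi]), mean(tab$masked[hi]) + 1e-9)
  # with a trivial mask and independent noise the correction is a no-op
  a2 <- density_map(signal + array(rnorm(prod(d)), d), 4)
  b2 <- density_map(signal + array(rnorm(prod(d)), d), 4)
  tab2 <- mask_corrected_fsc(a2, b2, array(1, d), randomization_freq = 0.04)
  expect_lt(mean(abs(tab2$corrected - tab2$masked), na.rm = TRUE), 0.02)
  expect_error(mask_corrected_fsc(a, b, array(2, d)), "\\[0, 1\\]")
})

test_that("sharpening follows exp(-B s^2 / 4) exactly", {
  m <- random_map(40, seed = 4)  # voxel 4 A -> Nyquist 0.125
  # B = -350 at s = 0.1: gain exp(350 * 0.01 / 4)
  sp <- sharpen_spec(bfactor = -350, final_lowpass = 8)
  out <- sharpen_and_filter(m, sp)
  f_in <- stats::fft(m$data); f_out <- stats::fft(out$data)
  s <- tubesta:::freq_grid(dim(m$data), m$voxel_size)
  pick <- which(abs(s - 0.1) < 1e-9 & Mod(f_in) > 1e-9)
  expect_gt(length(pick), 0)
  gain <- Mod(f_out[pick]) / Mod(f_in[pick])
  expect_equal(gain, rep(exp(350 * 0.01 / 4), length(pick)),
               tolerance = 1e-6)
  # B = 0 with lowpass at Nyquist: identity within the sub-Nyquist band
  # (the 3D spectrum corners beyond axial Nyquist are rolled off)
  idm <- sharpen_and_filter(m, sharpen_spec(0, 2 * m$voxel_size))
  sub_nyq <- s <= 0.9 / (2 * m$voxel_size) & s > 0
  gain0 <- Mod(stats::fft(idm$data)[sub_nyq]) /
    pmax(Mod(stats::fft(m$data)[sub_nyq]), 1e-12)
  expect_lt(max(abs(gain0 - 1)), 1e-9)
  # default spec carries the -350 sharpening convention
  expect_equal(sharpen_spec()$bfactor, -350)
  expect_error(sharpen_and_filter(m, sharpen_spec(0, 3)), "Nyquist")
})

test_that("local filtering tracks uniform and planted-heterogeneity resolution", {
  set.seed(6)
  d <- c(48, 48, 48)
  signal <- lowpass_map(density_map(array(rnorm(prod(d)), d), 4), 12)$data
  noise_sd <- 0.3
  a <- density_map(signal + noise_sd * array(rnorm(prod(d)), d), 4)
  b <- density_map(signal + noise_sd * array(rnorm(prod(d)), d), 4)
  comb <- density_map((a$data + b$data) / 2, 4)
  lf <- local_filter(comb, a, b, window = 24, stride = 12)
  # uniform SNR: every block's local resolution within ~1 shell of global
  gl <- resolution_at(fsc(a, b), 0.143)$freq
  shell_w <- 1 / (24 * 4)
  expect_lt(max(abs(lf$blocks$freq - gl)), 2.5 * shell_w)
  # noise-boosted octant: local resolution strictly worse there
  a2 <- a; b2 <- b
  a2$data[1:24, 1:24, 1:24] <- signal[1:24, 1:24, 1:24] +
    2 * array(rnorm(24^3), c(24, 24, 24))
  b2$data[1:24, 1:24, 1:24] <- signal[1:24, 1:24, 1:24] +
    2 * array(rnorm(24^3), c(24, 24, 24))
  lf2 <- local_filter(comb, a2, b2, window = 24, stride = 24)
  bad <- lf2$blocks$x0 == 1 & lf2$blocks$y0 == 1 & lf2$blocks$z0 == 1
  expect_lt(lf2$blocks$freq[bad], min(lf2$blocks$freq[!bad]))
  expect_error(local_filter(comb, a, b, window = 64), "larger")
})

test_that("resolution improves monotonically with particle count", {
  # disjoint noisy particle sets of the same motif at n = 50, 200, 800
  set.seed(17)
  mot <- coat_motif(32, 4)
  noise_sd <- 6
  res_at_n <- vapply(c(50, 200, 800), function(n) {
    half <- function(n_h) {
      acc <- array(0, dim(mot$data))
      for (i in seq_len(n_h))
        acc <- acc + mot$data + noise_sd * array(rnorm(length(acc)),
                                                 dim(acc))
      density_map(acc / n_h, mot$voxel_size)
    }
    cv <- fsc(half(n / 2), half(n / 2))
    resolution_at(cv, 0.143)$freq
  }, numeric(1))
  expect_true(all(diff(res_at_n) > 0))  # crossing frequency increases
})

test_that("backplotting reproduces the coat density at the recovered poses", {
  tb <- straight_tube()
  lp <- lattice_params(rise = 28, twist = 24, tube_radius = 120,
                       n_units = 12)
  truth <- build_lattice(lp, tb, 4, seed = 1)
  coat <- render_phantom(truth, tb, c(200, 200, 120), 4, membrane = FALSE)
  # back-plot the motif kernel at the ground-truth poses
  bp <- backplot(truth, coat_motif(24, 4), c(200, 200, 120))
  expect_identical(dim(bp$data), dim(coat$data))
  sel <- coat$data > 0.05 * max(coat$data) | bp$data > 0.05 * max(bp$data)
  cc <- stats::cor(coat$data[sel], bp$data[sel])
  expect_gt(cc, 0.95)
  # empty table gives a zero volume; a single particle pastes the average
  expect_equal(max(abs(backplot(particle_table(0), coat_motif(24, 4),
                                c(32, 32, 32))$data)), 0)
  one <- particle_table(1)
  one$x <- 16; one$y <- 16; one$z <- 16
  bp1 <- backplot(one, coat_motif(16, 4), c(32, 32, 32))
  expect_gt(stats::cor(as.numeric(bp1$data[9:24, 9:24, 9:24]),
                       as.numeric(coat_motif(16, 4)$data)), 0.99)
})

test_that("lattice statistics recover the generator's rise and twist", {
  tb <- straight_tube(10, 190)
  lp <- lattice_params(rise = 28, twist = 24, tube_radius = 120,
                       n_units = 24)
  truth <- build_lattice(lp, tb, 4, seed = 1)
  st <- lattice_stats(truth, tb, 4, expected_sites = 24)
  expect_equal(st$rise, 28, tolerance = 0.01)
  expect_equal(st$twist, 24, tolerance = 0.01)
  expect_equal(st$completeness, 1)
  # nearest-neighbour spacing: successive subunits at the coat radius
  # (160 A) differ by 28 A axially and a 24-degree chord
  nn_expect <- sqrt(28^2 + (2 * 160 * sin(12 * pi / 180))^2)
  expect_equal(stats::median(st$nn_dist), nn_expect, tolerance = 0.03)
  # single particle: no histogram, no error
  st1 <- lattice_stats(truth[1, ], tb, 4)
  expect_length(st1$nn_dist, 0)
  expect_true(is.na(st1$rise))
  # jittered lattices: fitted rise within the standard-error envelope
  set.seed(3)
  rises <- replicate(20, {
    lpj <- lattice_params(rise = 28, twist = 24, tube_radius = 120,
                          n_units = 24, jitter_sd = 2)
    tj <- build_lattice(lpj, tb, 4, seed = sample.int(1e6, 1))
    lattice_stats(tj, tb, 4)$rise
  })
  expect_lt(abs(mean(rises) - 28), 3 * 2 / sqrt(24) + 0.5)
})
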