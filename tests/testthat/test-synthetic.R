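test_that("lattice geometry follows the closed form", {
  tb <- straight_tube(10, 190)
  lp <- lattice_params(rise = 10, twist = 0, tube_radius = 120, n_units = 20)
  tab <- build_lattice(lp, tb, voxel_size = 4, seed = 1)
  expect_equal(nrow(tab), 20L)
  # axial extent (n - 1) * rise
  expect_equal((max(tab$y) - min(tab$y)) * 4, 190, tolerance = 1e-6)
  # twist 0 on a straight axis: one generatrix, equal azimuth
  expect_lt(diff(range(tab$x)), 1e-9)
  expect_lt(diff(range(tab$z)), 1e-9)
  # determinism
  expect_identical(tab, build_lattice(lp, tb, voxel_size = 4, seed = 1))
  # jittered lattices are deterministic too, but differ across seeds
  lpj <- lattice_params(rise = 10, twist = 24, tube_radius = 120,
                        n_units = 20, jitter_sd = 2, angle_jitter_sd = 1)
  j1 <- build_lattice(lpj, tb, 4, seed = 5)
  expect_identical(j1, build_lattice(lpj, tb, 4, seed = 5))
  expect_false(identical(j1, build_lattice(lpj, tb, 4, seed = 6)))
})

test_that("an oversized lattice reports the maximum unit count", {
  tb <- straight_tube(10, 190)
  lp <- lattice_params(rise = 10, n_units = 100, tube_radius = 120)
  expect_error(build_lattice(lp, tb, 4), "max n_units = 73")
})

test_that("lattice orientations encode the membrane normal and axis", {
  tb <- straight_tube()
  lp <- lattice_params(rise = 28, twist = 24, tube_radius = 120,
                       n_units = 15)
  tab <- build_lattice(lp, tb, voxel_size = 4, seed = 1)
  for (i in c(1, 7, 15)) {
    r <- euler_matrix(euler(tab$phi[i], tab$theta[i], tab$psi[i]))
    radial <- c(tab$x[i] - 100, 0, tab$z[i] - 60)
    radial <- radial / sqrt(sum(radial^2))
    expect_equal(as.numeric(r %*% c(0, 0, 1)), radial, tolerance = 1e-9)
    expect_equal(as.numeric(r %*% c(0, 1, 0)), c(0, 1, 0), tolerance = 1e-9)
  }
})

test_that("phantom rendering is linear and membrane-only is axisymmetric", {
  tb <- straight_tube()
  # membrane only: azimuthal variance about the axis vanishes (sample a
  # ring at the membrane midplane radius, 120 A = 30 voxels)
  tb_small <- tube_model(rbind(c(60, 10, 60), c(60, 50, 60)), radius = 120)
  ph0 <- render_phantom(particle_table(0), tb_small, c(120, 60, 120), 4)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- ph0$data[cbind(round(60 + 30 * cos(th)) + 1, 30,
                         round(60 + 30 * sin(th)) + 1)]
  expect_lt(stats::var(ring) / max(ph0$data)^2, 1e-4)
  # mass doubles with two particles
  lp1 <- lattice_params(rise = 28, twist = 0, tube_radius = 120, n_units = 1)
  lp2 <- lattice_params(rise = 28, twist = 0, tube_radius = 120, n_units = 2)
  t1 <- build_lattice(lp1, tb, 4, 1)
  t2 <- build_lattice(lp2, tb, 4, 1)
  m1 <- sum(render_phantom(t1, tb, c(200, 200, 120), 4,
                           membrane = FALSE)$data)
  m2 <- sum(render_phantom(t2, tb, c(200, 200, 120), 4,
                           membrane = FALSE)$data)
  expect_equal(m2 / m1, 2, tolerance = 1e-3)
  # motif too large for the box errors out
  expect_error(render_phantom(t1, tb, c(16, 16, 16), 4), "larger")
})

test_that("a particle view rotated back by its inverse pose recovers the motif", {
  tb <- straight_tube(60, 190)
  lp <- lattice_params(rise = 28, twist = 24, tube_radius = 120, n_units = 1)
  truth <- build_lattice(lp, tb, voxel_size = 4, seed = 1, azimuth0 = 35)
  ph <- render_phantom(truth, tb, c(200, 200, 120), 4, membrane = FALSE)
  sub <- extract_subvolumes(ph, truth, 24)$stack[[1]]
  rec <- rotate_volume(sub, euler_inverse(euler(truth$phi, truth$theta,
                                                truth$psi)))
  cc <- constrained_cc(rec, coat_motif(24, 4), lowpass = Inf)$cc
  expect_gt(cc, 0.99)
})

test_that("the dose-symmetric scheme and metadata follow the acquisition plan", {
  sch <- tilt_scheme(-60, 60, 3)
  expect_length(sch$angles, 41L)
  expect_identical(sch$angles[1:5], c(0, 3, -3, -6, 6))
  expect_setequal(sch$angles, seq(-60, 60, 3))
  meta <- tilt_metadata(sch)
  # total exposure ~140 e-/A^2 at 140/41 per tilt
  expect_equal(max(meta$accumulated_dose), 140, tolerance = 1e-9)
  expect_error(tilt_scheme(-95, 60), "-90")
})

test_that("the simulator is deterministic and honours the tilt scheme", {
  ph <- random_map(24, seed = 2)
  sch <- tilt_scheme(-60, 60, 30)
  nm <- noise_model(target_snr = 0.2, rng_seed = 9)
  s1 <- simulate_tilt_series(ph, sch, ctf_params(), nm)
  s2 <- simulate_tilt_series(ph, sch, ctf_params(), nm)
  expect_identical(s1$images, s2$images)
  expect_identical(dim(s1$images)[3], 5L)
  expect_true(all(s1$meta$defocus >= 1.5 & s1$meta$defocus <= 3.5))
  expect_error(simulate_tilt_series(ph, list(angles = numeric(0))), "empty")
})

test_that("a noise-free zero-tilt image matches the Fourier-slice oracle", {
  n <- 32
  co <- (seq_len(n) - 1 - n / 2)
  vol <- exp(-(outer(outer((co / 4)^2, (co / 5)^2, `+`), (co / 3)^2, `+`)))
  ph <- density_map(vol, voxel_size = 4)
  sim <- simulate_tilt_series(ph, tilt_scheme(-60, 60, 120), ctf = NULL,
                              noise = NULL, defocus_range = NULL)
  img <- sim$images[, , sim$meta$angle == 0]
  # Fourier-slice theorem: 2D FFT of the projection equals the kz = 0
  # plane of the 3D FFT
  fp <- stats::fft(img)
  f3 <- stats::fft(vol)
  rel <- max(Mod(fp - f3[, , 1])) / max(Mod(f3[, , 1]))
  expect_lt(rel, 1e-3)
})

test_that("the weak-phase CTF matches its closed forms", {
  cp <- ctf_params(defocus = 2.5, amplitude_contrast = 0.07)
  expect_equal(ctf_1d(cp, 0), -0.07)
  cpz <- ctf_params(defocus = 0, spherical_aberration = 0,
                    amplitude_contrast = 0)
  expect_equal(max(abs(ctf_1d(cpz, seq(0, 0.3, 0.01)))), 0)
  # first zero against a brute-force root find vs the chi = pi closed form
  cp0 <- ctf_params(defocus = 2.0, amplitude_contrast = 0)
  sg <- seq(1e-4, 0.1, by = 1e-4)
  v <- ctf_1d(cp0, sg)
  i <- which(diff(sign(v)) != 0)[1]
  root <- stats::uniroot(function(s) ctf_1d(cp0, s), c(sg[i], sg[i + 1]),
                         tol = 1e-12)$root
  lam <- electron_wavelength(300)
  s2 <- Re(polyroot(c(-1, lam * 2e4, -0.5 * 2.7e7 * lam^3)))
  s_star <- sqrt(min(s2[s2 > 0]))
  expect_lt(abs(root - s_star) / s_star, 1e-6)
  expect_error(ctf_params(amplitude_contrast = 1.4), "\\[0, 1\\]")
})
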