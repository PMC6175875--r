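test_that("model-derived maps conserve mass and respect the lowpass default", {
  shape <- c(48, 48, 48)
  m1 <- pseudo_model(rbind(c(96, 96, 96)), weights = 1)
  map1 <- model_to_map(m1, shape, voxel_size = 4, lowpass = 10)
  # radially symmetric kernel, centroid at the stated center
  idx <- which(map1$data > 0.1 * max(map1$data))
  ai <- arrayInd(idx, shape) - 1
  w <- map1$data[idx]
  centroid <- colSums(ai * w) / sum(w) * 4
  expect_equal(as.numeric(centroid), c(96, 96, 96), tolerance = 0.05)
  # weights 1 and 2 integrate in ratio 1:2
  m2 <- pseudo_model(rbind(c(64, 64, 64), c(128, 128, 128)),
                     weights = c(1, 2))
  map2 <- model_to_map(m2, shape, 4, 10)
  half <- map2$data[1:24, 1:24, 1:24]
  other <- map2$data[25:48, 25:48, 25:48]
  expect_equal(sum(other) / sum(half), 2, tolerance = 0.01)
  # centers outside the box are listed
  expect_error(model_to_map(pseudo_model(rbind(c(500, 0, 0))), shape, 4, 10),
               "rows 1")
  expect_error(model_to_map(m1, shape, 4, lowpass = 6), "Nyquist")
  # the default resolution of a model-derived map is 5 A
  expect_identical(formals(model_to_map)$lowpass, 5)
})

test_that("normalization is affine-invariant and guards zero variance", {
  m <- random_map(24, seed = 5)
  mask <- array(1, dim(m$data))
  n1 <- normalize_map(m, mask)
  expect_equal(mean(n1$data), 0, tolerance = 1e-9)
  expect_equal(stats::sd(n1$data) * sqrt((length(n1$data) - 1) /
                                          length(n1$data)), 1,
               tolerance = 1e-9)
  # already normalized: unchanged
  expect_equal(normalize_map(n1, mask)$data, n1$data, tolerance = 1e-9)
  # affine invariance
  m7 <- density_map(m$data * 7 + 3, m$voxel_size)
  expect_equal(normalize_map(m7, mask)$data, n1$data, tolerance = 1e-9)
  expect_error(normalize_map(density_map(array(2, c(8, 8, 8)), 1)),
               "zero variance")
})

test_that("the difference map is antisymmetric and mass-conserving", {
  em <- random_map(32, seed = 6)
  mod <- random_map(32, seed = 7)
  d1 <- difference_map(em, mod, gaussian_sd = 3)
  d2 <- difference_map(mod, em, gaussian_sd = 3)
  expect_equal(d1$data, -d2$data, tolerance = 1e-12)
  expect_equal(max(abs(difference_map(em, em)$data)), 0, tolerance = 1e-9)
  # planted kernel of integrated mass m: the filtered difference
  # integrates to m (convolution with a unit-sum kernel conserves mass)
  extra <- array(0, dim(em$data))
  extra[12:20, 12:20, 12:20] <- 0.5
  emx <- density_map(mod$data + extra, em$voxel_size)
  dm <- difference_map(emx, mod, gaussian_sd = 3)
  expect_equal(sum(dm$data), sum(extra), tolerance = 0.02 * sum(extra))
  # default filter sd is 3 voxels
  expect_identical(formals(difference_map)$gaussian_sd, 3)
  expect_error(difference_map(em, random_map(16)), "mismatched")
})

test_that("blob detection localizes planted densities without false positives", {
  d <- c(48, 48, 48)
  vs <- 4
  base <- array(0, d)
  plant <- function(arr, cen, amp, sd = 2) {
    co <- seq_len(48) - 1
    g <- amp * exp(-0.5 * (outer(outer((co - cen[1])^2, (co - cen[2])^2,
                                       `+`), (co - cen[3])^2, `+`)) / sd^2)
    arr + g
  }
  set.seed(21)
  ok_centroid <- TRUE; false_pos <- 0
  for (s in 1:10) {
    noise <- array(rnorm(prod(d), 0, 0.05), d)
    centers <- list(c(12, 12, 12), c(34, 30, 20))
    dm <- noise
    for (cc in centers) dm <- plant(dm, cc, amp = 1)
    dmap <- density_map(dm, vs)
    blobs <- detect_blobs(dmap, threshold_sigmas = 3, min_voxels = 20)
    if (nrow(blobs) != 2) false_pos <- false_pos + 1
    for (cc in centers) {
      derr <- min(sqrt((blobs$centroid_x - cc[1])^2 +
                       (blobs$centroid_y - cc[2])^2 +
                       (blobs$centroid_z - cc[3])^2))
      if (derr > 2) ok_centroid <- FALSE
    }
  }
  expect_identical(false_pos, 0)
  expect_true(ok_centroid)
  # a zero map yields an empty list
  expect_identical(nrow(detect_blobs(density_map(array(0, c(16, 16, 16)) +
                                                  stats::rnorm(16^3, 0, 1e-9),
                                                 1))), 0L)
})

test_that("a four-component planted scene yields exactly four regions", {
  # membrane band + three off-model kernels, mirroring the difference-map
  # readout of an assembled coat
  d <- c(64, 64, 48)
  co_x <- seq_len(64) - 1; co_z <- seq_len(48) - 1
  band <- exp(-0.5 * ((matrix(co_z, 64, 48, byrow = TRUE) - 8) / 1.5)^2)
  arr <- array(rep(band, each = 1), c(64, 48, 1))
  membrane <- array(0, d)
  for (y in 1:64) membrane[, y, ] <- band * 1
  plant <- function(arr, cen, amp, sd) {
    cox <- seq_len(dim(arr)[1]) - 1; coy <- seq_len(dim(arr)[2]) - 1
    coz <- seq_len(dim(arr)[3]) - 1
    arr + amp * exp(-0.5 * (outer(outer((cox - cen[1])^2, (coy - cen[2])^2,
                                        `+`), (coz - cen[3])^2, `+`)) / sd^2)
  }
  set.seed(33)
  dm <- membrane + array(rnorm(prod(d), 0, 0.05), d)
  dm <- plant(dm, c(16, 16, 30), 1.2, 2)   # unresolved loop density
  dm <- plant(dm, c(40, 20, 32), 1.2, 2)   # catalytic-fragment site
  dm <- plant(dm, c(28, 46, 34), 1.2, 2)   # tri-proline site
  blobs <- detect_blobs(density_map(dm, 4), threshold_sigmas = 3,
                        min_voxels = 20)
  expect_identical(nrow(blobs), 4L)
  # the membrane band is the largest region
  expect_equal(blobs$centroid_z[1], 8, tolerance = 1)
})

test_that("pseudo-model tables round-trip through TSV", {
  m <- pseudo_model(rbind(c(10, 20, 30), c(40, 50, 60)), c(1, 2),
                    c("sar1", "sec23"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$weight, c(1, 2))
  expect_identical(m2$label, c("sar1", "sec23"))
  expect_error(pseudo_model(rbind(c(1, 2, 3)), weights = -1), "> 0")
})
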