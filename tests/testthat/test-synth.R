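test_that("blob phantoms are deterministic, nonnegative, mass-consistent", {
  p1 <- random_blob_phantom(shape = 48, n_blobs = 4,
                            blob_sigma_range = c(1.5, 2), seed = 60)
  p2 <- random_blob_phantom(shape = 48, n_blobs = 4,
                            blob_sigma_range = c(1.5, 2), seed = 60)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$blobs, p2$blobs)
  expect_gte(min(p1$volume$data), 0)
  # centres stay in the central half of the box
  expect_true(all(as.matrix(p1$blobs[, c("x", "y", "z")]) >= 12 &
                  as.matrix(p1$blobs[, c("x", "y", "z")]) <= 36))
  # total mass = sum of analytic Gaussian integrals
  expected <- sum(p1$blobs$intensity * (2 * pi * p1$blobs$sigma^2)^(3 / 2))
  expect_equal(sum(p1$volume$data), expected, tolerance = 1e-6)
  # generator leaves the caller's RNG state alone
  set.seed(99); before <- .Random.seed
  invisible(random_blob_phantom(shape = 16, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("single central blob matches the Gaussian PSF up to scale", {
  n <- 32
  ph <- random_blob_phantom(shape = n, n_blobs = 1, seed = 61)
  b <- ph$blobs
  k1 <- exp(-(seq_len(n) - b$x[1])^2 / (2 * b$sigma[1]^2))
  k2 <- exp(-(seq_len(n) - b$y[1])^2 / (2 * b$sigma[1]^2))
  k3 <- exp(-(seq_len(n) - b$z[1])^2 / (2 * b$sigma[1]^2))
  ref <- b$intensity[1] * outer(outer(k1, k2), k3)
  expect_equal(ph$volume$data, ref, tolerance = 1e-12)
})

test_that("model_to_map is a superposition of resolution-width Gaussians", {
  atoms1 <- tibble::tibble(x = 15, y = 16, z = 17, weight = 2)
  atoms2 <- tibble::tibble(x = 10, y = 12, z = 20, weight = 1)
  m1 <- model_to_map(atoms1, res = 6, ps = 1, shape = 32)
  m2 <- model_to_map(atoms2, res = 6, ps = 1, shape = 32)
  m12 <- model_to_map(dplyr::bind_rows(atoms1, atoms2), res = 6, ps = 1,
                      shape = 32)
  expect_equal(m12$data, m1$data + m2$data, tolerance = 1e-12)

  # central atom reproduces gaussian_psf up to normalization
  ctr <- tibble::tibble(x = 16, y = 16, z = 16, weight = 1)
  mc <- model_to_map(ctr, res = 6, ps = 1, shape = 32)
  psf <- gaussian_psf(sigma_from_resolution(6, 1), 32)
  expect_equal(mc$data / max(mc$data), psf$data / max(psf$data),
               tolerance = 1e-9)

  expect_error(model_to_map(tibble::tibble(x = c(10, 99), y = 1:2, z = 1:2),
                            6, 1, 32), "rows: 2")

  # model map agrees with a same-atom phantom at low frequency
  hm <- global_fsc(mc, volume3d(mc$data * 3 + 1e-9, 1))
  expect_gt(hm$fsc[1], 0.99)
})

test_that("missing-cone degradation zeroes the right solid angle, idempotently", {
  v <- random_volume(64, seed = 62)
  deg <- degrade_missing_cone(v, 30)
  f <- cryodecon:::fft_center(stats::fft(deg$data))
  km <- cryodecon:::offset_matrix(64)
  r <- sqrt(rowSums(km^2))
  insphere <- r > 0 & r <= 32
  zeroed <- abs(as.vector(f))[insphere] < 1e-8
  expect_equal(mean(zeroed), 1 - cos(30 * pi / 180), tolerance = 0.02)

  deg2 <- degrade_missing_cone(deg, 30)
  expect_equal(deg2$data, deg$data, tolerance = 1e-12)

  # tiny cone: identity (strict membership keeps the axis voxels)
  almost <- degrade_missing_cone(v, 1e-9)
  expect_lt(max(abs(almost$data - v$data)), 1e-10)
  expect_error(degrade_missing_cone(v, 90), "0, 90")
})

test_that("sampling weights reproduce central-slice geometry", {
  # single z-view: only the kz = 0 plane is touched
  one <- orientation_table(rot = 0, tilt = 0)
  w <- sampling_weights(one, shape = 16)
  nzplane <- w$data[, , 9]
  expect_true(all(nzplane == 1))
  expect_true(all(w$data[, , -9] == 0))

  # uniform views: shell-mean weight falls as 1/frequency
  tab <- uniform_orientations(2000, seed = 7)
  wu <- sampling_weights(tab, shape = 32)
  rad <- cryodecon:::radius_grid(32)
  sm <- vapply(4:12, function(s) mean(wu$data[abs(rad - s) < 0.5]),
               numeric(1))
  prod_s <- sm * (4:12)
  expect_true(all(abs(prod_s - mean(prod_s)) / mean(prod_s) < 0.15))
  expect_error(sampling_weights(dplyr::mutate(tab, keep = FALSE), 16),
               "no kept")
})

test_that("tilt-filtered sampling leaves the axial double cone empty", {
  tab <- filter_by_tilt(uniform_orientations(4000, seed = 8))
  w <- sampling_weights(tab, shape = 32)
  km <- cryodecon:::offset_matrix(32)
  r <- sqrt(rowSums(km^2))
  # provable empty region: polar angle < 30 deg minus the half-voxel slice
  # blur asin(0.5/r)
  nz <- r > 0
  theta <- acos(pmin(1, abs(km[nz, 3]) / r[nz]))
  margin <- asin(pmin(1, 0.5 / r[nz]))
  incone <- theta < (30 * pi / 180 - margin)
  expect_gt(sum(incone), 100)
  expect_true(all(as.vector(w$data)[nz][incone] == 0))
  # ... and the equator is well sampled
  equator <- abs(theta - pi / 2) < 10 * pi / 180 & r[nz] > 4
  expect_gt(mean(as.vector(w$data)[nz][equator] > 0), 0.9)
})

test_that("weights_to_filter is a bounded, monotone attenuation", {
  w <- fourier_volume(array(c(0, 1, 2, 5, 10, rep(0, 16^3 - 5)),
                            c(16, 16, 16)), 1)
  f1 <- weights_to_filter(w, snr = 1)
  expect_identical(f1$data[1], 0)
  expect_equal(f1$data[2], 0.5)
  expect_true(all(f1$data >= 0 & f1$data < 1))
  expect_true(all(diff(f1$data[1:5]) > 0))          # monotone in w
  f2 <- weights_to_filter(w, snr = 2)
  expect_true(all(f2$data >= f1$data))              # monotone in snr
})

test_that("half-map pairs are seed-deterministic with independent noise", {
  v <- blob_volume(16, 2.5)
  a <- make_half_maps(v, noise_sd = 0.1, seed = 9)
  b <- make_half_maps(v, noise_sd = 0.1, seed = 9)
  expect_identical(a$half1$data, b$half1$data)
  expect_identical(a$half2$data, b$half2$data)
  expect_false(identical(a$half1$data, a$half2$data))

  z <- make_half_maps(v, noise_sd = 0, seed = 9)
  expect_identical(z$half1$data, v$data)
  r <- compute_dfsc(z$half1, z$half2, n_dirs = 20)
  expect_true(all(abs(r$curves$fsc[!is.na(r$curves$fsc)] - 1) < 1e-9))

  # overwhelming noise: high-frequency shells decorrelate
  noisy <- make_half_maps(blob_volume(32, 2), noise_sd = 5, seed = 10)
  gf <- global_fsc(noisy$half1, noisy$half2)
  expect_lt(mean(abs(gf$fsc[gf$freq > 0.25])), 0.1)
})

test_that("the degraded-phantom pipeline fixture shows the dFSC spread", {
  ph <- random_blob_phantom(shape = 32, seed = 63)
  deg <- degrade_missing_cone(ph$volume, 30)
  hm <- make_half_maps(deg, noise_sd = 0.03, seed = 63)
  r <- compute_dfsc(hm$half1, hm$half2, n_dirs = 100)
  cp <- cone_partition_resolution(r, c(0, 0, 1), 30)
  expect_gt(cp$inside_mean, cp$outside_mean)
})
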