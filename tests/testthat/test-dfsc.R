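test_that("global FSC: self-correlation 1, sign flip -1, noise ~ 0", {
  v <- random_volume(16, seed = 20)
  f <- global_fsc(v, v)
  expect_true(all(abs(f$fsc - 1) < 1e-9))
  neg <- volume3d(-v$data, v$voxel_size)
  expect_true(all(abs(global_fsc(v, neg)$fsc + 1) < 1e-9))
  # independent pure-noise volumes decorrelate
  f0 <- global_fsc(random_volume(64, seed = 2), random_volume(64, seed = 3))
  expect_lt(abs(mean(f0$fsc)), 0.05)
  expect_true(all(f0$fsc >= -1 & f0$fsc <= 1))
  expect_error(global_fsc(v, random_volume(32, seed = 1)), "shape")
})

test_that("conical FSC at 90 degrees equals global FSC bit-for-bit", {
  hm <- make_half_maps(blob_volume(16, 2.5), noise_sd = 0.02, seed = 21)
  g <- global_fsc(hm$half1, hm$half2)
  c90 <- conical_fsc(hm$half1, hm$half2, c(0.3, -0.5, 1), 90, min_voxels = 1L)
  expect_identical(c90$fsc, g$fsc)
  expect_identical(c90$n_voxels, g$n_voxels)
})

test_that("conical FSC is antipodally symmetric and 1 on self", {
  hm <- make_half_maps(blob_volume(16, 2.5), noise_sd = 0.05, seed = 22)
  ax <- c(0.2, 0.7, 0.4)
  cp <- conical_fsc(hm$half1, hm$half2, ax, 25)
  cm <- conical_fsc(hm$half1, hm$half2, -ax, 25)
  expect_identical(cp, cm)
  v <- blob_volume(16, 2)
  cs <- conical_fsc(v, v, c(0, 0, 1), 20)
  expect_true(all(abs(cs$fsc[!is.na(cs$fsc)] - 1) < 1e-9))
  expect_error(conical_fsc(v, v, c(0, 0, 0), 20), "zero axis")
})

test_that("conical FSC matches a brute-force per-voxel oracle on 16^3", {
  hm <- make_half_maps(blob_volume(16, 2.2), noise_sd = 0.05, seed = 23)
  n <- 16
  f1 <- stats::fft(hm$half1$data)
  f2 <- stats::fft(hm$half2$data)
  axis <- c(1, 2, -1) / sqrt(6)
  half <- 35 * pi / 180
  ns <- n / 2
  num <- d1 <- d2 <- cnt <- numeric(ns)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(n - 1)) {
    kk <- c(i, j, k)
    kk <- ifelse(kk >= n / 2, kk - n, kk)   # wrap to centered offsets
    r <- sqrt(sum(kk^2))
    s <- round(r)
    if (s < 1 || s > ns) next
    if (acos(min(1, abs(sum(kk * axis)) / r)) > half) next
    z1 <- f1[i + 1, j + 1, k + 1]; z2 <- f2[i + 1, j + 1, k + 1]
    num[s] <- num[s] + Re(z1 * Conj(z2))
    d1[s] <- d1[s] + Mod(z1)^2
    d2[s] <- d2[s] + Mod(z2)^2
    cnt[s] <- cnt[s] + 1
  }
  oracle <- ifelse(cnt >= 10, num / sqrt(d1 * d2), NA_real_)
  fast <- conical_fsc(hm$half1, hm$half2, axis, 35)
  expect_equal(fast$fsc, oracle, tolerance = 1e-10)
  expect_equal(fast$n_voxels, as.integer(cnt))
})

test_that("dFSC of identical half-maps is 1 everywhere; all-ones mask is a no-op", {
  v <- blob_volume(16, 2.5)
  r <- compute_dfsc(v, v, n_dirs = 40)
  expect_true(all(abs(r$curves$fsc[!is.na(r$curves$fsc)] - 1) < 1e-9))
  hm <- make_half_maps(v, noise_sd = 0.05, seed = 24)
  ones <- volume3d(array(1, dim = dim(v$data)), v$voxel_size)
  r1 <- compute_dfsc(hm$half1, hm$half2, n_dirs = 25)
  r2 <- compute_dfsc(hm$half1, hm$half2, n_dirs = 25, mask = ones)
  expect_identical(r1$curves, r2$curves)
})

test_that("dFSC values respect Cauchy-Schwarz bounds on noisy fixtures", {
  hm <- make_half_maps(blob_volume(16, 2), noise_sd = 0.3, seed = 25)
  r <- compute_dfsc(hm$half1, hm$half2, n_dirs = 30)
  ok <- !is.na(r$curves$fsc)
  expect_true(all(r$curves$fsc[ok] >= -1 - 1e-12 &
                  r$curves$fsc[ok] <= 1 + 1e-12))
})

test_that("resolution estimation interpolates crossings and flags non-crossing", {
  curve <- tibble::tibble(freq = c(0.1, 0.2, 0.3, 0.4), fsc = c(1, 1, 0, 0))
  r <- estimate_resolution(curve, 0.5)
  expect_equal(as.numeric(r), 4.0, tolerance = 1e-12)
  expect_true(attr(r, "crossed"))

  flat <- tibble::tibble(freq = seq(0.05, 0.5, by = 0.05), fsc = rep(1, 10))
  rf <- estimate_resolution(flat, 0.143)
  expect_equal(as.numeric(rf), 2.0)
  expect_false(attr(rf, "crossed"))

  # monotone curve: the 0.5 crossing is at lower frequency => larger Angstrom
  mono <- tibble::tibble(freq = seq(0.02, 0.4, by = 0.02),
                         fsc = seq(1, 0.05, length.out = 20))
  expect_gt(as.numeric(estimate_resolution(mono, 0.5)),
            as.numeric(estimate_resolution(mono, 0.143)))
})

test_that("rendered dFSC volume: identity case, symmetry, shell consistency", {
  v <- blob_volume(16, 2.5)
  r <- compute_dfsc(v, v, n_dirs = 60)
  dv <- render_dfsc_volume(r)
  expect_true(all(abs(dv$data - 1) < 1e-9))

  hm <- make_half_maps(v, noise_sd = 0.1, seed = 26)
  rn <- compute_dfsc(hm$half1, hm$half2, n_dirs = 60)
  dn <- render_dfsc_volume(rn)
  # antipodal symmetry: value at +k equals value at -k (indices 2..n pair up)
  a <- dn$data[2:16, 2:16, 2:16]
  expect_identical(a, a[15:1, 15:1, 15:1])
  # DC voxel set to 1
  expect_identical(dn$data[9, 9, 9], 1)
  # shell means of the volume track the direction-mean curves
  rad <- cryodecon:::radius_grid(16)
  curve_mean <- dplyr::summarise(dplyr::group_by(rn$curves, freq),
                                 m = mean(fsc, na.rm = TRUE))
  checked <- 0
  for (s in 2:8) {
    if (!is.finite(curve_mean$m[s])) next  # shell undefined in every cone
    sel <- abs(rad - s) < 0.5
    expect_lt(abs(mean(dn$data[sel]) - curve_mean$m[s]), 0.05)
    checked <- checked + 1
  }
  expect_gte(checked, 4)
})

test_that("tidy and glance methods expose directions and resolution summary", {
  hm <- make_half_maps(blob_volume(16, 2.5), noise_sd = 0.05, seed = 27)
  r <- compute_dfsc(hm$half1, hm$half2, n_dirs = 25)
  td <- tidy(r)
  expect_true(all(c("dir", "freq", "fsc", "x", "y", "z") %in% names(td)))
  expect_equal(nrow(td), 25 * 8)
  gl <- glance(r)
  expect_true(gl$res_min <= gl$res_mean && gl$res_mean <= gl$res_max)
})
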