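test_that("objective: perfect fit, constant input, and the quadratic limit", {
  n <- 16
  v <- blob_volume(n, 2.5)
  otf <- identity_otf(n)
  p <- deconv_params(smoothing = 1e-12, nonlinearity = 1e4)
  expect_lt(deconv_objective(v, v, otf, p), 1e-6)

  # Laplacian of a constant vanishes: only the data term remains
  const <- volume3d(array(3, c(n, n, n)), 1)
  g <- random_volume(n, seed = 50)
  p2 <- deconv_params(smoothing = 7, nonlinearity = 1e4)
  expect_equal(deconv_objective(const, g, otf, p2),
               sum((const$data - g$data)^2), tolerance = 1e-9)

  # T -> infinity: penalty approaches lambda * sum((Lf)^2) with L the
  # 27-point Laplacian — computed here by explicit neighbour averaging
  f <- blob_volume(n, 2)
  lf <- -f$data
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ix <- ((seq_len(n) - 1 + dx) %% n) + 1
    iy <- ((seq_len(n) - 1 + dy) %% n) + 1
    iz <- ((seq_len(n) - 1 + dz) %% n) + 1
    lf <- lf + f$data[ix, iy, iz] / 26
  }
  lam <- 0.8
  jT <- deconv_objective(f, g, otf, deconv_params(lam, 1e8))
  j_quad <- sum((f$data - g$data)^2) + lam * sum(lf^2)
  expect_equal(jT, j_quad, tolerance = 1e-6)
})

test_that("quadratic_solution: identity at lambda 0, smoothing limit", {
  n <- 16
  g <- random_volume(n, seed = 51)
  otf <- identity_otf(n)
  expect_equal(quadratic_solution(g, otf, 0)$data, g$data, tolerance = 1e-10)
  # huge lambda: solution collapses to its DC component
  s <- quadratic_solution(g, otf, 1e12)
  expect_lt(sd(s$data), 1e-6)
  expect_equal(mean(s$data), mean(g$data), tolerance = 1e-6)
  # linearity: solving a*g equals a * solution(g)
  s1 <- quadratic_solution(g, otf, 0.3)
  s2 <- quadratic_solution(volume3d(2.5 * g$data, 1), otf, 0.3)
  expect_equal(s2$data, 2.5 * s1$data, tolerance = 1e-10)
})

test_that("solver matches the closed-form oracle in the quadratic limit", {
  ph <- random_blob_phantom(shape = 32, seed = 5)
  otf <- gaussian_otf(32, 2)
  g <- apply_otf(ph$volume, otf)
  p <- deconv_params(smoothing = 0.5, nonlinearity = 1e7, max_iter = 400,
                     tol = 1e-13, positivity = FALSE)
  dr <- deconvolve(g, otf, p)
  oracle <- quadratic_solution(g, otf, 0.5)
  rel <- sqrt(sum((dr$volume$data - oracle$data)^2) / sum(oracle$data^2))
  expect_lt(rel, 1e-3)
  tr <- dr$objective_trace
  expect_true(all(diff(tr) <= 1e-12 * pmax(abs(tr[-length(tr)]), 1)))
})

test_that("identity forward model returns the input; positivity holds exactly", {
  ph <- random_blob_phantom(shape = 16, seed = 52)
  otf <- identity_otf(16)
  dr <- deconvolve(ph$volume, otf,
                   deconv_params(smoothing = 1e-6, max_iter = 50))
  expect_lt(sqrt(sum((dr$volume$data - ph$volume$data)^2) /
                 sum(ph$volume$data^2)), 1e-2)
  expect_gte(min(dr$volume$data), 0)
})

test_that("noiseless deblurring beats the blurred input and nears the truth", {
  ph <- random_blob_phantom(shape = 32, seed = 5)
  otf <- gaussian_otf(32, 2)
  g <- apply_otf(ph$volume, otf)
  dr <- deconvolve(g, otf, deconv_params(smoothing = 1e-4, max_iter = 150))
  expect_gt(ncc(dr$volume$data, ph$volume$data), ncc(g$data, ph$volume$data))
  expect_gt(ncc(dr$volume$data, ph$volume$data), 0.99)
})

test_that("deconvolution recovers information inside the missing cone", {
  ph <- random_blob_phantom(shape = 32, seed = 6)
  deg <- degrade_missing_cone(ph$volume, 30)
  hm <- make_half_maps(deg, noise_sd = 0.02, seed = 6)
  r <- compute_dfsc(hm$half1, hm$half2, n_dirs = 100)
  psf <- gaussian_psf(sigma_from_resolution(
    as.numeric(estimate_resolution(global_fsc(hm$half1, hm$half2))), 1), 32)
  otf <- build_otf(render_dfsc_volume(r), psf)
  dr <- deconvolve(deg, otf, deconv_params(max_iter = 80))
  cone_before <- fourier_cone_correlation(deg, ph$volume, c(0, 0, 1), 30)
  cone_after <- fourier_cone_correlation(dr$volume, ph$volume, c(0, 0, 1), 30)
  expect_gt(cone_after, cone_before)
})

test_that("runs are deterministic and smoothing monotonically smooths", {
  ph <- random_blob_phantom(shape = 16, seed = 53)
  otf <- gaussian_otf(16, 1.5)
  g <- apply_otf(ph$volume, otf)
  p <- deconv_params(max_iter = 40)
  d1 <- deconvolve(g, otf, p)
  d2 <- deconvolve(g, otf, p)
  expect_identical(d1$volume$data, d2$volume$data)
  expect_identical(d1$objective_trace, d2$objective_trace)

  lap_energy <- function(vol) {
    lt <- cryodecon:::laplacian_transfer(16)
    sum(cryodecon:::apply_transfer(vol$data, lt)^2)
  }
  e <- vapply(c(0.05, 0.5, 5), function(lam) {
    lap_energy(deconvolve(g, otf, deconv_params(smoothing = lam,
                                                nonlinearity = 1e7,
                                                max_iter = 120,
                                                tol = 1e-12))$volume)
  }, numeric(1))
  expect_true(all(diff(e) <= 1e-9 * pmax(e[-3], 1)))
})

test_that("tidy and glance summarize the optimization trace", {
  ph <- random_blob_phantom(shape = 16, seed = 54)
  dr <- deconvolve(ph$volume, identity_otf(16),
                   deconv_params(max_iter = 10))
  td <- tidy(dr)
  expect_equal(td$iteration[1], 0L)
  expect_equal(nrow(td), length(dr$objective_trace))
  gl <- glance(dr)
  expect_lte(gl$objective_final, gl$objective_initial)
})
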