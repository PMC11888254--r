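# Synthetic ground truth and degradation: blob phantoms, model maps from
# point scatterers, missing-cone Fourier attenuation, central-slice
# sampling weights from particle orientations, and noisy half-map pairs.
# Together these emulate the statistical structure of an anisotropic
# single-particle reconstruction at desk scale, with no external data.

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Separable accumulation of one isotropic Gaussian into an N^3 array.
add_gaussian <- function(acc, center_px, sigma_px, amplitude) {
  n <- dim(acc)[1]
  ax <- exp(-(seq_len(n) - center_px[1])^2 / (2 * sigma_px^2))
  ay <- exp(-(seq_len(n) - center_px[2])^2 / (2 * sigma_px^2))
  az <- exp(-(seq_len(n) - center_px[3])^2 / (2 * sigma_px^2))
  acc + amplitude * outer(outer(ax, ay), az)
}

#' Random Gaussian-blob phantom
#'
#' A sum of isotropic Gaussian blobs with centres drawn uniformly from the
#' central half of the box (preserving a solvent margin), widths and
#' intensities drawn uniformly from the given ranges. Fully deterministic
#' under the seed; the caller's RNG state is untouched.
#'
#' @param shape Cubic grid side (even, >= 8).
#' @param voxel_size Voxel size in Angstrom per pixel.
#' @param n_blobs Number of blobs (>= 1).
#' @param blob_sigma_range Blob widths in Angstrom, `c(min, max)`.
#' @param intensity_range Blob peak amplitudes, `c(min, max)`.
#' @param seed Integer seed.
#' @return List with `volume` (a [volume3d()]) and `blobs` (tibble of
#'   centres in pixels, sigma in Angstrom, intensity).
#' @export
random_blob_phantom <- function(shape = 64, voxel_size = 1, n_blobs = 6,
                                blob_sigma_range = c(2, 4),
                                intensity_range = c(0.5, 1.5), seed = 0) {
  stopifnot(n_blobs >= 1, length(blob_sigma_range) == 2,
            length(intensity_range) == 2)
  if (min(blob_sigma_range) < voxel_size / 2) {
    warning("blob sigma below voxel_size/2: blobs will be under-sampled")
  }
  n <- as.integer(shape)
  blobs <- with_preserved_rng(seed, {
    tibble::tibble(
      x = stats::runif(n_blobs, n / 4, 3 * n / 4),
      y = stats::runif(n_blobs, n / 4, 3 * n / 4),
      z = stats::runif(n_blobs, n / 4, 3 * n / 4),
      sigma = stats::runif(n_blobs, blob_sigma_range[1], blob_sigma_range[2]),
      intensity = stats::runif(n_blobs, intensity_range[1], intensity_range[2])
    )
  })
  acc <- array(0, dim = c(n, n, n))
  for (i in seq_len(n_blobs)) {
    acc <- add_gaussian(acc, c(blobs$x[i], blobs$y[i], blobs$z[i]),
                        blobs$sigma[i] / voxel_size, blobs$intensity[i])
  }
  list(volume = volume3d(acc, voxel_size), blobs = blobs)
}

#' Density map from point scatterers
#'
#' Each atom contributes an isotropic Gaussian of width
#' [sigma_from_resolution()]`(res, ps)` pixels scaled by its weight — the
#' molmap-style model map used for map-to-model comparisons.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` (Angstrom, grid
#'   coordinates relative to the volume origin corner) and `weight`.
#' @param res Target resolution in Angstrom.
#' @param ps Pixel size in Angstrom per pixel.
#' @param shape Cubic grid side.
#' @return A [volume3d()].
#' @export
model_to_map <- function(atoms, res, ps, shape) {
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z") %in% names(atoms)))
  w <- if ("weight" %in% names(atoms)) atoms$weight else rep(1, nrow(atoms))
  n <- as.integer(shape)
  px <- cbind(atoms$x, atoms$y, atoms$z) / ps + 1  # grid coordinates
  bad <- which(apply(px, 1, function(p) any(p < 1 | p > n)))
  if (length(bad)) {
    stop("atoms outside the box at rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sigma <- sigma_from_resolution(res, ps)
  acc <- array(0, dim = c(n, n, n))
  for (i in seq_len(nrow(atoms))) {
    acc <- add_gaussian(acc, px[i, ], sigma, w[i])
  }
  volume3d(acc, ps)
}

#' Remove a Fourier double cone (missing-cone degradation)
#'
#' Zeroes all Fourier coefficients whose direction lies strictly within
#' `half_angle` degrees of `axis` or `-axis`. DC is preserved and the
#' output is real. Removing all particle views tilted more than 60 degrees
#' from z leaves exactly such an unsampled double cone of half-angle 30
#' degrees about z (a classic random-conical-tilt missing cone of 60
#' degrees).
#'
#' @param v A [volume3d()].
#' @param half_angle Cone half-angle in degrees, in `(0, 90)`. The limit
#'   `half_angle -> 0` is the identity.
#' @param axis Cone axis (default z).
#' @return Degraded [volume3d()].
#' @export
degrade_missing_cone <- function(v, half_angle, axis = c(0, 0, 1)) {
  stopifnot(inherits(v, "volume3d"))
  if (!(half_angle > 0 && half_angle < 90)) {
    stop("half_angle must be in (0, 90) degrees", call. = FALSE)
  }
  n <- dim(v$data)[1]
  km <- offset_matrix(n)
  r <- sqrt(rowSums(km^2))
  a <- axis / sqrt(sum(axis^2))
  dot <- abs(drop(km %*% a))
  # strict inequality: on-edge voxels kept, DC (r = 0) kept
  kill <- r > 0 & dot > r * cos(half_angle * pi / 180)
  h <- array(1, dim = c(n, n, n))
  h[kill] <- 0
  ft <- fft_fwd(v$data) * fft_uncenter(h)
  volume3d(Re(fft_inv(ft)), v$voxel_size, v$origin)
}

#' Central-slice sampling weights from particle orientations
#'
#' For every kept orientation, adds 1 to each Fourier voxel within half a
#' voxel of the central plane perpendicular to the particle's view vector
#' (nearest-plane binning) — the accumulation pattern of a central-slice
#' reconstruction, whose shell-mean falls off as 1/frequency for uniform
#' orientations.
#'
#' @param orients An [orientation_table()]; only rows with `keep = TRUE`
#'   contribute.
#' @param shape Cubic grid side.
#' @param voxel_size Voxel size attached to the output (default 1).
#' @return A [fourier_volume()] of per-voxel sampling counts.
#' @export
sampling_weights <- function(orients, shape, voxel_size = 1) {
  stopifnot(is.data.frame(orients))
  kept <- orients[orients$keep, , drop = FALSE]
  if (nrow(kept) == 0) stop("no kept orientations", call. = FALSE)
  n <- as.integer(shape)
  km <- offset_matrix(n)
  counts <- numeric(n^3)
  vm <- as.matrix(kept[, c("vx", "vy", "vz")])
  for (i in seq_len(nrow(vm))) {
    counts <- counts + (abs(drop(km %*% vm[i, ])) <= 0.5)
  }
  fourier_volume(array(counts, dim = c(n, n, n)), voxel_size)
}

#' Convert sampling counts to a Fourier attenuation
#'
#' `c = (w * snr) / (1 + w * snr)` voxelwise: a Wiener-style conversion of
#' per-voxel sampling counts into an attenuation in `[0, 1)` that is 0
#' where nothing was sampled and approaches 1 with dense sampling.
#'
#' @param w A [fourier_volume()] of nonnegative sampling counts.
#' @param snr Per-observation signal-to-noise ratio (> 0).
#' @return A [fourier_volume()] attenuation.
#' @export
weights_to_filter <- function(w, snr) {
  stopifnot(inherits(w, "fourier_volume"), snr > 0, min(w$data) >= 0)
  fourier_volume((w$data * snr) / (1 + w$data * snr), w$voxel_size)
}

#' Independent-noise half-map pair
#'
#' Two copies of the input plus independent white Gaussian noise fields,
#' seeded from `seed * 2` and `seed * 2 + 1` — the stand-in for two
#' independent half-set reconstructions.
#'
#' @param v Ground-truth [volume3d()].
#' @param noise_sd Noise standard deviation in density units (>= 0).
#' @param seed Integer seed.
#' @return List with `half1` and `half2` ([volume3d()]s).
#' @export
make_half_maps <- function(v, noise_sd, seed = 0) {
  stopifnot(inherits(v, "volume3d"), noise_sd >= 0)
  n3 <- length(v$data)
  e1 <- with_preserved_rng(seed * 2, stats::rnorm(n3, sd = noise_sd))
  e2 <- with_preserved_rng(seed * 2 + 1, stats::rnorm(n3, sd = noise_sd))
  if (noise_sd == 0) { e1 <- numeric(n3); e2 <- numeric(n3) }
  list(
    half1 = volume3d(v$data + array(e1, dim = dim(v$data)), v$voxel_size,
                     v$origin),
    half2 = volume3d(v$data + array(e2, dim = dim(v$data)), v$voxel_size,
                     v$origin)
  )
}
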