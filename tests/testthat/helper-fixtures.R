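# Shared fixtures, all generated in code at test time.

# Centered isotropic Gaussian blob volume.
blob_volume <- function(n = 32, sigma_px = 2, voxel_size = 1,
                        amplitude = 1) {
  k <- seq_len(n) - (n / 2 + 1)
  g1 <- exp(-k^2 / (2 * sigma_px^2))
  volume3d(amplitude * outer(outer(g1, g1), g1), voxel_size)
}

random_volume <- function(n = 16, seed = 0, voxel_size = 1) {
  set.seed(seed)
  volume3d(array(rnorm(n^3), dim = c(n, n, n)), voxel_size)
}

# All-pass OTF (identity forward model).
identity_otf <- function(n, voxel_size = 1) {
  otf_volume(array(1, dim = c(n, n, n)), voxel_size)
}

# Isotropic Gaussian-envelope OTF.
gaussian_otf <- function(n, sigma_px, voxel_size = 1) {
  build_otf(fourier_volume(array(1, dim = c(n, n, n)), voxel_size),
            gaussian_psf(sigma_px, n, voxel_size))
}

# Apply the OTF forward model (blur) to a volume.
apply_otf <- function(v, otf) {
  n <- dim(v$data)[1]
  ft <- stats::fft(v$data) * cryodecon:::otf_transfer(otf, n)
  volume3d(Re(stats::fft(ft, inverse = TRUE)) / n^3, v$voxel_size)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Orientations uniform on the sphere (cos(tilt) ~ U(-1,1)).
uniform_orientations <- function(n, seed) {
  set.seed(seed)
  orientation_table(rot = runif(n, -180, 180),
                    tilt = acos(runif(n, -1, 1)) * 180 / pi,
                    psi = runif(n, -180, 180))
}
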