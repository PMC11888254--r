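#' Cubic 3D density volume
#'
#' Container for a cubic grid of real-valued densities with a physical voxel
#' size. All Fourier-space operations in the package assume this layout:
#' cubic, even-sided (N >= 8) grids so the DC voxel after centering is
#' unambiguous, and an isotropic voxel size in Angstrom per pixel.
#'
#' @param data Numeric 3D array with identical, even dimensions (N >= 8).
#' @param voxel_size Voxel size in Angstrom per pixel (single positive value).
#' @param origin Physical origin offset in Angstrom (length-3 numeric).
#'   Carried through I/O but never used by Fourier operations, which treat
#'   the grid centre as the rotation centre.
#'
#' @return An object of class `volume3d`.
#' @export
#' @examples
#' v <- volume3d(array(rnorm(16^3), dim = c(16, 16, 16)), voxel_size = 1.1)
#' dim(v)
volume3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, not a ", paste(dim(data), collapse = "x"),
         " object: not a 3D volume", call. = FALSE)
  }
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3]) {
    stop("volume must be cubic; got ", paste(d, collapse = "x"), call. = FALSE)
  }
  if (d[1] < 8L || d[1] %% 2L != 0L) {
    stop("grid side must be even and >= 8; got ", d[1], call. = FALSE)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume contains non-finite values", call. = FALSE)
  }
  stopifnot(is.numeric(origin), length(origin) == 3L)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Voxel size accessor
#' @param v A `volume3d` or `fourier_volume`.
#' @return Voxel size in Angstrom per pixel.
#' @export
voxel_size <- function(v) v$voxel_size

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %dx%dx%d, voxel %.4g A/px, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' Fourier-space scalar volume (DC-centred)
#'
#' A real scalar field on the frequency grid of a cubic volume, stored
#' DC-centred: the voxel at index `N/2 + 1` on each axis is DC and a voxel
#' at integer offset k from it has frequency `k / (N * voxel_size)` 1/A.
#'
#' @param data Real 3D array, DC-centred layout.
#' @param voxel_size Voxel size (A/px) of the originating real-space grid.
#' @return An object of class `fourier_volume`.
#' @export
fourier_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[1] == dim(data)[2], dim(data)[1] == dim(data)[3])
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "fourier_volume")
}

#' @export
dim.fourier_volume <- function(x) dim(x$data)

#' @export
print.fourier_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fourier_volume> %dx%dx%d, source voxel %.4g A/px\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

# ---- FFT conventions -------------------------------------------------------
# Forward transform unscaled, inverse carries 1/N^3. Fourier-space volumes
# exposed to users are DC-centred; internally the standard (DC-at-[1,1,1])
# layout of stats::fft is used and fft_center()/fft_uncenter() convert.
# For even N the two shifts coincide, but both are kept for clarity.

fft_fwd <- function(a) stats::fft(a)
fft_inv <- function(a) stats::fft(a, inverse = TRUE) / length(a)

shift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

#' Move the DC component to the grid centre (index N/2+1)
#' @param a 3D array in standard FFT layout.
#' @return Array with DC at the centre.
#' @keywords internal
fft_center <- function(a) {
  n <- dim(a)[1]
  i <- shift_idx(n)
  a[i, i, i]
}

#' Inverse of [fft_center()]
#' @param a DC-centred 3D array.
#' @keywords internal
fft_uncenter <- function(a) {
  n <- dim(a)[1]
  i <- order(shift_idx(n))
  a[i, i, i]
}

# Centered integer frequency offsets for an even grid: -N/2 .. N/2-1.
centered_offsets <- function(n) seq.int(-n / 2, n / 2 - 1)

# Per-voxel radius (in Fourier voxel units), as a 3D DC-centred array.
radius_grid <- function(n) {
  k <- centered_offsets(n)
  k2 <- k^2
  r2 <- outer(outer(k2, k2, `+`), k2, `+`)
  sqrt(r2)
}

# Matrix (N^3 x 3) of centered integer offsets, column-major voxel order.
offset_matrix <- function(n) {
  k <- centered_offsets(n)
  cbind(rep(k, times = n * n),
        rep(rep(k, each = n), times = n),
        rep(k, each = n * n))
}

#' Normalize a volume to zero mean and unit standard deviation
#'
#' Global statistics over all voxels (population standard deviation), the
#' behaviour of the "normalize" processor of common EM map tools.
#'
#' @param v A [volume3d()].
#' @return A `volume3d` with mean 0 and standard deviation 1.
#' @export
normalize_volume <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  mu <- mean(v$data)
  s <- sqrt(mean((v$data - mu)^2))
  if (s == 0) stop("zero variance: cannot normalize a constant volume",
                   call. = FALSE)
  volume3d((v$data - mu) / s, v$voxel_size, v$origin)
}

#' Radial raised-cosine low-pass filter
#'
#' Attenuates Fourier amplitudes beyond `1/res` with a raised-cosine edge of
#' relative width `edge_frac` (the edge spans frequencies `1/res` to
#' `(1 + edge_frac)/res`). DC is preserved exactly and the output is real.
#'
#' @param v A [volume3d()].
#' @param res Target resolution in Angstrom; must satisfy
#'   `res >= 2 * voxel_size` (the Nyquist limit).
#' @param edge_frac Relative width of the raised-cosine edge (default 0.1).
#' @return Filtered `volume3d`.
#' @export
lowpass_volume <- function(v, res, edge_frac = 0.1) {
  stopifnot(inherits(v, "volume3d"), edge_frac >= 0)
  if (res < 2 * v$voxel_size) {
    stop(sprintf("res = %g A is below the Nyquist limit 2*voxel_size = %g A",
                 res, 2 * v$voxel_size), call. = FALSE)
  }
  n <- dim(v$data)[1]
  freq <- radius_grid(n) / (n * v$voxel_size)  # 1/A, DC-centred
  fc <- 1 / res
  h <- array(0, dim = dim(freq))
  h[freq <= fc] <- 1
  if (edge_frac > 0) {
    edge <- freq > fc & freq < fc * (1 + edge_frac)
    h[edge] <- 0.5 * (1 + cos(pi * (freq[edge] - fc) / (fc * edge_frac)))
  }
  ft <- fft_fwd(v$data) * fft_uncenter(h)
  volume3d(Re(fft_inv(ft)), v$voxel_size, v$origin)
}
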