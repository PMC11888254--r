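# Anisotropic optical transfer function: rendered dFSC volume times the
# Fourier magnitude of an isotropic Gaussian point-spread function whose
# width is tied to the map's global resolution.

#' Gaussian PSF width from map resolution
#'
#' `sigma = res / (pi * sqrt(2) * ps)` in pixels: the width that makes the
#' Fourier transform of the Gaussian fall to 1/e of its maximum at
#' frequency `1/res` (the molmap convention). `res` is normally the global
#' half-map FSC resolution at threshold 0.143.
#'
#' @param res Resolution in Angstrom (> 0).
#' @param ps Pixel size in Angstrom per pixel (> 0).
#' @return Gaussian sigma in pixels.
#' @export
#' @examples
#' sigma_from_resolution(pi * sqrt(2), 1)  # 1 exactly
sigma_from_resolution <- function(res, ps) {
  if (!(is.numeric(res) && res > 0)) stop("res must be > 0", call. = FALSE)
  if (!(is.numeric(ps) && ps > 0)) stop("ps must be > 0", call. = FALSE)
  res / (pi * sqrt(2) * ps)
}

#' Isotropic Gaussian point-spread function
#'
#' `exp(-r^2 / (2 sigma^2))` centred on the grid centre (the DC voxel of
#' the centred Fourier convention, index N/2 + 1), normalized to unit sum.
#'
#' @param sigma Width in pixels (> 0). Sub-voxel widths (< 0.3 px) trigger
#'   an aliasing warning.
#' @param shape Cubic grid side.
#' @param voxel_size Voxel size attached to the output (default 1).
#' @return A [volume3d()].
#' @export
gaussian_psf <- function(sigma, shape, voxel_size = 1) {
  stopifnot(sigma > 0, shape >= 8)
  if (sigma < 0.3) {
    warning("sigma = ", signif(sigma, 3),
            " px is sub-voxel; the sampled Gaussian will alias")
  }
  k <- centered_offsets(shape)
  g1 <- exp(-k^2 / (2 * sigma^2))
  g <- outer(outer(g1, g1), g1)
  volume3d(g / sum(g), voxel_size)
}

#' Construct an OTF volume from raw transfer values
#'
#' Low-level constructor used when an OTF is loaded from disk or built
#' directly (e.g. an all-pass OTF for testing). Values must lie in
#' `[0, 1]`, with the DC voxel exactly 1.
#'
#' @param data Real DC-centred 3D array of transfer magnitudes.
#' @param voxel_size Voxel size (A/px) of the originating grid.
#' @param provenance Optional provenance list.
#' @return An `otf_volume`.
#' @export
otf_volume <- function(data, voxel_size, provenance = list()) {
  fv <- fourier_volume(data, voxel_size)
  n <- dim(data)[1]
  ctr <- n / 2 + 1
  if (min(data) < 0 || max(data) > 1) {
    stop("OTF values must lie in [0, 1]", call. = FALSE)
  }
  if (data[ctr, ctr, ctr] != 1) {
    stop("OTF DC value must be 1", call. = FALSE)
  }
  structure(c(fv, list(provenance = provenance)),
            class = c("otf_volume", "fourier_volume"))
}

#' Build the anisotropic OTF
#'
#' `OTF = clamp(dfsc, 0, 1) * |FT(psf)| / |FT(psf)|_DC`, DC-centred, with
#' the DC value exactly 1. Negative dFSC values are clamped to zero before
#' the product: negative shell correlations are noise and a transfer
#' magnitude is nonnegative. The Gaussian factor acts as an overall
#' B-factor-like envelope suppressing high-frequency noise build-up during
#' deconvolution.
#'
#' @param dfsc_vol A [fourier_volume()], typically from
#'   [render_dfsc_volume()].
#' @param psf A [volume3d()] point-spread function, typically from
#'   [gaussian_psf()].
#' @param provenance Optional list stored on the result (e.g. sigma,
#'   apex angle, direction count).
#' @return An `otf_volume`: a [fourier_volume()] subclass with values in
#'   `[0, 1]`, DC exactly 1.
#' @export
build_otf <- function(dfsc_vol, psf, provenance = list()) {
  stopifnot(inherits(dfsc_vol, "fourier_volume"), inherits(psf, "volume3d"))
  if (!identical(dim(dfsc_vol$data), dim(psf$data))) {
    stop("shape mismatch between dFSC volume and PSF", call. = FALSE)
  }
  n <- dim(psf$data)[1]
  # PSF is centred on the grid centre: uncenter before the FFT so its
  # transform has no phase ramp, then recenter the magnitude.
  g <- fft_center(Mod(fft_fwd(fft_uncenter(psf$data))))
  ctr <- n / 2 + 1
  g <- g / g[ctr, ctr, ctr]
  d <- dfsc_vol$data
  d[d < 0] <- 0
  d[d > 1] <- 1
  out <- d * g
  out[out > 1] <- 1       # guard the last ulp of the envelope division
  out[ctr, ctr, ctr] <- 1
  otf_volume(out, dfsc_vol$voxel_size, provenance)
}

#' @export
print.otf_volume <- function(x, ...) {
  cat(sprintf("<otf_volume> %d^3, range [%.4g, %.4g]\n",
              dim(x$data)[1], min(x$data), max(x$data)))
  invisible(x)
}
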