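# Anisotropy metrics and the smoothing/nonlinearity grid screen.

#' Default smoothing grid for the parameter screen
#'
#' The 18 smoothing weights of the standard screen.
#' @return Numeric vector of length 18.
#' @export
default_smoothing_grid <- function() {
  c(5e-5, 5e-4, 5e-3, 1e-2, 2e-2, 5e-2, 1e-1, 2e-1, 5e-1,
    1, 2, 5, 1e1, 2e1, 5e1, 1e2, 2e2, 5e2)
}

#' Default nonlinearity grid for the parameter screen
#'
#' The 8 nonlinearity scales of the standard screen.
#' @return Numeric vector of length 8.
#' @export
default_nonlinearity_grid <- function() {
  c(1, 1e1, 1e2, 1e3, 1e4, 1e5, 1e6, 1e7)
}

#' Full width at half maximum along the grid axes
#'
#' Measures the FWHM of a point feature along 1D profiles through `center`
#' parallel to x, y and z, with linear interpolation at the half-maximum
#' crossings. An anisotropically degraded blob is elongated along the
#' missing-cone axis, so the ratio `FWHM_z / FWHM_x` quantifies map
#' elongation.
#'
#' @param v A [volume3d()].
#' @param center Integer grid point `c(i, j, k)`; defaults to the global
#'   maximum voxel. Must sit on a positive local feature.
#' @return Tibble with `fwhm_x`, `fwhm_y`, `fwhm_z` in Angstrom.
#' @export
fwhm_axes <- function(v, center = NULL) {
  stopifnot(inherits(v, "volume3d"))
  if (is.null(center)) {
    center <- which(v$data == max(v$data), arr.ind = TRUE)[1, ]
  }
  center <- as.integer(center)
  peak <- v$data[center[1], center[2], center[3]]
  if (peak <= 0) stop("value at center must be positive", call. = FALSE)
  prof <- list(
    x = v$data[, center[2], center[3]],
    y = v$data[center[1], , center[3]],
    z = v$data[center[1], center[2], ]
  )
  w <- vapply(seq_along(prof), function(a) {
    fwhm_1d(prof[[a]], center[a], peak) * v$voxel_size
  }, numeric(1))
  tibble::tibble(fwhm_x = w[1], fwhm_y = w[2], fwhm_z = w[3])
}

# Half-max crossing positions by outward walk + linear interpolation.
fwhm_1d <- function(p, i0, peak) {
  half <- peak / 2
  n <- length(p)
  right <- NA_real_
  for (i in seq(i0, n - 1)) {
    if (p[i] >= half && p[i + 1] < half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1])
      break
    }
  }
  left <- NA_real_
  for (i in seq(i0, 2)) {
    if (p[i] >= half && p[i - 1] < half) {
      left <- i - (p[i] - half) / (p[i] - p[i - 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("half-maximum not crossed within the box", call. = FALSE)
  }
  right - left
}

#' Mean resolution inside and outside a cone of directions
#'
#' Splits the sampled dFSC directions into those within `half_angle`
#' degrees of `axis` (or its antipode) and the rest, and averages the
#' per-direction threshold resolutions over each partition — the summary
#' behind inside/outside-missing-cone comparisons.
#'
#' @param r A `dfsc_result`.
#' @param axis Cone axis.
#' @param half_angle Cone half-angle in degrees (< 90; at 90 the outside
#'   partition is empty).
#' @param threshold FSC threshold (default 0.143).
#' @return One-row tibble: `inside_mean`, `outside_mean` (Angstrom),
#'   `n_inside`, `n_outside`.
#' @export
cone_partition_resolution <- function(r, axis, half_angle,
                                      threshold = 0.143) {
  stopifnot(inherits(r, "dfsc_result"))
  res <- per_direction_resolution(r, threshold)
  a <- axis / sqrt(sum(axis^2))
  inside <- abs(as.matrix(res[, c("x", "y", "z")]) %*% a) >=
    cos(half_angle * pi / 180)
  if (!any(inside) || all(inside)) {
    stop("empty direction partition at half_angle = ", half_angle,
         call. = FALSE)
  }
  tibble::tibble(
    inside_mean = mean(res$resolution[inside]),
    outside_mean = mean(res$resolution[!inside]),
    n_inside = sum(inside), n_outside = sum(!inside)
  )
}

#' Anisotropy report
#'
#' Per-direction resolution statistics at a threshold, optionally the
#' inside/outside-cone means and the axial FWHM of a point feature.
#'
#' @param r A `dfsc_result`.
#' @param threshold FSC threshold (default 0.143).
#' @param axis,half_angle Optional cone for the inside/outside split.
#' @param volume,center Optional [volume3d()] (and feature position) for
#'   the FWHM columns.
#' @return One-row tibble.
#' @export
anisotropy_report <- function(r, threshold = 0.143, axis = NULL,
                              half_angle = NULL, volume = NULL,
                              center = NULL) {
  res <- per_direction_resolution(r, threshold)$resolution
  out <- tibble::tibble(res_min = min(res), res_mean = mean(res),
                        res_max = max(res))
  if (!is.null(axis) && !is.null(half_angle)) {
    out <- dplyr::bind_cols(out,
      cone_partition_resolution(r, axis, half_angle, threshold))
  }
  if (!is.null(volume)) {
    out <- dplyr::bind_cols(out, fwhm_axes(volume, center))
  }
  out
}

#' Write an anisotropy report as JSON
#'
#' @param report A one-row tibble from [anisotropy_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Grid screen of smoothing and nonlinearity parameters
#'
#' Deconvolves `g` for every (smoothing, nonlinearity) pair and scores each
#' restoration by the mean per-direction resolution of the dFSC between the
#' restored map and a reference (ground-truth or model) map at the 0.5
#' criterion — lower (better Angstrom) is better. The default grids are the
#' standard 18 x 8 screen.
#'
#' @param g Observed [volume3d()].
#' @param otf An `otf_volume`.
#' @param reference Reference [volume3d()] of the same shape.
#' @param smoothing_grid,nonlinearity_grid Parameter grids.
#' @param params Base [deconv_params()] supplying the iteration budget and
#'   positivity flag for every run.
#' @param n_dirs,apex_angle dFSC sampling used for scoring (modest defaults
#'   keep the screen fast; scoring only ranks, it is not the final dFSC).
#' @param threshold Scoring FSC threshold (default 0.5, the map-to-model
#'   convention).
#' @return A `screen_table` tibble: `smoothing`, `nonlinearity`,
#'   `score` (mean resolution, A), `objective`, `rank`, sorted best-first.
#' @export
screen_parameters <- function(g, otf, reference,
                              smoothing_grid = default_smoothing_grid(),
                              nonlinearity_grid = default_nonlinearity_grid(),
                              params = deconv_params(),
                              n_dirs = 60, apex_angle = 40,
                              threshold = 0.5) {
  stopifnot(length(smoothing_grid) >= 1, length(nonlinearity_grid) >= 1)
  if (!identical(dim(g$data), dim(reference$data))) {
    stop("reference shape differs from map", call. = FALSE)
  }
  grid <- expand.grid(smoothing = smoothing_grid,
                      nonlinearity = nonlinearity_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    p <- deconv_params(smoothing = grid$smoothing[i],
                       nonlinearity = grid$nonlinearity[i],
                       max_iter = params$max_iter, tol = params$tol,
                       positivity = params$positivity, seed = params$seed)
    dr <- deconvolve(g, otf, p)
    df <- compute_dfsc(dr$volume, reference, n_dirs = n_dirs,
                       apex_angle = apex_angle)
    tibble::tibble(
      smoothing = grid$smoothing[i],
      nonlinearity = grid$nonlinearity[i],
      score = mean(per_direction_resolution(df, threshold)$resolution),
      objective = utils::tail(dr$objective_trace, 1)
    )
  })
  out <- dplyr::arrange(rows, .data$score)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("screen_table", class(out))
  out
}

#' Fourier correlation restricted to a double cone
#'
#' Normalized complex cross-correlation between the Fourier coefficients of
#' two volumes, using only non-DC voxels whose direction lies within
#' `half_angle` degrees of `axis` or `-axis` (and within the Nyquist
#' sphere). Measures how much missing-cone information a restoration has
#' recovered relative to the ground truth.
#'
#' @param v,ref Two [volume3d()]s of identical shape.
#' @param axis Cone axis.
#' @param half_angle Cone half-angle in degrees.
#' @return Single numeric correlation in `[-1, 1]`.
#' @export
fourier_cone_correlation <- function(v, ref, axis, half_angle) {
  stopifnot(inherits(v, "volume3d"), inherits(ref, "volume3d"))
  if (!identical(dim(v$data), dim(ref$data))) {
    stop("shape mismatch", call. = FALSE)
  }
  tm <- fsc_terms(v, ref)
  keep <- cone_membership(tm$u, axis, half_angle)
  sum(tm$num[keep]) / sqrt(sum(tm$d1[keep]) * sum(tm$d2[keep]))
}
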