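# Global and directional Fourier shell correlation.
#
# Shell binning contract (used identically everywhere): a Fourier voxel at
# centered integer offset k belongs to shell round(|k|); shell 0 (DC) is
# excluded from all correlations and shells beyond N/2 (outside the Nyquist
# sphere) are dropped. Shell s has frequency s / (N * voxel_size) 1/A.

# Precompute the Fourier geometry shared by the FSC routines: cross-spectral
# terms, shell indices and unit voxel directions for all non-DC voxels with
# shell index <= N/2.
fsc_terms <- function(h1, h2, mask = NULL) {
  stopifnot(inherits(h1, "volume3d"), inherits(h2, "volume3d"))
  if (!identical(dim(h1$data), dim(h2$data))) {
    stop("half-map shapes differ", call. = FALSE)
  }
  if (abs(h1$voxel_size - h2$voxel_size) > 1e-6 * h1$voxel_size) {
    stop("half-map voxel sizes differ", call. = FALSE)
  }
  a <- h1$data; b <- h2$data
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "volume3d"))
    if (!identical(dim(mask$data), dim(a))) {
      stop("mask shape differs from maps", call. = FALSE)
    }
    a <- a * mask$data
    b <- b * mask$data
  }
  if (all(a == 0) || all(b == 0)) stop("all-zero input volume", call. = FALSE)
  n <- dim(a)[1]
  f1 <- fft_center(fft_fwd(a))
  f2 <- fft_center(fft_fwd(b))
  km <- offset_matrix(n)
  r <- sqrt(rowSums(km^2))
  shell <- as.integer(round(r))
  sel <- shell >= 1L & shell <= n %/% 2L
  u <- km[sel, , drop = FALSE] / r[sel]
  list(
    n = n, voxel_size = h1$voxel_size,
    shell = shell[sel],
    u = u,
    num = as.vector(Re(f1 * Conj(f2)))[sel],
    d1 = as.vector(Mod(f1)^2)[sel],
    d2 = as.vector(Mod(f2)^2)[sel]
  )
}

fsc_from_terms <- function(tm, keep = NULL, min_voxels = 1L) {
  shells <- seq_len(tm$n %/% 2L)
  if (is.null(keep)) {
    sh <- tm$shell; num <- tm$num; d1 <- tm$d1; d2 <- tm$d2
  } else {
    sh <- tm$shell[keep]; num <- tm$num[keep]
    d1 <- tm$d1[keep]; d2 <- tm$d2[keep]
  }
  cnt <- tabulate(sh, nbins = max(shells))
  s_num <- s_d1 <- s_d2 <- numeric(max(shells))
  if (length(sh)) {
    agg <- rowsum(cbind(num, d1, d2), group = sh, reorder = TRUE)
    idx <- as.integer(rownames(agg))
    s_num[idx] <- agg[, 1]; s_d1[idx] <- agg[, 2]; s_d2[idx] <- agg[, 3]
  }
  denom <- sqrt(s_d1 * s_d2)
  fsc <- ifelse(cnt >= min_voxels & denom > 0, s_num / denom, NA_real_)
  tibble::tibble(
    freq = shells / (tm$n * tm$voxel_size),
    fsc = fsc[shells],
    n_voxels = cnt[shells]
  )
}

#' Global Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation
#' `Re<F1 conj(F2)> / sqrt(<|F1|^2><|F2|^2>)` with shells one Fourier voxel
#' wide, DC excluded. If a mask is given both volumes are multiplied by it
#' first.
#'
#' @param h1,h2 Two [volume3d()]s of identical shape and voxel size
#'   (typically unfiltered half-maps).
#' @param mask Optional [volume3d()] mask with values in `[0, 1]`.
#' @return A tibble with columns `freq` (1/A), `fsc`, `n_voxels`.
#' @export
global_fsc <- function(h1, h2, mask = NULL) {
  fsc_from_terms(fsc_terms(h1, h2, mask))
}

#' Conical Fourier shell correlation along one axis
#'
#' FSC restricted to Fourier voxels whose direction lies within `half_angle`
#' degrees of `axis` or `-axis` (a double cone; real-input transforms are
#' Hermitian so both nappes carry the same information). Shells with fewer
#' than `min_voxels` voxels in the cone are reported as `NA`.
#'
#' @param h1,h2 Two [volume3d()]s.
#' @param axis Cone axis (length-3, non-zero).
#' @param half_angle Cone half-angle in degrees, `0 < half_angle <= 90`;
#'   90 degrees reproduces [global_fsc()] exactly.
#' @param mask Optional mask volume.
#' @param min_voxels Minimum cone voxels for a shell to be defined.
#' @return A tibble as in [global_fsc()].
#' @export
conical_fsc <- function(h1, h2, axis, half_angle, mask = NULL,
                        min_voxels = 10L) {
  if (sqrt(sum(axis^2)) == 0) stop("zero axis vector", call. = FALSE)
  stopifnot(half_angle > 0, half_angle <= 90)
  tm <- fsc_terms(h1, h2, mask)
  keep <- cone_membership(tm$u, axis, half_angle)
  fsc_from_terms(tm, keep, min_voxels = min_voxels)
}

cone_membership <- function(u, axis, half_angle) {
  if (half_angle >= 90) return(rep(TRUE, nrow(u)))
  a <- axis / sqrt(sum(axis^2))
  abs(drop(u %*% a)) >= cos(half_angle * pi / 180)
}

#' Directional FSC over a Fibonacci direction set
#'
#' Computes one conical FSC per sampled direction. The apex angle is the
#' full opening of the cone, so each cone uses voxels within
#' `apex_angle / 2` of its axis (or its antipode); with the defaults
#' (500 directions, apex 40 degrees) cones overlap and cover the sphere.
#'
#' @param h1,h2 Half-map [volume3d()]s.
#' @param n_dirs Number of Fibonacci directions (default 500).
#' @param apex_angle Full cone apex angle in degrees (default 40).
#' @param mask Optional mask volume applied to both maps first.
#' @param min_voxels Minimum voxels per defined shell.
#' @return A `dfsc_result`: list with `directions` (tibble), `curves`
#'   (long tibble: `dir`, `freq`, `fsc`, `n_voxels`), `apex_angle`,
#'   `n` (grid side) and `voxel_size`.
#' @export
compute_dfsc <- function(h1, h2, n_dirs = 500, apex_angle = 40, mask = NULL,
                         min_voxels = 10L) {
  stopifnot(n_dirs >= 1, apex_angle > 0, apex_angle <= 180)
  tm <- fsc_terms(h1, h2, mask)
  dirs <- fibonacci_directions(n_dirs)
  half <- apex_angle / 2
  dm <- as.matrix(dirs[, c("x", "y", "z")])
  curves <- purrr::map_dfr(seq_len(nrow(dm)), function(i) {
    keep <- cone_membership(tm$u, dm[i, ], half)
    cv <- fsc_from_terms(tm, keep, min_voxels = min_voxels)
    cv$dir <- dirs$id[i]
    cv
  })
  structure(
    list(directions = dirs,
         curves = curves[, c("dir", "freq", "fsc", "n_voxels")],
         apex_angle = apex_angle, n = tm$n, voxel_size = tm$voxel_size),
    class = "dfsc_result"
  )
}

#' @export
print.dfsc_result <- function(x, ...) {
  cat(sprintf("<dfsc_result> %d directions, apex %g deg, grid %d^3, voxel %.4g A/px\n",
              nrow(x$directions), x$apex_angle, x$n, x$voxel_size))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a directional FSC result
#'
#' @param x A `dfsc_result`.
#' @param ... Unused.
#' @return Long tibble: one row per (direction, shell) with the direction
#'   vector columns joined in.
#' @method tidy dfsc_result
#' @export
tidy.dfsc_result <- function(x, ...) {
  dplyr::left_join(x$curves,
                   dplyr::rename(x$directions, dir = "id"),
                   by = "dir")
}

#' Summarize a directional FSC result
#'
#' @param x A `dfsc_result`.
#' @param threshold FSC resolution criterion (default 0.143, the half-map
#'   convention).
#' @param ... Unused.
#' @return One-row tibble: number of directions, apex angle, and the
#'   min/mean/max of the per-direction resolutions (Angstrom).
#' @method glance dfsc_result
#' @export
glance.dfsc_result <- function(x, threshold = 0.143, ...) {
  res <- per_direction_resolution(x, threshold)$resolution
  tibble::tibble(
    n_dirs = nrow(x$directions), apex_angle = x$apex_angle,
    res_min = min(res), res_mean = mean(res), res_max = max(res)
  )
}

#' Per-direction resolution estimates
#'
#' @param x A `dfsc_result`.
#' @param threshold Correlation threshold.
#' @return Tibble: `dir`, direction vector, `resolution` (A), `crossed`.
#' @export
per_direction_resolution <- function(x, threshold = 0.143) {
  split_curves <- split(x$curves,
                        factor(x$curves$dir, levels = x$directions$id))
  res <- purrr::map_dfr(split_curves, function(cv) {
    r <- estimate_resolution(cv, threshold)
    tibble::tibble(dir = cv$dir[1], resolution = as.numeric(r),
                   crossed = attr(r, "crossed"))
  })
  dplyr::left_join(res, dplyr::rename(x$directions, dir = "id"), by = "dir")
}

#' Resolution at an FSC threshold
#'
#' Reciprocal frequency of the first crossing of the curve below the
#' threshold, linearly interpolated between shells. Undefined (`NA`) shells
#' are ignored. If the curve never drops below the threshold the Nyquist
#' resolution is returned with attribute `crossed = FALSE`.
#'
#' @param curve Tibble with `freq` (1/A, ascending) and `fsc` columns.
#' @param threshold Correlation threshold in (0, 1): 0.143 for half-map
#'   FSC, 0.5 for map-to-model comparisons.
#' @return Resolution in Angstrom (single numeric) with attribute `crossed`.
#' @export
estimate_resolution <- function(curve, threshold = 0.143) {
  stopifnot(threshold > 0, threshold < 1)
  ok <- !is.na(curve$fsc)
  f <- curve$freq[ok]
  v <- curve$fsc[ok]
  if (length(f) == 0) stop("empty FSC curve", call. = FALSE)
  below <- which(v < threshold)
  if (length(below) == 0) {
    return(structure(1 / f[length(f)], crossed = FALSE))
  }
  i <- below[1]
  if (i == 1) {
    fx <- f[1]
  } else {
    fx <- f[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) *
      (f[i] - f[i - 1])
  }
  structure(1 / fx, crossed = TRUE)
}

#' Render the 3D dFSC volume
#'
#' Paints every Fourier voxel with a weighted average of the directional
#' curves, each curve interpolated at the voxel's radial frequency. The
#' weight of the cone with axis d is `max(0, cos(theta) - cos(half_angle))`
#' where `theta` is the angle between the voxel direction and d or -d — a
#' linear-in-cosine falloff that vanishes at the cone edge. Voxels covered
#' by no cone receive the unweighted mean over all directions; DC is 1.
#'
#' @param r A `dfsc_result`.
#' @param shape Grid side of the output (defaults to the source grid).
#' @return A [fourier_volume()] (DC-centred).
#' @export
render_dfsc_volume <- function(r, shape = r$n) {
  stopifnot(inherits(r, "dfsc_result"), nrow(r$directions) >= 1)
  if (shape != r$n) {
    stop("shape mismatch: dFSC computed on a ", r$n, "^3 grid", call. = FALSE)
  }
  n <- shape
  km <- offset_matrix(n)
  rad <- sqrt(rowSums(km^2))
  nz <- rad > 0
  u <- km[nz, , drop = FALSE] / rad[nz]
  rad_nz <- rad[nz]
  dm <- as.matrix(r$directions[, c("x", "y", "z")])
  cos_half <- cos(r$apex_angle / 2 * pi / 180)
  shells <- sort(unique(r$curves$freq)) * (n * r$voxel_size)  # voxel units
  wsum <- vsum <- msum <- numeric(sum(nz))
  curves_by_dir <- split(r$curves, r$curves$dir)
  ids <- r$directions$id
  for (i in seq_along(ids)) {
    cv <- curves_by_dir[[as.character(ids[i])]]
    ok <- !is.na(cv$fsc)
    if (!any(ok)) next
    ci <- stats::approx(x = cv$freq[ok] * (n * r$voxel_size), y = cv$fsc[ok],
                        xout = rad_nz, rule = 2)$y
    w <- pmax(0, abs(drop(u %*% dm[i, ])) - cos_half)
    wsum <- wsum + w
    vsum <- vsum + w * ci
    msum <- msum + ci
  }
  val <- ifelse(wsum > 0, vsum / wsum, msum / length(ids))
  out <- numeric(n^3)
  out[nz] <- val
  out <- array(out, dim = c(n, n, n))
  # enforce exact antipodal symmetry (BLAS summation order can differ in
  # the last ulp between a voxel and its antipode)
  i <- 2:n
  out[i, i, i] <- (out[i, i, i] + out[rev(i), rev(i), rev(i)]) / 2
  ctr <- n / 2 + 1
  out[ctr, ctr, ctr] <- 1
  fourier_volume(out, r$voxel_size)
}

#' Export directional FSC curves as CSV
#'
#' One row per (direction, shell): direction vector, frequency, correlation.
#'
#' @param x A `dfsc_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dfsc_csv <- function(x, path) {
  utils::write.csv(tidy(x), path, row.names = FALSE)
  invisible(path)
}
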