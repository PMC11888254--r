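# Soft-edged bounding-sphere masks.

#' Soft bounding-sphere mask around the above-threshold density
#'
#' The mask centre is the midpoint of the axis-aligned bounding box of all
#' voxels at or above `threshold`; the radius is half the box diagonal, so
#' the sphere circumscribes the box and no above-threshold density is cut.
#' The mask is 1 inside the radius, 0 beyond `radius + edge_px`, with a
#' raised-cosine profile in between (a C0-continuous, band-limited edge).
#'
#' @param v A [volume3d()] (typically the full map).
#' @param threshold Density level delimiting the structure (the display
#'   contour level; e.g. 0.02 for a normalized experimental map).
#' @param edge_px Soft-edge width in pixels (default 20).
#' @return A [volume3d()] mask with values in `[0, 1]`.
#' @export
bounding_sphere_mask <- function(v, threshold, edge_px = 20) {
  stopifnot(inherits(v, "volume3d"), edge_px >= 0)
  idx <- which(v$data >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("empty mask: no voxel reaches threshold ", threshold, call. = FALSE)
  }
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  center <- (lo + hi) / 2
  radius <- max(sqrt(sum(((hi - lo) / 2)^2)), 0.5)
  n <- dim(v$data)[1]
  d1 <- (seq_len(n) - center[1])^2
  d2 <- (seq_len(n) - center[2])^2
  d3 <- (seq_len(n) - center[3])^2
  r <- sqrt(outer(outer(d1, d2, `+`), d3, `+`))
  m <- array(0, dim = dim(v$data))
  m[r <= radius] <- 1
  if (edge_px > 0) {
    e <- r > radius & r < radius + edge_px
    m[e] <- 0.5 * (1 + cos(pi * (r[e] - radius) / edge_px))
  }
  volume3d(m, v$voxel_size, v$origin)
}

#' Apply a mask to a volume
#'
#' Voxelwise product.
#'
#' @param v A [volume3d()].
#' @param m A mask [volume3d()] of the same shape, values in `[0, 1]`.
#' @return Masked `volume3d`.
#' @export
apply_mask <- function(v, m) {
  stopifnot(inherits(v, "volume3d"), inherits(m, "volume3d"))
  if (!identical(dim(v$data), dim(m$data))) {
    stop("mask shape differs from volume", call. = FALSE)
  }
  if (min(m$data) < 0 || max(m$data) > 1) {
    stop("mask values must lie in [0, 1]", call. = FALSE)
  }
  volume3d(v$data * m$data, v$voxel_size, v$origin)
}
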