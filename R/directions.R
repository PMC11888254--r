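# Direction sampling on the sphere and particle orientation handling.
#
# Euler convention (fixed package-wide): ZYZ, R = Rz(rot) then Ry(tilt) then
# Rz(psi) applied in the order R = Rz(psi) %*% Ry(tilt) %*% Rz(rot) — the
# convention of the common 3D refinement packages. The projection/view
# direction of a particle is the third row of that matrix, so its angle to
# the +z axis equals the tilt and is independent of the in-plane angle psi.

#' Quasi-uniform directions on the sphere (Fibonacci lattice)
#'
#' Samples `n` unit vectors from the spherical Fibonacci (golden-angle)
#' lattice covering the full sphere.
#'
#' @param n Number of directions (>= 1).
#' @return A tibble with columns `id`, `x`, `y`, `z` (unit vectors).
#' @export
#' @examples
#' fibonacci_directions(500)
fibonacci_directions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  tibble::tibble(id = i + 1L, x = rho * cos(phi), y = rho * sin(phi), z = z)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}

#' Projection direction from ZYZ Euler angles
#'
#' Returns the view (projection) axis of a particle: the third row of the
#' ZYZ rotation matrix. In closed form:
#' `(-sin(tilt) cos(rot), sin(tilt) sin(rot), cos(tilt))`, so the angle to
#' +z equals `tilt` and `psi` (in-plane rotation) has no effect.
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorised).
#' @return A numeric matrix with one row per angle triple and columns
#'   `x`, `y`, `z`; a single triple yields a 1-row matrix.
#' @export
euler_to_view <- function(rot, tilt, psi = 0) {
  stopifnot(all(is.finite(rot)), all(is.finite(tilt)), all(is.finite(psi)))
  r <- rot * pi / 180
  t <- tilt * pi / 180
  cbind(x = -sin(t) * cos(r), y = sin(t) * sin(r), z = cos(t))
}

#' Build an orientation table from Euler angles
#'
#' @param rot,tilt,psi Euler angles in degrees (ZYZ).
#' @return A tibble with the angles, the derived unit view vector
#'   (`vx`, `vy`, `vz`), the angle to the z axis (`angle_z`, degrees) and a
#'   `keep` flag (initially `TRUE`).
#' @export
orientation_table <- function(rot, tilt, psi = rep(0, length(rot))) {
  v <- euler_to_view(rot, tilt, psi)
  tibble::tibble(
    rot = as.numeric(rot), tilt = as.numeric(tilt), psi = as.numeric(psi),
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    angle_z = acos(pmin(1, pmax(-1, v[, 3]))) * 180 / pi,
    keep = TRUE
  )
}

#' Tilt-range particle selection
#'
#' Marks particles for inclusion when the angle between their view vector
#' and the z axis lies in `[0, lo]` or `[hi, 180]` degrees (boundaries
#' inclusive). With the defaults `lo = 60`, `hi = 120` this is the selection
#' that synthesizes a classic random-conical-tilt dataset with a 60-degree
#' missing cone about z: only near-axial views survive.
#'
#' @param table An [orientation_table()].
#' @param lo,hi Selection bounds in degrees, `0 <= lo <= hi <= 180`.
#' @return The table with the `keep` column updated.
#' @export
filter_by_tilt <- function(table, lo = 60, hi = 120) {
  stopifnot(is.data.frame(table), all(c("angle_z") %in% names(table)))
  if (!(lo >= 0 && hi >= lo && hi <= 180)) {
    stop("require 0 <= lo <= hi <= 180; got lo = ", lo, ", hi = ", hi,
         call. = FALSE)
  }
  # boundaries inclusive, robust to the rounding of acos(cos(angle))
  eps <- 1e-9
  dplyr::mutate(table,
                keep = .data$angle_z <= lo + eps | .data$angle_z >= hi - eps)
}

#' Read an orientation table from a STAR-style file
#'
#' Minimal reader for a single `loop_` block with `_rlnAngleRot`,
#' `_rlnAngleTilt`, `_rlnAnglePsi` columns (degrees); extra columns are
#' tolerated and ignored.
#'
#' @param path Path to the STAR file.
#' @return An [orientation_table()].
#' @export
read_star_orientations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  tags <- grep("^_", lines)
  if (length(tags) == 0) stop("no column tags found in ", path, call. = FALSE)
  tag_names <- sub("\\s.*$", "", lines[tags])
  body <- lines[(max(tags) + 1):length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "#") & !startsWith(body, "data_")]
  rows <- strsplit(body, "\\s+")
  rows <- rows[lengths(rows) == length(tag_names)]
  if (length(rows) == 0) stop("no data rows in ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- tag_names
  need <- c("_rlnAngleRot", "_rlnAngleTilt", "_rlnAnglePsi")
  if (!all(need %in% tag_names)) {
    stop("missing Euler angle columns: ",
         paste(setdiff(need, tag_names), collapse = ", "), call. = FALSE)
  }
  orientation_table(rot = as.numeric(m[, "_rlnAngleRot"]),
                    tilt = as.numeric(m[, "_rlnAngleTilt"]),
                    psi = as.numeric(m[, "_rlnAnglePsi"]))
}

#' Write an orientation table as a STAR-style file
#'
#' Emits the three Euler angle columns plus the keep flag.
#'
#' @param table An [orientation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_star_orientations <- function(table, path) {
  hdr <- c("data_particles", "", "loop_",
           "_rlnAngleRot #1", "_rlnAngleTilt #2", "_rlnAnglePsi #3",
           "_cryodeconKeep #4")
  body <- sprintf("%.6f %.6f %.6f %d",
                  table$rot, table$tilt, table$psi, as.integer(table$keep))
  writeLines(c(hdr, body), path)
  invisible(path)
}
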