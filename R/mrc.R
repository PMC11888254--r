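# MRC2014 / CCP4 map I/O. Little-endian, 1024-byte main header, no extended
# header on write. Only the fields the pipeline needs are interpreted; the
# rest are passed over. Axis order is assumed x-fastest (mapc/mapr/maps =
# 1/2/3), the layout every refinement package writes.

#' Read an MRC/CCP4 density map
#'
#' Reads modes 0 (int8), 1 (int16) and 2 (float32). The voxel size is taken
#' from the header cell dimensions divided by the sampling grid; a relative
#' mismatch above 1e-4 between axes is an error because the pipeline assumes
#' isotropic voxels. Non-cubic volumes are rejected.
#'
#' @param path Path to an existing MRC/CCP4 file.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4L, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                       # nxstart..nzstart
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                       # cellb
  ri(3)                       # mapc, mapr, maps
  rf(3)                       # dmin, dmax, dmean
  ri(2)                       # ispg, nsymbt
  nsymbt <- 0L                # re-read properly below
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 196)
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  if (any(nxyz < 2L) ) {
    stop("not a 3D volume: dimensions ", paste(nxyz, collapse = "x"),
         call. = FALSE)
  }
  nvox <- prod(as.double(nxyz))
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE)
  )
  if (length(dat) != nvox) stop("truncated MRC data block", call. = FALSE)
  vs <- cella / mxyz
  if (any(!is.finite(vs)) || any(vs <= 0)) {
    stop("zero or negative voxel size in MRC header", call. = FALSE)
  }
  if (max(abs(vs - vs[1])) / vs[1] > 1e-4) {
    stop("anisotropic voxel size in header: ",
         paste(signif(vs, 6), collapse = ", "), call. = FALSE)
  }
  volume3d(array(dat, dim = nxyz), voxel_size = vs[1], origin = origin)
}

#' Write a volume as an MRC2014 map (mode 2, float32)
#'
#' Populates the density statistics fields (dmin/dmax/dmean/rms) from the
#' data. Refuses to write non-finite values.
#'
#' @param v A [volume3d()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  if (!all(is.finite(v$data))) {
    stop("refusing to write non-finite voxel values", call. = FALSE)
  }
  n <- dim(v$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  mu <- mean(v$data)
  rms <- sqrt(mean((v$data - mu)^2))
  wi(n)                                   # nx ny nz
  wi(2L)                                  # mode: float32
  wi(c(0L, 0L, 0L))                       # nxstart..
  wi(n)                                   # mx my mz
  wf(n * v$voxel_size)                    # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(v$data), max(v$data), mu))     # dmin dmax dmean
  wi(c(1L, 0L))                           # ispg, nsymbt
  wi(c(0L, 0L, 0L))                       # extra words 25-26, exttyp
  wi(20140L)                              # nversion
  wi(rep(0L, 21))                         # extra words 29-49
  wf(v$origin)                            # origin x y z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(rms)
  wi(1L)                                  # nlabl
  lab <- formatC("cryodecon", width = -80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 720), con, nchars = 720, eos = NULL)
  wf(v$data)
  invisible(path)
}
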