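# End-to-end pipeline: mask -> dFSC -> OTF -> deconvolve -> normalize.

#' Pipeline configuration
#'
#' @param full_map,half1,half2 Paths to the full map and the two unfiltered
#'   half-maps (MRC).
#' @param mask Optional path to a mask volume; ignored when `auto_mask`.
#' @param out_dir Output directory for artifacts.
#' @param n_dirs,apex_angle dFSC sampling (defaults 500 directions,
#'   apex 40 degrees).
#' @param mask_threshold,mask_edge_px Auto-mask contour level and soft-edge
#'   width in pixels.
#' @param smoothing,nonlinearity,max_iter,tol,positivity,seed Deconvolution
#'   parameters (see [deconv_params()]).
#' @param auto_mask Generate a bounding-sphere mask from the full map
#'   (default `TRUE`; set `FALSE` and give `mask` to use an external one,
#'   or leave both off to run unmasked).
#' @param normalize_output Normalize the deconvolved map to zero mean and
#'   unit standard deviation (default `TRUE`).
#' @param res Resolution (Angstrom) for the Gaussian PSF; `NA` (default)
#'   means use the global half-map FSC 0.143 resolution.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(full_map, half1, half2, mask = NA_character_,
                            out_dir = ".", n_dirs = 500, apex_angle = 40,
                            mask_threshold = 0.02, mask_edge_px = 20,
                            smoothing = 0.5, nonlinearity = 10000,
                            max_iter = 100, tol = 1e-6, positivity = TRUE,
                            seed = 0, auto_mask = TRUE,
                            normalize_output = TRUE, res = NA_real_) {
  mask <- if (length(mask) != 1 || is.na(mask)) NA_character_ else
    as.character(mask)
  res <- as.numeric(res)
  structure(list(
    full_map = full_map, half1 = half1, half2 = half2, mask = mask,
    out_dir = out_dir, n_dirs = n_dirs, apex_angle = apex_angle,
    mask_threshold = mask_threshold, mask_edge_px = mask_edge_px,
    smoothing = smoothing, nonlinearity = nonlinearity,
    max_iter = max_iter, tol = tol, positivity = positivity, seed = seed,
    auto_mask = auto_mask, normalize_output = normalize_output, res = res
  ), class = "pipeline_config")
}

#' Write a pipeline config as a flat key = value file
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(x) {
    if (is.na(x)) "NA"
    else if (is.character(x)) sprintf('"%s"', x)
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 17)
  }, character(1))
  writeLines(paste(names(cfg), "=", fmt), path)
  invisible(path)
}

#' Read a pipeline config written by [write_pipeline_config()]
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (identical(v, "NA")) NA
    else if (grepl('^".*"$', v)) sub('^"(.*)"$', "\\1", v)
    else if (v %in% c("true", "false")) v == "true"
    else as.numeric(v)
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(pipeline_config, vals)
}

#' Run the full restoration pipeline
#'
#' Reads the full map and half-maps, checks their consistency, builds (or
#' loads) the mask, computes the directional FSC from the masked half-maps,
#' renders the dFSC volume, builds the OTF from it and the Gaussian PSF at
#' the global 0.143 resolution, deconvolves the masked full map and
#' (optionally) normalizes the result. Writes four artifacts under
#' `out_dir`: `dfsc.csv`, `dfsc_volume.mrc`, `otf.mrc`, `deconvolved.mrc`,
#' plus `pipeline.log` with parameters and the objective trace.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the `dfsc_result`, the OTF, the
#'   `deconv_result`, the global resolution used, and artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  full <- read_volume(cfg$full_map)
  h1 <- read_volume(cfg$half1)
  h2 <- read_volume(cfg$half2)
  for (v in list(h1, h2)) {
    if (!identical(dim(v$data), dim(full$data))) {
      stop("half-map shape differs from full map", call. = FALSE)
    }
    if (abs(v$voxel_size - full$voxel_size) > 1e-6 * full$voxel_size) {
      stop("half-map voxel size differs from full map", call. = FALSE)
    }
  }
  mask <- NULL
  if (isTRUE(cfg$auto_mask)) {
    mask <- bounding_sphere_mask(full, cfg$mask_threshold, cfg$mask_edge_px)
  } else if (!is.na(cfg$mask) && nzchar(cfg$mask)) {
    mask <- read_volume(cfg$mask)
  }

  r <- compute_dfsc(h1, h2, n_dirs = cfg$n_dirs,
                    apex_angle = cfg$apex_angle, mask = mask)
  gfsc <- global_fsc(h1, h2, mask = mask)
  res <- if (is.finite(cfg$res)) cfg$res else
    as.numeric(estimate_resolution(gfsc, 0.143))
  dvol <- render_dfsc_volume(r)
  psf <- gaussian_psf(sigma_from_resolution(res, full$voxel_size),
                      dim(full$data)[1], full$voxel_size)
  otf <- build_otf(dvol, psf,
                   provenance = list(res = res, apex_angle = cfg$apex_angle,
                                     n_dirs = cfg$n_dirs))
  target <- if (is.null(mask)) full else apply_mask(full, mask)
  p <- deconv_params(smoothing = cfg$smoothing,
                     nonlinearity = cfg$nonlinearity,
                     max_iter = cfg$max_iter, tol = cfg$tol,
                     positivity = cfg$positivity, seed = cfg$seed)
  dr <- deconvolve(target, otf, p)
  out_vol <- if (isTRUE(cfg$normalize_output)) normalize_volume(dr$volume)
             else dr$volume

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    dfsc_csv = file.path(cfg$out_dir, "dfsc.csv"),
    dfsc_volume = file.path(cfg$out_dir, "dfsc_volume.mrc"),
    otf = file.path(cfg$out_dir, "otf.mrc"),
    deconvolved = file.path(cfg$out_dir, "deconvolved.mrc"),
    log = file.path(cfg$out_dir, "pipeline.log")
  )
  write_dfsc_csv(r, paths$dfsc_csv)
  write_volume(volume3d(dvol$data, dvol$voxel_size), paths$dfsc_volume)
  write_volume(volume3d(otf$data, otf$voxel_size), paths$otf)
  write_volume(out_vol, paths$deconvolved)
  log_lines <- c(
    sprintf("cryodecon %s", as.character(utils::packageVersion("cryodecon"))),
    sprintf("global FSC(0.143) resolution: %.4f A", res),
    sprintf("params: smoothing=%g nonlinearity=%g max_iter=%d seed=%d",
            cfg$smoothing, cfg$nonlinearity, as.integer(cfg$max_iter),
            as.integer(cfg$seed)),
    sprintf("objective[%d]: %.10g", seq_along(dr$objective_trace) - 1L,
            dr$objective_trace),
    vapply(paths[1:4], function(pth)
      sprintf("artifact %s md5 %s", pth, unname(tools::md5sum(pth))),
      character(1))
  )
  writeLines(log_lines, paths$log)
  invisible(list(dfsc = r, otf = otf, deconv = dr, resolution = res,
                 volume = out_vol, paths = paths))
}
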