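# On-disk formats: map containers (directory of 32-bit TIFFs plus a JSON
# metadata sidecar), voxel grids and phantom specifications (YAML).
# Lengths are stored in um, densities in g/cm^3, counts in photons; the
# units and the per-map scale factors live in the metadata.

.write_scaled_tiff <- function(m, path) {
  scale <- max(m, 1e-300)
  if (scale <= 1) scale <- 1
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  scale
}

.read_scaled_tiff <- function(path, scale) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * scale
}

#' Write an XRF map set to a directory container
#'
#' Layout: `meta.json` (beam, geometry, seed, units and per-map scale
#' factors), `stxm.tif`, and `xrf/<detector>/<line>.tif`, every map a
#' max-scaled 32-bit TIFF (lossless to better than single precision).
#'
#' @param mapset an `xrf_map_set`.
#' @param path container directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_map_container <- function(mapset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scales <- list()
  for (det in names(mapset$xrf)) {
    ddir <- file.path(path, "xrf", det)
    dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
    for (l in names(mapset$xrf[[det]]))
      scales[[det]][[l]] <-
        .write_scaled_tiff(mapset$xrf[[det]][[l]],
                           file.path(ddir, paste0(l, ".tif")))
  }
  stxm_scale <- .write_scaled_tiff(mapset$stxm, file.path(path, "stxm.tif"))
  meta <- mapset$meta
  meta$units <- list(length = "um", counts = "photons", density = "g/cm^3")
  meta$scales <- scales
  meta$stxm_scale <- stxm_scale
  meta$format_version <- 1L
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an XRF map set from a directory container
#'
#' @param path container directory written by [write_map_container()].
#' @return An `xrf_map_set`.
#' @export
read_map_container <- function(path) {
  metaf <- file.path(path, "meta.json")
  if (!file.exists(metaf)) stop("not a map container: missing meta.json in ", path)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  stxmf <- file.path(path, "stxm.tif")
  if (!file.exists(stxmf)) stop("invalid container: missing dataset stxm")
  stxm <- .read_scaled_tiff(stxmf, meta$stxm_scale)
  scales <- meta$scales
  xrf <- lapply(names(scales), function(det) {
    maps <- lapply(names(scales[[det]]), function(l) {
      f <- file.path(path, "xrf", det, paste0(l, ".tif"))
      if (!file.exists(f)) stop("invalid container: missing dataset xrf/",
                                det, "/", l)
      m <- .read_scaled_tiff(f, scales[[det]][[l]])
      if (!all(dim(m) == dim(stxm)))
        stop("shape of xrf/", det, "/", l, " differs from stxm")
      m
    })
    names(maps) <- names(scales[[det]])
    maps
  })
  names(xrf) <- names(scales)
  meta$scales <- NULL
  meta$stxm_scale <- NULL
  structure(list(xrf = xrf, stxm = stxm, meta = meta),
            class = "xrf_map_set")
}

#' Write a single map as a scaled 32-bit TIFF with a JSON sidecar
#' @param m matrix.
#' @param path output `.tif` path (the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(m, path) {
  scale <- .write_scaled_tiff(m, path)
  jsonlite::write_json(list(scale = scale, units = "as-produced"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#' @param path `.tif` path.
#' @return Matrix.
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .read_scaled_tiff(path, meta$scale)
}

#' Write a voxel grid to a directory container
#' @param g a `voxel_grid`.
#' @param path directory.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scales <- list(
    thickness = .write_scaled_tiff(g$thickness, file.path(path, "thickness.tif")),
    zbot = .write_scaled_tiff(g$zbot, file.path(path, "zbot.tif")),
    density = .write_scaled_tiff(g$density, file.path(path, "density.tif")))
  fr <- list()
  for (el in names(g$fractions))
    fr[[el]] <- .write_scaled_tiff(g$fractions[[el]],
                                   file.path(path, paste0("fraction_", el, ".tif")))
  jsonlite::write_json(list(shape = c(g$ny, g$nx, g$nz), voxel = g$voxel,
                            scales = scales, fraction_scales = fr,
                            units = list(length = "um", density = "g/cm^3")),
                       file.path(path, "grid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a voxel grid container
#' @param path directory written by [write_grid()].
#' @return A `voxel_grid`.
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "grid.json"),
                              simplifyVector = TRUE)
  rd <- function(nm, sc) .read_scaled_tiff(file.path(path, nm), sc)
  fr <- lapply(names(meta$fraction_scales), function(el)
    rd(paste0("fraction_", el, ".tif"), meta$fraction_scales[[el]]))
  names(fr) <- names(meta$fraction_scales)
  voxel_grid(meta$shape, meta$voxel,
             thickness = round(rd("thickness.tif", meta$scales$thickness)),
             zbot = round(rd("zbot.tif", meta$scales$zbot)),
             density = rd("density.tif", meta$scales$density),
             fractions = fr)
}

#' Write a phantom specification as YAML
#' @param spec a `phantom_spec`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(list(
    grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
    hemispheres = as.list(as.data.frame(spec$hemispheres)),
    base_fractions = as.list(spec$base_fractions),
    density = spec$density,
    mg_rois = if (is.null(spec$mg_rois)) NULL else
      as.list(as.data.frame(spec$mg_rois)),
    roi_element = spec$roi_element), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#' @param path YAML file written by [write_phantom_spec()].
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(grid_shape = unlist(y$grid_shape),
               voxel_size = y$voxel_size,
               hemispheres = as.data.frame(y$hemispheres),
               base_fractions = unlist(y$base_fractions),
               density = y$density,
               mg_rois = if (is.null(y$mg_rois)) NULL else
                 as.data.frame(y$mg_rois),
               roi_element = y$roi_element)
}
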