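# Voxelized sample container and the three-cell test phantom.
#
# A sample is a grid of contiguous vertical columns resting at integer voxel
# offsets: per pixel the occupied interval along z is
# [zbot, zbot + thickness] voxels. Composition is homogeneous along z within
# a column (the stated assumption of the method), so density and mass
# fractions are per-pixel 2D fields.

#' Construct a voxelized sample grid
#'
#' @param shape integer `(ny, nx, nz)` voxel counts; maps are indexed
#'   `(row = y, col = x)` with pixel (1, 1) at the North-West corner and x
#'   increasing East; z counts up from the support plane.
#' @param voxel_size voxel edge in um.
#' @param thickness integer matrix `(ny, nx)` of occupied voxels per column.
#' @param zbot integer matrix of support offsets in voxels (0 = resting on
#'   the support); defaults to all zero.
#' @param density per-pixel density matrix in g/cm^3 (or a scalar).
#' @param fractions named list of per-pixel mass-fraction matrices (or a
#'   named vector of scalars applied uniformly).
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = 1, thickness,
                       zbot = NULL, density = 0, fractions = list()) {
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  thickness <- matrix(as.integer(round(thickness)), ny, nx)
  if (is.null(zbot)) zbot <- matrix(0L, ny, nx)
  zbot <- matrix(as.integer(round(zbot)), ny, nx)
  if (length(density) == 1) density <- matrix(density, ny, nx)
  if (!is.list(fractions))
    fractions <- lapply(as.list(fractions), function(w) matrix(w, ny, nx))
  g <- structure(list(ny = ny, nx = nx, nz = nz, voxel = voxel_size,
                      thickness = thickness, zbot = zbot,
                      density = density, fractions = fractions),
                 class = "voxel_grid")
  validate_voxel_grid(g)
  g
}

#' Validate voxel-grid invariants
#'
#' Occupied columns carry a positive density and mass fractions summing to
#' 1; columns fit inside the grid; empty pixels have zero density.
#'
#' @param g a `voxel_grid`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_voxel_grid <- function(g) {
  occ <- g$thickness > 0
  if (any(g$thickness < 0)) stop("negative column thickness")
  if (any(g$zbot < 0)) stop("negative column offset")
  if (any(g$zbot + g$thickness > g$nz)) stop("column extends above the grid")
  if (any(occ & (g$density <= 0))) stop("occupied pixel with non-positive density")
  if (length(g$fractions)) {
    wsum <- Reduce(`+`, g$fractions)
    if (any(occ & abs(wsum - 1) > 1e-9))
      stop("occupied pixel with mass fractions not summing to 1")
  }
  invisible(g)
}

#' 3D occupancy array of a grid
#' @param g a `voxel_grid`.
#' @return Logical array `(ny, nx, nz)`.
#' @export
occupancy_array <- function(g) {
  occ <- array(FALSE, c(g$ny, g$nx, g$nz))
  kz <- rep(seq_len(g$nz), each = g$ny * g$nx)
  zb <- rep(as.vector(g$zbot), g$nz)
  tv <- rep(as.vector(g$thickness), g$nz)
  occ[] <- (kz > zb) & (kz <= zb + tv)
  occ
}

#' Per-pixel thickness map
#' @param g a `voxel_grid`.
#' @return Matrix of sample thickness along the beam axis in um.
#' @export
thickness_map <- function(g) g$thickness * g$voxel

#' Total occupied sample volume
#' @param g a `voxel_grid`.
#' @return Volume in um^3.
#' @export
grid_volume <- function(g) sum(g$thickness) * g$voxel^3

#' Specification of a hemispherical-cell phantom
#'
#' @param grid_shape `(ny, nx, nz)` voxels.
#' @param voxel_size um.
#' @param hemispheres data frame with columns `cx`, `cy` (center, um) and
#'   `r` (radius, um); hemispheres rest flat on the support plane.
#' @param base_fractions named mass-fraction vector for the whole sample.
#' @param density g/cm^3.
#' @param mg_rois data frame with columns `cx`, `cy`, `r`, `fraction`:
#'   disk regions where the named `roi_element` is introduced at the given
#'   mass fraction, the remaining composition rescaled accordingly.
#' @param roi_element element introduced inside `mg_rois`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 14), voxel_size = 1,
                         hemispheres = data.frame(cx = numeric(), cy = numeric(),
                                                  r = numeric()),
                         base_fractions = lovo_fractions(),
                         density = 1.25,
                         mg_rois = NULL, roi_element = "Mg") {
  if (any(hemispheres$r <= 0)) stop("hemisphere radii must be positive")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 hemispheres = hemispheres, base_fractions = base_fractions,
                 density = density, mg_rois = mg_rois,
                 roi_element = roi_element),
            class = "phantom_spec")
}

#' The canonical three-cell phantom specification
#'
#' Three hemispherical cells of radii 6, 9 and 12 um with LoVo-like
#' composition (61% C, 17% N, 16% O, balance H) at 1.25 g/cm^3, resting on
#' the support plane with all three footprints mutually overlapping
#' slightly. The center placement was calibrated once so that the union 2D
#' footprint on the 1 um grid is exactly 778 pixels, then frozen. Three
#' 2 um disks (one per cell) carry 4% Mg with the remaining composition
#' rescaled by 0.96. `scale` magnifies all lengths (the 2.5x variant lives
#' in a 100 x 100 x 100 um^3 grid).
#'
#' @param scale geometric magnification factor.
#' @return A `phantom_spec`.
#' @export
canonical_phantom_spec <- function(scale = 1) {
  hemis <- data.frame(cx = c(16.4, 9.5, 27.5),
                      cy = c(28.8, 17.2, 17.2),
                      r = c(6, 9, 12))
  # ROI disks sit at half-radius off each apex: the thickest pixel of every
  # cell keeps the base composition, so the most-absorbing pixel used to
  # anchor the thickness retrieval carries the average density.
  rois <- data.frame(cx = hemis$cx, cy = hemis$cy - hemis$r / 2,
                     r = 2, fraction = 0.04)
  if (scale == 1) {
    shape <- c(40, 40, 14)
  } else {
    shape <- rep(ceiling(40 * scale / 10) * 10, 3)
  }
  phantom_spec(grid_shape = shape, voxel_size = 1,
               hemispheres = transform(hemis, cx = cx * scale,
                                       cy = cy * scale, r = r * scale),
               mg_rois = transform(rois, cx = cx * scale, cy = cy * scale,
                                   r = r * scale))
}

#' Build a voxelized phantom from its specification
#'
#' A voxel is occupied iff its center lies inside at least one hemisphere;
#' equivalently each column's thickness is the count of voxel z-centers
#' under the tallest covering hemisphere. Composition is the base mixture,
#' overridden inside the ROI disks.
#'
#' @param spec a `phantom_spec`.
#' @return A `voxel_grid`.
#' @export
build_phantom <- function(spec) {
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  vox <- spec$voxel_size
  xs <- matrix(rep((seq_len(nx) - 0.5) * vox, each = ny), ny, nx)
  ys <- matrix(rep((seq_len(ny) - 0.5) * vox, times = nx), ny, nx)
  h2 <- matrix(0, ny, nx)  # squared height of the union surface
  for (k in seq_len(nrow(spec$hemispheres))) {
    cx <- spec$hemispheres$cx[k]; cy <- spec$hemispheres$cy[k]
    r <- spec$hemispheres$r[k]
    if (cx - r < 0 || cx + r > nx * vox || cy - r < 0 || cy + r > ny * vox ||
        r > nz * vox)
      stop("hemisphere ", k, " does not fit inside the grid")
    h2 <- pmax(h2, r^2 - ((xs - cx)^2 + (ys - cy)^2))
  }
  # thickness = number of voxel z-centers (k - 0.5) vox below sqrt(h2)
  thick <- ifelse(h2 > 0, floor(pmax(0, sqrt(pmax(h2, 0))) / vox + 0.5), 0)
  thick <- pmin(thick, nz)

  fr <- lapply(spec$base_fractions, function(w) matrix(w, ny, nx))
  names(fr) <- names(spec$base_fractions)
  if (!is.null(spec$mg_rois) && nrow(spec$mg_rois)) {
    el <- spec$roi_element
    if (is.null(fr[[el]])) fr[[el]] <- matrix(0, ny, nx)
    for (k in seq_len(nrow(spec$mg_rois))) {
      d2 <- (xs - spec$mg_rois$cx[k])^2 + (ys - spec$mg_rois$cy[k])^2
      inroi <- d2 <= spec$mg_rois$r[k]^2 & thick > 0
      f <- spec$mg_rois$fraction[k]
      for (nm in names(fr))
        fr[[nm]][inroi] <- if (nm == el) f else fr[[nm]][inroi] * (1 - f)
    }
  }
  dens <- matrix(0, ny, nx)
  dens[thick > 0] <- spec$density
  for (nm in names(fr)) fr[[nm]][thick == 0] <- 0
  # renormalize occupied pixels exactly (guards accumulated rounding)
  wsum <- Reduce(`+`, fr)
  for (nm in names(fr)) fr[[nm]][thick > 0] <- fr[[nm]][thick > 0] / wsum[thick > 0]
  voxel_grid(c(ny, nx, nz), vox, thickness = thick, density = dens,
             fractions = fr)
}
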