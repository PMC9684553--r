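# Forward XRF simulation: incident-beam attenuation, per-voxel emission,
# exit-path self-absorption toward each detector, and the resulting 2D
# count maps plus the STXM transmission map.

#' Incident beam configuration
#'
#' @param E0 incident energy in eV (the low-energy multi-detector regime
#'   spans roughly 400-2200 eV; the default 1500 eV excites the K lines of
#'   C, N, O and Mg). Perpendicular incidence along -z onto the support.
#' @param I0 incident photons per pixel integrated over the exposure.
#' @param tables constants registry.
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(E0 = 1500, I0 = 1e8, tables = xrf_constants()) {
  if (I0 <= 0) stop("I0 must be positive")
  .check_energy(E0, tables)
  structure(list(E0 = E0, I0 = I0), class = "beam_config")
}

.compass <- data.frame(
  name = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
  ux = c(0, 1, 1, 1, 0, -1, -1, -1) / c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)),
  uy = c(-1, -1, 0, 1, 1, 1, 0, -1) / c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)),
  stringsAsFactors = FALSE
)

#' One silicon drift detector specification
#'
#' @param name detector label.
#' @param face_center `(x, y, z)` of the face center in um (sample frame,
#'   support plane at z = 0).
#' @param grid_center `(x, y, z)` the face normal points at.
#' @param face_side square face edge length in um.
#' @param n_face integer: ray targets are an `n_face x n_face` deterministic
#'   uniform grid over the face.
#' @return Object of class `detector_spec` with the face ray-target points
#'   and the far-field solid-angle fraction.
#' @export
detector_spec <- function(name, face_center, grid_center, face_side = 5000,
                          n_face = 3) {
  if (n_face < 1) stop("n_face must be >= 1")
  d <- grid_center - face_center
  dist <- sqrt(sum(d^2))
  nrm <- d / dist
  # in-face orthonormal axes
  zax <- c(0, 0, 1)
  e1 <- c(nrm[2], -nrm[1], 0)
  if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0) else e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  off <- if (n_face == 1) 0 else (seq_len(n_face) - (n_face + 1) / 2) *
    face_side / n_face
  pts <- as.matrix(expand.grid(a = off, b = off))
  face_points <- t(apply(pts, 1, function(p)
    face_center + p[1] * e1 + p[2] * e2))
  structure(list(name = name, face_center = face_center,
                 normal = nrm, face_side = face_side,
                 face_points = face_points,
                 distance = dist,
                 half_angle = atan((face_side / 2) / dist),
                 solid_angle_fraction = face_side^2 / (4 * pi * dist^2)),
            class = "detector_spec")
}

#' The eight-detector compass ring
#'
#' Detector geometry is instrument configuration, not part of the physical
#' model: defaults place eight detectors at azimuths 45 degrees apart
#' (named N, NE, ..., NW by the map convention: row 1 = North, x increasing
#' East), elevation 30 degrees above the support plane, face centers 28 mm
#' from the grid center, square 5 mm faces aimed at the grid center. In the
#' far field the solid-angle fraction is constant per detector,
#' `A cos(gamma) / (4 pi d^2)` with `gamma = 0`.
#'
#' @param grid a `voxel_grid` (fixes the grid center the ring aims at).
#' @param distance face-center distance from the grid center in um.
#' @param elevation_deg elevation above the support plane in degrees.
#' @param face_side face edge in um.
#' @param n_face ray-target grid order per face (default 3, i.e. 9 targets).
#' @param names subset of compass names to build.
#' @return Named list of `detector_spec`.
#' @export
detector_ring <- function(grid, distance = 28000, elevation_deg = 30,
                          face_side = 5000, n_face = 3,
                          names = .compass$name) {
  gc <- c(grid$nx * grid$voxel / 2, grid$ny * grid$voxel / 2,
          grid$nz * grid$voxel / 2)
  el <- elevation_deg * pi / 180
  out <- lapply(names, function(nm) {
    row <- .compass[.compass$name == nm, ]
    if (nrow(row) != 1) stop("unknown detector name '", nm, "'")
    fc <- c(gc[1] + distance * cos(el) * row$ux,
            gc[2] + distance * cos(el) * row$uy,
            gc[3] + distance * sin(el))
    detector_spec(nm, fc, gc, face_side, n_face)
  })
  names(out) <- names
  out
}

#' Per-pixel linear attenuation map of a grid at one energy
#'
#' Mixture-rule mass attenuation of the local composition times the local
#' density, converted to per-um units. Composition is homogeneous along z
#' within each column, so the field is 2D.
#'
#' @param g a `voxel_grid`.
#' @param E energy in eV.
#' @param tables constants registry.
#' @return Matrix `(ny, nx)` of mu_s * rho in um^-1 (zero on empty pixels).
#' @export
attenuation_map <- function(g, E, tables = xrf_constants()) {
  mus <- matrix(0, g$ny, g$nx)
  for (el in names(g$fractions))
    mus <- mus + g$fractions[[el]] * mu_element(el, E, tables)
  mus * g$density * 1e-4   # cm^2/g * g/cm^3 = cm^-1 -> um^-1
}

#' Incident-beam intensity per voxel
#'
#' Beer-Lambert attenuation of the beam along -z: each voxel sees
#' `I0 exp(-sum mu_s rho dz)` cumulated over the overburden above it, with
#' a half-voxel midpoint term for the voxel's own layer.
#'
#' @param g a `voxel_grid`.
#' @param beam a `beam_config`.
#' @param tables constants registry.
#' @return Array `(ny, nx, nz)` of photons per voxel.
#' @export
incident_profile <- function(g, beam, tables = xrf_constants()) {
  att <- attenuation_map(g, beam$E0, tables)   # per um
  prof <- array(beam$I0, c(g$ny, g$nx, g$nz))
  ztopv <- g$zbot + g$thickness
  for (k in seq_len(g$nz)) {
    # overburden (voxels) above voxel k inside the column, + half own layer
    over <- pmax(0, pmin(ztopv - k, g$thickness)) +
      ifelse(k > g$zbot & k <= ztopv, 0.5, 0)
    prof[, , k] <- beam$I0 * exp(-att * over * g$voxel)
  }
  prof
}

#' STXM transmission map
#'
#' @inheritParams incident_profile
#' @return Matrix of transmitted fraction in (0, 1].
#' @export
stxm_map <- function(g, beam, tables = xrf_constants()) {
  exp(-attenuation_map(g, beam$E0, tables) * thickness_map(g))
}

#' 3D emission matrix of one line (photons produced before self-absorption)
#'
#' Per voxel: `w_j rho tau_j(E0) Y I0 exp(-mu_s rho z) dz`, with the
#' incident transmission from [incident_profile()]. The detector
#' solid-angle fraction enters through `solid_angle_fraction` (set 1 to
#' apply the per-detector factor downstream).
#'
#' @param g a `voxel_grid`.
#' @param beam a `beam_config`.
#' @param element emitting element symbol.
#' @param line line label.
#' @param solid_angle_fraction Omega/4pi folded into the yield factor.
#' @param tables constants registry.
#' @return Array `(ny, nx, nz)` of produced photons, zero on empty voxels.
#' @export
emission_matrix <- function(g, beam, element, line = "K-alpha",
                            solid_angle_fraction = 1,
                            tables = xrf_constants()) {
  lc <- line_constants(element, line, tables)
  em <- array(0, c(g$ny, g$nx, g$nz))
  if (beam$E0 < lc$edge) {
    warning("E0 = ", beam$E0, " eV is below the ", element, " ", line,
            " excitation edge (", lc$edge, " eV): zero emission")
    return(em)
  }
  w <- g$fractions[[element]]
  if (is.null(w)) return(em)
  Y <- yield_factor(element, line, solid_angle_fraction, tables)
  tau <- tau_element(element, beam$E0, tables)
  base <- w * g$density * tau * Y * (g$voxel * 1e-4)  # dz in cm
  prof <- incident_profile(g, beam, tables)
  occ <- occupancy_array(g)
  for (k in seq_len(g$nz)) em[, , k] <- base * prof[, , k] * occ[, , k]
  em
}

#' Exit-path transmission between a point in the sample and a target
#'
#' Probability that a photon of the given energy travels the straight
#' segment unabsorbed: `exp(-sum mu_s rho chord)` over the occupied voxels
#' traversed, with exact per-voxel chord lengths (generalizing the
#' homogeneous single-path form to per-pixel composition).
#'
#' @param g a `voxel_grid`.
#' @param from `(x, y, z)` start point in um.
#' @param to `(x, y, z)` target point in um (typically on a detector face).
#' @param energy photon energy in eV.
#' @param tables constants registry.
#' @return Transmission in (0, 1].
#' @export
trace_path_transmission <- function(g, from, to, energy,
                                    tables = xrf_constants()) {
  att <- attenuation_map(g, energy, tables)
  zb <- g$zbot * g$voxel
  zt <- (g$zbot + g$thickness) * g$voxel
  res <- cpp_path(as.numeric(from), as.numeric(to), zb, zt, att, g$voxel,
                  -1L, -1L)
  exp(-res[1])
}

#' Self-absorption matrix K toward one detector
#'
#' Per occupied voxel, the mean over the detector-face ray targets of the
#' exit-path transmission at the line energy; 1 wherever no sample
#' intervenes (and on empty voxels, which emit nothing).
#'
#' @param g a `voxel_grid`.
#' @param detector a `detector_spec`.
#' @param element,line emission line.
#' @param tables constants registry.
#' @return Array `(ny, nx, nz)` with values in (0, 1].
#' @export
self_absorption_K <- function(g, detector, element, line = "K-alpha",
                              tables = xrf_constants()) {
  att <- attenuation_map(g, line_energy(element, line, tables), tables)
  cpp_k_matrices(g$zbot, g$thickness, list(att), detector$face_points,
                 g$voxel, g$nz)[[1]]
}

.line_key <- function(element, line) paste0(element, "_", gsub("[^A-Za-z0-9]", "", line))

#' Simulate the per-detector 2D XRF maps and the STXM map
#'
#' For every detector and emission line, the 3D response is the emission
#' matrix times the self-absorption matrix K; the 2D map is its sum along
#' the beam axis. Optionally the integer count maps (and the STXM photon
#' counts) are Poisson-resampled under a stored seed.
#'
#' @param g a `voxel_grid`.
#' @param beam a `beam_config`.
#' @param detectors named list of `detector_spec`.
#' @param elements emitting elements to simulate.
#' @param line line label.
#' @param poisson logical: resample the XRF count maps as Poisson
#'   variates (emulating a dose-limited acquisition).
#' @param stxm_poisson logical: also resample the STXM photon counts
#'   (off by default: the transmission map is acquired separately and is
#'   normally flux-normalized at adequate dose).
#' @param seed RNG seed used when resampling.
#' @param tables constants registry.
#' @return Object of class `xrf_map_set`: `xrf[[detector]][[line_key]]`
#'   count matrices, `stxm`, and `meta`.
#' @export
xrf_maps <- function(g, beam, detectors, elements = c("C", "N", "O", "Mg"),
                     line = "K-alpha", poisson = FALSE,
                     stxm_poisson = FALSE, seed = 1L,
                     tables = xrf_constants()) {
  elements <- intersect(elements, names(g$fractions))
  atts <- lapply(elements, function(el)
    attenuation_map(g, line_energy(el, line, tables), tables))
  ems <- lapply(elements, function(el)
    emission_matrix(g, beam, el, line, solid_angle_fraction = 1, tables))
  xrf <- lapply(detectors, function(det) {
    Ks <- cpp_k_matrices(g$zbot, g$thickness, atts, det$face_points,
                         g$voxel, g$nz)
    maps <- lapply(seq_along(elements), function(ix) {
      Y <- det$solid_angle_fraction
      apply(ems[[ix]] * Ks[[ix]], c(1, 2), sum) * Y
    })
    names(maps) <- vapply(elements, .line_key, "", line = line)
    maps
  })
  stxm <- stxm_map(g, beam, tables)
  if (poisson || stxm_poisson) {
    set.seed(seed)
    if (poisson)
      for (d in names(xrf)) for (l in names(xrf[[d]])) {
        m <- xrf[[d]][[l]]
        xrf[[d]][[l]] <- matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
      }
    if (stxm_poisson) {
      counts <- matrix(stats::rpois(length(stxm), beam$I0 * stxm),
                       nrow(stxm), ncol(stxm))
      stxm <- pmin(pmax(counts / beam$I0, 0.5 / beam$I0), 1)
    }
  }
  structure(list(xrf = xrf, stxm = stxm,
                 meta = list(E0 = beam$E0, I0 = beam$I0, line = line,
                             elements = elements, poisson = poisson,
                             seed = if (poisson) seed else NA_integer_,
                             voxel = g$voxel,
                             detectors = lapply(detectors, function(d)
                               d[c("name", "face_center", "face_side",
                                   "distance", "solid_angle_fraction")]))),
            class = "xrf_map_set")
}

#' Sum count maps across detectors
#' @param mapset an `xrf_map_set`.
#' @return Named list of per-line matrices summed over all detectors.
#' @export
summed_xrf <- function(mapset) {
  lines <- names(mapset$xrf[[1]])
  out <- lapply(lines, function(l)
    Reduce(`+`, lapply(mapset$xrf, function(d) d[[l]])))
  names(out) <- lines
  out
}
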