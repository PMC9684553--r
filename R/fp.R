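# Fundamental-parameter quantification: per-pixel element masses and mass
# fractions from cumulative line counts, the closed-form K_FP absorption
# factor, and pixelwise mixture attenuation maps.

#' Closed-form absorption correction factor K_FP
#'
#' `(1 - exp(-x)) / x` with
#' `x = rho h (mu_s(E0) cosec(theta) + mu_s(Ei) <cosec(phi)>)`:
#' the uniform-column absorption factor of the fundamental-parameter
#' method, covering both incident and emitted attenuation. Below
#' `x = 1e-8` the series limit 1 is used; K_FP is in (0, 1], strictly
#' decreasing in x and continuous at 0.
#'
#' @param h pixel thickness in um.
#' @param rho density in g/cm^3.
#' @param mu0 mixture mass attenuation at the incident energy, cm^2/g.
#' @param mui mixture mass attenuation at the line energy, cm^2/g.
#' @param cosec_theta cosecant of the incidence angle (1 for perpendicular
#'   incidence).
#' @param mean_cosec_phi mean cosecant of the take-off angles toward the
#'   detector face ray targets.
#' @return Dimensionless factor in (0, 1]; vectorized over `h`.
#' @export
k_fp <- function(h, rho, mu0, mui, cosec_theta = 1, mean_cosec_phi) {
  if (any(h < 0) || any(rho < 0)) stop("h and rho must be nonnegative")
  x <- rho * (h * 1e-4) * (mu0 * cosec_theta + mui * mean_cosec_phi)
  ifelse(x < 1e-8, 1, (1 - exp(-x)) / pmax(x, 1e-300))
}

#' Mean cosecant of take-off angles toward a detector
#'
#' Mean over the detector-face ray targets of `1/sin(phi)` where `phi` is
#' the elevation of the path from a reference point (the grid center at the
#' support plane by default) to each target.
#'
#' @param detector a `detector_spec`.
#' @param from `(x, y, z)` reference point in um.
#' @return Mean cosecant (dimensionless, >= 1).
#' @export
mean_cosec_phi <- function(detector, from) {
  d <- sweep(detector$face_points, 2, as.numeric(from))
  mean(sqrt(rowSums(d^2)) / d[, 3])
}

#' Element mass in a pixel from cumulative line counts
#'
#' `m_j = C_i S / (I0 Y_ij tau_j(E0) K_FP)`. With `kfp = 1` this is the
#' first-pass estimate that discards the absorption correction.
#'
#' @param counts cumulative counts C_i of the line (vectorized).
#' @param pixel_area_um2 pixel surface area S in um^2.
#' @param I0 incident photons per pixel.
#' @param yield yield factor Y_ij (including the solid-angle fraction;
#'   summed across detectors when counts are pooled).
#' @param tau photoionization cross-section of the element at E0, cm^2/g.
#' @param kfp absorption correction factor (default 1 = omitted).
#' @return Mass in g.
#' @export
element_mass <- function(counts, pixel_area_um2, I0, yield, tau, kfp = 1) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  den <- I0 * yield * tau * kfp
  if (any(den <= 0)) stop("zero or negative denominator in mass equation")
  counts * (pixel_area_um2 * 1e-8) / den   # S in cm^2
}

#' Normalize element masses to mass fractions
#'
#' @param masses named list of equal-shaped mass matrices (or a named
#'   numeric vector).
#' @return List with `fractions` (same shape, `w_j = m_j / sum m_j`) and
#'   `undefined` (pixels where all masses are zero, flagged and left NA).
#' @export
mass_fractions <- function(masses) {
  if (!is.list(masses)) masses <- lapply(as.list(masses), identity)
  tot <- Reduce(`+`, masses)
  undef <- tot <= 0
  fr <- lapply(masses, function(m) {
    f <- m / ifelse(undef, NA_real_, tot)
    f
  })
  list(fractions = fr, undefined = undef)
}

#' Pixelwise mixture attenuation maps at a set of energies
#'
#' @param fractions named list of per-pixel mass-fraction matrices
#'   (normalized on sample pixels).
#' @param energies numeric vector of energies in eV (named entries are
#'   carried through to the output).
#' @param tables constants registry.
#' @return Named list of `mu_s` matrices in cm^2/g.
#' @export
mu_maps <- function(fractions, energies, tables = xrf_constants()) {
  out <- lapply(energies, function(E) {
    m <- 0
    for (el in names(fractions))
      m <- m + ifelse(is.na(fractions[[el]]), 0, fractions[[el]]) *
        mu_element(el, E, tables)
    m
  })
  names(out) <- if (is.null(names(energies))) as.character(energies) else names(energies)
  out
}

#' First-pass fundamental-parameter quantification of a map set
#'
#' Pools the counts of each line across all detectors, applies the mass
#' equation with the absorption factor omitted (`K_FP = 1`, the first-pass
#' convention) using the detector-summed yield factor, and normalizes to
#' mass fractions over the detected elements. Hydrogen and other
#' non-fluorescing constituents are invisible to this estimate.
#'
#' @param mapset an `xrf_map_set`.
#' @param detectors the detector ring the maps were acquired with.
#' @param beam the `beam_config` of the acquisition.
#' @param tables constants registry.
#' @return List with `fractions` (named list of matrices), `masses`,
#'   `undefined` and `mu_at` (function mapping energy to a mu_s map).
#' @export
fp_first_pass <- function(mapset, detectors, beam, tables = xrf_constants()) {
  pooled <- summed_xrf(mapset)
  line <- mapset$meta$line
  elements <- mapset$meta$elements
  S <- mapset$meta$voxel^2
  omega_sum <- sum(vapply(detectors, function(d) d$solid_angle_fraction, 0))
  masses <- lapply(elements, function(el) {
    Y <- yield_factor(el, line, solid_angle_fraction = omega_sum, tables = tables)
    tau <- tau_element(el, beam$E0, tables)
    element_mass(pooled[[.line_key(el, line)]], S, beam$I0, Y, tau, kfp = 1)
  })
  names(masses) <- elements
  mf <- mass_fractions(masses)
  list(fractions = mf$fractions, masses = masses, undefined = mf$undefined,
       mu_at = function(E) mu_maps(mf$fractions, E, tables)[[1]])
}
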