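#' @useDynLib xrftopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Frozen element-wise physical constants for the low-energy (100-3000 eV)
# regime: total mass attenuation coefficients mu(E), photoionization
# cross-sections tau(E), K-line energies, fluorescence yields, transition
# probabilities and absorption-edge jump factors. Values were assembled once
# from standard soft X-ray tabulations (Henke-type anchor points with
# log-log interpolation and explicit K-edge discontinuities) and are frozen
# here so that results cannot drift with an external backend version.
#
# mu anchors are (energy eV, mu cm^2/g); between anchors interpolation is
# linear in log(E)-log(mu). tau is stored as a per-element fraction of mu
# (photoabsorption dominates over scattering by >2 orders of magnitude for
# C/N/O/Mg in this band; hydrogen is scattering-dominated at the top of the
# band and emits no tracked line).

.mu_anchor_tables <- list(
  H = cbind(E = c(100, 200, 277, 400, 500, 700, 1000, 1253.6, 1500, 2000, 3000),
            mu = c(7200, 900, 341, 113, 57.6, 21.0, 7.6, 3.9, 2.5, 1.3, 0.7)),
  C = cbind(E = c(100, 150, 200, 250, 277, 284.1,
                  284.3, 320, 392, 400, 500, 524.9, 700, 1000, 1253.6, 1500, 2000, 3000),
            mu = c(39000, 11700, 4920, 2520, 1850, 1730,
                   95000, 67400, 36700, 34500, 17700, 15300, 6440, 2210, 1150, 700, 303, 98)),
  N = cbind(E = c(100, 200, 277, 300, 392, 409.8,
                  410.0, 500, 524.9, 700, 1000, 1253.6, 1500, 2000, 3000),
            mu = c(64000, 8000, 3040, 2370, 1060, 935,
                   48000, 26500, 22900, 9650, 3310, 1700, 1100, 476, 154)),
  O = cbind(E = c(100, 200, 277, 392, 500, 524.9, 543.0,
                  543.2, 700, 1000, 1253.6, 1500, 2000, 3000),
            mu = c(90000, 21400, 8200, 2880, 1390, 1200, 1080,
                   28500, 13400, 4576, 2350, 1550, 690, 217)),
  Mg = cbind(E = c(100, 300, 500, 700, 1000, 1253.6, 1302.9,
                   1303.1, 1500, 2000, 3000),
             mu = c(80000, 32800, 7090, 2580, 886, 450, 402,
                    4800, 3150, 1330, 400))
)

.tau_fraction <- c(H = 0.50, C = 0.995, N = 0.995, O = 0.995, Mg = 0.995)

.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, Mg = 12)

# K-alpha lines. jump_ratio r is the mu discontinuity at the K edge taken
# from the frozen tables above; jump_factor (r-1)/r is the fraction of
# photoionization events occurring in the K shell just above the edge.
.line_table <- data.frame(
  element = c("C", "N", "O", "Mg"),
  line = "K-alpha",
  energy = c(277.0, 392.4, 524.9, 1253.6),
  edge = c(284.2, 409.9, 543.1, 1303.0),
  fluorescence_yield = c(0.0028, 0.0052, 0.0083, 0.0300),
  transition_probability = c(1.0, 1.0, 1.0, 0.99),
  jump_ratio = c(54.9, 51.3, 26.4, 11.9),
  jump_factor = c(0.9818, 0.9805, 0.9621, 0.9160),
  stringsAsFactors = FALSE
)

.energy_range <- c(100, 3000)

#' Frozen physical-constants tables
#'
#' Returns the package's constants registry: per-element mass attenuation
#' anchor tables, photoionization fractions, atomic numbers and the K-alpha
#' emission-line table. Every physical constant used anywhere in the package
#' is fetched through this registry, so substituting a different table (for
#' example pseudo-elements with synthetic attenuation coefficients in tests)
#' changes results in exactly one place.
#'
#' @param mu_tables optional replacement for the mu anchor tables: a named
#'   list of two-column matrices `(E, mu)` in eV and cm^2/g.
#' @param tau_fraction optional named vector of tau/mu fractions.
#' @param lines optional replacement emission-line table.
#' @return A list with components `mu_tables`, `tau_fraction`, `lines`,
#'   `Z` and `energy_range`.
#' @export
xrf_constants <- function(mu_tables = NULL, tau_fraction = NULL, lines = NULL) {
  list(
    mu_tables = if (is.null(mu_tables)) .mu_anchor_tables else mu_tables,
    tau_fraction = if (is.null(tau_fraction)) .tau_fraction else tau_fraction,
    lines = if (is.null(lines)) .line_table else lines,
    Z = .atomic_numbers,
    energy_range = .energy_range
  )
}

#' Elements with tabulated constants
#' @param tables constants registry, see [xrf_constants()].
#' @return Character vector of element symbols.
#' @export
xrf_elements <- function(tables = xrf_constants()) names(tables$mu_tables)

.check_energy <- function(E, tables) {
  rng <- tables$energy_range
  if (any(E < rng[1] | E > rng[2]))
    stop("energy ", paste(E[E < rng[1] | E > rng[2]], collapse = ", "),
         " eV outside tabulated range [", rng[1], ", ", rng[2], "] eV")
}

#' Total mass attenuation coefficient of one element
#'
#' Log-log interpolation of the frozen anchor tables; K-edge discontinuities
#' are represented by closely spaced anchor pairs.
#'
#' @param element element symbol.
#' @param E energy in eV (vectorized).
#' @param tables constants registry.
#' @return mu in cm^2/g.
#' @export
mu_element <- function(element, E, tables = xrf_constants()) {
  tab <- tables$mu_tables[[element]]
  if (is.null(tab)) stop("no attenuation table for element '", element, "'")
  .check_energy(E, tables)
  exp(stats::approx(log(tab[, 1]), log(tab[, 2]), xout = log(E), rule = 2)$y)
}

#' Photoionization cross-section of one element
#' @inheritParams mu_element
#' @return tau in cm^2/g; satisfies `tau <= mu` at every tabulated energy.
#' @export
tau_element <- function(element, E, tables = xrf_constants()) {
  fr <- tables$tau_fraction[[element]]
  if (is.null(fr)) stop("no photoionization fraction for element '", element, "'")
  fr * mu_element(element, E, tables)
}

.line_row <- function(element, line, tables) {
  lt <- tables$lines
  row <- lt[lt$element == element & lt$line == line, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown emission line: element '", element, "', line '", line, "'")
  row
}

#' Tabulated emission-line energy
#'
#' @param element element symbol (e.g. `"C"`).
#' @param line line label (e.g. `"K-alpha"`).
#' @param tables constants registry.
#' @return Line energy in eV.
#' @export
line_energy <- function(element, line = "K-alpha", tables = xrf_constants()) {
  .line_row(element, line, tables)$energy
}

#' Absorption-edge energy exciting an emission line
#' @inheritParams line_energy
#' @return Edge energy in eV.
#' @export
edge_energy <- function(element, line = "K-alpha", tables = xrf_constants()) {
  .line_row(element, line, tables)$edge
}

#' Full constants record for an emission line
#' @inheritParams line_energy
#' @return List with `energy`, `edge`, `fluorescence_yield`,
#'   `transition_probability`, `jump_factor`, `jump_ratio`.
#' @export
line_constants <- function(element, line = "K-alpha", tables = xrf_constants()) {
  row <- .line_row(element, line, tables)
  list(energy = row$energy, edge = row$edge,
       fluorescence_yield = row$fluorescence_yield,
       transition_probability = row$transition_probability,
       jump_factor = row$jump_factor, jump_ratio = row$jump_ratio)
}

#' Mixture-rule mass attenuation coefficient
#'
#' Weighted sum of elemental attenuation coefficients,
#' `mu_s(E) = sum_j w_j mu_j(E)`.
#'
#' @param mass_fractions named numeric vector of mass fractions; must be
#'   nonnegative and sum to 1 within 1e-9.
#' @param E energy in eV (vectorized).
#' @param tables constants registry.
#' @return mu_s in cm^2/g, same length as `E`.
#' @export
mixture_mu <- function(mass_fractions, E, tables = xrf_constants()) {
  if (is.null(names(mass_fractions)) || any(!nzchar(names(mass_fractions))))
    stop("mass_fractions must be a named vector of element symbols")
  if (any(mass_fractions < 0)) stop("mass fractions must be nonnegative")
  if (abs(sum(mass_fractions) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", sum(mass_fractions), ")")
  out <- numeric(length(E))
  for (el in names(mass_fractions)) {
    if (mass_fractions[[el]] == 0) next
    out <- out + mass_fractions[[el]] * mu_element(el, E, tables)
  }
  out
}

#' Emission-yield factor Y = (Omega/4pi) omega p J
#'
#' The product of the detector solid-angle fraction, fluorescence yield,
#' transition probability and edge jump factor for an emission line.
#'
#' @param element element symbol.
#' @param line line label.
#' @param solid_angle_fraction Omega/4pi in `[0, 1]`.
#' @param tables constants registry.
#' @return Dimensionless yield factor.
#' @export
yield_factor <- function(element, line = "K-alpha", solid_angle_fraction,
                         tables = xrf_constants()) {
  if (solid_angle_fraction < 0 || solid_angle_fraction > 1)
    stop("solid_angle_fraction must be in [0, 1]")
  lc <- line_constants(element, line, tables)
  solid_angle_fraction * lc$fluorescence_yield * lc$transition_probability *
    lc$jump_factor
}

#' Reference cell-like composition
#'
#' Mass fractions typical of a human colon carcinoma (LoVo-like) cell:
#' 61% C, 17% N, 16% O. The remaining 6% is assigned to a non-fluorescing
#' balance element (hydrogen by default) that contributes to the mixture
#' attenuation but emits no tracked line, so the fractions sum to 1 as the
#' mixture rule requires.
#'
#' @param balance symbol of the balance element.
#' @return Named mass-fraction vector summing to 1.
#' @export
lovo_fractions <- function(balance = "H") {
  fr <- c(C = 0.61, N = 0.17, O = 0.16)
  fr[[balance]] <- 1 - sum(fr)
  fr
}
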