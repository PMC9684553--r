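# Quantitative evaluation of the self-absorption correction: corrected /
# uncorrected / simulated emission matrices and summed count maps,
# least-squares map differences, volume overlap and paired statistics.

#' Corrected, uncorrected and simulated emission variants
#'
#' Emission matrices (summed along the beam axis) for one line of each
#' element: `EMc` on the reconstructed grid with the correct mass
#' fractions, `EMu` on the reconstructed grid with the first-pass
#' (absorption-uncorrected) fractions, and `EMs` on the true grid with the
#' correct fractions.
#'
#' @param recon_grid reconstructed `voxel_grid` (carrying the recovered
#'   density and uncorrected fractions).
#' @param true_grid ground-truth `voxel_grid`.
#' @param beam a `beam_config`.
#' @param elements elements to evaluate.
#' @param line line label.
#' @param solid_angle_fraction Omega/4pi folded into every variant
#'   (typically the detector-summed fraction).
#' @param tables constants registry.
#' @return List per element of list `(EMc, EMu, EMs)` 2D matrices.
#' @export
emission_variants <- function(recon_grid, true_grid, beam,
                              elements = c("C", "N", "O"), line = "K-alpha",
                              solid_angle_fraction = 1,
                              tables = xrf_constants()) {
  if (recon_grid$ny != true_grid$ny || recon_grid$nx != true_grid$nx)
    stop("grids must share their map shape")
  # reconstructed grid with the correct composition
  occ <- recon_grid$thickness > 0
  corr <- voxel_grid(c(recon_grid$ny, recon_grid$nx, recon_grid$nz),
                     recon_grid$voxel, thickness = recon_grid$thickness,
                     zbot = recon_grid$zbot,
                     density = ifelse(occ, true_grid$density, 0),
                     fractions = lapply(true_grid$fractions, function(f)
                       ifelse(occ, f, 0)))
  out <- lapply(elements, function(el) {
    list(EMc = apply(emission_matrix(corr, beam, el, line,
                                     solid_angle_fraction, tables),
                     c(1, 2), sum),
         EMu = apply(emission_matrix(recon_grid, beam, el, line,
                                     solid_angle_fraction, tables),
                     c(1, 2), sum),
         EMs = apply(emission_matrix(true_grid, beam, el, line,
                                     solid_angle_fraction, tables),
                     c(1, 2), sum))
  })
  names(out) <- elements
  out
}

#' Mean and standard deviation of per-pixel squared differences
#'
#' Maps are compared pixelwise over a mask (3D inputs are summed along the
#' beam axis first).
#'
#' @param a,b matrices or `(ny, nx, nz)` arrays.
#' @param mask logical matrix of sample pixels.
#' @return List `(mean, sd, n)` of the squared differences over the mask.
#' @export
least_squares_diff <- function(a, b, mask) {
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), sum)
  if (length(dim(b)) == 3) b <- apply(b, c(1, 2), sum)
  if (!all(dim(a) == dim(b))) stop("map shapes differ")
  if (!any(mask)) stop("empty evaluation mask")
  d2 <- (a - b)[mask]^2
  list(mean = mean(d2), sd = stats::sd(d2), n = length(d2))
}

#' Voxel volume overlap between a reconstruction and the truth
#'
#' `100 * |recon intersect truth| / |truth|`, computed per pixel from the
#' column z-intervals (exact, independent of grid heights). The companion
#' Jaccard index `|intersection| / |union|` is reported alongside.
#'
#' @param recon,truth `voxel_grid`s sharing the same map shape and voxel
#'   size.
#' @return List `(overlap_pct, jaccard_pct, inter_um3, truth_um3,
#'   recon_um3)`.
#' @export
volume_overlap <- function(recon, truth) {
  if (recon$ny != truth$ny || recon$nx != truth$nx ||
      recon$voxel != truth$voxel)
    stop("grids must share map shape and voxel size")
  if (sum(truth$thickness) == 0) stop("empty truth volume")
  lo <- pmax(recon$zbot, truth$zbot)
  hi <- pmin(recon$zbot + recon$thickness, truth$zbot + truth$thickness)
  inter <- sum(pmax(hi - lo, 0))
  vt <- sum(truth$thickness); vr <- sum(recon$thickness)
  v3 <- truth$voxel^3
  list(overlap_pct = 100 * inter / vt,
       jaccard_pct = 100 * inter / (vt + vr - inter),
       inter_um3 = inter * v3, truth_um3 = vt * v3, recon_um3 = vr * v3)
}

#' Paired comparison of uncorrected vs corrected per-pixel differences
#'
#' Paired t-test of the two squared-difference samples plus a one-sample
#' Kolmogorov-Smirnov normality check of the paired differences
#' (standardized against their sample mean and standard deviation).
#'
#' @param u_diffs,c_diffs equal-length paired samples (per-pixel squared
#'   differences over the sample mask).
#' @return List `(t_stat, t_p, df, ks_stat, ks_p, mean_u, mean_c)`.
#' @export
paired_stats <- function(u_diffs, c_diffs) {
  if (length(u_diffs) != length(c_diffs)) stop("samples must be paired")
  if (length(u_diffs) < 3) stop("need at least 3 pairs")
  d <- u_diffs - c_diffs
  if (stats::sd(d) == 0) {
    # degenerate pairing (identical samples): no evidence of a difference
    return(list(t_stat = 0, t_p = 1, df = length(d) - 1,
                ks_stat = NA_real_, ks_p = NA_real_,
                mean_u = mean(u_diffs), mean_c = mean(c_diffs)))
  }
  tt <- stats::t.test(u_diffs, c_diffs, paired = TRUE)
  ks <- suppressWarnings(stats::ks.test((d - mean(d)) / stats::sd(d), "pnorm"))
  list(t_stat = unname(tt$statistic), t_p = tt$p.value,
       df = unname(tt$parameter),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       mean_u = mean(u_diffs), mean_c = mean(c_diffs))
}

#' Full correction-evaluation report
#'
#' Simulates the summed count maps and emission matrices for the corrected,
#' uncorrected and true configurations and reports, per element, the mean
#' least-squares differences from the true maps with paired statistics.
#'
#' @param recon_grid reconstructed `voxel_grid` (uncorrected composition
#'   embedded).
#' @param true_grid ground-truth `voxel_grid`.
#' @param beam a `beam_config`.
#' @param detectors detector ring.
#' @param elements elements to evaluate.
#' @param line line label.
#' @param tables constants registry.
#' @return Nested list: per element, `sum_xrf` and `em` blocks each with
#'   `(u, c)` least-squares summaries and `stats` from [paired_stats()].
#' @export
correction_report <- function(recon_grid, true_grid, beam, detectors,
                              elements = c("C", "N", "O"),
                              line = "K-alpha", tables = xrf_constants()) {
  mask <- true_grid$thickness > 0
  omega_sum <- sum(vapply(detectors, function(d) d$solid_angle_fraction, 0))
  occ <- recon_grid$thickness > 0
  corr <- voxel_grid(c(recon_grid$ny, recon_grid$nx, recon_grid$nz),
                     recon_grid$voxel, thickness = recon_grid$thickness,
                     zbot = recon_grid$zbot,
                     density = ifelse(occ, true_grid$density, 0),
                     fractions = lapply(true_grid$fractions, function(f)
                       ifelse(occ, f, 0)))
  sim_s <- summed_xrf(xrf_maps(true_grid, beam, detectors, elements, line,
                               tables = tables))
  sim_c <- summed_xrf(xrf_maps(corr, beam, detectors, elements, line,
                               tables = tables))
  sim_u <- summed_xrf(xrf_maps(recon_grid, beam, detectors, elements, line,
                               tables = tables))
  ems <- emission_variants(recon_grid, true_grid, beam, elements, line,
                           solid_angle_fraction = omega_sum, tables = tables)
  out <- lapply(elements, function(el) {
    key <- .line_key(el, line)
    x_u <- (sim_u[[key]] - sim_s[[key]])[mask]^2
    x_c <- (sim_c[[key]] - sim_s[[key]])[mask]^2
    e_u <- (ems[[el]]$EMu - ems[[el]]$EMs)[mask]^2
    e_c <- (ems[[el]]$EMc - ems[[el]]$EMs)[mask]^2
    list(sum_xrf = list(u = list(mean = mean(x_u), sd = stats::sd(x_u)),
                        c = list(mean = mean(x_c), sd = stats::sd(x_c)),
                        stats = paired_stats(x_u, x_c)),
         em = list(u = list(mean = mean(e_u), sd = stats::sd(e_u)),
                   c = list(mean = mean(e_c), sd = stats::sd(e_c)),
                   stats = paired_stats(e_u, e_c)))
  })
  names(out) <- elements
  out
}
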