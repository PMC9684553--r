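# End-to-end orchestration: phantom -> forward simulation -> thickness
# retrieval -> first-pass quantification -> inverse reconstruction ->
# correction evaluation.

#' Run the full topography-reconstruction pipeline on the canonical phantom
#'
#' Builds the three-cell phantom, simulates its STXM and eight-detector XRF
#' maps, derives the thickness map from the STXM, quantifies the first-pass
#' mass fractions, runs the inverse reconstruction and (optionally) the
#' correction evaluation, returning every intermediate product and the
#' summary metrics.
#'
#' @param seed RNG seed (used by the optional Poisson resampling).
#' @param scale phantom magnification (2.5 = the upscaled variant in a
#'   100 x 100 x 100 um^3 grid).
#' @param I0 incident photons per pixel.
#' @param E0 incident energy in eV.
#' @param ir_os oversampling parameter of the reconstruction.
#' @param delta permutation threshold.
#' @param poisson Poisson-resample the simulated counts (both the XRF maps
#'   and the STXM photon counts: the robustness experiment emulates a
#'   dose-limited source, which affects every acquisition). The
#'   thickness-retrieval background threshold follows the shot-noise floor,
#'   `1 - 3 / sqrt(I0)`, capped at the noise-free default.
#' @param n_iter thickness-retrieval iterations.
#' @param do_recon run the inverse reconstruction.
#' @param do_eval run the correction evaluation (implies `do_recon`).
#' @param config optional `ir_config` overriding `ir_os` / `delta`.
#' @param tables constants registry.
#' @return List with `truth`, `mapset`, `zstate`, `fp`, `recon`, `overlap`,
#'   `report` and `metrics` (flat named list of the headline numbers).
#' @export
run_pipeline <- function(seed = 1, scale = 1, I0 = 1e8, E0 = 1500,
                         ir_os = 0.2, delta = 1000, poisson = FALSE,
                         n_iter = 1000, do_recon = TRUE, do_eval = FALSE,
                         config = NULL, tables = xrf_constants()) {
  spec <- canonical_phantom_spec(scale)
  truth <- build_phantom(spec)
  beam <- beam_config(E0 = E0, I0 = I0, tables = tables)
  detectors <- detector_ring(truth)
  mapset <- xrf_maps(truth, beam, detectors, poisson = poisson,
                     stxm_poisson = poisson, seed = seed, tables = tables)

  h_max <- max(spec$hemispheres$r)
  bg_thr <- min(0.999, 1 - 3 / sqrt(I0))
  zstate <- derive_zmap(mapset$stxm, rho_avg = spec$density, h_max = h_max,
                        n_iter = n_iter, background_threshold = bg_thr)
  fp <- truth$thickness > 0
  ztrue <- thickness_map(truth)
  mr_true <- attenuation_map(truth, beam$E0, tables)
  z_err_pct <- mean((zstate$z[fp] - ztrue[fp]) / ztrue[fp]) * 100
  z_err_sd <- stats::sd((zstate$z[fp] - ztrue[fp]) / ztrue[fp]) * 100
  mr_err_pct <- mean((zstate$mu_rho[fp] - mr_true[fp]) / mr_true[fp]) * 100
  mr_err_sd <- stats::sd((zstate$mu_rho[fp] - mr_true[fp]) / mr_true[fp]) * 100

  fpq <- fp_first_pass(mapset, detectors, beam, tables)
  wc <- fpq$fractions$C
  wc_dev_pct <- mean(abs(wc[fp] - 0.61) / 0.61, na.rm = TRUE) * 100

  metrics <- list(footprint_pixels = sum(fp),
                  truth_volume_um3 = grid_volume(truth),
                  z_err_pct = z_err_pct, z_err_sd = z_err_sd,
                  mu_rho_err_pct = mr_err_pct, mu_rho_err_sd = mr_err_sd,
                  wc_dev_pct = wc_dev_pct)

  recon <- NULL; overlap <- NULL; report <- NULL
  if (do_recon || do_eval) {
    if (is.null(config))
      config <- ir_config(ir_os = ir_os, delta = delta, seed = seed)
    recon <- inverse_reconstruct(mapset, zstate, fpq$fractions, beam,
                                 detectors, config, tables)
    overlap <- volume_overlap(recon$grid, truth)
    metrics$overlap_pct <- overlap$overlap_pct
    metrics$jaccard_pct <- overlap$jaccard_pct
    metrics$volume_diff_pct <- 100 *
      (overlap$recon_um3 - overlap$truth_um3) / overlap$truth_um3
  }
  if (do_eval) {
    report <- correction_report(recon$grid, truth, beam, detectors,
                                tables = tables)
    for (el in names(report)) {
      metrics[[paste0("lsq_xrf_u_", el)]] <- report[[el]]$sum_xrf$u$mean
      metrics[[paste0("lsq_xrf_c_", el)]] <- report[[el]]$sum_xrf$c$mean
      metrics[[paste0("lsq_em_u_", el)]] <- report[[el]]$em$u$mean
      metrics[[paste0("lsq_em_c_", el)]] <- report[[el]]$em$c$mean
    }
  }
  list(truth = truth, beam = beam, detectors = detectors, mapset = mapset,
       zstate = zstate, fpq = fpq, recon = recon, overlap = overlap,
       report = report, metrics = metrics)
}
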