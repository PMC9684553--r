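# Ray-tracing inverse reconstruction (IR): per-detector topography search
# over continuity-constrained column translations, scored by the L1 norm
# against target XRF maps, then merged across detectors.

#' Inverse-reconstruction configuration
#'
#' @param ir_os oversampling parameter in `[0, 1]`: a detector reconstructs
#'   a pixel iff its coverage, normalized by the pixel's maximum coverage
#'   across detectors, is at most `ir_os`; the least-covered detector is
#'   always included (0 = closest detector only, 1 = all detectors).
#' @param delta permutation threshold: maximum number of candidate
#'   topographies tested per conical region, sampled equidistantly from the
#'   lexicographic enumeration.
#' @param stride spacing (pixels) of the apexes picked along each seed
#'   line; `NULL` = half the cone footprint width at mid-range, so
#'   consecutive regions overlap about 50%.
#' @param n_face_points ray targets per scored voxel during candidate
#'   scoring (the final K matrices always use the detector's full target
#'   grid; scoring only ranks candidates, and with a far small face the
#'   path transmission varies little across it, so a single central ray is
#'   the default).
#' @param lines element symbols whose maps are scored (the C K-alpha map by
#'   default: lowest energy, most self-absorbed, hence most informative
#'   about topography).
#' @param roi_range maximum apex distance (um) of conical-region members;
#'   `NULL` = the distance beyond which no admissible column top can still
#'   intersect an exit ray, `h_max / tan(elevation - half_angle)`.
#' @param seed RNG seed recorded in outputs (the search itself is
#'   deterministic).
#' @return Object of class `ir_config`.
#' @export
ir_config <- function(ir_os = 0.2, delta = 1000, stride = NULL,
                      n_face_points = 1, lines = "C", roi_range = NULL,
                      seed = 1L) {
  if (ir_os < 0 || ir_os > 1) stop("ir_os must be in [0, 1]")
  if (delta < 1) stop("delta must be >= 1")
  structure(list(ir_os = ir_os, delta = delta, stride = stride,
                 n_face_points = n_face_points, lines = lines,
                 roi_range = roi_range, seed = as.integer(seed)),
            class = "ir_config")
}

#' Coverage-level map of one detector
#'
#' For each footprint pixel, the occupied path length (um) of the straight
#' segment from the pixel's column top center to the detector face center,
#' through the support-resting 3D expansion of the thickness map; the
#' pixel's own column is excluded.
#'
#' @param thickness thickness map in um.
#' @param detector a `detector_spec`.
#' @param voxel voxel size in um.
#' @return Matrix of path lengths (0 where no sample intervenes).
#' @export
coverage_map <- function(thickness, detector, voxel = 1) {
  cpp_coverage(thickness, detector$face_center, voxel)
}

#' Assign pixels to detectors by normalized coverage
#'
#' @param coverages named list of coverage maps (one per detector).
#' @param ir_os oversampling parameter.
#' @return List with `assigned` (named list of logical matrices) and
#'   `norm_cov` (coverage normalized per pixel by its maximum across
#'   detectors).
#' @export
detector_assignment <- function(coverages, ir_os) {
  maxcov <- Reduce(pmax, coverages)
  norm <- lapply(coverages, function(cv) ifelse(maxcov > 0, cv / maxcov, 0))
  mincov <- Reduce(pmin, coverages)
  assigned <- lapply(names(coverages), function(nm) {
    norm[[nm]] <= ir_os | coverages[[nm]] <= mincov
  })
  names(assigned) <- names(coverages)
  list(assigned = assigned, norm_cov = norm, max_cov = maxcov)
}

.pixel_centers <- function(ny, nx, voxel) {
  list(x = matrix(rep((seq_len(nx) - 0.5) * voxel, each = ny), ny, nx),
       y = matrix(rep((seq_len(ny) - 0.5) * voxel, times = nx), ny, nx))
}

#' Seed pixel and apex line toward a detector
#'
#' The seed is the unresolved eligible pixel with minimal coverage (ties
#' broken by smallest row-major index). The returned apexes are the
#' rasterized pixels of the line through the seed and the detector center,
#' walked away from the detector and subsampled every `stride` pixels.
#'
#' @param coverage coverage map of the detector.
#' @param eligible logical matrix of pixels this detector reconstructs.
#' @param resolved logical matrix of already-fixed pixels.
#' @param detector a `detector_spec`.
#' @param stride apex spacing in pixels.
#' @param voxel voxel size in um.
#' @return List with `seed` `(i, j)` and `apexes` (two-column matrix), or
#'   `NULL` when everything is resolved.
#' @export
select_seed_and_line <- function(coverage, eligible, resolved, detector,
                                 stride = 1, voxel = 1) {
  ny <- nrow(coverage); nx <- ncol(coverage)
  open <- eligible & !resolved
  if (!any(open)) return(NULL)
  cv <- ifelse(open, coverage, Inf)
  # row-major tie-break: scan transposed so j varies fastest within a row
  ord <- order(t(cv))
  lin <- ord[1]
  i <- (lin - 1) %/% nx + 1
  j <- (lin - 1) %% nx + 1
  p <- c((j - 0.5) * voxel, (i - 0.5) * voxel)
  d <- p - detector$face_center[1:2]
  d <- d / sqrt(sum(d^2))
  # rasterize from the seed moving away from the detector
  pix <- list(c(i, j))
  step <- voxel / 2
  t <- step
  repeat {
    q <- p + t * d
    jj <- floor(q[1] / voxel) + 1
    ii <- floor(q[2] / voxel) + 1
    if (ii < 1 || ii > ny || jj < 1 || jj > nx) break
    last <- pix[[length(pix)]]
    if (ii != last[1] || jj != last[2]) pix[[length(pix) + 1]] <- c(ii, jj)
    t <- t + step
  }
  m <- do.call(rbind, pix)
  m <- m[seq(1, nrow(m), by = max(1, round(stride))), , drop = FALSE]
  list(seed = c(i, j), apexes = m)
}

#' Conical region of interest toward a detector
#'
#' All eligible pixels whose direction from the apex lies within the
#' projected cone subtending the detector face (half-angle from face size
#' and distance, floored at one pixel wide), between the apex and
#' `roi_range`, ordered by distance from the apex.
#'
#' @param apex `(i, j)` pixel.
#' @param detector a `detector_spec`.
#' @param eligible logical matrix of admissible member pixels.
#' @param voxel voxel size in um.
#' @param roi_range maximum member distance from the apex in um.
#' @return Two-column matrix of member pixels `(i, j)` ordered by apex
#'   distance (the apex first).
#' @export
conical_roi <- function(apex, detector, eligible, voxel = 1,
                        roi_range = Inf) {
  ny <- nrow(eligible); nx <- ncol(eligible)
  ctr <- .pixel_centers(ny, nx, voxel)
  p <- c((apex[2] - 0.5) * voxel, (apex[1] - 0.5) * voxel)
  d <- detector$face_center[1:2] - p
  d <- d / sqrt(sum(d^2))
  vx <- ctr$x - p[1]; vy <- ctr$y - p[2]
  along <- vx * d[1] + vy * d[2]
  perp <- abs(vx * d[2] - vy * d[1])
  r <- sqrt(vx^2 + vy^2)
  halfw <- pmax(along * tan(detector$half_angle), 0) + 0.5 * voxel
  inside <- eligible & along >= 0 & perp <= halfw & r <= roi_range
  inside[apex[1], apex[2]] <- TRUE
  idx <- which(inside)
  ii <- (idx - 1) %% ny + 1
  jj <- (idx - 1) %/% ny + 1
  ord <- order(r[idx], ii, jj)
  cbind(i = ii[ord], j = jj[ord])
}

#' Enumerate gap-free candidate topographies of a member chain
#'
#' Spatially adjacent consecutive members (ordered by apex distance) must
#' keep a vertical overlap of at least one voxel, so the sample stays
#' continuous with no interleaving gaps. Candidates are the admissible
#' joint offset assignments, lexicographically ordered; when more than
#' `delta` exist, every `ceiling(total/delta)`-th candidate is taken
#' (equidistant subsampling avoids selection bias).
#'
#' @param thickness_vox member thicknesses in voxels (>= 1).
#' @param offset_max maximum offset per member in voxels.
#' @param fixed fixed offset per member (`NA` = free).
#' @param adjacent logical: is member m spatially adjacent to member m-1
#'   (the constrained pairs)? Default: every consecutive pair.
#' @param delta permutation threshold.
#' @return List with `total` (candidate count before subsampling) and
#'   `candidates` (matrix, one row per candidate, one column per member).
#' @export
enumerate_candidates <- function(thickness_vox, offset_max, fixed = NULL,
                                 adjacent = NULL, delta = 1000) {
  M <- length(thickness_vox)
  if (any(thickness_vox < 1)) stop("member thickness must be >= 1 voxel")
  if (is.null(fixed)) fixed <- rep(NA_integer_, M)
  if (is.null(adjacent)) adjacent <- c(FALSE, rep(TRUE, M - 1))
  fx <- ifelse(is.na(fixed), -1L, as.integer(fixed))
  cpp_enumerate_candidates(as.integer(thickness_vox),
                           as.integer(pmax(offset_max, 0)),
                           fx, as.integer(adjacent),
                           as.numeric(delta))
}

#' L1 score of one candidate topography
#'
#' Builds the trial column grid (context plus the candidate offsets on the
#' member pixels), simulates the per-line 2D XRF response of the scored
#' pixels and returns the summed absolute deviation from the targets.
#'
#' @param offsets candidate offsets, one per member (voxels).
#' @param members two-column `(i, j)` matrix of member pixels.
#' @param ob_ctx context offset matrix (voxels) with all previously fixed
#'   regions embedded.
#' @param thickness_vox full-grid thickness matrix (voxels).
#' @param att_list named list of per-line attenuation maps (um^-1).
#' @param em_profiles list (one per scored pixel) of `thickness x n_lines`
#'   matrices of per-voxel emission, top voxel first.
#' @param targets named list of per-line target count maps.
#' @param face_points ray-target matrix of the detector.
#' @param voxel voxel size in um.
#' @param scored indices into `members` of the scored pixels (default all).
#' @return The L1 score (scalar).
#' @export
score_topography <- function(offsets, members, ob_ctx, thickness_vox,
                             att_list, em_profiles, targets, face_points,
                             voxel = 1, scored = seq_len(nrow(members))) {
  cpp_score_candidates(matrix(as.integer(offsets), 1),
                       as.integer(members[, 1] - 1L),
                       as.integer(members[, 2] - 1L),
                       ob_ctx, thickness_vox,
                       att_list, em_profiles,
                       as.integer(scored - 1L), targets,
                       face_points, voxel)[1]
}

# Per-voxel emission profile of one pixel column, top voxel first.
.em_profile <- function(i, j, tvox, em0_list, att0, voxel) {
  nl <- length(em0_list)
  depth <- (seq_len(max(tvox, 1)) - 0.5) * voxel
  out <- matrix(0, max(tvox, 1), nl)
  for (l in seq_len(nl))
    out[, l] <- em0_list[[l]][i, j] * exp(-att0[i, j] * depth)
  out
}

#' Reconstruct the topography seen by a single detector
#'
#' Iterates seed lines and conical regions until every eligible footprint
#' pixel is resolved: each region's candidate topographies (gap-free column
#' translations, previously fixed members frozen) are scored against the
#' detector's target maps and the lowest-scoring one is fixed before moving
#' on. Pixels never visited keep the support-resting placement.
#'
#' @param targets named list of per-line target count maps for this
#'   detector.
#' @param thickness_vox thickness matrix in voxels.
#' @param em0_list named list of per-line surface emission maps (photons
#'   per voxel at zero overburden, including this detector's solid angle).
#' @param att0 attenuation map at the incident energy (um^-1).
#' @param att_list named list of per-line attenuation maps (um^-1).
#' @param detector a `detector_spec`.
#' @param eligible logical matrix of pixels assigned to this detector.
#' @param config an `ir_config`.
#' @param h_max_vox maximum admissible column top in voxels (offsets search
#'   `[0, h_max_vox - thickness]`).
#' @param coverage this detector's coverage map (seed ordering).
#' @param voxel voxel size in um.
#' @return List with `offsets` (matrix, voxels), `resolved` (logical
#'   matrix) and `fallbacks` (count of over-constrained regions).
#' @export
reconstruct_detector <- function(targets, thickness_vox, em0_list, att0,
                                 att_list, detector, eligible, config,
                                 h_max_vox, coverage, voxel = 1) {
  ny <- nrow(thickness_vox); nx <- ncol(thickness_vox)
  fp <- thickness_vox > 0
  eligible <- eligible & fp
  ob <- matrix(0L, ny, nx)
  resolved <- matrix(FALSE, ny, nx)
  fallbacks <- 0L

  elev <- atan2(detector$face_center[3],
                sqrt(sum((detector$face_center[1:2] -
                            c(nx, ny) * voxel / 2)^2)))
  roi_range <- config$roi_range
  if (is.null(roi_range))
    roi_range <- h_max_vox * voxel / tan(max(elev - detector$half_angle, 0.05))
  stride <- config$stride
  if (is.null(stride))
    stride <- max(1, round((roi_range / 2 * tan(detector$half_angle) +
                              0.5 * voxel) / voxel))
  npts <- detector$face_points
  if (config$n_face_points == 1 && nrow(npts) > 1)
    npts <- matrix(detector$face_center, 1)

  ctr <- .pixel_centers(ny, nx, voxel)
  dist_det <- sqrt((ctr$x - detector$face_center[1])^2 +
                     (ctr$y - detector$face_center[2])^2)

  while (any(eligible & !resolved)) {
    sl <- select_seed_and_line(coverage, eligible, resolved, detector,
                               stride, voxel)
    if (is.null(sl)) break
    progressed <- FALSE
    for (a in seq_len(nrow(sl$apexes))) {
      apex <- sl$apexes[a, ]
      if (!eligible[apex[1], apex[2]] || resolved[apex[1], apex[2]]) next
      mem <- conical_roi(apex, detector, eligible, voxel, roi_range)
      midx <- cbind(mem[, 1], mem[, 2])
      tv_m <- thickness_vox[midx]
      unres <- !resolved[midx]
      fixed <- ifelse(unres, NA_integer_, ob[midx])
      omax <- pmax(h_max_vox - tv_m, 0)
      # continuity binds spatially adjacent chain pairs; pairs already fixed
      # by earlier regions cannot change, so their link carries no constraint
      adj <- c(FALSE, abs(diff(mem[, 1])) <= 1 & abs(diff(mem[, 2])) <= 1)
      frozen <- !unres
      adj <- adj & !c(FALSE, frozen[-1] & frozen[-length(frozen)])
      en <- enumerate_candidates(tv_m, omax, fixed, adj, config$delta)
      if (nrow(en$candidates) == 0) {
        warning("over-constrained region at (", apex[1], ",", apex[2],
                "): keeping support-resting placement")
        fallbacks <- fallbacks + 1L
        resolved[midx] <- TRUE
        progressed <- TRUE
        next
      }
      # scored set: pixels whose response can depend on the free offsets
      # (everything at or behind the nearest unresolved member)
      dmin <- min(dist_det[midx][unres])
      scored <- which(unres | dist_det[midx] >= dmin - 1.5 * voxel)
      em_prof <- lapply(scored, function(s)
        .em_profile(mem[s, 1], mem[s, 2], tv_m[s], em0_list, att0, voxel))
      sc <- cpp_score_candidates(en$candidates,
                                 as.integer(mem[, 1] - 1L),
                                 as.integer(mem[, 2] - 1L),
                                 ob, thickness_vox,
                                 att_list, em_prof,
                                 as.integer(scored - 1L), targets,
                                 npts, voxel)
      best <- which.min(sc)
      ob[midx] <- en$candidates[best, ]
      resolved[midx] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) {  # guard: resolve the seed alone
      resolved[sl$seed[1], sl$seed[2]] <- TRUE
    }
  }
  list(offsets = ob, resolved = resolved & eligible, fallbacks = fallbacks)
}

#' Merge per-detector topographies into one sample
#'
#' Per pixel, each contributing detector (one that reconstructed the pixel)
#' receives weight `1 - normalized coverage` -- more weight to the
#' detectors least attenuated by the sample -- renormalized to sum to 1;
#' the merged column offset is the weighted mean rounded to the nearest
#' voxel. Thickness is preserved exactly. Pixels no detector reconstructed
#' keep the support-resting placement.
#'
#' @param per_detector named list of `reconstruct_detector()` results.
#' @param norm_cov named list of normalized coverage maps (from
#'   [detector_assignment()]).
#' @param thickness_vox thickness matrix in voxels.
#' @param nz grid height in voxels.
#' @return Integer matrix of merged column offsets (voxels).
#' @export
merge_topographies <- function(per_detector, norm_cov, thickness_vox, nz) {
  ny <- nrow(thickness_vox); nx <- ncol(thickness_vox)
  wsum <- matrix(0, ny, nx)
  osum <- matrix(0, ny, nx)
  nres <- matrix(0, ny, nx)
  oeq <- matrix(0, ny, nx)
  for (nm in names(per_detector)) {
    res <- per_detector[[nm]]$resolved
    w <- (1 - norm_cov[[nm]]) * res
    wsum <- wsum + w
    osum <- osum + w * per_detector[[nm]]$offsets
    nres <- nres + res
    oeq <- oeq + res * per_detector[[nm]]$offsets
  }
  merged <- ifelse(wsum > 0, osum / wsum,
                   ifelse(nres > 0, oeq / pmax(nres, 1), 0))
  ob <- matrix(as.integer(round(merged)), ny, nx)
  pmin(pmax(ob, 0L), nz - thickness_vox)
}

#' Full multi-detector inverse reconstruction
#'
#' Runs the per-detector topography search for every detector the
#' oversampling parameter assigns, then merges the results into a single
#' voxelized sample whose per-pixel thickness comes from the z-map.
#'
#' @param mapset `xrf_map_set` holding the target maps.
#' @param zstate `zmap_state` from [derive_zmap()].
#' @param fractions named list of per-pixel mass-fraction maps (typically
#'   the first-pass FP estimate).
#' @param beam a `beam_config`.
#' @param detectors named list of `detector_spec`.
#' @param config an `ir_config`.
#' @param tables constants registry.
#' @return List with `grid` (merged `voxel_grid`), `offsets`,
#'   `per_detector`, `assignment`, `coverages`, `rho_hat`.
#' @export
inverse_reconstruct <- function(mapset, zstate, fractions, beam, detectors,
                                config = ir_config(),
                                tables = xrf_constants()) {
  vox <- mapset$meta$voxel
  line <- mapset$meta$line
  fp <- zstate$footprint
  tvox <- matrix(as.integer(round(zstate$z / vox)), nrow(fp), ncol(fp))
  tvox[fp & tvox == 0L] <- 1L
  tvox[!fp] <- 0L
  h_max_vox <- as.integer(round(zstate$h_max / vox))
  tvox <- pmin(tvox, h_max_vox)
  nz <- h_max_vox + 2L   # head-room above the tallest admissible top

  # recovered composition-consistent attenuation and emission fields;
  # pixels without counts (undefined fractions) fall back to the
  # footprint-average composition
  frac0 <- lapply(fractions, function(f) ifelse(is.na(f) | !fp, 0, f))
  wsum <- Reduce(`+`, frac0)
  bad <- fp & wsum < 1e-9
  if (any(bad)) {
    for (el in names(frac0)) {
      avg <- mean(frac0[[el]][fp & !bad])
      frac0[[el]][bad] <- avg
    }
    wsum <- Reduce(`+`, frac0)
  }
  frac0 <- lapply(frac0, function(f) ifelse(fp, f / pmax(wsum, 1e-12), 0))
  mu_list <- mu_maps(frac0, c(E0 = beam$E0), tables)
  mu0 <- mu_list$E0                        # cm^2/g
  rho_hat <- matrix(0, nrow(fp), ncol(fp))
  rho_hat[fp] <- zstate$mu_rho[fp] / pmax(mu0[fp] * 1e-4, 1e-12)
  att0 <- zstate$mu_rho                    # um^-1 at E0
  att_list <- lapply(config$lines, function(el) {
    mui <- mu_maps(frac0, line_energy(el, line, tables), tables)[[1]]
    ifelse(fp, mui / pmax(mu0, 1e-12), 0) * att0
  })
  names(att_list) <- config$lines

  thick_um <- tvox * vox
  coverages <- lapply(detectors, function(d) coverage_map(thick_um, d, vox))
  assign <- detector_assignment(coverages, config$ir_os)

  per_det <- lapply(names(detectors), function(nm) {
    det <- detectors[[nm]]
    em0 <- lapply(config$lines, function(el) {
      lc <- line_constants(el, line, tables)
      Y <- det$solid_angle_fraction * lc$fluorescence_yield *
        lc$transition_probability * lc$jump_factor
      frac0[[el]] * rho_hat * tau_element(el, beam$E0, tables) * Y *
        beam$I0 * (vox * 1e-4)
    })
    names(em0) <- config$lines
    tg <- lapply(config$lines, function(el)
      mapset$xrf[[nm]][[.line_key(el, line)]])
    names(tg) <- config$lines
    reconstruct_detector(tg, tvox, em0, att0, att_list, det,
                         assign$assigned[[nm]], config, h_max_vox,
                         coverages[[nm]], vox)
  })
  names(per_det) <- names(detectors)

  ob <- merge_topographies(per_det, assign$norm_cov, tvox, nz)
  dens <- rho_hat
  dens[tvox > 0 & dens <= 0] <- zstate$rho_avg
  grid <- voxel_grid(c(nrow(fp), ncol(fp), nz), vox, thickness = tvox,
                     zbot = ob, density = ifelse(tvox > 0, dens, 0),
                     fractions = lapply(frac0, function(f)
                       ifelse(tvox > 0, f, 0)))
  list(grid = grid, offsets = ob, per_detector = per_det,
       assignment = assign, coverages = coverages, rho_hat = rho_hat)
}
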