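# Helpers building the per-detector scoring context the same way the
# reconstruction does, so single operations can be exercised in isolation.
toy_context <- function(g, beam, det, lines = "C",
                        tables = xrf_constants()) {
  att0 <- attenuation_map(g, beam$E0, tables)
  att_list <- lapply(lines, function(el)
    attenuation_map(g, line_energy(el, "K-alpha", tables), tables))
  names(att_list) <- lines
  em0 <- lapply(lines, function(el) {
    lc <- line_constants(el, "K-alpha", tables)
    g$fractions[[el]] * g$density * tau_element(el, beam$E0, tables) *
      det$solid_angle_fraction * lc$fluorescence_yield *
      lc$transition_probability * lc$jump_factor * beam$I0 * (g$voxel * 1e-4)
  })
  names(em0) <- lines
  list(att0 = att0, att_list = att_list, em0 = em0)
}

test_that("coverage is zero without interposed sample and matches a line integral", {
  thick <- matrix(0, 6, 6)
  det <- detector_spec("E", c(30000, 3, 3000), c(3, 3, 1.5))
  expect_true(all(coverage_map(thick, det) == 0))

  thick[3, 3] <- 4                       # isolated column: self excluded
  expect_equal(coverage_map(thick, det)[3, 3], 0)

  thick[3, 5] <- 3                       # column between pixel and detector
  cov <- coverage_map(thick, det)
  ref <- brute_path_depth(c(2.5, 2.5, 4), det$face_center,
                          matrix(0, 6, 6), thick * (row(thick) == 3 & col(thick) == 5),
                          matrix(1, 6, 6), 1, step = 0.002)
  expect_equal(cov[3, 3], ref, tolerance = 1e-3)
})

test_that("seed selection takes the least-covered pixel with row-major ties", {
  g <- build_phantom(phantom_spec(grid_shape = c(12, 12, 6),
                                  hemispheres = data.frame(cx = 6, cy = 6, r = 4),
                                  mg_rois = NULL))
  det <- detector_ring(g)[["SE"]]
  cov <- coverage_map(thickness_map(g), det)
  fp <- g$thickness > 0
  sl <- select_seed_and_line(cov, fp, matrix(FALSE, 12, 12), det)
  # argmin of coverage over the footprint
  expect_equal(cov[sl$seed[1], sl$seed[2]], min(cov[fp]))
  # uniform coverage: first open pixel in reading order
  slu <- select_seed_and_line(matrix(1, 12, 12), fp, matrix(FALSE, 12, 12), det)
  open <- which(t(fp))[1]
  expect_equal(slu$seed, c((open - 1) %/% 12 + 1, (open - 1) %% 12 + 1))
  # apexes walk away from the detector
  d0 <- sum((c(sl$seed[2] - .5, sl$seed[1] - .5) - det$face_center[1:2])^2)
  dl <- sum((c(sl$apexes[nrow(sl$apexes), 2] - .5,
               sl$apexes[nrow(sl$apexes), 1] - .5) - det$face_center[1:2])^2)
  expect_gt(dl, d0)
  # everything resolved: NULL
  expect_null(select_seed_and_line(cov, fp, fp | TRUE, det))
})

test_that("the conical region matches an independent geometric test", {
  elig <- matrix(TRUE, 15, 15)
  det <- detector_spec("E", c(40000, 7.5, 20000), c(7.5, 7.5, 3),
                       face_side = 5000)
  apex <- c(8, 3)
  roi <- conical_roi(apex, det, elig, roi_range = 50)
  # oracle: point-in-wedge with the same half-angle, plus the one-pixel floor
  p <- c(apex[2] - 0.5, apex[1] - 0.5)
  d <- det$face_center[1:2] - p; d <- d / sqrt(sum(d^2))
  in_wedge <- function(i, j) {
    v <- c(j - 0.5, i - 0.5) - p
    along <- sum(v * d); perp <- abs(v[1] * d[2] - v[2] * d[1])
    along >= 0 && perp <= along * tan(det$half_angle) + 0.5
  }
  oracle <- which(outer(1:15, 1:15, Vectorize(in_wedge)))
  got <- sort((roi[, 2] - 1) * 15 + roi[, 1])
  expect_equal(got, sort(oracle))
  # members are ordered by apex distance, apex first
  expect_equal(unname(roi[1, ]), apex)
  dists <- sqrt((roi[, 2] - apex[2])^2 + (roi[, 1] - apex[1])^2)
  expect_true(all(diff(dists) >= 0))
})

test_that("degenerate cones collapse to a pixel line or the apex alone", {
  elig <- matrix(TRUE, 9, 9)
  tiny <- detector_spec("E", c(50000, 4.5, 9000), c(4.5, 4.5, 1),
                        face_side = 1e-3)   # half-angle ~ 0
  roi <- conical_roi(c(5, 3), tiny, elig)
  expect_true(all(roi[, 1] == 5))           # a single pixel row toward E
  expect_equal(sort(roi[, 2]), 3:9)
  # apex on the detector-side edge
  roi2 <- conical_roi(c(5, 9), tiny, elig)
  expect_equal(nrow(roi2), 1L)
  expect_equal(unname(roi2[1, ]), c(5, 9))
})

test_that("candidate enumeration counts match brute force and delta subsampling", {
  # single pixel: H - t + 1 placements
  en <- enumerate_candidates(3, offset_max = 4, delta = 1e6)
  expect_equal(en$total, 5)
  expect_equal(en$candidates[, 1], 0:4)

  # two adjacent pixels under the overlap rule vs exhaustive enumeration
  brute <- expand.grid(o1 = 0:2, o2 = 0:2)
  keep <- with(brute, o2 <= o1 + 2 - 1 & o1 <= o2 + 2 - 1)
  en2 <- enumerate_candidates(c(2, 2), c(2, 2), delta = 1e6)
  expect_equal(en2$total, sum(keep))
  got <- apply(en2$candidates, 1, paste, collapse = ",")
  want <- apply(brute[keep, c("o1", "o2")], 1, paste, collapse = ",")
  expect_setequal(got, sort(want))
  # lexicographic order
  expect_true(all(diff(en2$candidates[, 1] * 10 + en2$candidates[, 2]) > 0))

  # delta = 1 keeps exactly the first candidate
  en3 <- enumerate_candidates(c(2, 2), c(2, 2), delta = 1)
  expect_equal(nrow(en3$candidates), 1L)
  expect_equal(unname(en3$candidates[1, ]), c(0, 0))

  # a three-pixel chain with a frozen middle member
  brute3 <- expand.grid(o1 = 0:3, o2 = 1, o3 = 0:3)
  keep3 <- with(brute3, abs(o1 - o2) <= 1 & abs(o2 - o3) <= 1) # t = 2 each
  en4 <- enumerate_candidates(c(2, 2, 2), c(3, 3, 3),
                              fixed = c(NA, 1, NA), delta = 1e6)
  expect_equal(en4$total, sum(keep3))

  # non-adjacent pairs are unconstrained
  en5 <- enumerate_candidates(c(1, 1), c(3, 3),
                              adjacent = c(FALSE, FALSE), delta = 1e6)
  expect_equal(en5$total, 16)
})

test_that("scoring is zero on self-consistent targets and ignores non-member pixels", {
  g <- build_phantom(phantom_spec(grid_shape = c(10, 10, 6),
                                  hemispheres = data.frame(cx = 5, cy = 5, r = 3.5),
                                  mg_rois = NULL))
  beam <- beam_config()
  det <- detector_ring(g)[["E"]]
  ctx <- toy_context(g, beam, det)
  ms <- xrf_maps(g, beam, list(E = det), elements = "C")
  targets <- list(C = ms$xrf$E$C_Kalpha)

  fpix <- which(g$thickness > 0, arr.ind = TRUE)
  mem <- fpix[order(fpix[, 1], fpix[, 2]), ][1:4, ]
  prof <- lapply(seq_len(nrow(mem)), function(s)
    xrftopo:::.em_profile(mem[s, 1], mem[s, 2], g$thickness[mem[s, , drop = FALSE]],
                          ctx$em0, ctx$att0, 1))
  sc <- score_topography(g$zbot[mem], mem, g$zbot, g$thickness,
                         ctx$att_list, prof, targets, det$face_points)
  expect_equal(sc, 0, tolerance = 1e-9)

  # perturbing the target outside the scored set leaves the score unchanged
  t2 <- targets
  out <- which(g$thickness == 0, arr.ind = TRUE)[1, ]
  t2$C[out[1], out[2]] <- 99
  sc2 <- score_topography(g$zbot[mem], mem, g$zbot, g$thickness,
                          ctx$att_list, prof, t2, det$face_points)
  expect_equal(sc2, sc)

  # a lifted candidate scores strictly worse on self-consistent targets
  off <- g$zbot[mem]; off[1] <- off[1] + 2
  sc3 <- score_topography(off, mem, g$zbot, g$thickness,
                          ctx$att_list, prof, targets, det$face_points)
  expect_gt(sc3, sc)
})

test_that("exhaustive search recovers a known topography on a toy grid", {
  # 1 x 4 strip, heights 2, with the third column lifted by 1
  ny <- 4; nx <- 4; nz <- 5
  thick <- matrix(0, ny, nx); thick[2, 1:4] <- 2
  zb <- matrix(0L, ny, nx); zb[2, 3] <- 1L
  truth <- voxel_grid(c(ny, nx, nz), 1, thickness = thick, zbot = zb,
                      density = 1.25,
                      fractions = lapply(lovo_fractions(), function(w)
                        matrix(w, ny, nx)))
  beam <- beam_config()
  det <- detector_spec("E", c(28000, 2, 14000), c(2, 2, 2.5))
  ms <- xrf_maps(truth, beam, list(E = det), elements = "C")
  ctx <- toy_context(truth, beam, det)
  targets <- list(C = ms$xrf$E$C_Kalpha)

  mem <- cbind(i = rep(2, 4), j = 4:1)     # ordered from the detector side
  tv <- truth$thickness[mem]
  en <- enumerate_candidates(tv, pmax(nz - tv, 0),
                             adjacent = c(FALSE, abs(diff(mem[, 2])) <= 1),
                             delta = 1e6)
  prof <- lapply(seq_len(nrow(mem)), function(s)
    xrftopo:::.em_profile(mem[s, 1], mem[s, 2], tv[s], ctx$em0, ctx$att0, 1))
  scores <- vapply(seq_len(nrow(en$candidates)), function(c)
    score_topography(en$candidates[c, ], mem, matrix(0L, ny, nx),
                     truth$thickness, ctx$att_list, prof, targets,
                     det$face_points), 0)
  best <- en$candidates[which.min(scores), ]
  expect_equal(unname(best), unname(truth$zbot[mem]))
})

test_that("a flat slab reconstructs itself exactly", {
  g <- make_slab(6, 6, 5, t = 2)
  beam <- beam_config()
  dets <- detector_ring(g)[c("E", "W")]
  ms <- xrf_maps(g, beam, dets, elements = "C")
  zs <- derive_zmap(ms$stxm, 1.25, h_max = 2, n_iter = 100)
  rec <- inverse_reconstruct(ms, zs, lapply(lovo_fractions(), function(w)
    matrix(w, 6, 6)), beam, dets, ir_config(ir_os = 1, delta = 1e5))
  expect_true(all(rec$grid$zbot == 0))
  expect_equal(rec$grid$thickness, g$thickness)
})

test_that("reconstruct_detector with unlimited delta matches the optimum and is deterministic", {
  ny <- 6; nx <- 6; nz <- 4
  thick <- matrix(0, ny, nx); thick[3, 2:5] <- c(1, 2, 2, 1)
  truth <- voxel_grid(c(ny, nx, nz), 1, thickness = thick,
                      density = 1.25,
                      fractions = lapply(lovo_fractions(), function(w)
                        matrix(w, ny, nx)))
  beam <- beam_config()
  det <- detector_spec("E", c(28000, 3, 14000), c(3, 3, 2))
  ms <- xrf_maps(truth, beam, list(E = det), elements = "C")
  ctx <- toy_context(truth, beam, det)
  targets <- list(C = ms$xrf$E$C_Kalpha)
  cov <- coverage_map(thickness_map(truth), det)
  # score with the full ray-target grid so the optimum of the search equals
  # the topography that generated the targets
  cfg <- ir_config(ir_os = 1, delta = 1e6, n_face_points = 9)
  r1 <- reconstruct_detector(targets, truth$thickness, ctx$em0, ctx$att0,
                             ctx$att_list, det, thick > 0, cfg,
                             h_max_vox = 3, coverage = cov)
  r2 <- reconstruct_detector(targets, truth$thickness, ctx$em0, ctx$att0,
                             ctx$att_list, det, thick > 0, cfg,
                             h_max_vox = 3, coverage = cov)
  expect_identical(r1, r2)
  expect_equal(r1$offsets[thick > 0], truth$zbot[thick > 0])
})

test_that("merging respects weights, preserves thickness and handles one detector", {
  thick <- matrix(2L, 3, 3)
  one <- list(A = list(offsets = matrix(1L, 3, 3),
                       resolved = matrix(TRUE, 3, 3), fallbacks = 0L))
  nc <- list(A = matrix(0.4, 3, 3))
  m1 <- merge_topographies(one, nc, thick, nz = 6)
  expect_true(all(m1 == 1))

  two <- list(A = list(offsets = matrix(0L, 3, 3),
                       resolved = matrix(TRUE, 3, 3), fallbacks = 0L),
              B = list(offsets = matrix(2L, 3, 3),
                       resolved = matrix(TRUE, 3, 3), fallbacks = 0L))
  nc2 <- list(A = matrix(0.5, 3, 3), B = matrix(0.5, 3, 3))
  m2 <- merge_topographies(two, nc2, thick, nz = 6)
  expect_true(all(m2 == 1))                 # equal weights: mean offset
  expect_true(all(m2 + thick <= 6))

  # unresolved pixels keep the support-resting placement
  part <- list(A = list(offsets = matrix(3L, 3, 3),
                        resolved = matrix(FALSE, 3, 3), fallbacks = 0L))
  m3 <- merge_topographies(part, nc, thick, nz = 6)
  expect_true(all(m3 == 0))
})

test_that("oversampling gates detectors by normalized coverage", {
  cov <- list(A = matrix(c(0, 2, 4, 8), 2), B = matrix(c(1, 1, 1, 1), 2))
  da <- detector_assignment(cov, ir_os = 0.2)
  # the least-covered detector is always assigned
  expect_true(all(da$assigned$A | da$assigned$B))
  expect_true(da$assigned$A[1, 1])          # zero coverage
  expect_false(da$assigned$A[2, 2])         # 8 vs max 8 -> 1 > 0.2
  expect_true(da$assigned$B[2, 2])
  da1 <- detector_assignment(cov, ir_os = 1)
  expect_true(all(da1$assigned$A & da1$assigned$B))
})
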