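test_that("incident profile follows Beer-Lambert attenuation", {
  # vacuum: full intensity everywhere
  g0 <- voxel_grid(c(3, 3, 4), 1, thickness = matrix(0, 3, 3),
                   density = 0, fractions = list(C = matrix(0, 3, 3)))
  beam <- beam_config(I0 = 1e6)
  expect_true(all(incident_profile(g0, beam) == 1e6))

  # half-value depth: mu rho z = ln 2 at 3.5 um below the surface
  a <- log(2) / 3.5                       # per um
  rho <- a * 1e4 / 100                    # with mu = 100 cm^2/g
  tabs <- flat_tables(list(A = 100))
  g <- voxel_grid(c(3, 3, 8), 1, thickness = matrix(8, 3, 3),
                  density = rho, fractions = list(A = matrix(1, 3, 3)))
  prof <- incident_profile(g, beam, tabs)
  expect_equal(prof[2, 2, 5], 1e6 / 2, tolerance = 1e-12)  # depth 3.5 um
  # analytic exponential at every depth (midpoint overburden)
  for (k in 1:8)
    expect_equal(prof[1, 1, k], 1e6 * exp(-a * (8 - k + 0.5)),
                 tolerance = 1e-12)
  # STXM equals the full-column transmission
  expect_equal(stxm_map(g, beam, tabs)[2, 2], exp(-a * 8), tolerance = 1e-12)
})

test_that("path transmission is exact through vacuum, slabs and oblique paths", {
  tabs <- flat_tables(list(A = 100))
  g0 <- voxel_grid(c(3, 3, 4), 1, thickness = matrix(0, 3, 3),
                   density = 0, fractions = list(A = matrix(0, 3, 3)))
  expect_equal(trace_path_transmission(g0, c(0.5, 0.5, 0.5),
                                       c(10, 10, 10), 500, tabs), 1)

  # horizontal path with mu rho delta = 1
  rho <- 1e4 / (100 * 5)                  # att = 0.2/um, 5 um path
  g <- voxel_grid(c(1, 5, 3), 1, thickness = matrix(1, 1, 5),
                  density = rho, fractions = list(A = matrix(1, 1, 5)))
  expect_equal(trace_path_transmission(g, c(0, 0.5, 0.5), c(5, 0.5, 0.5),
                                       500, tabs),
               exp(-1), tolerance = 1e-12)

  # oblique path through a 3x3x3 block vs fine-step numerical integral
  gb <- voxel_grid(c(3, 3, 3), 1, thickness = matrix(3, 3, 3),
                   density = 1.25, fractions = as.list(lovo_fractions()))
  att <- attenuation_map(gb, 277)
  p0 <- c(0.31, 0.27, 0.41); p1 <- c(7.7, 6.3, 5.9)
  ref <- brute_path_depth(p0, p1, matrix(0, 3, 3), thickness_map(gb), att,
                          1, step = 0.002)
  got <- -log(trace_path_transmission(gb, p0, p1, 277))
  expect_equal(got, ref, tolerance = 1e-4)
  # and against the independent 3D voxel walker
  att3 <- array(rep(att, 3), c(3, 3, 3)) * occupancy_array(gb)
  expect_equal(got,
               xrftopo:::cpp_path_3d(p0, p1, att3, c(3L, 3L, 3L), 1),
               tolerance = 1e-10)
})

test_that("self-absorption K lies in (0,1], is 1 in vacuum and decreases with density", {
  g0 <- voxel_grid(c(4, 4, 3), 1, thickness = matrix(0, 4, 4),
                   density = 0, fractions = list(C = matrix(0, 4, 4)))
  det <- detector_ring(g0)[["SE"]]
  expect_true(all(self_absorption_K(g0, det, "C") == 1))

  g1 <- build_phantom(phantom_spec(grid_shape = c(20, 20, 8),
                                   hemispheres = data.frame(cx = 10, cy = 10, r = 6),
                                   mg_rois = NULL))
  det <- detector_ring(g1)[["SE"]]
  K1 <- self_absorption_K(g1, det, "C")
  expect_true(all(K1 > 0 & K1 <= 1))

  g2 <- g1; g2$density <- g1$density * 2
  K2 <- self_absorption_K(g2, det, "C")
  expect_true(all(K2 <= K1 + 1e-12))
})

test_that("slab response matches the closed-form absorption factor", {
  vox <- 0.25
  n <- 200                                 # 50 um slab extent
  tabs <- xrf_constants()
  for (h in c(1, 5, 10)) {
    g <- voxel_grid(c(n, n, round(h / vox) + 2), vox,
                    thickness = matrix(round(h / vox), n, n),
                    density = 1.25, fractions = as.list(lovo_fractions()))
    beam <- beam_config()
    det <- detector_ring(g)[["E"]]
    EM <- emission_matrix(g, beam, "C", solid_angle_fraction =
                            det$solid_angle_fraction)
    ic <- n / 2
    tvox <- g$thickness[ic, ic]
    # K per voxel of the central column from exported path tracing
    Ks <- vapply(seq_len(tvox), function(k) {
      from <- c((ic - 0.5) * vox, (ic - 0.5) * vox, (k - 0.5) * vox)
      mean(vapply(seq_len(nrow(det$face_points)), function(p)
        trace_path_transmission(g, from, det$face_points[p, ], 277),
        0))
    }, 0)
    detected <- sum(EM[ic, ic, seq_len(tvox)] * Ks)

    mu0 <- mixture_mu(lovo_fractions(), beam$E0)
    mui <- mixture_mu(lovo_fractions(), 277)
    kfp <- k_fp(h, 1.25, mu0, mui,
                mean_cosec_phi = mean_cosec_phi(det, c((ic - 0.5) * vox,
                                                       (ic - 0.5) * vox, 0)))
    B <- 0.61 * 1.25 * tau_element("C", beam$E0) *
      yield_factor("C", "K-alpha", det$solid_angle_fraction) * beam$I0
    closed <- B * (h * 1e-4) * kfp
    expect_equal(detected, closed, tolerance = 0.02)
  }
})

test_that("2D maps are the z-sum of EM times K, bounded by the unabsorbed sum", {
  g <- build_phantom(phantom_spec(grid_shape = c(24, 24, 8),
                                  hemispheres = data.frame(cx = 12, cy = 12, r = 6),
                                  mg_rois = NULL))
  beam <- beam_config()
  dets <- detector_ring(g)[c("N", "SE")]
  ms <- xrf_maps(g, beam, dets, elements = c("C", "N"))
  for (dn in names(dets)) {
    K <- self_absorption_K(g, dets[[dn]], "C")
    EM <- emission_matrix(g, beam, "C",
                          solid_angle_fraction = dets[[dn]]$solid_angle_fraction)
    expect_equal(ms$xrf[[dn]]$C_Kalpha, apply(EM * K, c(1, 2), sum))
    expect_true(all(ms$xrf[[dn]]$C_Kalpha <=
                      apply(EM, c(1, 2), sum) + 1e-9))
  }
  expect_true(all(ms$stxm > 0 & ms$stxm <= 1))
})

test_that("symmetric phantoms give rotation-equivalent maps", {
  g <- build_phantom(phantom_spec(grid_shape = c(40, 40, 10),
                                  hemispheres = data.frame(cx = 20, cy = 20, r = 8),
                                  mg_rois = NULL))
  beam <- beam_config()
  dets <- detector_ring(g)[c("N", "E")]
  ms <- xrf_maps(g, beam, dets, elements = "C")
  rot_cw <- function(m) t(m[nrow(m):1, ])   # scene rotated N -> E
  expect_equal(rot_cw(ms$xrf$N$C_Kalpha), ms$xrf$E$C_Kalpha,
               tolerance = 1e-9)
})

test_that("tall cells shadow pixels seen from behind", {
  g <- build_phantom(canonical_phantom_spec())
  beam <- beam_config()
  dets <- detector_ring(g)[c("SE", "NW")]
  ms <- xrf_maps(g, beam, dets, elements = "C")
  cov_se <- coverage_map(thickness_map(g), dets$SE)
  cov_nw <- coverage_map(thickness_map(g), dets$NW)
  sel <- cov_se > 5 & cov_nw < 1 & g$thickness > 0
  expect_gt(sum(sel), 5)
  expect_lt(sum(ms$xrf$SE$C_Kalpha[sel]), sum(ms$xrf$NW$C_Kalpha[sel]))
})

test_that("simulation is deterministic, including seeded noise", {
  g <- build_phantom(phantom_spec(grid_shape = c(16, 16, 8),
                                  hemispheres = data.frame(cx = 8, cy = 8, r = 5),
                                  mg_rois = NULL))
  beam <- beam_config(I0 = 1e4)
  dets <- detector_ring(g)[c("S", "W")]
  a <- xrf_maps(g, beam, dets, elements = "C", poisson = TRUE,
                stxm_poisson = TRUE, seed = 7)
  b <- xrf_maps(g, beam, dets, elements = "C", poisson = TRUE,
                stxm_poisson = TRUE, seed = 7)
  expect_identical(a$xrf, b$xrf)
  expect_identical(a$stxm, b$stxm)
})

test_that("emission below the excitation edge is zero with a warning", {
  g <- make_slab(4, 4, 4, t = 2)
  beam <- beam_config(E0 = 400)            # below the O and Mg edges
  expect_warning(em <- emission_matrix(g, beam, "O"), "below")
  expect_true(all(em == 0))
})

test_that("a surface voxel emits w rho tau Y I0 dz exactly", {
  g <- make_slab(3, 3, 2, t = 1, density = 1.25)
  beam <- beam_config()
  em <- emission_matrix(g, beam, "C", solid_angle_fraction = 0.01)
  expect_equal(em[2, 2, 1],
               0.61 * 1.25 * tau_element("C", 1500) *
                 yield_factor("C", "K-alpha", 0.01) * 1e8 * 1e-4 *
                 exp(-attenuation_map(g, 1500)[2, 2] * 0.5),
               tolerance = 1e-12)
})
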