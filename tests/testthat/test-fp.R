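test_that("the absorption factor has its analytic values and limits", {
  # x = rho * h_cm * (mu0 + mui * cosec); build x = 1 and x = 2 exactly
  expect_equal(k_fp(1e4, 1, 0.5, 0.5, 1, 1), 1 - exp(-1))
  expect_equal(k_fp(2e4, 1, 0.5, 0.5, 1, 1), (1 - exp(-2)) / 2)
  expect_equal(k_fp(0, 1.25, 100, 200, 1, 2), 1)
  expect_equal(k_fp(1e-9, 1.25, 1, 1, 1, 1), 1)
  expect_error(k_fp(-1, 1, 1, 1, 1, 1), "nonnegative")
})

test_that("the absorption factor is strictly decreasing and in (0,1]", {
  h <- seq(0, 50, by = 0.5)
  v <- k_fp(h, 1.25, 800, 2000, 1, 2)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))
})

test_that("element mass is linear in counts and errors on bad input", {
  m1 <- element_mass(100, 1, 1e8, 1e-5, 2000)
  expect_equal(element_mass(200, 1, 1e8, 1e-5, 2000), 2 * m1)
  expect_equal(element_mass(0, 1, 1e8, 1e-5, 2000), 0)
  expect_error(element_mass(-1, 1, 1e8, 1e-5, 2000), "nonnegative")
  expect_error(element_mass(1, 1, 1e8, 0, 2000), "denominator")
})

test_that("mass fractions normalize and flag undefined pixels", {
  mf <- mass_fractions(c(C = 3, N = 0))
  expect_equal(mf$fractions$C, 1)
  mf2 <- mass_fractions(c(C = 1, N = 1))
  expect_equal(mf2$fractions$N, 0.5)
  mf3 <- mass_fractions(list(C = matrix(c(1, 0), 1), N = matrix(c(1, 0), 1)))
  expect_true(mf3$undefined[1, 2])
  expect_true(is.na(mf3$fractions$C[1, 2]))
})

test_that("mixture maps delegate to the mixture rule", {
  fr <- list(C = matrix(0.5, 2, 2), N = matrix(0.5, 2, 2))
  mm <- mu_maps(fr, c(E0 = 1500))
  expect_equal(mm$E0[1, 1], mixture_mu(c(C = .5, N = .5), 1500))
})

test_that("a thin slab round-trips through simulation and quantification", {
  # 1 um slab at 0.1 um voxels: fine enough along z that the column-integral
  # absorption factor applies even to the strongly absorbed N/O lines
  vox <- 0.1
  g <- make_slab(40, 40, 12, t = 10, voxel = vox)
  beam <- beam_config()
  dets <- detector_ring(g)
  ms <- xrf_maps(g, beam, dets)

  ic <- 20
  S <- vox^2                                # um^2
  m_true <- 0.61 * 1.25 * (S * 1e-8) * 1e-4 # w rho S h in g
  # with the absorption factor included the mass is recovered within 2%
  omega <- sum(vapply(dets, function(d) d$solid_angle_fraction, 0))
  mcphi <- mean(vapply(dets, function(d)
    mean_cosec_phi(d, c((ic - 0.5) * vox, (ic - 0.5) * vox, 0)), 0))
  kfp <- k_fp(1, 1.25, mixture_mu(lovo_fractions(), beam$E0),
              mixture_mu(lovo_fractions(), 277), 1, mcphi)
  m_est <- element_mass(summed_xrf(ms)$C_Kalpha[ic, ic], S, beam$I0,
                        yield_factor("C", "K-alpha", omega),
                        tau_element("C", beam$E0), kfp)
  expect_equal(m_est, m_true, tolerance = 0.02)

  # corrected fractions recover the composition of the detected elements
  masses <- lapply(c(C = "C", N = "N", O = "O"), function(el) {
    ei <- line_energy(el)
    kfp_el <- k_fp(1, 1.25, mixture_mu(lovo_fractions(), beam$E0),
                   mixture_mu(lovo_fractions(), ei), 1, mcphi)
    element_mass(summed_xrf(ms)[[paste0(el, "_Kalpha")]][ic, ic], S, beam$I0,
                 yield_factor(el, "K-alpha", omega),
                 tau_element(el, beam$E0), kfp_el)
  })
  w <- mass_fractions(masses)$fractions
  expect_equal(w$C, 0.61 / 0.94, tolerance = 0.02)
  expect_equal(w$N, 0.17 / 0.94, tolerance = 0.02)
})
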