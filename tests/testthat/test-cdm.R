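opt_ag <- optical_constants(532)
opt_free <- optical_constants(532, substrate = NULL)
opt_pec <- optical_constants(532, substrate = constant_medium(-1e9 + 0i, "pec"))
eps_ag_532 <- permittivity(silver_drude_lorentz(), 532)

test_that("generate_ensemble places non-overlapping resting spheres deterministically", {
  e1 <- generate_ensemble(1, c(20, 25), c(200, 200), 2, seed = 3)
  expect_equal(e1$centers[1, 3], e1$radii[1])   # resting on the substrate
  # bit-identical under the same seed
  a <- generate_ensemble(12, c(20, 25), c(500, 500), 2, seed = 42)
  b <- generate_ensemble(12, c(20, 25), c(500, 500), 2, seed = 42)
  expect_identical(a$centers, b$centers)
  expect_identical(a$radii, b$radii)
  # exhaustive pairwise surface-gap check at the documented scale
  big <- generate_ensemble(50, c(20, 25), c(1000, 1000), 2, seed = 7)
  d <- as.matrix(dist(big$centers))
  rsum <- outer(big$radii, big$radii, "+")
  diag(d) <- Inf
  expect_true(all(d - rsum >= 2 - 1e-9))
})

test_that("infeasible packings and invalid ensembles are rejected", {
  expect_error(generate_ensemble(100, c(20, 25), c(100, 100), 2, seed = 1),
               "packing")
  expect_error(ensemble(matrix(c(0, 0, 25, 10, 0, 25), 2, byrow = TRUE),
                        c(25, 25), optics = opt_ag), "overlap")
  expect_error(ensemble(matrix(c(0, 0, 10), 1), 25, optics = opt_ag),
               "interpenetrate")
})

test_that("external field obeys boundary and polarization geometry", {
  # PEC, normal incidence: tangential field vanishes on the surface
  for (pol in c("TM", "TE")) {
    E <- external_field(c(15, -8, 0), plane_wave(532, 0, pol), opt_pec)
    expect_lt(max(Mod(E[1, 1:2])), 1e-4)
  }
  # TE never has a z-component
  for (ang in c(0, 30, 65)) {
    E <- external_field(rbind(c(0, 0, 10), c(50, 20, 80)),
                        plane_wave(532, ang, "TE"), opt_ag)
    expect_equal(max(Mod(E[, 3])), 0)
  }
  expect_error(external_field(c(0, 0, -5), plane_wave(532, 0, "TM"), opt_ag),
               "z >= 0")
})

test_that("oblique TM external field matches a standalone two-wave sum", {
  pt <- c(37, -12, 25)
  E_pkg <- external_field(pt, plane_wave(532, 65, "TM"), opt_ag)
  E_orc <- two_wave_oracle(pt, 532, 65, "TM", 1, eps_ag_532)
  expect_equal(as.vector(E_pkg), as.vector(E_orc), tolerance = 1e-10)
  E_pkg_te <- external_field(pt, plane_wave(532, 65, "TE"), opt_ag)
  E_orc_te <- two_wave_oracle(pt, 532, 65, "TE", 1, eps_ag_532)
  expect_equal(as.vector(E_pkg_te), as.vector(E_orc_te), tolerance = 1e-10)
})

test_that("solver reproduces the decoupled single-particle closed form", {
  ens <- ensemble(matrix(c(0, 0, 25), 1), 25, optics = opt_free)
  wv <- plane_wave(532, 0, "TM")
  sol <- solve_dipoles(ens, wv)
  alpha <- mie_dipole_polarizability(25, 532, eps_ag_532)
  E <- external_field(c(0, 0, 25), wv, opt_free)
  expect_equal(as.vector(sol$moments), as.vector(alpha * E), tolerance = 1e-12)
  expect_lt(sol$residual_norm, 1e-10)
  # homogeneity: zero driving amplitude gives zero moments
  sol0 <- solve_dipoles(ens, plane_wave(532, 0, "TM", amplitude = 0))
  expect_equal(max(Mod(sol0$moments)), 0)
})

test_that("weak-coupling solution agrees with the two-term Born series", {
  centers <- rbind(c(0, 0, 25), c(2800, 300, 25), c(-500, 3100, 25))
  ens <- ensemble(centers, 25, optics = opt_free)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  alph <- rep(mie_dipole_polarizability(25, 532, eps_ag_532) / 8.8541878128e-21, 3)
  E_in <- external_field(centers, wv, opt_free)
  born <- born_two_term(centers, alph, E_in, opt_free$k0, opt_free$k)
  for (i in 1:3)
    expect_lt(max(Mod(sol$moments_reduced[i, ] - born[[i]])) /
                max(Mod(born[[i]])), 1e-4)
})

test_that("solver matches an independently assembled direct inversion", {
  centers <- rbind(c(0, 0, 22), c(70, 10, 25), c(-40, 60, 21))
  ens <- ensemble(centers, c(22, 25, 21), optics = opt_ag)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  eps0 <- 8.8541878128e-21
  alph <- vapply(ens$radii, function(a)
    mie_dipole_polarizability(a, 532, eps_ag_532) / eps0, complex(1))
  E_in <- external_field(centers, wv, opt_ag)
  p_orc <- cdm_direct_oracle(centers, alph, E_in, opt_ag$k0, opt_ag$k,
                             1, eps_ag_532)
  expect_lt(max(Mod(sol$moments_reduced - p_orc)) / max(Mod(p_orc)), 1e-10)
})

test_that("solution is linear in the driving field and permutation invariant", {
  ens <- generate_ensemble(6, c(20, 25), c(400, 400), 2, seed = 9)
  wv1 <- plane_wave(532, 65, "TM", amplitude = 1)
  wv3 <- plane_wave(532, 65, "TM", amplitude = 3)
  s1 <- solve_dipoles(ens, wv1)
  s3 <- solve_dipoles(ens, wv3)
  expect_lt(max(Mod(s3$moments - 3 * s1$moments)) / max(Mod(s3$moments)), 1e-12)
  # relabeling particles leaves the fields unchanged
  perm <- c(4, 1, 6, 2, 5, 3)
  ens_p <- ensemble(ens$centers[perm, ], ens$radii[perm], optics = ens$optics)
  s_p <- solve_dipoles(ens_p, wv1)
  pts <- plane_grid(60, c(400, 400), 7, 7)
  f1 <- total_field(ens, s1, pts)
  f2 <- total_field(ens_p, s_p, pts)
  expect_equal(f1$intensity, f2$intensity, tolerance = 1e-10)
  # scattered field scales with the drive too
  f3 <- total_field(ens, s3, pts)
  scat1 <- f1$field - external_field(pts, wv1, ens$optics)
  scat3 <- f3$field - external_field(pts, wv3, ens$optics)
  expect_lt(max(Mod(scat3 - 3 * scat1)) / max(Mod(scat3)), 1e-12)
})

test_that("substrate interaction suppresses in-plane and boosts normal response (PEC limit)", {
  mk <- function(opt) ensemble(matrix(c(0, 0, 22.5), 1), 22.5, optics = opt)
  # normal incidence drives an in-plane dipole
  p_pec <- solve_dipoles(mk(opt_pec), plane_wave(532, 0, "TM"))$moments
  p_free <- solve_dipoles(mk(opt_free), plane_wave(532, 0, "TM"))$moments
  expect_lt(max(Mod(p_pec)), max(Mod(p_free)))
  # oblique TM drives a normal component
  p_pec65 <- solve_dipoles(mk(opt_pec), plane_wave(532, 65, "TM"))$moments
  p_free65 <- solve_dipoles(mk(opt_free), plane_wave(532, 65, "TM"))$moments
  expect_gt(Mod(p_pec65[3]), Mod(p_free65[3]))
})

test_that("total field reduces to the external field without scatterers", {
  ens <- ensemble(matrix(c(0, 0, 25), 1), 25, optics = opt_ag)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  sol$moments_reduced[] <- 0
  pts <- plane_grid(80, c(300, 300), 5, 5)
  g <- total_field(ens, sol, pts)
  expect_equal(g$field, external_field(pts, wv, opt_ag))
  expect_equal(g$intensity, rowSums(Mod(g$field)^2))
})

test_that("scattered field decays to the background far from the ensemble", {
  ens <- generate_ensemble(5, c(20, 25), c(300, 300), 2, seed = 5)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  far <- rbind(c(20000, 0, 5320), c(0, 20000, 5320), c(-20000, 5000, 5320))
  g <- total_field(ens, sol, far)
  bg <- background_field(far, wv, ens$optics)
  expect_true(all(abs(g$intensity / bg$intensity - 1) < 0.01))
})

test_that("single vertical dipole field matches the closed-form superposition", {
  ens <- ensemble(matrix(c(0, 0, 20), 1), 20, optics = opt_pec)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  p_bar <- sol$moments_reduced[1, ]
  k0 <- opt_pec$k0
  for (zf in c(120, 300, 700)) {
    pt <- c(0, 0, zf)
    g <- total_field(ens, sol, pt)
    # hand-built: external + direct dipole + image dipole (beta = 1 for PEC)
    e_ext <- as.vector(external_field(pt, wv, opt_pec))
    g_dir <- free_space_green(pt, c(0, 0, 20), opt_pec$k)
    g_img <- free_space_green(pt, c(0, 0, -20), opt_pec$k)
    beta <- image_reflection_factor(1, opt_pec$eps_substrate)
    p_img <- beta * c(-p_bar[1], -p_bar[2], p_bar[3])
    e_hand <- e_ext + k0^2 * as.vector(g_dir %*% p_bar) +
      k0^2 * as.vector(g_img %*% p_img)
    expect_equal(as.vector(g$field), e_hand, tolerance = 1e-10)
  }
})

test_that("points inside particles are masked with a warning", {
  ens <- ensemble(matrix(c(0, 0, 25), 1), 25, optics = opt_ag)
  sol <- solve_dipoles(ens, plane_wave(532, 0, "TM"))
  expect_warning(g <- total_field(ens, sol, rbind(c(0, 0, 25), c(0, 0, 90))),
                 "masked")
  expect_true(is.na(g$intensity[1]))
  expect_false(is.na(g$intensity[2]))
})

test_that("enhancement statistics behave on identity, scaling and null planes", {
  ens <- generate_ensemble(4, c(20, 25), c(300, 300), 2, seed = 2)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  pts <- plane_grid(60, c(300, 300), 9, 9)
  bg <- background_field(pts, wv, ens$optics)
  expect_equal(enhancement_summary(bg, bg)$mean_enhancement, 1)
  expect_equal(enhancement_summary(bg, bg)$max_enhancement, 1)
  g <- total_field(ens, sol, pts)
  e1 <- enhancement_summary(g, bg)
  sol2 <- sol
  sol2$moments_reduced <- 2 * sol$moments_reduced
  g2 <- total_field(ens, sol2, pts)
  e2 <- enhancement_summary(g2, bg)
  expect_gt(e2$max_enhancement, e1$max_enhancement)
  # background null plane (PEC standing wave) is excluded with a warning
  opt_pec16 <- optical_constants(532, substrate = constant_medium(-1e16 + 0i))
  ens_pec <- ensemble(matrix(c(0, 0, 25), 1), 25, optics = opt_pec16)
  sol_pec <- solve_dipoles(ens_pec, plane_wave(532, 0, "TM"))
  z_null <- pi / opt_pec16$k
  pts_null <- rbind(c(150, 0, z_null), c(150, 0, 60))
  g_null <- total_field(ens_pec, sol_pec, pts_null)
  b_null <- background_field(pts_null, plane_wave(532, 0, "TM"), opt_pec16)
  expect_warning(s <- enhancement_summary(g_null, b_null), "excluded")
  expect_equal(s$n_used, 1L)
})

test_that("height profile is reproducible, decaying, and favors 7 over 17 nm", {
  ens <- generate_ensemble(12, c(20, 25), c(400, 400), 2, seed = 21)
  wv <- plane_wave(532, 65, "TM")
  sol <- solve_dipoles(ens, wv)
  rep2 <- field_vs_height(ens, sol, c(10, 10), nx = 9, ny = 9,
                          region = c(400, 400))
  expect_equal(rep2$mean_intensity[1], rep2$mean_intensity[2])
  prof_far <- field_vs_height(ens, sol, c(100, 200, 400, 800), nx = 9, ny = 9,
                              region = c(400, 400))
  expect_true(all(diff(prof_far$mean_scattered) <= 0))
  prof_band <- field_vs_height(ens, sol, c(7, 17), nx = 15, ny = 15,
                               region = c(400, 400))
  expect_gte(prof_band$mean_intensity[1], prof_band$mean_intensity[2])
  expect_error(field_vs_height(ens, sol, c(-1, 5)), "heights")
})

test_that("mirror-symmetric configurations give mirror-symmetric TM intensity maps", {
  centers <- rbind(c(-80, 90, 22), c(-80, -90, 22), c(60, 0, 25),
                   c(150, 140, 23), c(150, -140, 23))
  ens <- ensemble(centers, c(22, 22, 25, 23, 23), optics = opt_ag)
  wv <- plane_wave(532, 65, "TM")   # plane of incidence x-z
  sol <- solve_dipoles(ens, wv)
  y <- seq(-150, 150, by = 50)
  pts_pos <- cbind(40, y, 70)
  pts_neg <- cbind(40, -y, 70)
  g_pos <- total_field(ens, sol, pts_pos)
  g_neg <- total_field(ens, sol, pts_neg)
  expect_equal(g_pos$intensity, g_neg$intensity, tolerance = 1e-10)
})
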