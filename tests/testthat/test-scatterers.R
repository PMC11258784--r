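# Dipole models, Mie theory and the far-field interface correction.

test_that("quasistatic polarizability matches the Clausius-Mossotti form", {
  expect_equal(polarizability_sphere(2, 1.33^2, 1.33^2), 0 + 0i)
  a <- 25
  al <- polarizability_sphere(50, 1.59^2, 1.33^2)
  cm <- (1.59^2 - 1.33^2) / (1.59^2 + 2 * 1.33^2)      # 0.12516
  expect_equal(al / a^3, cm + 0i, tolerance = 1e-12)
  expect_equal(Re(cm), 0.1252, tolerance = 1e-3)
  eps_au <- material_db("Au")$permittivity(520)
  al_au <- polarizability_sphere(50, eps_au, 1.33^2)
  expect_equal(al_au, a^3 * (eps_au - 1.33^2) / (eps_au + 2 * 1.33^2),
               tolerance = 1e-12)
  expect_error(polarizability_sphere(50, -2 * 1.33^2, 1.33^2), "resonance")
  expect_error(polarizability_sphere(0, 2, 1), "positive")
})

test_that("Mie series agrees with an independently coded oracle", {
  for (eps_p in list(1.59^2, material_db("Au")$permittivity(520))) {
    s1 <- mie_cross_sections(50, eps_p, 1.33^2, 520)$sigma_sca
    s2 <- mie_oracle_sigma_sca(50, eps_p, 1.33^2, 520)
    expect_equal(s1, s2, tolerance = 1e-6)
  }
})

test_that("lossless spheres conserve energy and small spheres are dipolar", {
  cs <- mie_cross_sections(50, 1.59^2, 1.33^2, 520)
  expect_equal(cs$sigma_ext, cs$sigma_sca, tolerance = 1e-8)
  # d <= 20 nm: within 1% of the (radiation-corrected) dipole cross section
  al <- polarizability_sphere(20, 1.59^2, 1.33^2, radiative_correction = TRUE,
                              wavelength = 520)
  k <- 2 * pi * 1.33 / 520
  sig_dip <- 8 * pi / 3 * k^4 * Mod(al)^2
  expect_equal(mie_cross_sections(20, 1.59^2, 1.33^2, 520)$sigma_sca, sig_dip,
               tolerance = 0.01)
  # far-field pattern converges to the dipole pattern
  pw <- plane_wave(520, theta = 0, polarization = "TE", direction = "up")
  g <- direction_grid(20, 21)
  fm <- mie_farfield(20, 1.59^2, 1.33^2, pw, grid = g)
  fd <- dipole_farfield_free(al * make_planewave(pw, 1.33)$eps[1, ], k, g,
                             k0 = 2 * pi / 520)
  expect_lt(max(Mod(fm$E - fd$E)) / max(Mod(fd$E)), 0.01)
  # integrated far field equals the series cross section
  expect_equal(scattering_cross_section(mie_farfield(50, 1.59^2, 1.33^2, pw,
                                                     grid = direction_grid(30, 31))),
               cs$sigma_sca, tolerance = 1e-6)
})

test_that("dip1 equals the free dipole for matched media", {
  st <- matched_stack(1.33)
  wave <- plane_wave(520, theta = 0, polarization = "TM", direction = "up")
  drv <- incident_field(st, wave, "above")
  dip <- dipole_scatterer(c(0, 0, 40), 1000 + 200i, 1.33^2)
  g <- direction_grid(24, 25)
  f1 <- dipole_farfield_dip1(dip, drv, st, 520, g)
  p <- iscatsim:::induced_moment(dip, drv)
  ff <- dipole_farfield_free(p, 2 * pi * 1.33 / 520, g, origin = c(0, 0, 40),
                             k0 = 2 * pi / 520)
  ff <- shift_field(ff, c(0, 0, -40))
  expect_lt(max(Mod(f1$E - ff$E)) / max(Mod(ff$E)), 1e-10)
})

test_that("dip1 upper pattern is the exact two-ray interference", {
  gw <- glass_water()
  wave <- plane_wave(520, theta = 0, polarization = "TM", direction = "up")
  drv <- incident_field(gw, wave, "above")
  z0 <- 5 * 520                                  # large height: many lobes
  g <- direction_grid(80, 17)
  k1 <- 2 * pi * 1.33 / 520
  # unit horizontal (y) dipole moment via a constant drive and alpha = 1
  drv_y <- function(pts) {
    n <- nrow(matrix(pts, ncol = 3))
    list(E = matrix(rep(c(0, 1, 0), each = n), ncol = 3), H = matrix(0i, n, 3))
  }
  f1 <- dipole_farfield_dip1(dipole_scatterer(c(0, 0, z0), 1, 1.33^2),
                             drv_y, gw, 520, g)
  nodes <- iscatsim:::grid_nodes(g)
  sel <- nodes$dir[, 3] > 0 & abs(nodes$phi) < 1e-9   # phi = 0: pure s for p || y
  ct <- nodes$dir[sel, 3]
  rs <- vapply(acos(ct) * 180 / pi, function(t)
    fresnel(gw, t, "TE", 520, from = "top")$r, complex(1))
  I_pred <- Mod(1 + rs * exp(2i * k1 * ct * z0))^2 * (k1^2)^2
  I_have <- rowSums(Mod(f1$E[sel, ])^2)
  expect_lt(max(abs(I_have - I_pred)) / max(I_pred), 1e-9)
})

test_that("vertical and horizontal dipoles radiate correctly into the substrate", {
  # oracle: transmitted far field assembled by hand from the angular-spectrum
  # formula at a few directions (independent arithmetic, no package calls)
  gw <- glass_water()
  n1 <- 1.33; n2 <- 1.5; k0 <- 2 * pi / 520
  z0 <- 35
  drv_const <- function(E0) function(pts) {
    n <- nrow(matrix(pts, ncol = 3))
    list(E = matrix(rep(E0, each = n), ncol = 3), H = matrix(0i, n, 3))
  }
  g <- direction_grid(60, 13)
  for (orient in list(c(0, 0, 1), c(1, 0, 0))) {
    f <- dipole_farfield_dip1(dipole_scatterer(c(0, 0, z0), 1, n1^2),
                              drv_const(orient), gw, 520, g)
    nodes <- iscatsim:::grid_nodes(f$grid)
    j <- which(nodes$dir[, 3] < 0 & abs(nodes$phi) < 1e-9)[3]
    th2 <- pi - nodes$theta[j]                   # angle from -z
    s1 <- n2 * sin(th2) / n1
    c1 <- sqrt(1 - s1^2 + 0i); c1 <- ifelse(Im(c1) < 0, -c1, c1)
    src <- c(s1, 0, -c1)
    Ffree <- (k0 * n1)^2 * (orient - src * sum(src * orient))
    shat <- c(0, 1, 0)
    phat_src <- c(shat[2] * src[3], -shat[1] * src[3],
                  shat[1] * src[2] - shat[2] * src[1])
    dout <- nodes$dir[j, ]
    phat_out <- c(shat[2] * dout[3], -shat[1] * dout[3],
                  shat[1] * dout[2] - shat[2] * dout[1])
    kx <- n2 * sin(th2)
    cs <- iscatsim:::snell_cos(c(n1, n2), kx)
    fcs <- iscatsim:::fresnel_interface(n1, cs[1], n2, cs[2], "TE")
    fcp <- iscatsim:::fresnel_interface(n1, cs[1], n2, cs[2], "TM")
    Fpred <- (n2 * cos(th2)) / (n1 * c1) * exp(1i * k0 * n1 * c1 * z0) *
      (fcs$t * sum(Ffree * shat) * shat + fcp$t * sum(Ffree * phat_src) * phat_out)
    expect_lt(max(Mod(f$E[j, ] - Fpred)), 1e-9 * max(Mod(f$E)))
  }
})

test_that("interface_correct is the identity for matched media and equals dip1", {
  st <- matched_stack(1.33)
  k1 <- 2 * pi * 1.33 / 520
  g <- direction_grid(30, 31)
  p <- c(1, 2i, 0.5)
  ff <- dipole_farfield_free(p, k1, g, origin = c(0, 0, 60), k0 = 2 * pi / 520)
  fc <- interface_correct(ff, st, 520)
  ff0 <- shift_field(ff, c(0, 0, -60))
  expect_lt(max(Mod(fc$E - ff0$E)) / max(Mod(ff0$E)), 1e-10)
  # and against dip1 on a real interface (model equivalence by construction)
  gw <- glass_water()
  wave <- plane_wave(520, theta = -20, polarization = "TM", direction = "up")
  drv <- incident_field(gw, wave, "above")
  al <- polarizability_sphere(30, material_db("Au")$permittivity(520), 1.33^2,
                              radiative_correction = TRUE, wavelength = 520)
  dip <- dipole_scatterer(c(0, 0, 20), al, 1.33^2)
  f1 <- dipole_farfield_dip1(dip, drv, gw, 520, g)
  f2 <- dipole_farfield_dip2(dip, drv, gw, 520, g)
  expect_lt(max(Mod(f1$E - f2$E)) / max(Mod(f1$E)), 1e-6)
  expect_error(interface_correct(shift_field(ff, c(0, 0, -100)), gw, 520),
               "above")
})

test_that("linearity: doubling the drive doubles the scattered fields", {
  gw <- glass_water()
  g <- direction_grid(16, 17)
  al <- polarizability_sphere(30, 1.59^2, 1.33^2)
  dip <- dipole_scatterer(c(0, 0, 20), al, 1.33^2)
  f1 <- dipole_farfield_dip2(dip, incident_field(gw,
        plane_wave(520, theta = 10, polarization = "TE", direction = "up"),
        "above"), gw, 520, g)
  f2 <- dipole_farfield_dip2(dip, incident_field(gw,
        plane_wave(520, theta = 10, polarization = "TE", direction = "up",
                   amplitude = 2), "above"), gw, 520, g)
  expect_lt(max(Mod(f2$E - 2 * f1$E)), 1e-12 * max(Mod(f1$E)))
})
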