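# Boundary-element solver: validation against Mie theory and physical
# invariants.  Meshes are kept small; the acceptance suite runs the larger
# convergence and dimer configurations.

pw_te <- plane_wave(520, theta = 0, polarization = "TE", direction = "up")
drv_hom <- function(n_host = 1.33, pw = pw_te) pwd_field(make_planewave(pw, n_host))

test_that("sphere solution matches Mie in amplitude and phase", {
  mesh <- icosphere(50, frequency = 3)
  sol <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  g <- direction_grid(20, 21)
  ff <- bem_farfield(sol, g)
  ffm <- mie_farfield(50, 1.59^2, 1.33^2, pw_te, grid = g)
  expect_equal(scattering_cross_section(ff), scattering_cross_section(ffm),
               tolerance = 0.02)
  # complex amplitudes agree pointwise (pins sign and phase conventions)
  expect_lt(max(Mod(ff$E - ffm$E)) / max(Mod(ffm$E)), 0.05)
})

test_that("gold sphere (complex permittivity) matches Mie", {
  eps_au <- material_db("Au")$permittivity(520)
  mesh <- icosphere(50, frequency = 3)
  sol <- bem_solve(mesh, eps_au, 1.33^2, drv_hom(), 520)
  ff <- bem_farfield(sol, direction_grid(20, 21))
  expect_equal(scattering_cross_section(ff),
               mie_cross_sections(50, eps_au, 1.33^2, 520)$sigma_sca,
               tolerance = 0.02)
})

test_that("index-matched particles scatter at the discretization floor", {
  mesh <- icosphere(50, frequency = 3)
  sol <- bem_solve(mesh, 1.33^2, 1.33^2, drv_hom(), 520)
  ff <- bem_farfield(sol, direction_grid(16, 17))
  ps <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  fps <- bem_farfield(ps, direction_grid(16, 17))
  expect_lt(radiated_power(ff) / radiated_power(fps), 1e-5)
})

test_that("linearity: doubling the incident amplitude doubles the currents", {
  mesh <- icosphere(40, frequency = 2)
  pw2 <- plane_wave(520, theta = 0, polarization = "TE", direction = "up",
                    amplitude = 2)
  s1 <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  s2 <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(pw = pw2), 520)
  expect_lt(max(Mod(s2$xJ - 2 * s1$xJ)) / max(Mod(s1$xJ)), 1e-10)
  expect_lt(max(Mod(s2$xM - 2 * s1$xM)) / max(Mod(s1$xM)), 1e-10)
})

test_that("optical theorem holds for a lossless sphere", {
  mesh <- icosphere(50, frequency = 4)
  sol <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  ff <- bem_farfield(sol, direction_grid(24, 25))
  sig_sca <- scattering_cross_section(ff)
  # forward amplitude: sigma_ext = (4 pi / k) Im(F(k0_hat) . e_hat*)
  amp <- attr(ff, "amp_fun")(rbind(c(0, 0, 1) + 0i))
  sig_ext <- 4 * pi / sol$k1 * Im(amp[1, 2])    # TE drive along +y
  expect_equal(sig_ext, sig_sca, tolerance = 0.01)
})

test_that("far field is the asymptotic limit of the near-field evaluation", {
  mesh <- icosphere(50, frequency = 3)
  sol <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  ff <- bem_farfield(sol, direction_grid(30, 31))
  d <- c(0.48, -0.6, sqrt(1 - 0.48^2 - 0.36))
  r <- 1e3 * 520
  En <- bem_nearfield(sol, rbind(d * r))
  Ef <- attr(ff, "amp_fun")(rbind(d + 0i)) * exp(1i * sol$k1 * r) / r
  expect_lt(max(Mod(En - Ef)) / max(Mod(Ef)), 1e-3)
})

test_that("near field outside a sphere matches Mie via the dipole limit", {
  # small sphere: scattered near field ~ radiating dipole field of moment
  # alpha E0; checked at a few exterior points
  mesh <- icosphere(20, frequency = 3)
  sol <- bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520)
  al <- polarizability_sphere(20, 1.59^2, 1.33^2, radiative_correction = TRUE,
                              wavelength = 520)
  k <- sol$k1
  pts <- rbind(c(40, 0, 0), c(0, 0, -45), c(20, 25, 10))
  En <- bem_nearfield(sol, pts)
  p <- al * c(0, 1, 0)
  rr <- sqrt(rowSums(pts^2)); rh <- pts / rr
  rp <- drop(rh %*% p)
  Ed <- k^2 * (matrix(p, 3, 3, byrow = TRUE) - rh * rp) * exp(1i * k * rr) / rr +
    (3 * rh * rp - matrix(p, 3, 3, byrow = TRUE)) *
      (1 / rr^3 - 1i * k / rr^2) * exp(1i * k * rr)
  expect_lt(max(Mod(En - Ed)) / max(Mod(Ed)), 0.05)
  expect_error(bem_nearfield(sol, rbind(c(10.05, 0, 0))), "close")
})

test_that("surface charge is neutral, dipolar for ps, phase-shifted for gold", {
  gw <- glass_water()
  wave <- plane_wave(520, theta = -20, polarization = "TM", direction = "up")
  drv <- incident_field(gw, wave, "above")
  mesh <- icosphere(50, frequency = 3, center = c(0, 0, 30))
  cen <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
          mesh$vertices[mesh$faces[, 3], ]) / 3
  sol_ps <- bem_solve(mesh, 1.59^2, 1.33^2, drv, 520)
  sig_ps <- surface_charge(sol_ps)
  expect_lt(abs(sum(sig_ps * mesh$areas)) / sum(Mod(sig_ps) * mesh$areas), 1e-3)
  # dipolar +- pattern aligned with the drive polarization: complex
  # correlation between sigma and the coordinate along the driving field
  E0 <- drv(rbind(c(0, 0, 30)))$E[1, ]
  u <- Re(E0) / sqrt(sum(Re(E0)^2))
  proj <- drop(sweep(cen, 2, c(0, 0, 30)) %*% u)
  rho <- Mod(sum(Conj(sig_ps) * proj)) /
    sqrt(sum(Mod(sig_ps)^2) * sum(proj^2))
  expect_gt(rho, 0.9)
  phase_at <- function(sig) Arg(sum(sig * (cen[, 1] > 15)))
  sol_au <- bem_solve(mesh, material_db("Au")$permittivity(520), 1.33^2, drv, 520)
  dphi <- (phase_at(surface_charge(sol_au)) - phase_at(sig_ps)) %% (2 * pi)
  if (dphi > pi) dphi <- 2 * pi - dphi
  expect_gt(dphi * 180 / pi, 45)              # near-resonant plasmon delay
  expect_lt(dphi * 180 / pi, 135)
})

test_that("reciprocity holds on the cube", {
  mesh <- cube_mesh(80, divisions = 3)
  k <- 2 * pi * 1.33 / 520
  d1 <- c(0, 0, 1); e1 <- c(1, 0, 0)
  d2 <- c(sin(0.6), 0.3, NA); d2[3] <- sqrt(1 - sum(d2[1:2]^2)); e2 <- c(d2[3], 0, -d2[1])
  e2 <- e2 / sqrt(sum(e2^2))
  drv1 <- pwd_field(pw_decomposition(rbind(d1), rbind(e1), k = k, k0 = 2 * pi / 520))
  drv2 <- pwd_field(pw_decomposition(rbind(d2), rbind(e2), k = k, k0 = 2 * pi / 520))
  s1 <- bem_solve(mesh, 1.59^2, 1.33^2, drv1, 520)
  s2 <- bem_solve(mesh, 1.59^2, 1.33^2, drv2, 520)
  # amplitude for observation along -d2 projected on e2 under drive (d1, e1)
  # equals observation along -d1 projected on e1 under drive (d2, e2)
  a12 <- sum(attr(bem_farfield(s1), "amp_fun")(rbind(-d2 + 0i))[1, ] * e2)
  a21 <- sum(attr(bem_farfield(s2), "amp_fun")(rbind(-d1 + 0i))[1, ] * e1)
  expect_equal(a12, a21, tolerance = 0.02)
})

test_that("coated spheres reproduce the homogeneous limits against Mie", {
  mo <- icosphere(60, frequency = 3)
  mi <- icosphere(40, frequency = 3)
  drv <- drv_hom()
  solA <- bem_solve_coated(mo, mi, eps_core = 1.59^2, eps_shell = 1.33^2,
                           eps_host = 1.33^2, drive = drv, wavelength = 520)
  expect_equal(scattering_cross_section(bem_farfield(solA, direction_grid(16, 17))),
               mie_cross_sections(40, 1.59^2, 1.33^2, 520)$sigma_sca,
               tolerance = 0.02)
  solB <- bem_solve_coated(mo, mi, eps_core = 1.59^2, eps_shell = 1.59^2,
                           eps_host = 1.33^2, drive = drv, wavelength = 520)
  expect_equal(scattering_cross_section(bem_farfield(solB, direction_grid(16, 17))),
               mie_cross_sections(60, 1.59^2, 1.33^2, 520)$sigma_sca,
               tolerance = 0.02)
})

test_that("solver rejects open meshes and over-budget meshes", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(V, rbind(c(1, 2, 3))), "closed")
  mesh <- icosphere(50, frequency = 3)
  expect_error(bem_solve(mesh, 1.59^2, 1.33^2, drv_hom(), 520,
                         max_elements = 100), "cap")
  expect_warning(bem_solve(icosphere(400, frequency = 2), 1.59^2, 1.33^2,
                           drv_hom(), 520), "refine")
})

test_that("analytic singular integrals match brute-force quadrature", {
  V <- rbind(c(0, 0, 0), c(30, 0, 0), c(8, 25, 0))
  F <- rbind(c(1, 2, 3))
  brute <- function(x, n = 120) {
    pts <- NULL
    for (i in 0:(n - 1)) for (j in 0:(n - 1 - i)) {
      pts <- rbind(pts,
        ((i + 1/3) * V[2, ] + (j + 1/3) * V[3, ] + (n - i - j - 2/3) * V[1, ]) / n,
        if (j < n - 1 - i)
          ((i + 2/3) * V[2, ] + (j + 2/3) * V[3, ] + (n - i - j - 4/3) * V[1, ]) / n)
    }
    a <- V[2, ] - V[1, ]; b <- V[3, ] - V[1, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    w <- 0.5 * sqrt(sum(cr^2)) / nrow(pts)
    d <- sweep(-pts, 2, -x); R <- sqrt(rowSums(d^2))
    list(I0 = w * sum(1 / R), Iv = w * colSums(pts / R),
         gI0 = w * colSums(-d / R^3))
  }
  for (x in list(c(10, 8, 17), c(10, 8, -9), c(35, 10, 2))) {
    s <- iscatsim:::static_integrals_debug(V, F - 1L, x)
    b <- brute(x)
    expect_equal(s$I0, b$I0, tolerance = 1e-3)
    expect_equal(s$Iv, b$Iv, tolerance = 1e-3)
    expect_equal(s$gI0, b$gI0, tolerance = 1e-3)
  }
  # graded outer rules integrate smooth and edge-log integrands correctly
  for (mode in 0:1) {
    g <- iscatsim:::graded_outer_debug(V, mode)
    expect_equal(sum(g$w), 0.5 * 30 * 25, tolerance = 1e-12)
    expect_equal(colSums(as.vector(g$w) * g$pts) / sum(g$w), colMeans(V),
                 tolerance = 1e-12)
  }
  g0 <- iscatsim:::graded_outer_debug(V, 0)
  n <- 4000; ys <- ((1:n) - 0.5) / n * 25
  ref <- sum(((30 - (22 / 25) * ys) - (8 / 25) * ys) * log(ys)) * 25 / n
  expect_equal(sum(as.vector(g0$w) * log(pmax(g0$pts[, 2], 1e-300))), ref,
               tolerance = 1e-3)
})
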