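# Richards-Wolf imaging: magnification, energy conservation, the Bessel
# route, back-focal-plane transforms and focused excitation.

test_that("aplanatic magnification follows (n/n')(f'/f)", {
  expect_equal(magnification(optical_train(0.9, n = 1.2, n_prime = 1.2,
                                           f = 3, f_prime = 3)), 1)
  expect_equal(magnification(optical_train(1.3, n = 1.5, n_prime = 1.0,
                                           f = 2, f_prime = 200)), 150)
  expect_error(optical_train(1.42, n = 1.33), "exceeds")
})

test_that("unit plane waves image to unit flat intensity; tilts give the sine-condition ramp", {
  tr <- std_train()
  gi <- image_grid(2000, 21)
  k <- 2 * pi * 1.5 / 520
  pw <- pw_decomposition(rbind(c(0, 0, 1)), rbind(c(1, 0, 0)), k = k,
                         k0 = 2 * pi / 520)
  ci <- image_pwd(pw, tr, gi)
  expect_lt(max(abs(ci$intensity - 1)), 1e-8)
  th0 <- 25 * pi / 180
  pwt <- pw_decomposition(rbind(c(sin(th0), 0, cos(th0))),
                          rbind(c(cos(th0), 0, -sin(th0))), k = k,
                          k0 = 2 * pi / 520)
  ct <- image_pwd(pwt, tr, gi)
  q <- Arg(ct$E[2, 1] / ct$E[1, 1]) / (gi$x[2] - gi$x[1])
  expect_equal(q, 2 * pi / 520 * 1.5 * sin(th0), tolerance = 1e-9)
  # components beyond the aperture are dropped with a warning
  pwo <- pw_decomposition(rbind(c(sin(1.2), 0, cos(1.2))),
                          rbind(c(cos(1.2), 0, -sin(1.2))), k = k,
                          k0 = 2 * pi / 520)
  expect_warning(image_pwd(pwo, tr, gi), "dropped")
})

test_that("imaging conserves energy and is linear; on-axis images are symmetric", {
  tr <- std_train()
  f <- dipole_farfield_free(c(1, 0.5, 0.2), k = 2 * pi * 1.5 / 520,
                            grid = direction_grid(50, 51), k0 = 2 * pi / 520)
  gi <- image_grid(8000, 151)
  cam <- image_farfield_bessel(f, tr, gi)
  expect_equal(image_power(cam) / collected_power(f, tr), 1, tolerance = 0.01)
  # linearity / superposition
  f2 <- dipole_farfield_free(c(0, 1i, 0.4), k = 2 * pi * 1.5 / 520,
                             grid = direction_grid(50, 51), k0 = 2 * pi / 520)
  fsum <- f; fsum$E <- f$E + f2$E
  gi2 <- image_grid(2000, 21)
  Esum <- image_farfield_bessel(fsum, tr, gi2)$E
  expect_lt(max(Mod(Esum - image_farfield_bessel(f, tr, gi2)$E -
                    image_farfield_bessel(f2, tr, gi2)$E)),
            1e-12 * max(Mod(Esum)))
  # symmetric emitter at focus: intensity even under point reflection
  fz <- dipole_farfield_free(c(0, 0, 1), k = 2 * pi * 1.5 / 520,
                             grid = direction_grid(40, 41), k0 = 2 * pi / 520)
  cz <- image_farfield_bessel(fz, tr, image_grid(3000, 31))
  expect_lt(max(abs(cz$intensity - cz$intensity[31:1, 31:1])),
            1e-10 * max(cz$intensity))
})

test_that("a displaced emitter moves by the magnification in true image coordinates", {
  tr <- std_train()
  k <- 2 * pi * 1.5 / 520
  f <- dipole_farfield_free(c(1, 0, 0), k, direction_grid(50, 51),
                            k0 = 2 * pi / 520)
  delta <- c(400, -200, 0)                     # multiples of the pixel pitch
  ftr <- f
  ftr$E <- ftr$E * exp(-1i * k * drop(field_directions(f) %*% delta))
  gi <- image_grid(4000, 81)                   # 50 nm object-referred pixels
  c0 <- image_farfield_bessel(f, tr, gi)
  c1 <- image_farfield_bessel(ftr, tr, gi)
  i0 <- which.max(c0$intensity); i1 <- which.max(c1$intensity)
  xy <- function(i) c(gi$x[(i - 1) %% 81 + 1], gi$y[(i - 1) %/% 81 + 1])
  expect_equal(xy(i1) - xy(i0), delta[1:2], tolerance = 1e-9)
})

test_that("Bessel-accelerated imaging equals the direct quadrature", {
  tr <- std_train()
  f51 <- dipole_farfield_free(c(1, 0.3, 0.1), k = 2 * pi * 1.5 / 520,
                              grid = direction_grid(50, 51), k0 = 2 * pi / 520)
  f201 <- dipole_farfield_free(c(1, 0.3, 0.1), k = 2 * pi * 1.5 / 520,
                               grid = direction_grid(50, 201), k0 = 2 * pi / 520)
  gi <- image_grid(3000, 41)
  cb <- image_farfield_bessel(f51, tr, gi)
  cd <- image_farfield(f201, tr, gi)
  expect_lt(max(Mod(cb$E - cd$E)) / max(Mod(cd$E)), 1e-3)
  # near-axisymmetric fields need only low azimuthal orders
  cb2 <- image_farfield_bessel(f51, tr, gi, m_max = 2)
  expect_lt(max(Mod(cb2$E - cb$E)) / max(Mod(cb$E)), 1e-8)
  expect_error(image_farfield_bessel(f51, tr, gi, m_max = 40), "Nyquist")
})

test_that("a single azimuthal order images to the analytic Bessel kernel", {
  tr <- std_train(NA_ = 0.75)
  g <- direction_grid(50, 51)
  nodes <- iscatsim:::grid_nodes(g)
  m <- 2
  # concentrate the far field on one theta ring inside the cone, with the
  # back-focal-plane Cartesian x-component carrying e^{i m phi}
  ring_th <- nodes$theta[abs(nodes$theta - 0.35) ==
                         min(abs(nodes$theta - 0.35))][1]
  sel <- abs(nodes$theta - ring_th) < 1e-12
  tht <- cbind(cos(nodes$theta) * cos(nodes$phi),
               cos(nodes$theta) * sin(nodes$phi), -sin(nodes$theta))
  pht <- cbind(-sin(nodes$phi), cos(nodes$phi), 0)
  E <- matrix(0i, nrow(nodes$dir), 3)
  amp <- exp(1i * m * nodes$phi[sel])
  E[sel, ] <- amp * (cos(nodes$phi[sel]) * tht[sel, ] -
                     sin(nodes$phi[sel]) * pht[sel, ])
  f <- farfield(E, k = 2 * pi * 1.5 / 520, grid = g, k0 = 2 * pi / 520)
  gi <- image_grid(4000, 41)
  cam <- image_farfield_bessel(f, tr, gi)
  pix <- expand.grid(x = gi$x, y = gi$y)
  rho <- sqrt(pix$x^2 + pix$y^2)
  pred <- besselJ(2 * pi / 520 * 1.5 * sin(ring_th) * rho, m)
  ratio <- Mod(cam$E[, 1]) / max(Mod(cam$E[, 1]))
  predn <- abs(pred) / max(abs(pred))
  expect_lt(max(abs(ratio - predn)), 1e-6)
})

test_that("back-focal-plane Jones elements act as optical components", {
  # quarter-wave plate at 45 deg applied twice acts as a half-wave plate
  qwp <- bfp_waveplate(pi / 2, 45)
  J2 <- qwp(0, 0) %*% qwp(0, 0)
  out <- J2 %*% c(1, 0)
  expect_lt(Mod(out[1]), 1e-12)
  expect_equal(Mod(out[2]), 1, tolerance = 1e-12)
  # attenuator scales the reference intensity by t^2 exactly
  tr_att <- std_train(bfp = bfp_attenuator(0.3))
  tr0 <- std_train()
  k <- 2 * pi * 1.5 / 520
  pw <- pw_decomposition(rbind(c(0, 0, 1)), rbind(c(1, 0, 0)), k = k,
                         k0 = 2 * pi / 520)
  gi <- image_grid(1000, 11)
  expect_equal(image_pwd(pw, tr_att, gi)$intensity,
               0.09 * image_pwd(pw, tr0, gi)$intensity, tolerance = 1e-12)
  # a zero-radius block is the identity; a central block removes the beam
  tr_b0 <- std_train(bfp = bfp_block(0))
  expect_equal(image_pwd(pw, tr_b0, gi)$E, image_pwd(pw, tr0, gi)$E,
               tolerance = 1e-12)
  tr_blk <- std_train(bfp = bfp_block(10))
  expect_lt(sum(image_pwd(pw, tr_blk, gi)$intensity), 1e-10)
})

test_that("focused beams have diffraction-limited spots with vectorial symmetry", {
  tr <- optical_train(NA_ = 1.3, n = 1.5, n_prime = 1, mag = 100)
  beam <- focus_beam(tr, c(1, 0), 520, n_theta = 24, n_phi = 28)
  y <- seq(-600, 600, by = 5)
  Ey0 <- pwd_field(beam)(cbind(0, y, 0))$E
  I <- rowSums(Mod(Ey0)^2)
  fwhm <- diff(range(y[I > max(I) / 2]))
  expect_lt(abs(fwhm - 520 / (2 * 1.3)) / (520 / (2 * 1.3)), 0.2)
  # symmetric under y -> -y for x-polarized fill
  pts <- cbind(100, c(-200, 200), 50)
  Ey <- pwd_field(beam)(pts)$E
  expect_equal(rowSums(Mod(Ey)^2)[1], rowSums(Mod(Ey)^2)[2], tolerance = 1e-6)
  # NA -> 0: field approaches a plane wave over the focal region
  trs <- optical_train(NA_ = 0.02, n = 1.5, n_prime = 1, mag = 100)
  bs <- focus_beam(trs, c(1, 0), 520, n_theta = 8, n_phi = 8)
  Ez <- pwd_field(bs)(cbind(c(0, 500), 0, 0))$E
  expect_equal(Mod(Ez[1, 1]), Mod(Ez[2, 1]), tolerance = 1e-3)
})
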