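# Full image assembly: iSCAT/COBRI/dark-field, contrast maps, focus
# estimation, Brewster tuning, partial coherence and scanning.

test_that("the camera is the interference of reference and scattered images", {
  sim <- simulate_image(au55_cfg(), z_foc = 400)
  I <- matrix(rowSums(Mod(sim$ref$E + sim$sca$E)^2),
              length(sim$camera$x), length(sim$camera$y))
  expect_lt(max(abs(sim$camera$intensity - I)), 1e-12 * max(I))
  # contrast-map identity: camera - |ref|^2 = 2|Er||Es|cos(phi) + |Es|^2
  ctr <- iscat_contrast(sim$camera, sim$ref)
  cross <- matrix(rowSums(sim$ref$E * Conj(sim$sca$E)), 31, 31)
  rhs <- 2 * Mod(cross) * cos(ctr$phase) + sim$sca$intensity
  expect_lt(max(abs(ctr$values - rhs)), 1e-10 * max(abs(ctr$values)))
})

test_that("an empty sample reproduces the reference exactly", {
  cfg <- au55_cfg(); cfg$scatterer <- NULL
  sim <- simulate_image(cfg, 200)
  expect_identical(sim$camera$intensity, sim$ref$intensity)
})

test_that("modality contracts: direction checks, COBRI reference, dark-field", {
  expect_error(microscope_config("cobri", glass_air(),
    plane_wave(517, theta = 0, direction = "up"), std_train()), "down")
  cfgc <- microscope_config("cobri", glass_air(),
    plane_wave(517, theta = 0, polarization = "TM", direction = "down"),
    std_train(),
    scatterer = list(engine = "mie", diameter = 55, material = "Au",
                     position = c(0, 0, 32.5)),
    fov = 3900, npix = 21, n_theta = 30, n_phi = 31)
  simc <- simulate_image(cfgc, 0)
  ft <- fresnel(glass_air(), 0, "TM", 517, from = "top")
  expect_equal(mean(simc$ref$intensity), Mod(ft$t)^2, tolerance = 1e-6)
  # dark-field: no block -> reject; block -> camera = |sca|^2
  cfgd <- au55_cfg(); cfgd$modality <- "darkfield"; cfgd$npix <- 21
  expect_error(simulate_image(cfgd, 0), "block")
  cfgd$train <- std_train(bfp = bfp_block(theta_max_deg = 20))
  simd <- simulate_image(cfgd, 0)
  expect_equal(simd$camera$intensity, simd$sca$intensity, tolerance = 1e-12)
  expect_error(iscat_contrast(simd$camera, simd$ref, normalized = TRUE), "dark")
})

test_that("Michelson contrast is bounded and handles edge cases", {
  expect_equal(michelson_contrast(matrix(3, 5, 5)), 0)
  expect_equal(michelson_contrast(matrix(c(0, 1, 2, 3), 2)), 1)
  expect_error(michelson_contrast(matrix(0, 2, 2)), "contrast")
  expect_error(michelson_contrast(matrix(-1, 2, 2)), "non-negative")
  sim <- simulate_image(au55_cfg(npix = 21), 300)
  m <- michelson_contrast(sim$camera)
  expect_gte(m, 0); expect_lte(m, 1)
})

test_that("the iPSF is ring-symmetric in focus and flips phase with defocus", {
  cfg <- microscope_config("iscat", glass_water(),
    plane_wave(520, theta = 0, polarization = "TM", direction = "up"),
    std_train(),
    scatterer = list(engine = "dipole", diameter = 20, material = "ps",
                     position = c(0, 0, 10)),
    fov = 3000, npix = 41, n_theta = 40, n_phi = 41)
  psf <- ipsf(cfg, 0)
  expect_lt(max(abs(psf$values - psf$values[41:1, 41:1])),
            1e-8 * max(abs(psf$values)))
  # defocus sign flips the radial phase progression
  slope <- function(z) {
    ph <- ipsf(cfg, z)$phase[21:41, 21]        # along +x through center
    mean(diff(ph[1:5]))                        # inner rings, before any wrap
  }
  expect_lt(slope(600) * slope(-600), 0)
  expect_error(ipsf(au55_cfg()), "dipole")
})

test_that("Mie and dipole engines agree for small particles", {
  mk <- function(engine) microscope_config("iscat", glass_water(),
    plane_wave(520, theta = 0, polarization = "TM", direction = "up"),
    std_train(),
    scatterer = list(engine = engine, diameter = 20, material = "ps",
                     position = c(0, 0, 10)),
    fov = 2000, npix = 21, n_theta = 40, n_phi = 41)
  cm <- simulate_image(mk("mie"), 300)
  cd <- simulate_image(mk("dipole"), 300)
  vm <- cm$camera$intensity - cm$ref$intensity
  vd <- cd$camera$intensity - cd$ref$intensity
  expect_lt(max(abs(vm - vd)) / max(abs(vd)), 0.02)
})

test_that("off-axis illumination breaks the mirror symmetry of the contrast", {
  v14 <- iscat_contrast(simulate_image(au55_cfg(14, 21), 500)$camera,
                        simulate_image(au55_cfg(14, 21), 500)$ref)$values
  cfg0 <- au55_cfg(0, 21)
  s0 <- simulate_image(cfg0, 500)
  v0 <- iscat_contrast(s0$camera, s0$ref)$values
  asym <- function(v) sum(abs(v - v[21:1, ])) / sum(abs(v))
  expect_lt(asym(v0), 0.01)
  expect_gt(asym(v14), 0.2)
})

test_that("focus correlation recovers noiseless queries and shows the on-axis ambiguity", {
  zs <- seq(-1000, 1000, by = 250)
  st14 <- focal_stack(au55_cfg(14, 21), zs)
  st0 <- focal_stack(au55_cfg(0, 21), zs)
  for (j in c(1, 4, 9)) {
    expect_identical(focus_correlate(st14, st14[[j]]$image)$z_best, zs[j])
  }
  # negated slice correlates at -1
  fc <- focus_correlate(st14, -st14[[5]]$image)
  expect_equal(min(fc$curve$correlation), -1, tolerance = 1e-12)
  # noisy recovery at moderate SNR (seeded)
  q <- add_noise(st14[[3]]$image - min(st14[[3]]$image), "gaussian",
                 sd = 0.05, seed = 7) + min(st14[[3]]$image)
  expect_identical(focus_correlate(st14, q)$z_best, zs[3])
  # ambiguity structure: mirror focal slices resemble each other only on axis
  mirror_cor <- function(st) cor(as.vector(st[[1]]$image),
                                 as.vector(st[[9]]$image))
  expect_gt(mirror_cor(st0), 0.25)
  expect_lt(abs(mirror_cor(st14)), 0.15)
  expect_error(focus_correlate(st14, matrix(1, 21, 21)), "variance")
})

test_that("Brewster-angle illumination suppresses the reference and boosts contrast", {
  cfg <- microscope_config("iscat", glass_water(),
    plane_wave(520, theta = 40, polarization = "TM", direction = "up"),
    std_train(),
    scatterer = list(engine = "mie", diameter = 40, material = "Au",
                     position = c(0, 0, 25)),
    fov = 3000, npix = 21, n_theta = 30, n_phi = 31)
  thB <- brewster_angle(1.5, 1.33)
  sw <- brewster_sweep(cfg, c(38, 40, thB, 43, 45))
  expect_lt(sw$ref_power[3], 1e-8 * max(sw$ref_power))
  expect_equal(which.max(sw$michelson), 3L)
  # contrast tunes monotonically on each side of the Brewster angle
  sw2 <- brewster_sweep(cfg, thB + c(-2, -1, 1, 2))
  expect_gt(sw2$michelson[2], sw2$michelson[1])
  expect_gt(sw2$michelson[3], sw2$michelson[4])
  cfg_te <- cfg; cfg_te$illumination <- plane_wave(520, theta = 40,
    polarization = "TE", direction = "up")
  expect_error(brewster_sweep(cfg_te, 40:42), "TM")
})

test_that("partial coherence reduces defocus fringe visibility monotonically", {
  cfg <- microscope_config("iscat", glass_water(),
    plane_wave(520, theta = 0, polarization = "TM", direction = "up"),
    std_train(),
    scatterer = list(engine = "dipole", diameter = 30, material = "ps",
                     position = c(0, 0, 15)),
    fov = 3000, npix = 31, n_theta = 30, n_phi = 31)
  pc0 <- partial_coherence(cfg, 520, 1, z_foc = 1500)
  s0 <- simulate_image(cfg, 1500)
  expect_equal(pc0$intensity, s0$camera$intensity, tolerance = 1e-12)
  expect_error(partial_coherence(cfg, c(500, 540), c(0.7, 0.5), 0), "sum to 1")
  expect_error(partial_coherence(cfg, numeric(0), numeric(0), 0), "empty")
  vis <- sapply(c(0, 20, 45), function(bw) {
    wl <- seq(520 - bw, 520 + bw, length.out = if (bw == 0) 1 else 7)
    I <- partial_coherence(cfg, wl, rep(1 / length(wl), length(wl)), 1500)$intensity
    ring <- I[, 16]                             # profile through the rings
    (max(ring) - min(ring)) / (max(ring) + min(ring))
  })
  expect_true(all(diff(vis) < 0))
})

test_that("scanning excitation localizes the particle and respects symmetry", {
  cfg <- microscope_config("iscat", glass_water(),
    illumination = list(focused = TRUE, wavelength = 520, profile = c(1, 0)),
    train = std_train(),
    scatterer = list(engine = "dipole", diameter = 30, material = "Au",
                     position = c(0, 0, 20)),
    fov = 1000, npix = 21, n_theta = 30, n_phi = 31)
  sc <- scan_image(cfg, seq(-400, 400, by = 200), c(-200, 0, 200))
  dev <- abs(sc - stats::median(sc))
  expect_equal(which(dev == max(dev), arr.ind = TRUE)[1, ], c(row = 3, col = 2))
  expect_equal(sc[, 1], sc[, 3], tolerance = 1e-6)    # mirror symmetry in y
  expect_equal(sc[1, ], sc[5, ], tolerance = 1e-6)    # and in x
  cfg0 <- cfg; cfg0$scatterer <- NULL
  sc0 <- scan_image(cfg0, c(-200, 0, 200), 0)
  expect_lt(diff(range(sc0)) / mean(sc0), 1e-10)
})

test_that("system magnification composes objective and relay", {
  expect_equal(system_magnification(40, c(150, 500)), 133.33, tolerance = 1e-4)
  expect_equal(system_magnification(60, c(75, 200)), 160)
  expect_equal(system_magnification(63, c(180, 180)), 63)
  expect_error(system_magnification(-40, c(150, 500)), "positive")
})

test_that("identical configuration and seed reproduce identical images", {
  cfg <- au55_cfg(14, 21)
  a <- simulate_image(cfg, 250)
  b <- simulate_image(cfg, 250)
  expect_identical(a$camera$intensity, b$camera$intensity)
  n1 <- add_noise(a$camera$intensity, "poisson", counts = 1e4, seed = 11)
  n2 <- add_noise(a$camera$intensity, "poisson", counts = 1e4, seed = 11)
  expect_identical(n1, n2)
})
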