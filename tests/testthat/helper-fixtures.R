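# Shared fixtures: small stacks, trains and illumination used across tests.

glass_water <- function()
  layer_stack(list(material_db("water"), material_db("glass")))

glass_air <- function()
  layer_stack(list(material_db("air"), material_db("glass")))

matched_stack <- function(n = 1.33)
  layer_stack(list(material("a", index = n), material("b", index = n)))

std_train <- function(NA_ = 1.3, bfp = NULL)
  optical_train(NA_ = NA_, n = 1.5, n_prime = 1, mag = 133.33, bfp = bfp)

# Independent Mie oracle: spherical Bessel functions from base R half-integer
# Bessel routines with the textbook coefficient formulas written directly in
# terms of psi/xi (a second route, not shared with mie_coefficients()).
mie_oracle <- function(x, m, n_max = 10) {
  sph_j <- function(n, z) sqrt(pi / (2 * z)) * besselJ(z, n + 0.5)
  sph_y <- function(n, z) sqrt(pi / (2 * z)) * besselY(z, n + 0.5)
  psi <- function(n, z) z * sph_j(n, z)
  chi <- function(n, z) -z * sph_y(n, z)
  xi <- function(n, z) psi(n, z) - 1i * chi(n, z)
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  # complex-argument spherical j via its power series:
  # j_n(z) = z^n sum_k (-z^2/2)^k / (k! (2n+2k+1)!!)
  sph_j_c <- function(n, z) {
    s <- 0i
    for (k in 0:60) {
      df <- prod(seq(2 * n + 2 * k + 1, 1, by = -2))
      s <- s + (-z^2 / 2)^k / (factorial(k) * df)
    }
    z^n * s
  }
  psi_c <- function(n, z) z * sph_j_c(n, z)
  dpsi_c <- function(n, z) psi_c(n - 1, z) - n / z * psi_c(n, z)
  a <- b <- complex(n_max)
  mx <- m * x
  for (n in 1:n_max) {
    a[n] <- (m * psi_c(n, mx) * dpsi(n, x) - psi(n, x) * dpsi_c(n, mx)) /
            (m * psi_c(n, mx) * dxi(n, x) - xi(n, x) * dpsi_c(n, mx))
    b[n] <- (psi_c(n, mx) * dpsi(n, x) - m * psi(n, x) * dpsi_c(n, mx)) /
            (psi_c(n, mx) * dxi(n, x) - m * xi(n, x) * dpsi_c(n, mx))
  }
  list(a = a, b = b)
}

mie_oracle_sigma_sca <- function(diameter, eps_p, eps_h, wavelength, n_max = 10) {
  nh <- Re(sqrt(eps_h + 0i))
  k <- 2 * pi * nh / wavelength
  x <- k * diameter / 2
  m <- sqrt(eps_p + 0i) / nh
  cf <- mie_oracle(x, m, n_max)
  n <- 1:n_max
  2 * pi / k^2 * sum((2 * n + 1) * (Mod(cf$a)^2 + Mod(cf$b)^2))
}

# standard 55 nm gold sphere in air on glass, tilted illumination
au55_cfg <- function(theta = 14, npix = 31, engine = "mie") {
  microscope_config("iscat", glass_air(),
    plane_wave(517, theta = theta, polarization = "TM", direction = "up"),
    std_train(),
    scatterer = list(engine = engine, diameter = 55, material = "Au",
                     position = c(0, 0, 32.5)),
    fov = 3900, npix = npix, n_theta = 40, n_phi = 41)
}
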