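# Mie theory for homogeneous spheres: series coefficients, cross sections and
# the vector far-field amplitude for an arbitrary incident plane wave.  Used
# both as a scattering engine for spherical particles and as the exact oracle
# against which the boundary-element solver is validated.

#' Mie series coefficients
#'
#' Lorenz-Mie coefficients `a_n`, `b_n` for a sphere of size parameter
#' `x = k_host * radius` and relative index `m = n_particle / n_host`
#' (complex allowed).  Riccati-Bessel functions by upward recurrence, the
#' logarithmic derivative by downward recurrence.
#'
#' @param x size parameter (> 0).
#' @param m complex relative refractive index.
#' @param n_max series truncation; default is the standard
#'   `x + 4 x^(1/3) + 2` rule.
#' @return list with complex vectors `a`, `b` of length `n_max`.
#' @export
mie_coefficients <- function(x, m, n_max = NULL) {
  stopifnot(x > 0)
  if (is.null(n_max)) n_max <- max(3L, ceiling(x + 4 * x^(1 / 3) + 2))
  nmx <- max(n_max + 15L, ceiling(Mod(m * x)) + 15L)
  D <- complex(nmx + 1)                           # D[i] = D_i(mx), D[nmx+1] = 0
  rho <- m * x
  for (i in nmx:1) D[i] <- (i + 1) / rho - 1 / (D[i + 1] + (i + 1) / rho)
  psi <- numeric(n_max + 1)                       # psi[n+1] = psi_n(x)
  chi <- numeric(n_max + 1)
  psi_m1 <- cos(x); psi[1] <- sin(x)
  chi_m1 <- -sin(x); chi[1] <- cos(x)
  for (n in 1:n_max) {
    psi[n + 1] <- (2 * n - 1) / x * psi[n] - if (n == 1) psi_m1 else psi[n - 1]
    chi[n + 1] <- (2 * n - 1) / x * chi[n] - if (n == 1) chi_m1 else chi[n - 1]
  }
  xi <- psi - 1i * chi
  n <- 1:n_max
  Da <- D[n] / m + n / x
  Db <- D[n] * m + n / x
  list(a = (Da * psi[n + 1] - psi[n]) / (Da * xi[n + 1] - xi[n]),
       b = (Db * psi[n + 1] - psi[n]) / (Db * xi[n + 1] - xi[n]))
}

#' Mie cross sections
#'
#' Scattering and extinction cross sections (nm^2) of a homogeneous sphere in
#' a lossless host.  For a lossless particle `sigma_ext = sigma_sca`.
#'
#' @param diameter sphere diameter (nm).
#' @param eps_particle,eps_host complex relative permittivities.
#' @param wavelength vacuum wavelength (nm).
#' @return list with `sigma_sca`, `sigma_ext`, `sigma_abs` (nm^2).
#' @export
mie_cross_sections <- function(diameter, eps_particle, eps_host, wavelength) {
  if (diameter <= 0) stop("diameter must be positive")
  nh <- sqrt(as.complex(eps_host))
  k <- 2 * pi * Re(nh) / wavelength
  x <- k * diameter / 2
  m <- sqrt(as.complex(eps_particle)) / nh
  cf <- mie_coefficients(x, m)
  n <- seq_along(cf$a)
  sca <- 2 * pi / k^2 * sum((2 * n + 1) * (Mod(cf$a)^2 + Mod(cf$b)^2))
  ext <- 2 * pi / k^2 * sum((2 * n + 1) * Re(cf$a + cf$b))
  list(sigma_sca = sca, sigma_ext = ext, sigma_abs = ext - sca)
}

# Angular functions pi_n, tau_n and the amplitudes S1, S2 at (complex) mu =
# cos(Theta).  Returns n x 2 matrix cbind(S1, S2) for a vector mu.
mie_S12 <- function(cf, mu) {
  nmax <- length(cf$a)
  S1 <- S2 <- rep(0i, length(mu))
  p_nm1 <- rep(0 + 0i, length(mu))                # pi_0
  p_n <- rep(1 + 0i, length(mu))                  # pi_1
  for (n in 1:nmax) {
    tau <- n * mu * p_n - (n + 1) * p_nm1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (cf$a[n] * p_n + cf$b[n] * tau)
    S2 <- S2 + fac * (cf$a[n] * tau + cf$b[n] * p_n)
    p_np1 <- ((2 * n + 1) * mu * p_n - (n + 1) * p_nm1) / n
    p_nm1 <- p_n
    p_n <- p_np1
  }
  cbind(S1, S2)
}

#' Mie far field of a sphere under plane-wave illumination
#'
#' Exact far-field amplitude `F(r_hat)` (with `E = F e^{ikr}/r`) for a sphere
#' in a homogeneous host driven by a plane wave with direction `k_hat0` and
#' complex transverse polarization `eps0`.  The returned far field is expanded
#' about the sphere center and carries an analytic amplitude function, so the
#' interface correction can continue it to complex directions.
#'
#' @param diameter sphere diameter (nm).
#' @param eps_particle,eps_host complex relative permittivities.
#' @param drive a [plane_wave()] (its direction/polarization resolved in the
#'   host), or a list `list(dir =, eps =)` with an explicit direction and
#'   complex amplitude.
#' @param wavelength vacuum wavelength (nm); taken from `drive` when it is a
#'   [plane_wave()].
#' @param grid a [direction_grid()].
#' @param center sphere center (nm); the drive's phase at the center is
#'   applied, so far fields from several plane-wave components superpose
#'   correctly.
#' @return A [farfield()] with attributes `sigma_sca`, `sigma_ext`.
#' @export
mie_farfield <- function(diameter, eps_particle, eps_host, drive,
                         wavelength = NULL, grid = direction_grid(),
                         center = c(0, 0, 0)) {
  if (diameter <= 0) stop("diameter must be positive")
  nh <- Re(sqrt(as.complex(eps_host)))
  if (inherits(drive, "plane_wave_spec")) {
    wavelength <- drive$wavelength
    pw <- make_planewave(drive, n_host = nh)
    khat0 <- pw$dir[1, ]; eps0 <- pw$eps[1, ]
  } else {
    khat0 <- drive$dir; eps0 <- as.complex(drive$eps)
  }
  if (is.null(wavelength)) stop("wavelength required")
  k <- 2 * pi * nh / wavelength
  x <- k * diameter / 2
  m <- sqrt(as.complex(eps_particle)) / nh
  cf <- mie_coefficients(x, m)
  eps0 <- eps0 * exp(1i * k * sum(khat0 * c(center)))  # drive phase at center
  amp_fun <- function(dirs) {
    dirs <- matrix(dirs, ncol = 3)
    mu <- drop(dirs %*% khat0)
    S <- mie_S12(cf, mu)
    out <- matrix(0i, nrow(dirs), 3)
    cr <- cbind(khat0[2] * dirs[, 3] - khat0[3] * dirs[, 2],
                khat0[3] * dirs[, 1] - khat0[1] * dirs[, 3],
                khat0[1] * dirs[, 2] - khat0[2] * dirs[, 1])
    s2 <- rowSums(cr * cr)                        # sin^2(Theta), bilinear
    deg <- Mod(s2) < 1e-12
    if (any(!deg)) {
      eperp <- cr[!deg, , drop = FALSE] / sqrt(s2[!deg])
      epar <- cbind(eperp[, 2] * khat0[3] - eperp[, 3] * khat0[2],
                    eperp[, 3] * khat0[1] - eperp[, 1] * khat0[3],
                    eperp[, 1] * khat0[2] - eperp[, 2] * khat0[1])
      d <- dirs[!deg, , drop = FALSE]
      ths <- cbind(eperp[, 2] * d[, 3] - eperp[, 3] * d[, 2],
                   eperp[, 3] * d[, 1] - eperp[, 1] * d[, 3],
                   eperp[, 1] * d[, 2] - eperp[, 2] * d[, 1])
      apar <- drop(epar %*% eps0)
      aperp <- drop(eperp %*% eps0)
      out[!deg, ] <- (1i / k) * (S[!deg, 2] * apar * ths +
                                 S[!deg, 1] * aperp * eperp)
    }
    if (any(deg)) {                               # forward/backward limit
      d <- dirs[deg, , drop = FALSE]
      proj <- eps0 - d * drop(d %*% eps0)
      out[deg, ] <- (1i / k) * S[deg, 1] * proj
    }
    out
  }
  ff <- farfield(function(dirs, th, ph) amp_fun(dirs), k = k, grid = grid,
                 origin = center, k0 = 2 * pi / wavelength)
  attr(ff, "amp_fun") <- amp_fun
  cs <- mie_cross_sections(diameter, eps_particle, eps_host, wavelength)
  attr(ff, "sigma_sca") <- cs$sigma_sca * sum(Mod(eps0)^2)
  attr(ff, "sigma_ext") <- cs$sigma_ext * sum(Mod(eps0)^2)
  ff
}
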