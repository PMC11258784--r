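# Point-dipole scattering models and the far-field interface correction.
#
# Two dipole routes are provided, mirroring the two standard approximations
# for a small particle above a substrate:
#  * dip1 - the exact far field of a point dipole above a single interface
#    (direct + Fresnel-reflected ray in the upper half space; Fresnel
#    transmission with the Snell direction mapping, the spectral energy
#    factor and the height phase in the lower half space, including the
#    supercritical "forbidden light" band via analytic continuation);
#  * dip2 - dipole radiation in a homogeneous host followed by diffraction of
#    the emitted far field at the interface.  Implemented by the generic
#    interface_correct(), which applies the same construction to *any* far
#    field (Mie, BEM) and is the package's substitute for layered-medium
#    solver kernels.  For a point dipole dip1 and dip2 coincide by
#    construction.

#' Point-dipole scatterer
#'
#' @param position dipole position (nm), above the top interface.
#' @param alpha polarizability (nm^3): complex scalar (isotropic) or 3x3
#'   matrix; see [polarizability_sphere()].
#' @param eps_host complex permittivity of the host (top) medium.
#' @return Object of class `dipole_scatterer`.
#' @export
dipole_scatterer <- function(position, alpha, eps_host = 1.33^2) {
  structure(list(position = as.numeric(position), alpha = alpha,
                 eps_host = as.complex(eps_host)),
            class = "dipole_scatterer")
}

#' Quasistatic sphere polarizability
#'
#' Clausius-Mossotti polarizability `a^3 (eps_p - eps_h)/(eps_p + 2 eps_h)`
#' of a sphere of radius `a` (units nm^3; the dipole moment is `p = alpha E`
#' and the radiated far field `F = k^2 (I - rr) p`).  The optional radiative
#' correction `alpha / (1 - i 2 k^3 alpha / 3)` restores the optical theorem
#' for lossless spheres.
#'
#' @param diameter sphere diameter (nm).
#' @param eps_particle,eps_host complex relative permittivities.
#' @param radiative_correction logical (default off).
#' @param wavelength vacuum wavelength (nm), needed for the correction.
#' @return complex scalar polarizability (nm^3).
#' @export
polarizability_sphere <- function(diameter, eps_particle, eps_host,
                                  radiative_correction = FALSE,
                                  wavelength = NULL) {
  if (diameter <= 0) stop("diameter must be positive")
  eps_particle <- as.complex(eps_particle)
  eps_host <- as.complex(eps_host)
  den <- eps_particle + 2 * eps_host
  if (Mod(den) < 1e-12 * Mod(eps_host))
    stop("quasistatic resonance singularity: eps_p + 2 eps_h = 0")
  a <- diameter / 2
  alpha <- a^3 * (eps_particle - eps_host) / den
  if (radiative_correction) {
    if (is.null(wavelength)) stop("wavelength required for radiative correction")
    k <- 2 * pi * Re(sqrt(eps_host)) / wavelength
    alpha <- alpha / (1 - 1i * 2 * k^3 * alpha / 3)
  }
  alpha
}

induced_moment <- function(dip, drive) {
  E <- drive(rbind(dip$position))$E[1, ]
  if (is.matrix(dip$alpha)) drop(dip$alpha %*% E) else dip$alpha * E
}

#' Far field of a dipole in a homogeneous medium
#'
#' `F(r_hat) = k^2 (p - r_hat (r_hat . p))`, the textbook `sin(Theta)`
#' pattern, expanded about the dipole position.
#'
#' @param p complex dipole moment vector (alpha * E, nm^3 * field).
#' @param k host wavenumber (nm^-1).
#' @param grid a [direction_grid()].
#' @param origin dipole position (nm).
#' @param k0 vacuum wavenumber (defaults to `k`).
#' @return A [farfield()] with an analytic amplitude attribute.
#' @export
dipole_farfield_free <- function(p, k, grid = direction_grid(),
                                 origin = c(0, 0, 0), k0 = NULL) {
  p <- as.complex(p)
  amp_fun <- function(dirs) {
    dirs <- matrix(dirs, ncol = 3)
    k^2 * (matrix(p, nrow(dirs), 3, byrow = TRUE) - dirs * drop(dirs %*% p))
  }
  ff <- farfield(function(dirs, th, ph) amp_fun(dirs), k = k, grid = grid,
                 origin = origin, k0 = k0)
  attr(ff, "amp_fun") <- amp_fun
  ff
}

# s/p basis vectors for a (possibly complex) direction with azimuth phi:
# s = (-sin phi, cos phi, 0) fixed by the azimuth, p = s x dir (bilinear unit).
sp_basis <- function(dirs, phi) {
  s <- cbind(-sin(phi), cos(phi), 0)
  p <- cbind(s[, 2] * dirs[, 3] - 0,
             0 - s[, 1] * dirs[, 3],
             s[, 1] * dirs[, 2] - s[, 2] * dirs[, 1])
  list(s = s, p = p)
}

#' Interface correction of a far field
#'
#' Combines each direction of a far field expanded about a source at height
#' `z0` above the top interface with its Fresnel-reflected and transmitted
#' counterparts: upward directions acquire the interface-reflected image
#' contribution (`r(theta)`, two-path phase `2 k1 cos(theta) z0`), downward
#' directions are replaced by the transmitted wave with the Snell direction
#' mapping, the spectral factor `n2 cos(theta2) / (n1 cos(theta1))` and the
#' height phase `e^{i k1 cos(theta1) z0}`; the supercritical band uses the
#' analytic continuation of the source amplitude when available (attribute
#' `amp_fun`, exact for dipole/Mie/BEM far fields) and is dropped otherwise.
#' The output is expanded about the interface point below the source and
#' carries a per-node wavenumber (upper-medium `k1` above, substrate `k2`
#' below).  Generalizes the dipole model dip2 to arbitrary scatterers; this
#' far-field treatment of the substrate is the package's main physical
#' approximation (accurate for particles up to about 50 nm near the
#' interface).
#'
#' @param far a [farfield()] in the top medium, origin at the source center
#'   with height `origin[3] > 0`, unrotated.
#' @param stack a [layer_stack()] with top interface at z = 0.
#' @param wavelength vacuum wavelength (nm).
#' @return A [farfield()] about `(origin_x, origin_y, 0)`.
#' @export
interface_correct <- function(far, stack, wavelength) {
  stopifnot(inherits(far, "farfield"), inherits(stack, "layer_stack"))
  if (max(abs(far$R - diag(3))) > 1e-12)
    stop("interface_correct expects an unrotated far field")
  if (length(far$k) != 1) stop("far field must live in a single medium")
  z0 <- far$origin[3]
  if (z0 <= 0) stop("source must lie strictly above the top interface")
  k0 <- 2 * pi / wavelength
  n_all <- stack_indices(stack, wavelength)
  n1 <- n_all[1]; nN <- n_all[length(n_all)]
  if (abs(far$k - k0 * Re(n1)) > 1e-6 * far$k)
    stop("far-field wavenumber inconsistent with the top medium")
  amp <- attr(far, "amp_fun")
  if (is.null(amp)) {
    amp <- function(dirs) {
      dirs <- Re(matrix(dirs, ncol = 3))
      nr <- sqrt(rowSums(dirs^2))
      farfield_interp(far, dirs / nr)$F
    }
    attr(amp, "sampled") <- TRUE
  }
  nodes <- grid_nodes(far$grid)
  th <- nodes$theta; ph <- nodes$phi; dirs <- nodes$dir
  k1 <- k0 * Re(n1); kN <- k0 * Re(nN)
  E <- matrix(0i, nrow(dirs), 3)
  up <- dirs[, 3] > 0
  ## upper hemisphere: direct + reflected image
  if (any(up)) {
    d <- dirs[up, , drop = FALSE]
    c1 <- d[, 3]
    dm <- cbind(d[, 1], d[, 2], -c1)
    Fd <- amp(d); Fm <- amp(dm)
    b_up <- sp_basis(d, ph[up])
    b_dn <- sp_basis(dm, ph[up])
    kx0 <- Re(n1) * sqrt(d[, 1]^2 + d[, 2]^2)
    rs <- rp <- rep(0i, nrow(d))
    for (u in unique(round(kx0, 12))) {
      sel <- round(kx0, 12) == u
      rs[sel] <- fresnel_core(n_all, stack$interface_z, u, "TE", k0)$r
      rp[sel] <- fresnel_core(n_all, stack$interface_z, u, "TM", k0)$r
    }
    Fs <- rowSums(Fm * b_dn$s)
    Fp <- rowSums(Fm * b_dn$p)
    # reflected TM amplitude carries the basis flip -p_hat (see layers.R)
    E[up, ] <- Fd * exp(-1i * k1 * c1 * z0) +
      (rs * Fs * b_up$s - rp * Fp * b_up$p) * exp(1i * k1 * c1 * z0)
  }
  ## lower hemisphere: transmitted with Snell mapping
  if (any(!up)) {
    d <- dirs[!up, , drop = FALSE]
    c2 <- -d[, 3]                                  # cos of angle from -z
    s2 <- sqrt(d[, 1]^2 + d[, 2]^2)
    kx0 <- Re(nN) * s2                             # conserved transverse k/k0
    s1 <- kx0 / Re(n1)                             # source-side sine (may be > 1)
    c1 <- sqrt(1 - s1^2 + 0i)
    c1 <- ifelse(Im(c1) < 0, -c1, c1)
    src <- cbind(s1 * cos(ph[!up]), s1 * sin(ph[!up]), -c1)
    if (isTRUE(attr(amp, "sampled"))) {
      keep <- s1 <= 1
      F1 <- matrix(0i, nrow(d), 3)
      if (any(keep)) F1[keep, ] <- amp(Re(src[keep, , drop = FALSE]))
    } else {
      F1 <- amp(src)
    }
    b_src <- sp_basis(src, ph[!up])
    b_out <- sp_basis(d, ph[!up])
    ts <- tp <- rep(0i, nrow(d))
    for (u in unique(round(kx0, 12))) {
      sel <- round(kx0, 12) == u
      ts[sel] <- fresnel_core(n_all, stack$interface_z, u, "TE", k0)$t
      tp[sel] <- fresnel_core(n_all, stack$interface_z, u, "TM", k0)$t
    }
    fac <- (Re(nN) * c2) / (Re(n1) * c1) * exp(1i * k1 * c1 * z0)
    Fs <- rowSums(F1 * b_src$s)
    Fp <- rowSums(F1 * b_src$p)
    E[!up, ] <- fac * (ts * Fs * b_out$s + tp * Fp * b_out$p)
  }
  out <- far
  out$E <- E
  out$k <- ifelse(up, k1, kN)
  out$origin <- c(far$origin[1:2], 0)
  attr(out, "amp_fun") <- NULL
  attr(out, "sigma_sca") <- NULL
  attr(out, "sigma_ext") <- NULL
  out
}

#' Dipole far fields above a substrate
#'
#' `dipole_farfield_dip1()` computes the exact far field of a point dipole
#' above a single interface (direct + Fresnel image above, Fresnel-transmitted
#' with the angle mapping and height phase below).
#' `dipole_farfield_dip2()` models dipole radiation in the homogeneous host
#' followed by diffraction of the emitted far field at the (possibly
#' multilayer) stack via [interface_correct()].  The induced moment is
#' `p = alpha E_drive(position)` with the total driving field from
#' [incident_field()].
#'
#' @param dip a [dipole_scatterer()] positioned strictly above the top
#'   interface.
#' @param drive field evaluator (from [incident_field()] or [pwd_field()]).
#' @param stack a [layer_stack()]; `dip1` requires a single interface.
#' @param wavelength vacuum wavelength (nm).
#' @param grid a [direction_grid()].
#' @return A [farfield()] about the interface point below the dipole, with a
#'   per-node wavenumber (upper medium above, substrate below).
#' @export
dipole_farfield_dip2 <- function(dip, drive, stack, wavelength,
                                 grid = direction_grid()) {
  if (dip$position[3] <= 0) stop("dipole must lie strictly above the top interface")
  p <- induced_moment(dip, drive)
  n1 <- Re(refractive_index(stack$materials[[1]], wavelength))
  ff <- dipole_farfield_free(p, k = 2 * pi * n1 / wavelength, grid = grid,
                             origin = dip$position, k0 = 2 * pi / wavelength)
  interface_correct(ff, stack, wavelength)
}

#' @rdname dipole_farfield_dip2
#' @export
dipole_farfield_dip1 <- function(dip, drive, stack, wavelength,
                                 grid = direction_grid()) {
  if (length(stack$materials) != 2)
    stop("dip1 handles a single interface; use dipole_farfield_dip2 for multilayers")
  if (dip$position[3] <= 0) stop("dipole must lie strictly above the top interface")
  p <- induced_moment(dip, drive)
  k0 <- 2 * pi / wavelength
  n1 <- Re(refractive_index(stack$materials[[1]], wavelength))
  n2 <- Re(refractive_index(stack$materials[[2]], wavelength))
  k1 <- k0 * n1; k2 <- k0 * n2
  z0 <- dip$position[3]
  nodes <- grid_nodes(grid)
  dirs <- nodes$dir; ph <- nodes$phi
  pat <- function(d) k0^2 * n1^2 *
    (matrix(p, nrow(d), 3, byrow = TRUE) - d * drop(d %*% p))
  E <- matrix(0i, nrow(dirs), 3)
  up <- dirs[, 3] > 0
  # upper half space: two-ray (direct + image) construction
  d <- dirs[up, , drop = FALSE]
  c1 <- d[, 3]
  th1 <- acos(pmin(1, c1))
  dm <- cbind(d[, 1], d[, 2], -c1)
  b_up <- sp_basis(d, ph[up]); b_dn <- sp_basis(dm, ph[up])
  rs <- vapply(th1, function(t) fresnel(stack, t / DEG, "TE", wavelength,
                                        from = "top")$r, complex(1))
  rp <- vapply(th1, function(t) fresnel(stack, t / DEG, "TM", wavelength,
                                        from = "top")$r, complex(1))
  Fm <- pat(dm)
  E[up, ] <- pat(d) * exp(-1i * k1 * c1 * z0) +
    (rs * rowSums(Fm * b_dn$s) * b_up$s -
     rp * rowSums(Fm * b_dn$p) * b_up$p) * exp(1i * k1 * c1 * z0)
  # lower half space: angular-spectrum transmission
  d <- dirs[!up, , drop = FALSE]
  c2 <- -d[, 3]
  s2 <- sqrt(d[, 1]^2 + d[, 2]^2)
  s1 <- n2 * s2 / n1
  c1 <- sqrt(1 - s1^2 + 0i)
  c1 <- ifelse(Im(c1) < 0, -c1, c1)
  src <- cbind(s1 * cos(ph[!up]), s1 * sin(ph[!up]), -c1)
  b_src <- sp_basis(src, ph[!up]); b_out <- sp_basis(d, ph[!up])
  kx0 <- n2 * s2
  ts <- tp <- rep(0i, nrow(d))
  n_all <- c(n1, n2)
  for (u in unique(round(kx0, 12))) {
    sel <- round(kx0, 12) == u
    ts[sel] <- fresnel_core(n_all, 0, u, "TE", k0)$t
    tp[sel] <- fresnel_core(n_all, 0, u, "TM", k0)$t
  }
  F1 <- pat(src)
  fac <- (n2 * c2) / (n1 * c1) * exp(1i * k1 * c1 * z0)
  E[!up, ] <- fac * (ts * rowSums(F1 * b_src$s) * b_out$s +
                     tp * rowSums(F1 * b_src$p) * b_out$p)
  ff <- farfield(E, k = ifelse(up, k1, k2), grid = grid,
                 origin = c(dip$position[1:2], 0), k0 = k0)
  ff
}
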