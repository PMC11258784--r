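# Vectorial Richards-Wolf imaging through an aplanatic two-lens system.
#
# The imaging frame has the optical axis along +z and the focus at the
# origin; fields must be rotated/shifted into this frame beforehand (the
# microscope assembly does this).  TE (phi) components keep their orientation
# through the train, TM (theta) components are rotated to the image-side
# radial direction; with the paraxial image side (cos theta' ~ 1, f' >> f)
# both recombine into the Cartesian transverse components of the back focal
# plane, where the optional Jones transform acts.  The energy factor
# sqrt(n cos(theta) / n') enforces power conservation along ray bundles.
#
# Conventions: the global phase of the imaging integral is set to zero; the
# intensity scale is normalized so that a unit-amplitude on-axis reference
# plane wave maps to unit image intensity with an identity back-focal-plane
# transform.  Image coordinates are object-referred (image coordinate
# divided by the magnification, in nm), so fields of view read in
# sample-plane units.  The far-field and plane-wave imaging routes are
# mutually consistent through the Debye identity eps(khat) = (ik/2pi) F(khat).

#' Aplanatic optical train
#'
#' @param NA_ numerical aperture (`n sin(theta_max) = NA`).
#' @param n,n_prime refractive indices on the object and image side.
#' @param f,f_prime reference-sphere focal lengths (mm); alternatively give
#'   `mag` directly.
#' @param mag transverse magnification `(n/n') (f'/f)`; overrides `f`,
#'   `f_prime` when given.
#' @param bfp optional back-focal-plane transform: a function
#'   `function(theta, phi)` returning a 2x2 complex Jones matrix acting on
#'   the Cartesian transverse components (see [bfp_waveplate()],
#'   [bfp_attenuator()], [bfp_block()], [bfp_compose()]).
#' @return Object of class `optical_train`.
#' @export
optical_train <- function(NA_, n = 1.5, n_prime = 1.0, f = 3, f_prime = NULL,
                          mag = NULL, bfp = NULL) {
  if (NA_ > n) stop("NA exceeds object-side index")
  if (is.null(mag)) {
    if (is.null(f_prime)) stop("give either mag or both f and f_prime")
    mag <- (n / n_prime) * (f_prime / f)
  } else {
    f_prime <- mag * f * n_prime / n
  }
  structure(list(NA_ = NA_, n = n, n_prime = n_prime, f = f,
                 f_prime = f_prime, mag = mag,
                 theta_max = asin(NA_ / n), bfp = bfp),
            class = "optical_train")
}

#' Magnification of an optical train
#' @param train an [optical_train()].
#' @return scalar `M = (n/n') (f'/f)`.
#' @export
magnification <- function(train) train$mag

#' Image-plane sampling grid
#' @param fov field of view (nm, object-referred full width).
#' @param npix pixels per side.
#' @return list with `x`, `y` coordinate vectors (nm).
#' @export
image_grid <- function(fov, npix = 101) {
  list(x = seq(-fov / 2, fov / 2, length.out = npix),
       y = seq(-fov / 2, fov / 2, length.out = npix))
}

#' Back-focal-plane Jones transforms
#'
#' Per-direction 2x2 Jones actions on the transverse field components in the
#' back focal plane: a waveplate of given retardance and fast-axis angle, a
#' neutral attenuator (`|t| <= 1`), and a radial/annular beam block in
#' direction space (`theta` in degrees; a zero-radius block is the
#' identity).  Transforms compose right-to-left with [bfp_compose()].
#'
#' @param retardance phase retardance in radians (`pi/2` for a quarter-wave
#'   plate).
#' @param fast_axis_deg fast-axis angle in degrees (clockwise positive, i.e.
#'   measured from +x toward -y).
#' @param t complex amplitude transmission, `|t| <= 1`.
#' @param theta_min_deg,theta_max_deg blocked annulus in polar angle.
#' @param ... Jones functions, applied right to left.
#' @return `function(theta, phi)` returning a 2x2 complex matrix.
#' @export
bfp_waveplate <- function(retardance, fast_axis_deg = 45) {
  psi <- -fast_axis_deg * DEG                      # clockwise-positive axis
  R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
  J <- R %*% diag(c(exp(-1i * retardance / 2), exp(1i * retardance / 2))) %*% t(R)
  function(theta, phi) J
}

#' @rdname bfp_waveplate
#' @export
bfp_attenuator <- function(t) {
  if (Mod(t) > 1 + 1e-12) stop("|t| must be <= 1")
  function(theta, phi) diag(2) * as.complex(t)
}

#' @rdname bfp_waveplate
#' @export
bfp_block <- function(theta_max_deg, theta_min_deg = 0) {
  function(theta, phi) {
    if (theta_max_deg > theta_min_deg &&
        theta >= theta_min_deg * DEG && theta <= theta_max_deg * DEG)
      matrix(0i, 2, 2)
    else diag(2) + 0i
  }
}

#' @rdname bfp_waveplate
#' @export
bfp_compose <- function(...) {
  fs <- list(...)
  function(theta, phi) {
    J <- diag(2) + 0i
    for (f in rev(fs)) J <- f(theta, phi) %*% J
    J
  }
}

# Apply the vector mapping + energy factor + Jones transform to transverse
# amplitudes given per direction: returns n x 3 (Cartesian image components).
bfp_map <- function(amp, theta, phi, train) {
  tht <- cbind(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
  pht <- cbind(-sin(phi), cos(phi), 0)
  Ft <- rowSums(amp * tht)
  Fp <- rowSums(amp * pht)
  vx <- Ft * cos(phi) - Fp * sin(phi)
  vy <- Ft * sin(phi) + Fp * cos(phi)
  if (!is.null(train$bfp)) {
    for (j in seq_along(theta)) {
      J <- train$bfp(theta[j], phi[j])
      v <- J %*% c(vx[j], vy[j])
      vx[j] <- v[1]; vy[j] <- v[2]
    }
  }
  fac <- sqrt(train$n * cos(theta) / train$n_prime)
  cbind(fac * vx, fac * vy, 0i)
}

camera_image <- function(E, grid, train) {
  I <- matrix(rowSums(Mod(E)^2), length(grid$x), length(grid$y))
  structure(list(x = grid$x, y = grid$y, E = E, intensity = I,
                 mag = train$mag, n = train$n, n_prime = train$n_prime),
            class = "camera_image")
}

#' Image a far field through the optical train
#'
#' Direct two-dimensional quadrature of the Richards-Wolf integral over the
#' collection cone `theta <= theta_max`: TE/TM components mapped to the image
#' side, energy factor and back-focal-plane transform applied, and the
#' transverse phase `exp(i k0 n sin(theta) rho cos(phi - phi_img))`
#' accumulated per pixel.  The far field must be expanded about the train
#' focus with the optical axis along +z.
#'
#' @param far a [farfield()] (rotated/shifted into imaging coordinates).
#' @param train an [optical_train()].
#' @param grid an [image_grid()] (object-referred nm).
#' @return A `camera_image` (complex field per pixel plus intensity).
#' @export
image_farfield <- function(far, train, grid) {
  dirs <- field_directions(far)
  th <- acos(pmin(1, pmax(-1, dirs[, 3])))
  sel <- th <= train$theta_max
  th <- th[sel]
  phi <- atan2(dirs[sel, 2], dirs[sel, 1])
  w <- field_weights(far)[sel]
  amp <- far$E[sel, , drop = FALSE]
  k0 <- far$k0
  n_phi_grid <- length(far$grid$phi)
  rho_max <- sqrt(2) * max(abs(c(grid$x, grid$y)))
  if (k0 * train$n * sin(train$theta_max) * rho_max * 2 * pi / n_phi_grid > 2)
    warning("far-field azimuthal grid coarser than the image bandwidth; expect aliasing artifacts at large radii (refine n_phi or use the Bessel route)",
            call. = FALSE)
  mapped <- bfp_map(amp, th, phi, train)
  pref <- 1i * k0 * sqrt(train$n * train$n_prime) / (2 * pi)
  q <- k0 * train$n * sin(th)
  pix <- expand.grid(x = grid$x, y = grid$y)
  E <- pref * imaging_sum(pix$x, pix$y, q * cos(phi), q * sin(phi), w * mapped)
  camera_image(E, grid, train)
}

#' Bessel-accelerated Richards-Wolf imaging
#'
#' Discrete azimuthal Fourier transform of the (uniformly sampled) far field
#' followed by the analytic azimuthal integration, which turns each Fourier
#' order into a Bessel-function radial kernel
#' `2 pi i^m J_m(k0 n sin(theta) rho) e^{i m phi}`.  Equivalent to
#' [image_farfield()] in the joint refinement limit, but free of the
#' large-radius aliasing artifacts of the direct quadrature at coarse
#' azimuthal sampling.
#'
#' @param far,train,grid as in [image_farfield()].
#' @param m_max Fourier truncation (default `floor((n_phi - 1) / 2)`, i.e. no
#'   truncation).
#' @return A `camera_image`.
#' @export
image_farfield_bessel <- function(far, train, grid, m_max = NULL) {
  nphi <- length(far$grid$phi)
  mlim <- floor((nphi - 1) / 2)
  if (is.null(m_max)) m_max <- mlim
  if (m_max > mlim) stop("m_max exceeds the azimuthal Nyquist order n_phi/2")
  dirs <- field_directions(far)
  th_all <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi_all <- atan2(dirs[, 2], dirs[, 1])
  w_all <- field_weights(far)
  thr <- round(th_all, 10)
  thu <- sort(unique(thr))
  thu <- thu[thu <= train$theta_max + 1e-10]
  k0 <- far$k0
  pref <- 1i * k0 * sqrt(train$n * train$n_prime) / (2 * pi)
  pix <- expand.grid(x = grid$x, y = grid$y)
  rho <- sqrt(pix$x^2 + pix$y^2)
  phg <- atan2(pix$y, pix$x)
  E <- matrix(0i, nrow(pix), 3)
  ms <- -m_max:m_max
  for (tv in thu) {
    ring <- thr == tv
    phj <- phi_all[ring]
    gj <- bfp_map(far$E[ring, , drop = FALSE], th_all[ring], phj, train)
    wt <- sum(w_all[ring]) / (2 * pi)            # theta weight (w_theta)
    q <- k0 * train$n * sin(tv)
    Gm <- exp(-1i * outer(ms, phj)) %*% gj / length(phj)   # Fourier coeffs
    for (im in seq_along(ms)) {
      m <- ms[im]
      Jm <- besselJ(q * rho, abs(m))
      if (m < 0 && m %% 2 != 0) Jm <- -Jm
      kern <- wt * 2 * pi * (1i)^m * Jm * exp(1i * m * phg)
      E <- E + kern %*% Gm[im, , drop = FALSE]
    }
  }
  camera_image(pref * E, grid, train)
}

#' Image a plane-wave decomposition
#'
#' Applies the same transformation chain as [image_farfield()] to the
#' discrete components of a decomposition (used for reference and reflected
#' beams); each component within the collection cone maps to a plane wave in
#' the image plane, components outside the cone are dropped with a warning.
#'
#' @param pwd a [pw_decomposition()] in imaging coordinates.
#' @param train an [optical_train()].
#' @param grid an [image_grid()].
#' @return A `camera_image`.
#' @export
image_pwd <- function(pwd, train, grid) {
  # fold the origin phase into the amplitudes: components referenced to the focus
  eps <- pwd$eps * exp(-1i * pwd$k * drop(pwd$dir %*% pwd$origin))
  th <- acos(pmin(1, pmax(-1, pwd$dir[, 3])))
  sel <- th <= train$theta_max
  if (any(!sel))
    warning(sprintf("%d plane-wave component(s) outside the collection cone dropped",
                    sum(!sel)), call. = FALSE)
  if (!any(sel)) {
    E <- matrix(0i, length(grid$x) * length(grid$y), 3)
    return(camera_image(E, grid, train))
  }
  th <- th[sel]
  phi <- atan2(pwd$dir[sel, 2], pwd$dir[sel, 1])
  mapped <- bfp_map(eps[sel, , drop = FALSE], th, phi, train)
  pref <- sqrt(train$n_prime / train$n)
  q <- (pwd$k0 %||% pwd$k) * train$n * sin(th)
  pix <- expand.grid(x = grid$x, y = grid$y)
  E <- pref * imaging_sum(pix$x, pix$y, q * cos(phi), q * sin(phi),
                          pwd$w[sel] * mapped)
  camera_image(E, grid, train)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrated image-plane power
#'
#' Integrated intensity in object-referred coordinates, scaled so that it is
#' directly comparable with the collected-cone power
#' [collected_power()] of the imaged far field (equal for a lossless train
#' with identity back-focal-plane transform).
#'
#' @param img a `camera_image`.
#' @return scalar power (arbitrary but consistent units).
#' @export
image_power <- function(img) {
  dx <- mean(diff(img$x)); dy <- mean(diff(img$y))
  img$n * sum(img$intensity) * dx * dy
}

#' Power collected within the aperture cone
#' @param far a [farfield()] in imaging coordinates.
#' @param train an [optical_train()].
#' @return scalar power.
#' @export
collected_power <- function(far, train) {
  dirs <- field_directions(far)
  th <- acos(pmin(1, pmax(-1, dirs[, 3])))
  sel <- th <= train$theta_max
  nmed <- Re(far$k) / far$k0
  if (length(nmed) == 1) nmed <- rep(nmed, nrow(dirs))
  sum((field_weights(far) * nmed * rowSums(Mod(far$E)^2))[sel])
}

#' Focused excitation beam
#'
#' Vectorial focal field of an aperture illumination, by angular-spectrum
#' superposition over the train's collection cone: the aperture profile is
#' refracted onto the Gaussian reference sphere (apodization
#' `sqrt(cos theta)`), giving a plane-wave decomposition focused at `focus`
#' whose evaluator provides the excitation field for scanning modalities.
#'
#' @param train an [optical_train()]; the beam converges along +z with the
#'   train's NA.
#' @param profile aperture field: complex length-2 (Cartesian transverse
#'   Jones vector, uniform fill) or `function(theta, phi)` returning one.
#' @param wavelength vacuum wavelength (nm).
#' @param focus focal point (nm).
#' @param n_theta,n_phi cone quadrature.
#' @return A [pw_decomposition()] (quadrature type, weights in steradians).
#' @export
focus_beam <- function(train, profile = c(1, 0), wavelength,
                       focus = c(0, 0, 0), n_theta = 20, n_phi = 24) {
  gl <- gauss_legendre(n_theta, cos(train$theta_max), 1)
  th <- acos(gl$x)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  nodes <- expand.grid(th = th, phi = phi)
  wts <- rep(gl$w, n_phi) * (2 * pi / n_phi)
  if (!is.function(profile)) {
    pr <- as.complex(profile)
    profile <- function(theta, phi) pr
  }
  k <- 2 * pi * train$n / wavelength
  eps <- matrix(0i, nrow(nodes), 3)
  for (j in seq_len(nrow(nodes))) {
    t1 <- nodes$th[j]; p1 <- nodes$phi[j]
    Eb <- profile(t1, p1)
    tht <- c(cos(t1) * cos(p1), cos(t1) * sin(p1), -sin(t1))
    pht <- c(-sin(p1), cos(p1), 0)
    er <- c(cos(p1), sin(p1)); ep <- c(-sin(p1), cos(p1))
    eps[j, ] <- sqrt(cos(t1)) * (sum(Eb * er) * tht + sum(Eb * ep) * pht)
  }
  # Debye prefactor folded into the amplitudes for consistency with imaging
  eps <- eps * (1i * k / (2 * pi))
  dirs <- cbind(sin(nodes$th) * cos(nodes$phi), sin(nodes$th) * sin(nodes$phi),
                cos(nodes$th))
  pwd <- pw_decomposition(dirs, eps, k = k, w = wts, origin = c(0, 0, 0),
                          k0 = 2 * pi / wavelength)
  if (any(focus != 0)) pwd <- translate_beam(pwd, as.numeric(focus))
  pwd
}

#' Translate a beam laterally (moving the field pattern, not the origin)
#' @param pwd a [pw_decomposition()].
#' @param dr displacement (nm): the field becomes `E(r - dr)`.
#' @return A [pw_decomposition()].
#' @export
translate_beam <- function(pwd, dr) {
  pwd$eps <- pwd$eps * exp(-1i * pwd$k * drop(pwd$dir %*% as.numeric(dr)))
  pwd
}
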