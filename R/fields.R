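# Field representations: far fields (outgoing spherical waves modulated by an
# angular amplitude F(r_hat)) and plane-wave decompositions, together with
# their rigid transforms (rotation, origin shift) and evaluation.
#
# Far fields live on a product quadrature grid: Gauss-Legendre nodes in
# cos(theta) times a uniform (periodic trapezoid) azimuthal grid.  Vector
# amplitudes are stored in Cartesian components so rotations are exact; the
# grid itself is kept in a reference frame and a proper rotation matrix `R`
# maps grid directions to laboratory directions.

#' Direction quadrature grid
#'
#' Gauss-Legendre nodes in `cos(theta)` over the full sphere and a uniform
#' azimuthal grid; weights sum to the full solid angle `4*pi`.
#'
#' @param n_theta,n_phi number of polar and azimuthal nodes (defaults 50, 51).
#' @return list with `theta`, `phi`, `w_theta` (weights for the cos-theta
#'   integral), `w_phi`.
#' @export
direction_grid <- function(n_theta = 50, n_phi = 51) {
  gl <- gauss_legendre(n_theta, -1, 1)
  ord <- order(acos(gl$x))                  # increasing theta
  list(theta = acos(gl$x)[ord], phi = 2 * pi * (seq_len(n_phi) - 1) / n_phi,
       w_theta = gl$w[ord], w_phi = 2 * pi / n_phi)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric
# tridiagonal eigendecomposition).
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1) {
    x <- 0; w <- 2
  } else {
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta
    J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    ord <- order(x)
    x <- x[ord]; w <- w[ord]
  }
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
}

grid_nodes <- function(grid) {
  th <- rep(grid$theta, times = length(grid$phi))
  ph <- rep(grid$phi, each = length(grid$theta))
  list(theta = th, phi = ph,
       dir = cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
       w = rep(grid$w_theta, times = length(grid$phi)) * grid$w_phi)
}

#' Far-field representation
#'
#' An outgoing spherical wave `E(r) = F(r_hat) e^{ikr}/r` sampled on a
#' direction grid, expanded about `origin`.  `amplitude` may be a function
#' `f(dir, theta, phi)` returning an `n x 3` complex matrix of Cartesian
#' amplitudes, or such a matrix directly (node order: theta fastest).
#'
#' @param amplitude far-field amplitude (matrix or function, see above).
#' @param k wavenumber in the embedding medium (`2*pi*n/lambda`, nm^-1);
#'   a scalar, or a per-node vector for fields spanning two media.
#' @param k0 vacuum wavenumber (defaults to `k` assuming vacuum; used to
#'   weight power by the local refractive index).
#' @param grid a [direction_grid()].
#' @param origin expansion center (nm).
#' @return Object of class `farfield`.
#' @export
farfield <- function(amplitude, k, grid = direction_grid(), origin = c(0, 0, 0),
                     k0 = NULL) {
  nodes <- grid_nodes(grid)
  if (is.function(amplitude))
    amplitude <- amplitude(nodes$dir, nodes$theta, nodes$phi)
  amplitude <- matrix(as.complex(amplitude), ncol = 3)
  stopifnot(nrow(amplitude) == nrow(nodes$dir))
  structure(list(grid = grid, E = amplitude, k = k,
                 k0 = if (is.null(k0)) max(Re(k)) else k0,
                 origin = as.numeric(origin), R = diag(3)),
            class = "farfield")
}

#' Laboratory directions of a far field or decomposition
#' @param field a `farfield` or `pwdecomp`.
#' @return `n x 3` matrix of unit direction vectors.
#' @export
field_directions <- function(field) {
  if (inherits(field, "farfield"))
    grid_nodes(field$grid)$dir %*% t(field$R)
  else field$dir
}

#' Quadrature weights of a field representation
#' @param field a `farfield` or `pwdecomp`.
#' @return numeric vector of solid-angle weights (1 for discrete plane waves).
#' @export
field_weights <- function(field) {
  if (inherits(field, "farfield")) grid_nodes(field$grid)$w else field$w
}

#' Plane-wave decomposition
#'
#' A beam represented as `E(r) = sum_j w_j eps_j exp(i k khat_j . (r - origin))`
#' over propagation directions `khat_j`.  A single plane wave is the singleton
#' case with `w = 1`.
#'
#' @param dir `n x 3` unit direction matrix.
#' @param eps `n x 3` complex transverse amplitudes (Cartesian).
#' @param k wavenumber in the host medium (nm^-1).
#' @param w weights (solid-angle quadrature weights, or 1 for discrete waves).
#' @param origin phase reference point (nm).
#' @param k0 vacuum wavenumber (defaults to `k`); sets the magnetic field
#'   scale `H = (k/k0) khat x E`.
#' @return Object of class `pwdecomp`.
#' @export
pw_decomposition <- function(dir, eps, k, w = 1, origin = c(0, 0, 0), k0 = NULL) {
  dir <- matrix(dir, ncol = 3)
  eps <- matrix(as.complex(eps), ncol = 3)
  stopifnot(nrow(dir) == nrow(eps))
  tr <- Mod(rowSums(eps * dir))
  if (any(tr > 1e-9 * (sqrt(rowSums(Mod(eps)^2)) + 1e-300)))
    stop("amplitudes must be transverse to their propagation directions")
  structure(list(dir = dir, eps = eps, k = k, w = rep(w, length.out = nrow(dir)),
                 origin = as.numeric(origin), k0 = if (is.null(k0)) k else k0),
            class = "pwdecomp")
}

#' Single plane wave as a decomposition
#'
#' Resolves the TE/TM (or Jones) polarization of a [plane_wave()] against its
#' plane of incidence and returns the singleton decomposition carrying the
#' amplitude `eps_0` at direction `khat_0`.  The host index fixes the
#' wavenumber `k = 2 pi n / lambda`.
#'
#' @param spec a [plane_wave()].
#' @param n_host refractive index of the host medium.
#' @return A [pw_decomposition()] with one direction.
#' @export
make_planewave <- function(spec, n_host = 1) {
  stopifnot(inherits(spec, "plane_wave_spec"))
  th <- spec$theta * DEG
  b <- pol_basis(sin(th), cos(th), spec$phi * DEG, up = spec$direction == "up")
  eps <- spec$amplitude * (spec$jones[1] * b$s + spec$jones[2] * b$p)
  pw_decomposition(rbind(b$k), rbind(eps), k = 2 * pi * n_host / spec$wavelength,
                   k0 = 2 * pi / spec$wavelength)
}

check_rotation <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) || max(abs(t(R) %*% R - diag(3))) > 1e-10)
    stop("R must be orthogonal")
  if (det(R) < 0) stop("improper rotation (det = -1) rejected")
  R
}

#' Rotate a field representation
#'
#' Rotates both propagation directions and vector amplitudes about the
#' expansion origin; radiated power is unchanged.
#'
#' @param field a `farfield` or `pwdecomp`.
#' @param R proper orthogonal 3x3 matrix.
#' @return Field of the same class.
#' @export
rotate_field <- function(field, R) {
  R <- check_rotation(R)
  if (inherits(field, "farfield")) {
    field$R <- R %*% field$R
    field$E <- field$E %*% t(R)
    attr(field, "amp_fun") <- NULL          # analytic amplitude not composed
  } else {
    field$dir <- field$dir %*% t(R)
    field$eps <- field$eps %*% t(R)
  }
  field
}

#' Shift the expansion origin of a field representation
#'
#' Moves the phase-reference point to `origin + r0` while leaving the physical
#' field unchanged: each far-field amplitude is multiplied by
#' `exp(+i k r_hat . r0)` (plane-wave components by `exp(+i k khat . r0)`).
#' The sign is pinned by the asymptotic re-expansion oracle in the tests:
#' evaluating the shifted far field at fixed physical points reproduces the
#' unshifted field in the radiation zone.  Shifting by `r0` then `-r0`
#' restores the input.
#'
#' @param field a `farfield` or `pwdecomp`.
#' @param r0 displacement of the expansion origin (nm).
#' @return Field of the same class.
#' @export
shift_field <- function(field, r0) {
  r0 <- as.numeric(r0)
  dir <- field_directions(field)
  if (inherits(field, "farfield")) {
    field$E <- field$E * exp(1i * field$k * drop(dir %*% r0))
    af <- attr(field, "amp_fun")
    if (!is.null(af) && length(field$k) == 1) {
      k <- field$k
      attr(field, "amp_fun") <- function(dirs)
        af(dirs) * exp(1i * k * drop(dirs %*% r0))
    }
  } else {
    field$eps <- field$eps * exp(1i * field$k * drop(dir %*% r0))
  }
  field$origin <- field$origin + r0
  field
}

#' Radiated power of a far field
#'
#' Quadrature of the medium-weighted flux `n |F|^2` over the direction grid
#' (arbitrary units consistent across the package; equals the scattering
#' cross section for unit incident amplitude in a uniform host).
#'
#' @param field a `farfield`.
#' @param hemisphere `"all"`, `"up"` or `"down"` (laboratory z > 0 / z < 0).
#' @return non-negative scalar.
#' @export
radiated_power <- function(field, hemisphere = c("all", "up", "down")) {
  hemisphere <- match.arg(hemisphere)
  w <- field_weights(field)
  dirz <- field_directions(field)[, 3]
  sel <- switch(hemisphere, all = TRUE, up = dirz > 0, down = dirz < 0)
  nmed <- Re(field$k) / field$k0
  sum((w * nmed * rowSums(Mod(field$E)^2))[sel])
}

# Bilinear interpolation of the far-field amplitude at arbitrary laboratory
# directions (theta clamped to the grid range, phi periodic).
farfield_interp <- function(field, dirs) {
  dg <- dirs %*% field$R                     # into grid frame (R^T on rows)
  th <- acos(pmin(1, pmax(-1, dg[, 3])))
  ph <- atan2(dg[, 2], dg[, 1]) %% (2 * pi)
  gt <- field$grid$theta; gp <- field$grid$phi
  nt <- length(gt); np <- length(gp)
  it <- findInterval(th, gt, all.inside = TRUE)
  ft <- (th - gt[it]) / (gt[it + 1] - gt[it])
  ft <- pmin(1, pmax(0, ft))
  dphi <- 2 * pi / np
  ip <- floor(ph / dphi) + 1
  fp <- ph / dphi - (ip - 1)
  ip2 <- ip %% np + 1
  idx <- function(i_t, i_p) (i_p - 1) * nt + i_t
  out <- matrix(0i, length(th), 3)
  for (c3 in 1:3) {
    v <- field$E[, c3]
    out[, c3] <-
      (1 - ft) * (1 - fp) * v[idx(it, ip)] +
      ft * (1 - fp) * v[idx(it + 1, ip)] +
      (1 - ft) * fp * v[idx(it, ip2)] +
      ft * fp * v[idx(it + 1, ip2)]
  }
  kk <- if (length(field$k) > 1) {
    kv <- field$k
    kv[idx(it, ip)]                          # k constant per hemisphere
  } else field$k
  list(F = out, k = kk)
}

#' Evaluate a far field at positions
#'
#' `E(r) = F(r_hat) e^{ikr} / r` with `r`, `r_hat` taken relative to the
#' expansion origin and the amplitude looked up by bilinear interpolation on
#' the `(theta, phi)` grid.  Physically meaningful only in the radiation zone
#' (`|r - origin| >> lambda`); no check is enforced.
#'
#' @param field a `farfield`.
#' @param points `n x 3` matrix of positions (nm).
#' @return `n x 3` complex matrix of field values.
#' @export
evaluate_farfield <- function(field, points) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, field$origin)
  r <- sqrt(rowSums(rel^2))
  if (any(r == 0)) stop("cannot evaluate a far field at its origin")
  dirs <- rel / r
  fi <- farfield_interp(field, dirs)
  fi$F * exp(1i * fi$k * r) / r
}

#' Evaluator for a plane-wave decomposition
#'
#' @param pwd a [pw_decomposition()].
#' @return `function(points)` returning `list(E, H)`; plane-wave components
#'   attached as attribute `"components"` (as in [incident_field()]).
#' @export
pwd_field <- function(pwd) {
  comps <- lapply(seq_len(nrow(pwd$dir)), function(j) {
    kvec <- pwd$k * pwd$dir[j, ]
    list(kvec = kvec,
         E = pwd$w[j] * pwd$eps[j, ] * exp(-1i * sum(kvec * pwd$origin)))
  })
  planewave_sum_evaluator(comps, k0 = pwd$k0)
}

#' Beam power carried by a plane-wave decomposition
#'
#' For quadrature decompositions, `sum w n |eps|^2 cos(theta)`-free convention:
#' power through a plane transverse to each component is proportional to
#' `n |eps|^2`; this helper reports `sum(w * n * |eps|^2)` with `n = k/k0`
#' absorbed into `k` (host index supplied by the caller at construction).
#'
#' @param pwd a [pw_decomposition()].
#' @return scalar.
#' @export
pwd_power <- function(pwd) sum(pwd$w * rowSums(Mod(pwd$eps)^2))
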