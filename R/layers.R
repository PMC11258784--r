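# Materials, planar layer stacks, Fresnel coefficients and incident fields.
#
# Conventions used throughout the package (fixed once, enforced in tests):
#  * time dependence e^{-i w t}; a plane wave propagating upward is e^{+ikz};
#  * the (top) interface of the layer stack sits at z = 0, z increases upward,
#    the uppermost medium is the sample medium and the lowermost the substrate;
#  * lengths in nm, angles in degrees at the API surface (radians internally);
#  * fields are dimensionless, relative to a unit incident amplitude;
#  * passive media have Im(permittivity) >= 0.

DEG <- pi / 180

#' Optical material
#'
#' A material is defined by its complex relative permittivity as a function of
#' vacuum wavelength, either constant (via a refractive index or permittivity)
#' or linearly interpolated from a table of `(wavelength_nm, n, k)` values.
#' Relative permeability is fixed at 1.
#'
#' @param name label for the material.
#' @param index constant (possibly complex) refractive index `n + ik`.
#' @param permittivity constant complex relative permittivity (alternative to
#'   `index`).
#' @param table data frame or CSV path with columns `wavelength_nm`, `n`, `k`;
#'   queried only inside the tabulated wavelength range.
#' @return An object of class `material` with a `$permittivity(wavelength)`
#'   accessor.
#' @export
material <- function(name, index = NULL, permittivity = NULL, table = NULL) {
  if (!is.null(table)) {
    if (is.character(table)) table <- utils::read.csv(table, comment.char = "#")
    stopifnot(all(c("wavelength_nm", "n", "k") %in% names(table)))
    tab <- table[order(table$wavelength_nm), ]
    if (any(tab$k < 0)) stop("passive media require k >= 0")
    eps_fun <- function(wavelength) {
      if (any(wavelength < min(tab$wavelength_nm) - 1e-9) ||
          any(wavelength > max(tab$wavelength_nm) + 1e-9)) {
        stop(sprintf("wavelength outside table range [%g, %g] nm for material '%s'",
                     min(tab$wavelength_nm), max(tab$wavelength_nm), name))
      }
      n <- stats::approx(tab$wavelength_nm, tab$n, wavelength, rule = 1)$y
      k <- stats::approx(tab$wavelength_nm, tab$k, wavelength, rule = 1)$y
      (n + 1i * k)^2
    }
  } else {
    if (is.null(permittivity)) {
      if (is.null(index)) stop("give one of index, permittivity, table")
      permittivity <- as.complex(index)^2
    }
    permittivity <- as.complex(permittivity)
    if (Im(permittivity) < 0) stop("passive media require Im(permittivity) >= 0")
    eps_fun <- function(wavelength) rep(permittivity, length(wavelength))
  }
  structure(list(name = name, permittivity = eps_fun, permeability = 1),
            class = "material")
}

#' Built-in materials
#'
#' Constant-index media (`"air"`, `"water"`, `"glass"`, `"ps"` polystyrene)
#' and the bundled gold/silver optical-constant tables (`"Au"`, `"Ag"`).
#' The metal tables are approximate transcriptions of the standard published
#' compilation of measured optical constants (Johnson & Christy); see the
#' files under `inst/extdata` for the precision caveat.
#'
#' @param name one of `"air"`, `"water"`, `"glass"`, `"ps"`, `"Au"`, `"Ag"`.
#' @return A [material()].
#' @export
material_db <- function(name) {
  consts <- c(air = 1.0, water = 1.33, glass = 1.5, ps = 1.59)
  if (name %in% names(consts)) return(material(name, index = consts[[name]]))
  file <- switch(name,
    Au = "au_optical_constants_approx.csv",
    Ag = "ag_optical_constants_approx.csv",
    stop("unknown material: ", name))
  material(name, table = system.file("extdata", file, package = "iscatsim",
                                     mustWork = TRUE))
}

#' Refractive index of a material
#' @param mat a [material()].
#' @param wavelength vacuum wavelength in nm.
#' @return Complex refractive index with `Im >= 0`.
#' @export
refractive_index <- function(mat, wavelength) {
  eps <- mat$permittivity(wavelength)
  n <- sqrt(eps)
  ifelse(Im(n) < 0, -n, n)
}

#' Planar layer stack
#'
#' Ordered planar media, listed from top (sample side) to bottom (substrate
#' side), separated by horizontal interfaces at strictly decreasing positions
#' `interface_z` (nm).  The default single-interface convention places the
#' interface at z = 0 with the upper medium being the sample medium.
#'
#' @param materials list of [material()], ordered top to bottom (at least 2).
#' @param interface_z interface positions in nm, strictly decreasing; length
#'   `length(materials) - 1`. Defaults place the top interface at 0.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(materials, interface_z = NULL) {
  stopifnot(length(materials) >= 2)
  if (is.null(interface_z)) {
    if (length(materials) != 2)
      stop("interface_z must be given for more than two media")
    interface_z <- 0
  }
  if (length(interface_z) != length(materials) - 1)
    stop("count(interface_z) must equal count(materials) - 1")
  if (length(interface_z) > 1 && any(diff(interface_z) >= 0))
    stop("interface_z must be strictly decreasing (top to bottom)")
  structure(list(materials = materials, interface_z = as.numeric(interface_z)),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("layer stack (top to bottom):\n")
  z <- c(Inf, x$interface_z, -Inf)
  for (i in seq_along(x$materials))
    cat(sprintf("  %-8s  z in (%g, %g] nm\n", x$materials[[i]]$name, z[i + 1], z[i]))
  invisible(x)
}

stack_indices <- function(stack, wavelength) {
  vapply(stack$materials, function(m) refractive_index(m, wavelength),
         complex(1))
}

# Interface Fresnel coefficients for a single interface n1 -> n2 with the
# cosines c1, c2 on either side.  The TM reflection sign is chosen so that
# r_TM -> (n1 - n2)/(n1 + n2) at normal incidence, co-oriented with TE
# (textbooks differ here; this convention is asserted in the tests).
fresnel_interface <- function(n1, c1, n2, c2, pol) {
  if (pol == "TE") {
    d <- n1 * c1 + n2 * c2
    list(r = (n1 * c1 - n2 * c2) / d, t = 2 * n1 * c1 / d)
  } else {
    d <- n1 * c2 + n2 * c1
    list(r = (n1 * c2 - n2 * c1) / d, t = 2 * n1 * c1 / d)
  }
}

# Cosine of the propagation angle in medium n for conserved transverse
# wavevector kx (in units of k0): cos = sqrt(1 - (kx/n)^2), principal branch
# with Im(n cos) >= 0 so that evanescent waves decay along propagation.
snell_cos <- function(n, kx0) {
  nc <- sqrt(n^2 - kx0^2 + 0i)
  nc <- ifelse(Im(nc) < 0 | (Im(nc) == 0 & Re(nc) < 0), -nc, nc)
  nc / n
}

#' Fresnel reflection and transmission of a layer stack
#'
#' Amplitude coefficients for a plane wave hitting the stack, computed with the
#' standard transfer-matrix recursion; for a single interface they reduce to
#' the two-media Fresnel formulas.  Angles beyond the critical angle yield
#' evanescent transmitted waves (complex cosine, principal branch with
#' `Im >= 0`).
#'
#' @param stack a [layer_stack()].
#' @param theta incidence angle in degrees, measured in the incidence-side
#'   medium.
#' @param pol `"TE"` or `"TM"`.
#' @param wavelength vacuum wavelength in nm.
#' @param from `"top"` (wave travelling downward onto the stack) or
#'   `"bottom"` (upward, the iSCAT illumination side).
#' @return list with complex `r` and `t`; `t` is the field amplitude in the
#'   exit medium referenced to the exit interface.
#' @export
fresnel <- function(stack, theta, pol = c("TE", "TM"), wavelength,
                    from = c("top", "bottom")) {
  pol <- match.arg(pol)
  from <- match.arg(from)
  n_all <- stack_indices(stack, wavelength)
  z_all <- stack$interface_z
  if (from == "bottom") {
    n_all <- rev(n_all)
    z_all <- rev(z_all)
  }
  if (abs(Im(n_all[1])) > 1e-12 && abs(theta) > 1e-12)
    stop("absorbing incidence medium at nonzero angle: incidence angle ill-defined")
  kx0 <- Re(n_all[1]) * sin(theta * DEG)         # kx / k0, conserved
  fresnel_core(n_all, z_all, kx0, pol, 2 * pi / wavelength)
}

# Transfer-matrix recursion for ordered media n_all with interfaces z_all
# (in propagation order) at conserved transverse wavevector kx0 (units of k0,
# may exceed the incidence index: evanescent drive, used by the far-field
# interface correction).
fresnel_core <- function(n_all, z_all, kx0, pol, k0) {
  L <- length(n_all)
  cosv <- snell_cos(n_all, kx0)
  M <- diag(2) + 0i
  for (j in seq_len(L - 1)) {
    if (j > 1) {                                  # propagation through layer j
      d <- abs(z_all[j] - z_all[j - 1])
      beta <- k0 * n_all[j] * cosv[j] * d
      M <- M %*% diag(c(exp(-1i * beta), exp(1i * beta)))
    }
    fc <- fresnel_interface(n_all[j], cosv[j], n_all[j + 1], cosv[j + 1], pol)
    M <- M %*% (matrix(c(1, fc$r, fc$r, 1), 2, 2) / fc$t)
  }
  list(r = M[2, 1] / M[1, 1], t = 1 / M[1, 1])
}

#' Brewster angle
#'
#' TM incidence angle of vanishing reflection at an interface between two
#' lossless media: `atan(n_out / n_in)`, in degrees.  At this angle the iSCAT
#' reference beam is suppressed, turning the microscope into a dark-field
#' instrument; small deviations tune the reference amplitude continuously.
#'
#' @param n_in,n_out real positive refractive indices on the incidence and
#'   exit side.
#' @return Angle in degrees.
#' @export
brewster_angle <- function(n_in, n_out) {
  if (!is.numeric(n_in) || !is.numeric(n_out) || n_in <= 0 || n_out <= 0)
    stop("indices must be real and positive")
  atan2(n_out, n_in) / DEG
}

#' Plane-wave specification
#'
#' @param wavelength vacuum wavelength in nm.
#' @param theta signed polar angle in degrees from the +z axis (anticlockwise
#'   positive in the plane of incidence), `|theta| < 90`.
#' @param phi azimuth of the plane of incidence in degrees.
#' @param polarization `"TE"`, `"TM"`, or a complex Jones vector `c(s, p)`
#'   (normalized to unit magnitude).
#' @param direction `"up"` (iSCAT illumination, from the substrate side) or
#'   `"down"` (COBRI, from the sample side).
#' @param amplitude complex scalar amplitude.
#' @return An object of class `plane_wave_spec`.
#' @export
plane_wave <- function(wavelength, theta = 0, phi = 0, polarization = "TM",
                       direction = c("up", "down"), amplitude = 1) {
  direction <- match.arg(direction)
  if (abs(theta) >= 90) stop("|theta| must be < 90 degrees")
  if (is.character(polarization)) {
    polarization <- match.arg(polarization, c("TE", "TM"))
    jones <- if (polarization == "TE") c(1, 0) else c(0, 1)
  } else {
    jones <- as.complex(polarization)
    if (length(jones) != 2) stop("Jones vector must have length 2 (s, p)")
    nrm <- sqrt(sum(Mod(jones)^2))
    if (abs(nrm - 1) > 1e-9) stop("Jones vector must be normalized to unit magnitude")
  }
  structure(list(wavelength = wavelength, theta = theta, phi = phi,
                 jones = jones, direction = direction,
                 amplitude = as.complex(amplitude)),
            class = "plane_wave_spec")
}

# Unit vectors of the plane-of-incidence basis for a signed polar angle.
# s_hat is fixed by the azimuth (continuous through theta = 0); p_hat =
# s_hat x k_hat lies in the plane of incidence.  Works for complex cos(theta)
# (evanescent continuation) as well.
pol_basis <- function(sin_t, cos_t, phi_rad, up = TRUE) {
  sz <- if (up) 1 else -1
  khat <- c(sin_t * cos(phi_rad), sin_t * sin(phi_rad), sz * cos_t)
  shat <- c(-sin(phi_rad), cos(phi_rad), 0)
  phat <- c(shat[2] * khat[3] - shat[3] * khat[2],
            shat[3] * khat[1] - shat[1] * khat[3],
            shat[1] * khat[2] - shat[2] * khat[1])
  list(k = khat, s = shat, p = phat)
}

# A driving field as a finite sum of plane waves: components is a list of
# list(kvec, E) with kvec the full (complex) wavevector in nm^-1 and E the
# complex amplitude vector.  H = (k x E)/k0 under e^{-iwt} Gaussian units.
planewave_sum_evaluator <- function(components, k0) {
  force(components); force(k0)
  f <- function(points) {
    points <- matrix(points, ncol = 3)
    n <- nrow(points)
    E <- matrix(0i, n, 3)
    H <- matrix(0i, n, 3)
    for (cmp in components) {
      ph <- exp(1i * (points %*% cmp$kvec))
      E <- E + ph %*% t(cmp$E)
      Hc <- c(cmp$kvec[2] * cmp$E[3] - cmp$kvec[3] * cmp$E[2],
              cmp$kvec[3] * cmp$E[1] - cmp$kvec[1] * cmp$E[3],
              cmp$kvec[1] * cmp$E[2] - cmp$kvec[2] * cmp$E[1]) / k0
      H <- H + ph %*% t(Hc)
    }
    list(E = E, H = H)
  }
  attr(f, "components") <- components
  attr(f, "k0") <- k0
  f
}

#' Total driving field of a plane wave hitting a layer stack
#'
#' Builds the total monochromatic field in the requested region: incident plus
#' reflected plane waves on the incidence side, the transmitted wave on the
#' far side, with Snell-refracted wavevectors and phases referenced to the
#' interfaces (top interface at z = 0).  For iSCAT the primary wave impinges
#' from below (`direction = "up"`); for COBRI from above (`"down"`).
#'
#' @param stack a [layer_stack()].
#' @param wave a [plane_wave()].
#' @param region `"above"` (sample side, top medium) or `"below"` (substrate
#'   side, bottom medium); on an interface the field is the limit from the
#'   requested region.
#' @return A field evaluator `function(points)` returning `list(E, H)` for an
#'   `n x 3` matrix of positions (nm); the plane-wave components are attached
#'   as attribute `"components"`.
#' @export
incident_field <- function(stack, wave, region = c("above", "below")) {
  region <- match.arg(region)
  stopifnot(inherits(wave, "plane_wave_spec"))
  up <- wave$direction == "up"
  n_all <- stack_indices(stack, wave$wavelength)
  z_all <- stack$interface_z
  # propagation-ordered media: first = incidence medium
  n_seq <- if (up) rev(n_all) else n_all
  z_seq <- if (up) rev(z_all) else z_all
  k0 <- 2 * pi / wave$wavelength
  th <- wave$theta * DEG
  phr <- wave$phi * DEG
  kx0 <- Re(n_seq[1]) * sin(th)
  c_in <- snell_cos(n_seq[1], kx0)
  c_out <- snell_cos(n_seq[length(n_seq)], kx0)
  fr_s <- fresnel(stack, wave$theta, "TE", wave$wavelength,
                  from = if (up) "bottom" else "top")
  fr_p <- fresnel(stack, wave$theta, "TM", wave$wavelength,
                  from = if (up) "bottom" else "top")
  a_s <- wave$amplitude * wave$jones[1]
  a_p <- wave$amplitude * wave$jones[2]
  z_first <- if (up) z_seq[length(z_seq)] else z_seq[1]   # first interface hit
  z_last  <- if (up) z_seq[1] else z_seq[length(z_seq)]   # exit interface
  on_incidence_side <- (region == "below") == up
  comps <- list()
  if (on_incidence_side) {
    n1 <- n_seq[1]
    b_inc <- pol_basis(sin(th), c_in, phr, up = up)
    b_ref <- pol_basis(sin(th), c_in, phr, up = !up)
    k_inc <- k0 * n1 * b_inc$k
    k_ref <- k0 * n1 * b_ref$k
    ph_ref <- function(kz) exp(-1i * kz * z_first)  # reference plane z_first
    E_inc <- a_s * b_inc$s + a_p * b_inc$p
    # reflected TM basis is -p_hat(k_ref): with our r_TM sign convention
    # (co-oriented with TE at normal incidence) this is what makes the
    # tangential fields continuous across the interface
    E_ref <- fr_s$r * a_s * b_ref$s - fr_p$r * a_p * b_ref$p
    comps <- list(
      list(kvec = k_inc, E = E_inc * ph_ref(k_inc[3]), role = "incident"),
      list(kvec = k_ref, E = E_ref * ph_ref(k_ref[3]), role = "reflected"))
  } else {
    nL <- n_seq[length(n_seq)]
    sin_out <- kx0 / nL                             # Snell, possibly complex
    b_out <- pol_basis(sin_out, c_out, phr, up = up)
    k_out <- k0 * nL * b_out$k
    E_out <- fr_s$t * a_s * b_out$s + fr_p$t * a_p * b_out$p
    comps <- list(list(kvec = k_out, E = E_out * exp(-1i * k_out[3] * z_last),
                       role = "transmitted"))
  }
  planewave_sum_evaluator(comps, k0)
}
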