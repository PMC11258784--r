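# Assembly of full interference-microscopy images: iSCAT (illumination from
# below, reflected reference), COBRI (illumination from above, transmitted
# reference) and dark-field (reference blocked in the back focal plane).
# The camera records |E'_ref + E'_sca|^2; both beams pass the identical
# imaging chain (detection along -z, mapped onto the imaging +z axis by a
# 180-degree rotation about x applied to reference and scattered fields
# alike, so their relative geometry and phase are preserved).

#' Microscope configuration
#'
#' @param modality `"iscat"`, `"cobri"` or `"darkfield"`.
#' @param stack a [layer_stack()] (top interface at z = 0, sample medium on
#'   top, substrate below; the detection side).
#' @param illumination a [plane_wave()] (direction `"up"` for iSCAT and
#'   dark-field, `"down"` for COBRI) or a focused-beam spec
#'   `list(focused = TRUE, wavelength =, profile =, n_theta =, n_phi =)` for
#'   scanning.
#' @param train an [optical_train()]; its object-side index must match the
#'   substrate (detection) medium.
#' @param scatterer scatterer spec: `list(engine = "dipole"|"mie"|"bem", ...)`
#'   with `position` (nm, center above the interface), and either `alpha`
#'   (dipole polarizability, nm^3) or `diameter` + `material` (a
#'   [material()] or [material_db()] name); for `engine = "bem"` optionally
#'   an explicit `mesh` ([tri_mesh()] or list) and `frequency`.  `NULL` for
#'   an empty sample.
#' @param fov,npix image field of view (object-referred nm) and pixels.
#' @param n_theta,n_phi far-field direction grid.
#' @param imaging_method `"bessel"` (default; the analytic azimuthal
#'   integration is free of the large-radius artifacts of the direct
#'   quadrature at coarse azimuthal sampling) or `"direct"`.
#' @param normalized_contrast default contrast mode for [iscat_contrast()].
#' @param seed integer seed for stochastic additions (detector noise).
#' @return Object of class `microscope_config`.
#' @export
microscope_config <- function(modality = c("iscat", "cobri", "darkfield"),
                              stack, illumination, train, scatterer = NULL,
                              fov = 3000, npix = 61, n_theta = 50, n_phi = 51,
                              imaging_method = c("bessel", "direct"),
                              normalized_contrast = FALSE, seed = 1L) {
  modality <- match.arg(modality)
  imaging_method <- match.arg(imaging_method)
  if (inherits(illumination, "plane_wave_spec")) {
    want <- if (modality == "cobri") "down" else "up"
    if (illumination$direction != want)
      stop(sprintf("%s requires illumination direction '%s'", modality, want))
  }
  structure(list(modality = modality, stack = stack,
                 illumination = illumination, train = train,
                 scatterer = scatterer, fov = fov, npix = npix,
                 n_theta = n_theta, n_phi = n_phi,
                 imaging_method = imaging_method,
                 normalized_contrast = normalized_contrast,
                 seed = as.integer(seed)),
            class = "microscope_config")
}

scatterer_eps <- function(sc, wavelength) {
  mat <- sc$material
  if (is.character(mat)) mat <- material_db(mat)
  mat$permittivity(wavelength)
}

# Scattered far field about the interface origin (after the far-field
# interface correction), for the engine selected in the scatterer spec.
scattered_farfield <- function(cfg, drive, wavelength) {
  sc <- cfg$scatterer
  grid <- direction_grid(cfg$n_theta, cfg$n_phi)
  n_top <- Re(refractive_index(cfg$stack$materials[[1]], wavelength))
  k0 <- 2 * pi / wavelength
  if (is.null(sc)) {
    return(farfield(matrix(0i, cfg$n_theta * cfg$n_phi, 3), k = k0 * n_top,
                    grid = grid, k0 = k0))
  }
  eps_top <- n_top^2
  pos <- sc$position
  if (is.null(pos)) stop("scatterer position required")
  switch(sc$engine,
    dipole = {
      alpha <- sc$alpha
      if (is.null(alpha))
        alpha <- polarizability_sphere(sc$diameter, scatterer_eps(sc, wavelength),
                                       eps_top, radiative_correction = TRUE,
                                       wavelength = wavelength)
      dip <- dipole_scatterer(pos, alpha, eps_top)
      dipole_farfield_dip2(dip, drive, cfg$stack, wavelength, grid)
    },
    mie = {
      comps <- attr(drive, "components")
      ff <- NULL
      for (cmp in comps) {
        kn <- sqrt(sum(Re(cmp$kvec)^2 + 0i))
        if (abs(Im(sum(cmp$kvec^2))) > 1e-9 * Mod(kn)^2) next  # evanescent drive
        f1 <- mie_farfield(sc$diameter, scatterer_eps(sc, wavelength), eps_top,
                           drive = list(dir = Re(cmp$kvec) / Re(kn), eps = cmp$E),
                           wavelength = wavelength, grid = grid, center = pos)
        ff <- if (is.null(ff)) f1 else add_farfields(ff, f1)
      }
      interface_correct(ff, cfg$stack, wavelength)
    },
    bem = {
      mesh <- sc$mesh
      if (is.null(mesh))
        mesh <- icosphere(sc$diameter, frequency = sc$frequency %||% 4,
                          center = pos)
      sol <- bem_solve(mesh, scatterer_eps(sc, wavelength), eps_top, drive,
                       wavelength, max_elements = sc$max_elements %||% 10000)
      ff <- bem_farfield(sol, grid)
      ff <- shift_field(ff, pos)        # re-expand about the particle center
      interface_correct(ff, cfg$stack, wavelength)
    },
    stop("unknown scattering engine: ", sc$engine))
}

add_farfields <- function(a, b) {
  stopifnot(max(abs(a$origin - b$origin)) < 1e-9)
  fa <- attr(a, "amp_fun"); fb <- attr(b, "amp_fun")
  a$E <- a$E + b$E
  if (!is.null(fa) && !is.null(fb))
    attr(a, "amp_fun") <- function(dirs) fa(dirs) + fb(dirs)
  else attr(a, "amp_fun") <- NULL
  a
}

reference_pwd <- function(cfg, wavelength) {
  wave <- cfg$illumination
  below <- incident_field(cfg$stack, wave, "below")
  comps <- attr(below, "components")
  role <- if (cfg$modality == "cobri") "transmitted" else "reflected"
  cmp <- Filter(function(c) c$role == role, comps)
  if (length(cmp) == 0) stop("no ", role, " reference component")
  cmp <- cmp[[1]]
  kn <- sqrt(sum(Re(cmp$kvec)^2))
  pw_decomposition(rbind(Re(cmp$kvec) / kn), rbind(cmp$E), k = kn, w = 1,
                   origin = c(0, 0, 0), k0 = 2 * pi / wavelength)
}

ROT_DETECT <- diag(c(1, -1, -1))   # detection axis -z mapped to imaging +z

#' Simulate a full interference-microscopy image
#'
#' Runs the whole pipeline at one focal-plane position: total driving field
#' above the stack, scattered far field (selected engine plus the far-field
#' interface correction), reference beam (reflected for iSCAT, transmitted
#' for COBRI), rotation into imaging coordinates and origin shift to the
#' focal plane, Richards-Wolf imaging of both beams, and the camera
#' superposition `|E'_ref + E'_sca|^2`.
#'
#' @param cfg a [microscope_config()].
#' @param z_foc focal-plane position (nm, relative to the interface;
#'   positive into the sample medium).
#' @return list with `camera`, `ref`, `sca` (`camera_image` objects) and
#'   `z_foc`.
#' @export
simulate_image <- function(cfg, z_foc = 0) {
  wave <- cfg$illumination
  stopifnot(inherits(wave, "plane_wave_spec"))
  wavelength <- wave$wavelength
  n_bot <- Re(refractive_index(
    cfg$stack$materials[[length(cfg$stack$materials)]], wavelength))
  if (abs(cfg$train$n - n_bot) > 1e-9)
    stop("train object-side index must match the substrate (detection) medium")
  drive <- incident_field(cfg$stack, wave, "above")
  f_sca <- scattered_farfield(cfg, drive, wavelength)
  ref <- reference_pwd(cfg, wavelength)
  if (cfg$modality == "darkfield") {
    thr <- acos(abs(ref$dir[1, 3]))
    if (is.null(cfg$train$bfp))
      stop("dark-field requires a back-focal-plane block covering the reference beam")
    J <- cfg$train$bfp(thr, atan2(-ref$dir[1, 2], ref$dir[1, 1]))
    if (max(Mod(J)) > 1e-12)
      stop("dark-field back-focal-plane transform does not block the reference beam")
  }
  shift_img <- c(0, 0, -z_foc)
  f_img <- shift_field(rotate_field(f_sca, ROT_DETECT), shift_img)
  r_img <- shift_field(rotate_field(ref, ROT_DETECT), shift_img)
  grid <- image_grid(cfg$fov, cfg$npix)
  cam_sca <- if (cfg$imaging_method == "bessel")
    image_farfield_bessel(f_img, cfg$train, grid)
  else image_farfield(f_img, cfg$train, grid)
  cam_ref <- image_pwd(r_img, cfg$train, grid)
  tot <- camera_image(cam_ref$E + cam_sca$E, grid, cfg$train)
  list(camera = tot, ref = cam_ref, sca = cam_sca, z_foc = z_foc)
}

#' Interferometric contrast and phase map
#'
#' Background-subtracted interference `|E'_tot|^2 - |E'_ref|^2` per pixel
#' (optionally normalized by `|E'_ref|^2`), together with the phase map
#' `phi = arg(E'_ref . conj(E'_sca))` between reference and scattered fields.
#'
#' @param camera,ref `camera_image` objects on identical grids (from
#'   [simulate_image()]).
#' @param normalized divide by the reference intensity (rejected when the
#'   reference is dark).
#' @return Object of class `contrast_map` with `values`, `phase`, `x`, `y`.
#' @export
iscat_contrast <- function(camera, ref, normalized = FALSE) {
  stopifnot(identical(camera$x, ref$x), identical(camera$y, ref$y))
  values <- camera$intensity - ref$intensity
  if (normalized) {
    if (min(ref$intensity) < 1e-12 * max(camera$intensity))
      stop("normalized contrast undefined for a dark reference; use the raw map")
    values <- values / ref$intensity
  }
  Esca <- camera$E - ref$E
  ph <- matrix(Arg(rowSums(ref$E * Conj(Esca))), length(camera$x),
               length(camera$y))
  structure(list(values = values, phase = ph, x = camera$x, y = camera$y,
                 normalized = normalized),
            class = "contrast_map")
}

#' Interferometric point spread function
#'
#' Contrast map of a point-dipole scatterer: the iPSF of interferometric
#' microscopy.  Convenience wrapper over [simulate_image()] +
#' [iscat_contrast()] requiring the dipole engine.
#'
#' @param cfg a [microscope_config()] with a dipole scatterer.
#' @param z_foc focal-plane position (nm).
#' @param normalized contrast normalization.
#' @return A `contrast_map`.
#' @export
ipsf <- function(cfg, z_foc = 0, normalized = cfg$normalized_contrast) {
  if (is.null(cfg$scatterer) || cfg$scatterer$engine != "dipole")
    stop("ipsf requires a point-dipole scatterer")
  sim <- simulate_image(cfg, z_foc)
  iscat_contrast(sim$camera, sim$ref, normalized)
}

#' Michelson contrast of an intensity image
#'
#' `(I_max - I_min) / (I_max + I_min)`, bounded in `[0, 1]`.
#'
#' @param image a `camera_image` or a non-negative intensity matrix.
#' @return scalar in `[0, 1]`.
#' @export
michelson_contrast <- function(image) {
  I <- if (inherits(image, "camera_image")) image$intensity else image
  if (any(I < 0)) stop("intensity image must be non-negative")
  if (max(I) == 0) stop("all-zero image has no defined contrast")
  (max(I) - min(I)) / (max(I) + min(I))
}

#' Sweep the illumination angle around the Brewster angle
#'
#' Simulates TM-illuminated images over a set of incidence angles; at the
#' Brewster angle the reflected reference vanishes and the image becomes a
#' dark-field image, and for small deviations the reference magnitude (and
#' with it the Michelson contrast of the raw image) is tuned continuously.
#'
#' @param cfg a [microscope_config()] with TM illumination.
#' @param angles incidence angles in degrees (measured in the incidence
#'   medium).
#' @param z_foc focal-plane position (nm).
#' @return data frame with `angle`, `michelson`, `ref_power`; images in
#'   attribute `"images"`.
#' @export
brewster_sweep <- function(cfg, angles, z_foc = 0) {
  if (max(Mod(cfg$illumination$jones - c(0, 1))) > 1e-12)
    stop("Brewster sweep requires TM illumination (no TE Brewster zero)")
  res <- lapply(angles, function(a) {
    cfg$illumination$theta <- a
    sim <- simulate_image(cfg, z_foc)
    list(m = michelson_contrast(sim$camera),
         rp = sum(sim$ref$intensity), sim = sim)
  })
  out <- data.frame(angle = angles,
                    michelson = vapply(res, `[[`, 0, "m"),
                    ref_power = vapply(res, `[[`, 0, "rp"))
  attr(out, "images") <- lapply(res, `[[`, "sim")
  out
}

#' Focal stack of simulated images
#' @param cfg a [microscope_config()].
#' @param z_list focal-plane positions (nm).
#' @param what `"contrast"` (background-subtracted values) or `"camera"`
#'   (raw intensity).
#' @return list of `list(z, image)` with matrices.
#' @export
focal_stack <- function(cfg, z_list, what = c("contrast", "camera")) {
  what <- match.arg(what)
  lapply(z_list, function(z) {
    sim <- simulate_image(cfg, z)
    img <- if (what == "contrast")
      iscat_contrast(sim$camera, sim$ref, cfg$normalized_contrast)$values
    else sim$camera$intensity
    list(z = z, image = img)
  })
}

#' Focus estimation by image correlation
#'
#' Two-dimensional Pearson correlation between each simulated focal slice and
#' a query image; the estimated focus is the slice of highest correlation
#' (ties broken toward the smallest `|z|`).
#'
#' @param sim_stack a [focal_stack()] result (list of `list(z, image)`).
#' @param query image matrix on the same grid.
#' @return list with `z_best` and the correlation `curve` (data frame).
#' @export
focus_correlate <- function(sim_stack, query) {
  qv <- as.vector(query)
  if (stats::sd(qv) == 0) stop("query image has zero variance")
  cors <- vapply(sim_stack, function(s) {
    sv <- as.vector(s$image)
    if (stats::sd(sv) == 0) stop("stack slice has zero variance")
    stats::cor(sv, qv)
  }, 0)
  zs <- vapply(sim_stack, `[[`, 0, "z")
  best <- which(cors == max(cors))
  if (length(best) > 1) best <- best[which.min(abs(zs[best]))]
  list(z_best = zs[best], curve = data.frame(z = zs, correlation = cors))
}

#' Partial longitudinal coherence
#'
#' Weighted incoherent sum of the per-wavelength image intensities, emulating
#' excitation with a source of limited longitudinal coherence (the weights
#' sample the source spectrum and must be normalized to 1).
#'
#' @param cfg a [microscope_config()].
#' @param wavelengths vacuum wavelengths (nm).
#' @param weights non-negative spectral weights summing to 1.
#' @param z_foc focal-plane position (nm).
#' @return list with `intensity` (matrix), `x`, `y`.
#' @export
partial_coherence <- function(cfg, wavelengths, weights, z_foc = 0) {
  if (length(wavelengths) == 0) stop("empty spectrum")
  if (length(weights) != length(wavelengths) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  I <- NULL
  for (j in seq_along(wavelengths)) {
    cfg$illumination$wavelength <- wavelengths[j]
    sim <- simulate_image(cfg, z_foc)
    I <- if (is.null(I)) weights[j] * sim$camera$intensity
    else I + weights[j] * sim$camera$intensity
  }
  list(intensity = I, x = seq(-cfg$fov / 2, cfg$fov / 2, length.out = cfg$npix),
       y = seq(-cfg$fov / 2, cfg$fov / 2, length.out = cfg$npix))
}

#' Confocal scanning image
#'
#' iSCAT in a scanning geometry: the focused excitation (built with
#' [focus_beam()] in the substrate and split at the interface into the
#' transmitted driving beam and the reflected descanned reference) is
#' translated across the sample; at each position the scattering is
#' recomputed and the detected signal is the camera intensity summed over a
#' pinhole of one Airy-unit radius centered on the (descanned) excitation.
#'
#' @param cfg a [microscope_config()] with a dipole or Mie scatterer.
#' @param scan_x,scan_y scan positions (nm).
#' @param pinhole_radius pinhole radius in object-referred nm (default one
#'   Airy unit `0.61 lambda / NA`).
#' @param n_theta,n_phi cone quadrature of the focused beam.
#' @return matrix of detected signals, `length(scan_x) x length(scan_y)`.
#' @export
scan_image <- function(cfg, scan_x, scan_y, pinhole_radius = NULL,
                       n_theta = 12, n_phi = 16) {
  ill <- cfg$illumination
  if (!is.list(ill) || !isTRUE(ill$focused))
    stop("scan_image requires a focused illumination spec (focused = TRUE)")
  if (!is.null(cfg$scatterer) && cfg$scatterer$engine == "bem")
    warning("BEM scatterer in scanning mode is slow; dipole or Mie recommended",
            call. = FALSE)
  wavelength <- ill$wavelength
  if (is.null(pinhole_radius))
    pinhole_radius <- 0.61 * wavelength / cfg$train$NA_
  beam <- focus_beam(cfg$train, ill$profile %||% c(1, 0), wavelength,
                     n_theta = n_theta, n_phi = n_phi)
  spl <- split_focused_beam(beam, cfg$stack, wavelength)
  npin <- 7
  offs <- expand.grid(dx = seq(-pinhole_radius, pinhole_radius, length.out = npin),
                      dy = seq(-pinhole_radius, pinhole_radius, length.out = npin))
  inside <- sqrt(offs$dx^2 + offs$dy^2) <= pinhole_radius + 1e-9
  out <- matrix(0, length(scan_x), length(scan_y))
  for (ix in seq_along(scan_x)) for (iy in seq_along(scan_y)) {
    dr <- c(scan_x[ix], scan_y[iy], 0)
    drv <- pwd_field(translate_beam(spl$drive, dr))
    refb <- translate_beam(spl$ref, dr)
    cfg_j <- cfg
    f_sca <- scattered_farfield_scan(cfg_j, drv, wavelength)
    f_img <- rotate_field(f_sca, ROT_DETECT)
    r_img <- rotate_field(refb, ROT_DETECT)
    ctr <- c(scan_x[ix], -scan_y[iy])           # descanned center, imaging frame
    g <- list(x = ctr[1] + sort(unique(offs$dx)), y = ctr[2] + sort(unique(offs$dy)))
    cam_s <- suppressWarnings(image_farfield(f_img, cfg$train, g))
    cam_r <- image_pwd(r_img, cfg$train, g)
    I <- matrix(rowSums(Mod(cam_r$E + cam_s$E)^2), npin, npin)
    out[ix, iy] <- sum(I[matrix(inside, npin, npin)])
  }
  out
}

# scattering engine for scanning (no plane-wave spec available)
scattered_farfield_scan <- function(cfg, drive, wavelength) {
  sc <- cfg$scatterer
  grid <- direction_grid(cfg$n_theta, cfg$n_phi)
  n_top <- Re(refractive_index(cfg$stack$materials[[1]], wavelength))
  k0 <- 2 * pi / wavelength
  if (is.null(sc))
    return(farfield(matrix(0i, cfg$n_theta * cfg$n_phi, 3), k = k0 * n_top,
                    grid = grid, k0 = k0))
  eps_top <- n_top^2
  alpha <- sc$alpha
  if (is.null(alpha))
    alpha <- polarizability_sphere(sc$diameter, scatterer_eps(sc, wavelength),
                                   eps_top, radiative_correction = TRUE,
                                   wavelength = wavelength)
  dip <- dipole_scatterer(sc$position, alpha, eps_top)
  dipole_farfield_dip2(dip, drive, cfg$stack, wavelength, grid)
}

# Split an upward focused beam in the substrate into the transmitted driving
# decomposition above the stack and the reflected (descanned reference)
# decomposition below; evanescent transmitted components are dropped.
split_focused_beam <- function(beam, stack, wavelength) {
  n_all <- stack_indices(stack, wavelength)
  n_bot <- Re(n_all[length(n_all)])
  n_top <- Re(n_all[1])
  k0 <- 2 * pi / wavelength
  nc <- nrow(beam$dir)
  dirs_t <- matrix(0, nc, 3); eps_t <- matrix(0i, nc, 3)
  dirs_r <- matrix(0, nc, 3); eps_r <- matrix(0i, nc, 3)
  keep <- rep(TRUE, nc)
  for (j in seq_len(nc)) {
    d <- beam$dir[j, ]
    st <- sqrt(d[1]^2 + d[2]^2); ct <- d[3]
    phi <- atan2(d[2], d[1])
    kx0 <- n_bot * st
    frs <- fresnel_core(rev(n_all), rev(stack$interface_z), kx0, "TE", k0)
    frp <- fresnel_core(rev(n_all), rev(stack$interface_z), kx0, "TM", k0)
    b_in <- pol_basis(st, ct, phi, up = TRUE)
    a_s <- sum(beam$eps[j, ] * b_in$s); a_p <- sum(beam$eps[j, ] * b_in$p)
    # reflected (down in substrate)
    b_r <- pol_basis(st, ct, phi, up = FALSE)
    dirs_r[j, ] <- b_r$k
    eps_r[j, ] <- frs$r * a_s * b_r$s + frp$r * a_p * b_r$p
    # transmitted (up in sample medium)
    st_t <- kx0 / n_top
    if (st_t >= 1) { keep[j] <- FALSE; next }
    ct_t <- sqrt(1 - st_t^2)
    b_t <- pol_basis(st_t, ct_t, phi, up = TRUE)
    dirs_t[j, ] <- b_t$k
    eps_t[j, ] <- frs$t * a_s * b_t$s + frp$t * a_p * b_t$p
  }
  list(drive = pw_decomposition(dirs_t[keep, , drop = FALSE],
                                eps_t[keep, , drop = FALSE],
                                k = k0 * n_top, w = beam$w[keep], k0 = k0),
       ref = pw_decomposition(dirs_r, eps_r, k = k0 * n_bot, w = beam$w,
                              k0 = k0))
}

#' Total system magnification
#'
#' Rated objective magnification relayed by a lens pair:
#' `M_tot = M_objective * f4 / f3`.
#'
#' @param objective_mag rated objective magnification (> 0).
#' @param relay_focal_lengths `c(f3, f4)` in mm (> 0).
#' @return scalar magnification.
#' @export
system_magnification <- function(objective_mag, relay_focal_lengths) {
  f <- as.numeric(relay_focal_lengths)
  if (objective_mag <= 0 || length(f) != 2 || any(f <= 0))
    stop("magnification and focal lengths must be positive")
  objective_mag * f[2] / f[1]
}

#' Add detector noise to an intensity image
#' @param intensity non-negative matrix.
#' @param model `"gaussian"` (additive, `sd` relative to the maximum) or
#'   `"poisson"` (`counts` photons at the maximum).
#' @param sd relative standard deviation for the Gaussian model.
#' @param counts full-scale photon count for the Poisson model.
#' @param seed integer seed.
#' @return noisy intensity matrix.
#' @export
add_noise <- function(intensity, model = c("gaussian", "poisson"), sd = 0.01,
                      counts = 1e4, seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  mx <- max(intensity)
  if (model == "gaussian")
    intensity + matrix(stats::rnorm(length(intensity), sd = sd * mx),
                       nrow(intensity))
  else
    matrix(stats::rpois(length(intensity), intensity / mx * counts),
           nrow(intensity)) * mx / counts
}
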