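# Triangulated particle surfaces: constructors, generators (icosphere, cube,
# dimer, coated sphere), OBJ/ASCII-STL input/output and the RWG edge setup
# used by the boundary-element solver.

#' Triangle surface mesh
#'
#' A closed, orientable, outward-oriented triangulated surface.  Construction
#' validates that every edge is shared by exactly two triangles with opposite
#' orientation and flips the global orientation if the enclosed volume is
#' negative, so normals point outward.
#'
#' @param vertices `nV x 3` matrix of positions (nm).
#' @param faces `nF x 3` integer matrix of vertex indices (1-based).
#' @return Object of class `tri_mesh` with `normals`, `areas`, `volume`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices)) stop("face index out of range")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(key(faces[, 1], faces[, 2]), key(faces[, 2], faces[, 3]),
          key(faces[, 3], faces[, 1]))
  tab <- table(ek)
  if (any(tab != 2))
    stop("mesh is not a closed surface (every edge must be shared by exactly 2 triangles)")
  # opposite orientation across each shared edge: each directed edge unique
  dk <- c(paste(faces[, 1], faces[, 2]), paste(faces[, 2], faces[, 3]),
          paste(faces[, 3], faces[, 1]))
  if (any(table(dk) != 1))
    stop("inconsistent triangle orientation (a directed edge appears twice)")
  vol <- mesh_signed_volume(vertices, faces)
  if (vol < 0) {
    faces <- faces[, c(1, 3, 2)]
    vol <- -vol
  }
  a <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  b <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- sqrt(rowSums(cr^2))
  structure(list(vertices = vertices, faces = faces,
                 normals = cr / nrm, areas = nrm / 2, volume = vol),
            class = "tri_mesh")
}

mesh_signed_volume <- function(V, F) {
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
      v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles, area %.4g nm^2, volume %.4g nm^3\n",
              nrow(x$vertices), nrow(x$faces), sum(x$areas), x$volume))
  invisible(x)
}

#' Euler characteristic of a mesh
#' @param mesh a [tri_mesh()].
#' @return integer `V - E + F` (2 for sphere-like surfaces).
#' @export
mesh_euler <- function(mesh) {
  F <- mesh$faces
  ek <- unique(paste(pmin(F[, c(1, 2, 3)], F[, c(2, 3, 1)]),
                     pmax(F[, c(1, 2, 3)], F[, c(2, 3, 1)])))
  nrow(mesh$vertices) - length(ek) + nrow(F)
}

#' Shift a mesh
#' @param mesh a [tri_mesh()].
#' @param dr displacement vector (nm).
#' @return Translated [tri_mesh()].
#' @export
translate_mesh <- function(mesh, dr) {
  tri_mesh(sweep(mesh$vertices, 2, -as.numeric(dr)), mesh$faces)
}

dedupe_vertices <- function(V, F, tol = 1e-9) {
  scale <- max(abs(V)) + 1e-300
  keyv <- apply(round(V / scale / tol), 1, paste, collapse = "/")
  first <- !duplicated(keyv)
  map <- match(keyv, keyv[first])               # old vertex -> new index
  list(V = V[first, , drop = FALSE], F = matrix(map[F], ncol = 3))
}

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(V = V / sqrt(1 + p^2), F = F)
}

#' Geodesic icosphere
#'
#' Each icosahedron face is subdivided into `frequency^2` triangles and the
#' vertices are projected onto the sphere, giving `20 * frequency^2` faces.
#' By default the mesh is rescaled so that its enclosed volume equals the
#' sphere volume: a flat-facet mesh inscribed in the sphere otherwise carries
#' a systematic quadratic volume deficit that biases scattering quantities
#' (which scale with the particle volume) and masks the boundary-element
#' solution error in convergence studies.
#'
#' @param diameter sphere diameter (nm).
#' @param frequency subdivision frequency (1 = plain icosahedron).
#' @param center sphere center.
#' @param preserve_volume rescale so the enclosed volume matches the sphere
#'   (default `TRUE`).
#' @return A [tri_mesh()].
#' @export
icosphere <- function(diameter, frequency = 4, center = c(0, 0, 0),
                      preserve_volume = TRUE) {
  stopifnot(diameter > 0, frequency >= 1)
  ico <- icosahedron()
  nu <- as.integer(frequency)
  Vs <- list(); Fs <- list(); off <- 0
  for (f in seq_len(nrow(ico$F))) {
    A <- ico$V[ico$F[f, 1], ]; B <- ico$V[ico$F[f, 2], ]; C <- ico$V[ico$F[f, 3], ]
    idx <- matrix(NA_integer_, nu + 1, nu + 1)
    pts <- list(); n <- 0
    for (i in 0:nu) for (j in 0:(nu - i)) {
      n <- n + 1
      idx[i + 1, j + 1] <- n
      pts[[n]] <- ((nu - i - j) * A + i * B + j * C) / nu
    }
    tris <- list(); t <- 0
    for (i in 0:(nu - 1)) for (j in 0:(nu - 1 - i)) {
      t <- t + 1
      tris[[t]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1], idx[i + 1, j + 2])
      if (j < nu - 1 - i) {
        t <- t + 1
        tris[[t]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2], idx[i + 1, j + 2])
      }
    }
    Vs[[f]] <- do.call(rbind, pts)
    Fs[[f]] <- do.call(rbind, tris) + off
    off <- off + n
  }
  V <- do.call(rbind, Vs)
  V <- V / sqrt(rowSums(V^2)) * diameter / 2
  dd <- dedupe_vertices(V, do.call(rbind, Fs), tol = 1e-6 / nu)
  if (preserve_volume) {
    vol <- abs(mesh_signed_volume(dd$V, dd$F))
    dd$V <- dd$V * (pi / 6 * diameter^3 / vol)^(1 / 3)
  }
  tri_mesh(sweep(dd$V, 2, -as.numeric(center)), dd$F)
}

#' Cube mesh
#'
#' Axis-aligned cube of edge length `side`, each face split into a
#' `divisions x divisions` grid of quads (two triangles each).  An optional
#' fillet radius rounds edges and corners by p-norm projection of the
#' vertices (`p = side / fillet`), a smooth approximation adequate for
#' nanocube scattering.
#'
#' @param side edge length (nm).
#' @param divisions grid divisions per face edge.
#' @param fillet fillet radius (nm), 0 for sharp edges.
#' @param center cube center.
#' @return A [tri_mesh()].
#' @export
cube_mesh <- function(side, divisions = 6, fillet = 0, center = c(0, 0, 0)) {
  stopifnot(side > 0, divisions >= 1, fillet >= 0, fillet < side / 2)
  n <- as.integer(divisions)
  h <- side / 2
  axes <- list(
    list(o = c(-h, -h, h),  u = c(1, 0, 0),  v = c(0, 1, 0)),   # +z
    list(o = c(-h, h, -h),  u = c(1, 0, 0),  v = c(0, -1, 0)),  # -z
    list(o = c(h, -h, -h),  u = c(0, 1, 0),  v = c(0, 0, 1)),   # +x
    list(o = c(-h, -h, -h), u = c(0, 0, 1),  v = c(0, 1, 0)),   # -x
    list(o = c(-h, h, -h),  u = c(0, 0, 1),  v = c(1, 0, 0)),   # +y
    list(o = c(-h, -h, -h), u = c(1, 0, 0),  v = c(0, 0, 1)))   # -y
  Vs <- list(); Fs <- list(); off <- 0
  for (ax in axes) {
    g <- expand.grid(i = 0:n, j = 0:n)
    P <- t(sapply(seq_len(nrow(g)), function(r)
      ax$o + g$i[r] / n * side * ax$u + g$j[r] / n * side * ax$v))
    id <- function(i, j) i + 1 + j * (n + 1)
    tris <- list(); t <- 0
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      t <- t + 1; tris[[t]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
      t <- t + 1; tris[[t]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
    }
    Vs[[length(Vs) + 1]] <- P
    Fs[[length(Fs) + 1]] <- do.call(rbind, tris) + off
    off <- off + nrow(P)
  }
  V <- do.call(rbind, Vs)
  if (fillet > 0) {
    p <- max(2, side / fillet)
    u <- V / h
    pn <- (rowSums(abs(u)^p))^(1 / p)
    mx <- pmax(abs(u[, 1]), pmax(abs(u[, 2]), abs(u[, 3])))
    V <- V * (mx / pn)
  }
  dd <- dedupe_vertices(V, do.call(rbind, Fs))
  tri_mesh(sweep(dd$V, 2, -as.numeric(center)), dd$F)
}

#' Built-in particle meshes
#'
#' Canonical scatterer geometries: `sphere` (icosphere), `cube`,
#' `coated_sphere` (two concentric spheres, returned as a list with the outer
#' boundary first) and `dimer` (two spheres with centers separated by
#' `diameter + gap` along `axis`).
#'
#' @param shape `"sphere"`, `"cube"`, `"coated_sphere"` or `"dimer"`.
#' @param diameter sphere diameter (nm) for sphere-based shapes.
#' @param side cube edge length (nm).
#' @param coating coating thickness (nm) for `coated_sphere`.
#' @param gap surface-to-surface gap (nm) for `dimer` (> 0).
#' @param axis dimer axis (unit vector, default x).
#' @param frequency icosphere subdivision frequency.
#' @param divisions cube face divisions.
#' @param fillet cube fillet radius (nm).
#' @param center common center.
#' @return A [tri_mesh()] or a list of them (coated sphere, dimer).
#' @export
make_mesh <- function(shape = c("sphere", "cube", "coated_sphere", "dimer"),
                      diameter = 50, side = 100, coating = 5, gap = 10,
                      axis = c(1, 0, 0), frequency = 4, divisions = 6,
                      fillet = 0, center = c(0, 0, 0)) {
  shape <- match.arg(shape)
  switch(shape,
    sphere = icosphere(diameter, frequency, center),
    cube = cube_mesh(side, divisions, fillet, center),
    coated_sphere = {
      stopifnot(coating > 0)
      list(outer = icosphere(diameter + 2 * coating, frequency, center),
           inner = icosphere(diameter, frequency, center))
    },
    dimer = {
      if (gap <= 0) stop("dimer gap must be > 0")
      axis <- axis / sqrt(sum(axis^2))
      s <- (diameter + gap) / 2
      list(a = icosphere(diameter, frequency, center + s * axis),
           b = icosphere(diameter, frequency, center - s * axis))
    })
}

#' Merge disjoint meshes into one surface
#' @param ... [tri_mesh()] objects (must not intersect).
#' @return A [tri_mesh()] containing all components.
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "tri_mesh"))
    ms <- ms[[1]]
  V <- do.call(rbind, lapply(ms, `[[`, "vertices"))
  off <- cumsum(c(0, utils::head(vapply(ms, function(m) nrow(m$vertices), 1), -1)))
  F <- do.call(rbind, Map(function(m, o) m$faces + o, ms, off))
  tri_mesh(V, F)
}

#' Read and write Wavefront OBJ meshes
#'
#' Minimal OBJ support: `v` and (triangular) `f` records; texture/normal
#' indices after slashes are ignored.
#'
#' @param path file path.
#' @param mesh a [tri_mesh()] (for writing).
#' @return [read_obj()] returns a [tri_mesh()]; [write_obj()] returns `path`.
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  tri_mesh(V, F)
}

#' @rdname read_obj
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read and write ASCII STL meshes
#'
#' @param path file path.
#' @param mesh a [tri_mesh()] (for writing).
#' @param name solid name written to the file.
#' @return [read_stl()] returns a [tri_mesh()]; [write_stl()] returns `path`.
#' @export
read_stl <- function(path) {
  ln <- trimws(readLines(path))
  vt <- ln[startsWith(ln, "vertex")]
  V <- do.call(rbind, lapply(strsplit(sub("^vertex\\s+", "", vt), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  if (nrow(V) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  dd <- dedupe_vertices(V, F)
  tri_mesh(dd$V, dd$F)
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, name = "iscatsim") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (f in seq_len(nrow(mesh$faces))) {
    n <- mesh$normals[f, ]
    writeLines(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("  outer loop", con)
    for (v in mesh$faces[f, ]) {
      p <- mesh$vertices[v, ]
      writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("  endloop", "endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

# RWG edge setup: every interior edge carries one divergence-conforming basis
# function flowing from its plus triangle to its minus triangle.  Returns the
# per-face edge incidence used by the compiled assembly kernels (0-based
# indices for C++).
rwg_setup <- function(mesh) {
  F <- mesh$faces
  nF <- nrow(F)
  pairs <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  uk <- unique(keys)
  eid <- match(keys, uk)
  nE <- length(uk)
  face_edges <- matrix(eid, nF, 3)              # local edge l: opposite vertex l+2 mod 3
  face_signs <- matrix(0L, nF, 3)
  face_opp <- matrix(0L, nF, 3)
  opp_local <- c(3, 1, 2)                       # vertex not on edge (1,2),(2,3),(3,1)
  for (l in 1:3) face_opp[, l] <- F[, opp_local[l]]
  # first face met at an edge is its plus triangle, the second its minus
  seen <- integer(nE)
  for (f in seq_len(nF)) for (l in 1:3) {
    e <- face_edges[f, l]
    if (seen[e] == 0) {
      face_signs[f, l] <- 1L
      seen[e] <- 1L
    } else {
      face_signs[f, l] <- -1L
    }
  }
  v1 <- as.integer(sub(" .*", "", uk))
  v2 <- as.integer(sub(".* ", "", uk))
  edge_len <- sqrt(rowSums((mesh$vertices[v1, , drop = FALSE] -
                            mesh$vertices[v2, , drop = FALSE])^2))
  list(n_edges = nE,
       face_edges = face_edges - 1L,            # 0-based for C++
       face_signs = face_signs,
       face_opp = face_opp - 1L,
       edge_len = edge_len)
}
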