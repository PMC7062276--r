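## ---- minimal incremental 3-D convex hull -----------------------------------
## No 3-D hull routine ships with the installed stack, and particle counts
## here are tiny (tens of vertices), so a plain incremental algorithm is used:
## seed with an extremal tetrahedron, then for each remaining point delete the
## visible facets and re-stitch across the horizon edges. Facets are kept
## outward-oriented relative to an interior point.

.hull3d <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) stop("degenerate geometry: need at least 4 points for a 3-D hull")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop("degenerate geometry: all points coincide")
  tol <- 1e-9 * scale

  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }

  # extremal, non-degenerate starting tetrahedron
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < tol^2) stop("degenerate geometry: all points coincide")
  ab <- pts[i2, ] - pts[i1, ]
  ap <- sweep(pts, 2, pts[i1, ])
  cr <- t(apply(ap, 1, function(v) cross3(ab, v)))
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (d2[i3] < tol^2) stop("degenerate geometry: points are collinear")
  nrm <- cross3(ab, pts[i3, ] - pts[i1, ])
  d3 <- abs(ap %*% nrm)
  i4 <- which.max(d3)
  if (d3[i4] < tol * sqrt(sum(nrm^2))) {
    stop("degenerate geometry: points are coplanar")
  }
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  orient <- function(f) {
    nv <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nv * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(list(c(i1, i2, i3), c(i1, i2, i4),
                       c(i1, i3, i4), c(i2, i3, i4)), orient)

  face_normal <- function(f) {
    cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  }

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    vis <- vapply(faces, function(f) {
      nv <- face_normal(f)
      sum(nv * (pts[p, ] - pts[f[1], ])) > tol * sqrt(sum(nv^2))
    }, logical(1))
    if (!any(vis)) next  # interior or on-hull point
    # horizon = edges used by exactly one visible facet
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(sort(f[c(1, 2)]), sort(f[c(2, 3)]), sort(f[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[!vis]
    for (k in seq_len(nrow(horizon))) {
      faces[[length(faces) + 1L]] <- orient(c(horizon[k, ], p))
    }
  }

  faces <- do.call(rbind, faces)
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    rbind(sort(f[c(1, 2)]), sort(f[c(2, 3)]), sort(f[c(1, 3)]))
  })))
  list(faces = faces, edges = edges, interior = interior, tol = tol)
}

## volume and volume centroid by fanning tetrahedra from an interior point
.hull_measure <- function(pts, hull) {
  vol <- 0
  cen <- c(0, 0, 0)
  o <- hull$interior
  for (i in seq_len(nrow(hull$faces))) {
    f <- hull$faces[i, ]
    a <- pts[f[1], ] - o; b <- pts[f[2], ] - o; d <- pts[f[3], ] - o
    v <- abs(det(rbind(a, b, d))) / 6
    vol <- vol + v
    cen <- cen + v * (o + pts[f[1], ] + pts[f[2], ] + pts[f[3], ]) / 4
  }
  list(volume = vol, centroid = cen / vol)
}

## ---- particle type ---------------------------------------------------------

#' Irregular convex particle
#'
#' A convex polyhedron standing in for an MCP whose shape deviates from a
#' sphere. The particle is stored as its hull vertices (nm coordinates),
#' centred so that its volume centroid sits at the origin; facets, edges,
#' volume and max Feret diameter (largest caliper width, equal to the largest
#' inter-vertex distance for a convex body) are precomputed.
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (nm).
#' @return An object of class `"convex_particle"` with elements `vertices`,
#'   `faces`, `edges`, `volume`, `centroid` (always the origin after
#'   recentring), `max_feret`, `circumradius`.
#' @export
convex_particle <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !is.numeric(vertices) || anyNA(vertices)) {
    stop("`vertices` must be a numeric n x 3 matrix without NAs")
  }
  hull <- .hull3d(vertices)
  keep <- sort(unique(as.vector(hull$faces)))
  if (length(keep) < nrow(vertices)) {
    # points interior to the hull are not part of a convex particle surface
    vertices <- vertices[keep, , drop = FALSE]
    hull <- .hull3d(vertices)
  }
  meas <- .hull_measure(vertices, hull)
  vertices <- sweep(vertices, 2, meas$centroid)
  hull$interior <- hull$interior - meas$centroid
  dmat <- as.matrix(stats::dist(vertices))
  structure(
    list(vertices = vertices, faces = hull$faces, edges = hull$edges,
         volume = meas$volume, centroid = c(0, 0, 0),
         max_feret = max(dmat),
         circumradius = max(sqrt(rowSums(vertices^2)))),
    class = "convex_particle"
  )
}

#' @export
print.convex_particle <- function(x, ...) {
  cat("Convex particle\n")
  cat(sprintf("  vertices    : %d (facets: %d)\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  max Feret   : %.4g nm\n", x$max_feret))
  cat(sprintf("  volume      : %.4g nm^3\n", x$volume))
  invisible(x)
}

## regular icosahedron vertices on the unit circumsphere
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(1 + phi^2)
}

#' Generate an irregular MCP-like convex particle
#'
#' Starts from a regular icosahedron, perturbs each vertex radially by a
#' uniform multiplicative factor in `1 +/- irregularity`, restores convexity
#' by re-hulling, recentres at the volume centroid, and rescales so the max
#' Feret diameter equals `target_diameter` exactly.
#'
#' @param target_diameter Desired max Feret diameter, nm (> 0).
#' @param irregularity Relative radial vertex perturbation, in \[0, 0.3\].
#' @param seed Integer RNG seed.
#' @return A [convex_particle()].
#' @examples
#' p <- make_irregular_particle(140, 0.15, seed = 1)
#' p$max_feret  # 140
#' @export
make_irregular_particle <- function(target_diameter, irregularity = 0.15,
                                    seed = 1L) {
  .assert_scalar_pos(target_diameter, "target_diameter")
  if (!is.numeric(irregularity) || length(irregularity) != 1L ||
      irregularity < 0 || irregularity > 0.3) {
    stop("`irregularity` must lie in [0, 0.3]")
  }
  v <- .icosahedron()
  fac <- local_seed(seed, stats::runif(nrow(v), 1 - irregularity,
                                       1 + irregularity))
  p <- convex_particle(v * fac)
  p$vertices <- p$vertices * (target_diameter / p$max_feret)
  convex_particle(p$vertices)
}

#' Section a convex particle with a plane
#'
#' Intersects the plane `{x : x . normal = offset}` with the particle hull
#' and measures the section as its max Feret diameter (the largest pairwise
#' distance among the intersection polygon's vertices), mirroring the manual
#' longest-diameter measurement convention used on micrographs.
#'
#' @param particle A [convex_particle()].
#' @param plane_normal Nonzero 3-vector; normalised internally.
#' @param plane_offset Signed distance of the plane from the particle
#'   centroid, nm.
#' @return An object of class `"section_sample"`: list with `plane_offset`,
#'   `plane_normal` (unit), and `section_feret_max` (0 when the plane misses
#'   the particle).
#' @export
section_particle <- function(particle, plane_normal, plane_offset) {
  stopifnot(inherits(particle, "convex_particle"))
  if (!is.numeric(plane_normal) || length(plane_normal) != 3L ||
      sum(plane_normal^2) == 0) {
    stop("`plane_normal` must be a nonzero 3-vector")
  }
  u <- plane_normal / sqrt(sum(plane_normal^2))
  pts <- particle$vertices
  s <- drop(pts %*% u) - plane_offset
  tol <- 1e-9 * particle$max_feret

  on_plane <- pts[abs(s) <= tol, , drop = FALSE]
  e <- particle$edges
  si <- s[e[, 1]]; sj <- s[e[, 2]]
  crossing <- which(si * sj < -tol^2)
  if (length(crossing)) {
    tfrac <- si[crossing] / (si[crossing] - sj[crossing])
    cuts <- pts[e[crossing, 1], , drop = FALSE] +
      tfrac * (pts[e[crossing, 2], , drop = FALSE] -
                 pts[e[crossing, 1], , drop = FALSE])
  } else {
    cuts <- matrix(numeric(0), ncol = 3)
  }
  poly <- rbind(on_plane, cuts)
  feret <- if (nrow(poly) >= 2L) max(stats::dist(poly)) else 0
  structure(list(plane_offset = plane_offset, plane_normal = u,
                 section_feret_max = feret),
            class = "section_sample")
}

#' @export
print.section_sample <- function(x, ...) {
  cat(sprintf("Section at offset %.4g nm: Feret %.4g nm\n",
              x$plane_offset, x$section_feret_max))
  invisible(x)
}

#' Monte-Carlo sectioning of a convex particle
#'
#' Draws isotropic random plane normals (normalised standard Gaussians) and,
#' per draw, an offset along the normal over `[0, h]` where `h` is the
#' particle's support radius in that direction: uniformly for the
#' `uniform_plane` scheme or with density proportional to offset^2 for the
#' `volume_weighted` scheme. Sections whose max Feret diameter falls below
#' `detection_limit` are discarded.
#'
#' @param particle A [convex_particle()].
#' @param scheme `"volume_weighted"` or `"uniform_plane"`.
#' @param n Number of sections (>= 1).
#' @param seed Integer RNG seed.
#' @param detection_limit Minimum recordable section Feret diameter, nm.
#' @return Numeric vector of recorded section Feret diameters, nm.
#' @export
mc_section_particle <- function(particle,
                                scheme = c("volume_weighted", "uniform_plane"),
                                n, seed, detection_limit = 0) {
  stopifnot(inherits(particle, "convex_particle"))
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer")
  }
  n <- as.integer(n)
  d <- local_seed(seed, {
    z <- matrix(stats::rnorm(3L * n), ncol = 3L)
    z <- z / sqrt(rowSums(z^2))
    u <- stats::runif(n)
    vapply(seq_len(n), function(i) {
      h <- max(particle$vertices %*% z[i, ])  # support radius along normal
      off <- switch(scheme,
                    volume_weighted = h * u[i]^(1 / 3),
                    uniform_plane   = h * u[i])
      section_particle(particle, z[i, ], off)$section_feret_max
    }, numeric(1))
  })
  d <- d[d >= detection_limit]
  if (length(d) == 0L) {
    warning("all sections fell below the detection limit; returning empty")
  }
  d
}
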