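#' Axial lumen-radius profile of a stenosed vessel
#'
#' Builds the axial radius function induced by a lesion. The constriction uses
#' a C1 cosine-squared shape function `s(z') = cos(pi * z' / 2)^2` over the
#' lesion half-span (`z'` is the normalised distance from the throat), applied
#' to both the radius reduction and, for eccentric lesions, the lumen-centre
#' offset. The lesion is centred in the proximal third of the segment (centre
#' at `segment_length / 6`, shifted inward where the lesion would otherwise
#' protrude past the inlet).
#'
#' For eccentric lesions the centre offset equals the radius reduction, so
#' `center_offset + radius = reference_radius` throughout the lesion: the
#' plaque grows from one wall and the lumen stays tangent to the healthy wall.
#'
#' @param spec A `coro_stenosis` from [stenosis_spec()].
#' @param n_axial Number of axial stations of the uniform base grid (>= 11).
#'   The throat and the lesion edges are inserted into the grid so the minimum
#'   radius is represented exactly.
#' @return A tibble of class `coro_profile` with columns `z` (cm), `radius`
#'   (cm) and `center_offset` (cm), plus attributes `spec`, `throat_z`,
#'   `lesion` (span) carrying the generating specification.
#' @examples
#' prof <- stenosed_radius_profile(stenosis_spec("LAD", 0.3, "eccentric"))
#' min(prof$radius)
#' @export
stenosed_radius_profile <- function(spec, n_axial = 201) {
  stopifnot(inherits(spec, "coro_stenosis"))
  if (n_axial < 11) {
    stop("`n_axial` must be at least 11 for a resolved lesion", call. = FALSE)
  }
  v <- spec$vessel
  r0 <- v$reference_diameter / 2
  rt <- r0 * (1 - spec$ds)
  Ls <- v$stenosis_site_length
  L <- v$segment_length
  zc <- lesion_center(L, Ls)

  z <- seq(0, L, length.out = n_axial)
  if (spec$ds > 0) {
    # represent the throat and lesion edges exactly; drop near-duplicates so
    # no degenerate (zero-height) ring ends up in the mesh
    z <- sort(c(z, zc, max(0, zc - Ls / 2), min(L, zc + Ls / 2)))
    z <- z[c(TRUE, diff(z) > 1e-9)]
  }
  s <- lesion_shape(z, zc, Ls)
  depth <- (r0 - rt) * s
  radius <- r0 - depth
  offset <- if (spec$eccentricity == "eccentric") depth else rep(0, length(z))

  out <- tibble::tibble(z = z, radius = radius, center_offset = offset)
  class(out) <- c("coro_profile", class(out))
  attr(out, "spec") <- spec
  attr(out, "throat_z") <- zc
  attr(out, "lesion") <- c(zc - Ls / 2, zc + Ls / 2)
  out
}

# Cosine-squared constriction shape: 1 at the throat, 0 outside the lesion,
# C1 at the lesion edges.
lesion_shape <- function(z, zc, Ls) {
  zp <- (z - zc) / (Ls / 2)
  ifelse(abs(zp) < 1, cos(pi * zp / 2)^2, 0)
}

# Lesion centre: proximal third (L/6), kept inside [Ls/2, L - Ls/2].
lesion_center <- function(L, Ls) {
  min(max(L / 6, Ls / 2), L - Ls / 2)
}

#' Triangulated lumen surface mesh from a radius profile
#'
#' Sweeps the radius/centre-offset profile into a structured tube
#' triangulation. Ring centres sit at `(center_offset(z), 0, z)` (the
#' eccentric direction is the fixed azimuth theta = 0), so for eccentric
#' lesions the theta = 0 vertex line lies exactly on the healthy-wall
#' cylinder. The mesh is the open lateral surface between the inlet and
#' outlet rims; per-triangle areas are computed exactly from the triangle
#' geometry.
#'
#' @param profile A `coro_profile` from [stenosed_radius_profile()].
#' @param n_circumferential Number of circumferential vertices per ring
#'   (>= 12).
#' @return An object of class `coro_mesh`: list with `vertices` (n x 3
#'   matrix, cm), `triangles` (m x 3 integer matrix, 1-based), `patch_area`
#'   (length-m vector, cm^2), `ring` and `z` per vertex, and the generating
#'   `profile`.
#' @examples
#' mesh <- build_surface_mesh(stenosed_radius_profile(stenosis_spec("LM", 0.5)))
#' sum(mesh$patch_area)
#' @export
build_surface_mesh <- function(profile, n_circumferential = 48) {
  stopifnot(inherits(profile, "coro_profile") || is.data.frame(profile))
  if (n_circumferential < 12) {
    stop("`n_circumferential` must be at least 12", call. = FALSE)
  }
  if (any(profile$radius <= 0)) {
    stop("degenerate profile: radius must be positive everywhere", call. = FALSE)
  }
  nz <- nrow(profile)
  nc <- n_circumferential
  theta <- 2 * pi * (seq_len(nc) - 1) / nc

  ct <- cos(theta); st <- sin(theta)
  x <- as.vector(outer(ct, profile$radius) +
                   matrix(profile$center_offset, nc, nz, byrow = TRUE))
  y <- as.vector(outer(st, profile$radius))
  z <- rep(profile$z, each = nc)
  vertices <- cbind(x = x, y = y, z = z)

  # two triangles per quad between consecutive rings
  i <- rep(seq_len(nc), nz - 1)                       # circumferential index
  ring <- rep(seq_len(nz - 1), each = nc)             # proximal ring index
  inext <- ifelse(i == nc, 1L, i + 1L)
  v00 <- (ring - 1L) * nc + i
  v01 <- (ring - 1L) * nc + inext
  v10 <- ring * nc + i
  v11 <- ring * nc + inext
  triangles <- rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))

  mesh <- structure(
    list(
      vertices = vertices,
      triangles = triangles,
      patch_area = triangle_areas(vertices, triangles),
      ring = rep(seq_len(nz), each = nc),
      z = z,
      profile = profile
    ),
    class = "coro_mesh"
  )
  mesh
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total area and basic facts about a surface mesh
#'
#' @param x A `coro_mesh`.
#' @param ... Unused.
#' @return One-row tibble with vertex/triangle counts and total area (cm^2).
#' @export
glance.coro_mesh <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$vertices),
    n_triangles = nrow(x$triangles),
    total_area = sum(x$patch_area)
  )
}

#' @export
print.coro_mesh <- function(x, ...) {
  cat(sprintf("<coro_mesh> %d vertices, %d triangles, area %.4f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$patch_area)))
  invisible(x)
}

#' Tidy a surface mesh into a vertex tibble
#'
#' @param x A `coro_mesh`.
#' @param ... Unused.
#' @return Tibble with one row per vertex: `vertex`, `x`, `y`, `z`, `ring`.
#' @export
tidy.coro_mesh <- function(x, ...) {
  tibble::tibble(
    vertex = seq_len(nrow(x$vertices)),
    x = x$vertices[, 1],
    y = x$vertices[, 2],
    z = x$vertices[, 3],
    ring = x$ring
  )
}

#' Analytic surface-of-revolution area of a concentric profile
#'
#' Lateral area of the surface of revolution induced by the radius profile,
#' used as the mesh-convergence reference:
#' `A = integral 2 pi r(z) sqrt(1 + r'(z)^2) dz`, evaluated by adaptive
#' quadrature on the exact cosine-squared radius function.
#'
#' @param spec A `coro_stenosis`.
#' @return Area in cm^2.
#' @export
analytic_revolution_area <- function(spec) {
  stopifnot(inherits(spec, "coro_stenosis"))
  v <- spec$vessel
  r0 <- v$reference_diameter / 2
  rt <- r0 * (1 - spec$ds)
  Ls <- v$stenosis_site_length
  zc <- lesion_center(v$segment_length, Ls)
  rfun <- function(z) r0 - (r0 - rt) * lesion_shape(z, zc, Ls)
  # derivative of the depth (r0 - rt) * cos^2(pi zp / 2) wrt z
  drfun <- function(z) {
    zp <- (z - zc) / (Ls / 2)
    ifelse(abs(zp) < 1, (r0 - rt) * sin(pi * zp) * pi / Ls, 0)
  }
  f <- function(z) 2 * pi * rfun(z) * sqrt(1 + drfun(z)^2)
  stats::integrate(f, 0, v$segment_length, subdivisions = 2000L,
                   rel.tol = 1e-10)$value
}
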