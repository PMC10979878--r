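# Forward models: Biot-Savart field of a triangular phantom coil, current
# dipole in a homogeneous conducting sphere (Sarvas closed form), uniform
# background fields, and lead-field assembly for beamforming.

#' Triangular phantom coil
#'
#' A single-turn triangular coil used as a dry current-dipole phantom. The
#' default geometry is an isosceles triangle with a 5 mm base and 45 mm
#' height (area 1.125e-4 m^2), matching the reference phantom; a small coil
#' of this shape driven at sub-mA currents produces fields of tens to
#' hundreds of pT at typical sensor standoffs.
#'
#' @param vertices 3 x 3 matrix, one vertex per row, metres. The coil is the
#'   closed polyline v1 -> v2 -> v3 -> v1.
#' @param current Coil current, amperes.
#' @return Object of class `triangular_coil`.
#' @export
triangular_coil <- function(vertices = default_triangle_vertices(),
                            current = 1e-3) {
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(3, 3))) stop("vertices must be a 3 x 3 matrix")
  e1 <- vertices[2, ] - vertices[1, ]
  e2 <- vertices[3, ] - vertices[1, ]
  area2 <- vnorm(cross3(e1, e2))
  if (area2 < 1e-12) stop("coil vertices are collinear")
  stopifnot_number(current, "current")
  structure(list(vertices = vertices, current = current,
                 area = area2 / 2,
                 normal = unitv(cross3(e1, e2)),
                 centroid = colMeans(vertices)),
            class = "triangular_coil")
}

# Isosceles triangle, 5 mm base, 45 mm height, in the x-y plane centred on
# its own centroid (normal along +z).
default_triangle_vertices <- function() {
  v <- rbind(c(-0.0025, 0, 0), c(0.0025, 0, 0), c(0, 0.045, 0))
  sweep(v, 2, colMeans(v))
}

#' Place the phantom coil at a helmet slot
#'
#' Positions a triangular coil inside the helmet the way the physical
#' phantom is mounted: in an empty sensor casing, with the coil normal along
#' the local radial direction and the centroid `depth` metres radially
#' inward of the chosen sensor position.
#'
#' @param array A [sensor_array()].
#' @param slot_sensor sensor_id of the casing slot; default 1.
#' @param depth Radial distance from the slot sensor to the coil centroid,
#'   metres (default 0.045, reproducing a 20-200 pT field scale at the
#'   best-coupled channel over 0.01-1 mA drive currents).
#' @param current Coil current, amperes.
#' @return A [triangular_coil()] in head-frame coordinates.
#' @export
place_phantom_coil <- function(array, slot_sensor = 1L, depth = 0.045,
                               current = 1e-3) {
  rows <- triad_rows(array, slot_sensor)
  if (length(rows) == 0) stop("unknown slot sensor id: ", slot_sensor)
  p <- channel_positions(array)[rows[1], ]
  r <- unitv(p - array$helmet_origin)
  tb <- tangential_basis(r)
  # rotate the template (normal +z) so z -> radial, x/y -> tangential
  Rm <- rbind(tb[1, ], tb[2, ], r)        # rows: new x, y, z axes
  v <- default_triangle_vertices() %*% Rm # template expressed in head frame
  centre <- p - depth * r
  v <- sweep(v, 2, centre, "+")
  triangular_coil(v, current = current)
}

# Field of one straight current segment a -> b carrying `current`, at rows
# of `points` (n x 3). Exact finite-segment Biot-Savart formula.
segment_field <- function(a, b, points, current) {
  r1 <- sweep(-points, 2, a, "+")   # a - p
  r2 <- sweep(-points, 2, b, "+")   # b - p
  n1 <- sqrt(rowSums(r1^2))
  n2 <- sqrt(rowSums(r2^2))
  cr <- cross3_rows(r1, r2)
  denom <- n1 * n2 * (n1 * n2 + rowSums(r1 * r2))
  seg <- vnorm(b - a)
  # distance from the segment line: |r1 x r2| / |b - a|
  d <- sqrt(rowSums(cr^2)) / seg
  on_line <- !is.finite(denom) | denom <= 0 | d < 1e-6
  if (any(on_line))
    stop("singular geometry: field point within 1e-6 m of a coil segment")
  MU0_4PI * current * cr * ((n1 + n2) / denom)
}

#' Magnetic field of a triangular coil (Biot-Savart)
#'
#' Exact closed-form field of the closed three-segment polyline, linear in
#' the coil current.
#'
#' @param coil A [triangular_coil()].
#' @param points 3-vector or n x 3 matrix of field points, metres.
#' @return n x 3 matrix of fields in tesla (a single 3-vector if `points`
#'   was a vector).
#' @export
triangle_coil_field <- function(coil, points) {
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, 1) else as.matrix(points)
  v <- coil$vertices
  B <- segment_field(v[1, ], v[2, ], pts, coil$current) +
       segment_field(v[2, ], v[3, ], pts, coil$current) +
       segment_field(v[3, ], v[1, ], pts, coil$current)
  if (single) drop(B) else B
}

#' Homogeneous conductor sphere
#'
#' Minimal standard volume-conductor model for MEG: a homogeneous sphere.
#' External magnetic fields depend only on the sphere centre.
#'
#' @param centre 3-vector, metres.
#' @param radius Sphere radius, metres (> 0).
#' @return Object of class `conductor_sphere`.
#' @export
conductor_sphere <- function(centre = c(0, 0, 0), radius = 0.09) {
  stopifnot_number(radius, "radius", positive = TRUE)
  structure(list(centre = as.numeric(centre), radius = radius),
            class = "conductor_sphere")
}

#' Field of a current dipole in a conducting sphere (Sarvas formula)
#'
#' Closed-form external magnetic field of a current dipole inside a
#' homogeneous conducting sphere, including the contribution of volume
#' currents. The field is linear in the dipole moment; radially oriented
#' dipoles are externally silent, and the radial field component equals that
#' of the free-space (primary) dipole field.
#'
#' @param position Dipole position, 3-vector, metres (inside the sphere).
#' @param moment Dipole moment, 3-vector, ampere-metres.
#' @param sphere A [conductor_sphere()].
#' @param points 3-vector or n x 3 matrix of field points outside the
#'   sphere, metres.
#' @return n x 3 matrix (or 3-vector) of fields, tesla.
#' @export
dipole_field_sphere <- function(position, moment, sphere, points) {
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, 1) else as.matrix(points)
  r0 <- as.numeric(position) - sphere$centre
  if (vnorm(r0) >= sphere$radius)
    stop("domain error: dipole must lie inside the conductor sphere")
  rr <- sweep(pts, 2, sphere$centre)      # field points relative to centre
  rn <- sqrt(rowSums(rr^2))
  if (any(rn <= sphere$radius))
    stop("domain error: field points must lie outside the conductor sphere")
  q <- as.numeric(moment)
  a_v <- rr - matrix(r0, nrow(rr), 3, byrow = TRUE)   # r - r0
  a <- sqrt(rowSums(a_v^2))
  adotr <- rowSums(a_v * rr)
  r0dotr <- as.numeric(rr %*% r0)
  Fv <- a * (rn * a + rn^2 - r0dotr)
  # grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0
  c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + adotr / a
  gradF <- rr * c1 - matrix(r0, nrow(rr), 3, byrow = TRUE) * c2
  qxr0 <- cross3(q, r0)
  qxr0_dot_r <- as.numeric(rr %*% qxr0)
  B <- (matrix(qxr0, nrow(rr), 3, byrow = TRUE) * Fv - gradF * qxr0_dot_r) *
    (MU0_4PI / Fv^2)
  if (single) drop(B) else B
}

#' Free-space field of a current dipole
#'
#' Primary (Biot-Savart) field of a point current dipole without a volume
#' conductor; used as an independent check of the spherical-conductor model.
#'
#' @inheritParams dipole_field_sphere
#' @return n x 3 matrix (or 3-vector) of fields, tesla.
#' @export
dipole_field_free <- function(position, moment, points) {
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, 1) else as.matrix(points)
  d <- sweep(pts, 2, as.numeric(position))
  dn <- sqrt(rowSums(d^2))
  qxd <- cross3_rows(matrix(moment, nrow(d), 3, byrow = TRUE), d)
  B <- MU0_4PI * qxd / dn^3
  if (single) drop(B) else B
}

#' Regular source grid inside a conductor sphere
#'
#' Builds a regular lattice of voxels with the given spacing. By default the
#' lattice covers the whole sphere interior (with a small margin); a cubic
#' region of interest can be requested instead, which keeps scanning cheap
#' when the source region is known.
#'
#' @param sphere A [conductor_sphere()].
#' @param spacing Lattice spacing, metres (default 0.004).
#' @param centre Optional ROI centre (3-vector); defaults to sphere centre.
#' @param half_width Optional ROI half-width, metres; `NULL` covers the
#'   sphere.
#' @param margin Voxels closer than `margin` to the sphere surface are
#'   dropped (default 0.008 m) so lead fields stay well conditioned.
#' @return Object of class `source_grid` with `positions` (n x 3) and
#'   `spacing`.
#' @export
make_source_grid <- function(sphere, spacing = 0.004, centre = NULL,
                             half_width = NULL, margin = 0.008) {
  stopifnot_number(spacing, "spacing", positive = TRUE)
  if (is.null(centre)) centre <- sphere$centre
  if (is.null(half_width)) half_width <- sphere$radius
  ax <- seq(-half_width, half_width, by = spacing)
  g <- as.matrix(expand.grid(x = ax + centre[1], y = ax + centre[2],
                             z = ax + centre[3]))
  dimnames(g) <- NULL
  d <- sqrt(rowSums(sweep(g, 2, sphere$centre)^2))
  g <- g[d <= sphere$radius - margin, , drop = FALSE]
  if (nrow(g) == 0) stop("empty source grid")
  structure(list(positions = g, spacing = spacing), class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d voxels, %.1f mm spacing\n",
              nrow(x$positions), 1000 * x$spacing))
  invisible(x)
}

# Index of the grid voxel nearest to a position (error if > spacing away).
grid_voxel_index <- function(grid, position, strict = TRUE) {
  d2 <- rowSums(sweep(grid$positions, 2, as.numeric(position))^2)
  i <- which.min(d2)
  if (strict && sqrt(d2[i]) > grid$spacing * 0.75)
    stop("lookup error: position is not on the source grid")
  i
}

#' Build lead fields for a sensor array over a source grid
#'
#' For every voxel, computes the sensor-array response (projection of the
#' spherical-conductor dipole field onto each channel's sensitive axis) to
#' two orthogonal unit tangential dipole moments. Radial moments are
#' externally silent in a sphere, so two tangential orientations span the
#' visible source space.
#'
#' @param array A [sensor_array()].
#' @param grid A [make_source_grid()] grid; all voxels must lie inside the
#'   sphere.
#' @param sphere A [conductor_sphere()].
#' @return Object of class `lead_fields`: list with `L` (array
#'   channels x 2 x n_voxels, tesla per ampere-metre), `tangentials`
#'   (n_voxels x 2 x 3 unit moment directions), `grid`.
#' @export
build_lead_fields <- function(array, grid, sphere) {
  pos <- channel_positions(array)
  ori <- channel_orientations(array)
  nv <- nrow(grid$positions)
  nc <- nrow(pos)
  L <- array(0, dim = c(nc, 2L, nv))
  tang <- array(0, dim = c(nv, 2L, 3L))
  for (v in seq_len(nv)) {
    p <- grid$positions[v, ]
    radial <- p - sphere$centre
    tb <- if (vnorm(radial) < 1e-9) {
      rbind(c(1, 0, 0), c(0, 1, 0))   # centre voxel: any two axes
    } else tangential_basis(radial)
    for (k in 1:2) {
      Bf <- dipole_field_sphere(p, tb[k, ], sphere, pos)
      L[, k, v] <- rowSums(Bf * ori)
      tang[v, k, ] <- tb[k, ]
    }
  }
  structure(list(L = L, tangentials = tang, grid = grid),
            class = "lead_fields")
}
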