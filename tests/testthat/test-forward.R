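# Oracles: midpoint-rule quadrature of the Biot-Savart line integral, the
# far-field point-dipole approximation, and the free-space current-dipole
# field.

biot_savart_quadrature <- function(a, b, p, current, n = 20000) {
  t <- (seq_len(n) - 0.5) / n
  dl <- (b - a) / n
  mid <- outer(t, b - a) + matrix(a, n, 3, byrow = TRUE)
  r <- matrix(p, n, 3, byrow = TRUE) - mid
  rn <- sqrt(rowSums(r^2))
  dB <- 1e-7 * current *
    cbind(dl[2] * r[, 3] - dl[3] * r[, 2],
          dl[3] * r[, 1] - dl[1] * r[, 3],
          dl[1] * r[, 2] - dl[2] * r[, 1]) / rn^3
  colSums(dB)
}

coil_field_quadrature <- function(coil, p) {
  v <- coil$vertices
  biot_savart_quadrature(v[1, ], v[2, ], p, coil$current) +
    biot_savart_quadrature(v[2, ], v[3, ], p, coil$current) +
    biot_savart_quadrature(v[3, ], v[1, ], p, coil$current)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr.Q(qr(M)) * sign(det(qr.Q(qr(M))))
}

test_that("triangular coil field matches the line-integral quadrature", {
  coil <- triangular_coil(current = 1e-3)
  pts <- list(coil$centroid + 0.05 * coil$normal,
              coil$centroid + c(0.03, -0.02, 0.04),
              coil$centroid + c(-0.06, 0.01, -0.03))
  for (p in pts) {
    B <- triangle_coil_field(coil, p)
    Bq <- coil_field_quadrature(coil, p)
    expect_lt(sqrt(sum((B - Bq)^2)) / sqrt(sum(Bq^2)), 1e-8)
  }
})

test_that("coil field is linear in current and vanishes at zero current", {
  p <- c(0.02, 0.03, 0.05)
  expect_equal(triangle_coil_field(triangular_coil(current = 0), p),
               c(0, 0, 0))
  B1 <- triangle_coil_field(triangular_coil(current = 1e-3), p)
  B3 <- triangle_coil_field(triangular_coil(current = 3e-3), p)
  expect_equal(B3, 3 * B1, tolerance = 1e-12)
})

test_that("far coil field matches the point-dipole approximation", {
  coil <- triangular_coil(current = 1e-3)
  # 10x the coil extent (45 mm) in a few directions
  for (dir in list(c(0, 0, 1), c(1, 1, 1) / sqrt(3), c(0.2, -0.9, 0.4))) {
    p <- coil$centroid + 0.45 * dir / sqrt(sum(dir^2))
    B <- triangle_coil_field(coil, p)
    m <- coil$current * coil$area * coil$normal
    d <- p - coil$centroid
    dn <- sqrt(sum(d^2))
    dh <- d / dn
    Bdip <- 1e-7 * (3 * sum(m * dh) * dh - m) / dn^3
    expect_lt(sqrt(sum((B - Bdip)^2)) / sqrt(sum(Bdip^2)), 0.02)
  }
  expect_equal(coil$area, 1.125e-4, tolerance = 1e-12)
})

test_that("points on a coil segment raise a singular-geometry error", {
  coil <- triangular_coil(current = 1e-3)
  v <- coil$vertices
  mid <- (v[1, ] + v[2, ]) / 2
  expect_error(triangle_coil_field(coil, mid), "singular")
  expect_error(triangular_coil(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("Biot-Savart is rotation-equivariant and superposable", {
  set.seed(42)
  coil <- triangular_coil(current = 2e-3)
  p <- c(0.04, -0.01, 0.06)
  B <- triangle_coil_field(coil, p)
  for (i in 1:10) {
    R <- random_rotation()
    coil_r <- triangular_coil(coil$vertices %*% t(R), current = 2e-3)
    Br <- triangle_coil_field(coil_r, as.numeric(R %*% p))
    expect_lt(max(abs(Br - as.numeric(R %*% B))), 1e-10 * max(abs(B)))
  }
  # superposition of two coils equals the sum of individual fields
  coil2 <- triangular_coil(sweep(coil$vertices, 2, c(0.01, 0.02, 0)),
                           current = 1e-3)
  Bsum <- triangle_coil_field(coil, p) + triangle_coil_field(coil2, p)
  expect_equal(Bsum,
               triangle_coil_field(coil, p) + triangle_coil_field(coil2, p),
               tolerance = 1e-12)
})

test_that("spherical-conductor dipole field has the Sarvas properties", {
  sph <- default_sphere()
  pos <- c(0.02, 0.01, 0.05)
  pts <- rbind(c(0.05, -0.03, 0.10), c(-0.08, 0.06, 0.04),
               c(0.0, 0.1, 0.02))
  # radial dipoles are externally silent
  Br <- dipole_field_sphere(pos, 2e-8 * pos / sqrt(sum(pos^2)), sph, pts)
  expect_lt(max(abs(Br)), 1e-25)
  # linearity at three magnitudes
  q <- c(1e-8, -2e-8, 5e-9)
  B1 <- dipole_field_sphere(pos, q, sph, pts)
  for (s in c(2, 10, 0.1))
    expect_equal(dipole_field_sphere(pos, s * q, sph, pts), s * B1,
                 tolerance = 1e-12)
  # radial component equals the free-space radial component
  Bf <- dipole_field_free(pos, q, pts)
  for (i in 1:3) {
    rh <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    expect_lt(abs(sum(B1[i, ] * rh) - sum(Bf[i, ] * rh)),
              1e-10 * max(abs(Bf)))
  }
})

test_that("dipole / field-point domain errors are raised", {
  sph <- default_sphere()
  expect_error(dipole_field_sphere(c(0.1, 0, 0), c(0, 1e-8, 0), sph,
                                   c(0.2, 0, 0)), "inside")
  expect_error(dipole_field_sphere(c(0.02, 0, 0), c(0, 1e-8, 0), sph,
                                   c(0.03, 0, 0)), "outside")
})

test_that("lead fields are definitionally consistent with the dipole model", {
  h <- small_helmet()
  sph <- default_sphere()
  grid <- make_source_grid(sph, 0.01, centre = c(0, 0, 0.04),
                           half_width = 0.02)
  lf <- build_lead_fields(h, grid, sph)
  pos <- channel_positions(h)
  ori <- channel_orientations(h)
  for (v in c(1, nrow(grid$positions))) {
    for (k in 1:2) {
      B <- dipole_field_sphere(grid$positions[v, ], lf$tangentials[v, k, ],
                               sph, pos)
      expect_equal(lf$L[, k, v], rowSums(B * ori), tolerance = 1e-12)
    }
  }
})

test_that("lead-field norm decays monotonically with source depth", {
  h <- small_helmet()
  sph <- default_sphere()
  dir <- unname(c(-0.5, 0.1, 0.8) / sqrt(sum(c(-0.5, 0.1, 0.8)^2)))
  depths <- c(0.08, 0.07, 0.055, 0.04, 0.02)  # radius along the line
  norms <- vapply(depths, function(r) {
    g <- structure(list(positions = matrix(r * dir, 1), spacing = 0.004),
                   class = "source_grid")
    lf <- build_lead_fields(h, g, sph)
    sqrt(sum(lf$L[, , 1]^2))
  }, 0)
  expect_true(all(diff(norms) < 0))  # deeper (smaller radius) -> weaker
})

test_that("a dipole at the sphere centre is externally silent", {
  # any moment at the centre points along a radius through the source, so
  # the conductor field vanishes; the free-space oracle agrees in that its
  # radial component (q x r) . r / r^3 is identically zero
  h <- small_helmet()
  sph <- default_sphere()
  g <- structure(list(positions = matrix(sph$centre, 1), spacing = 0.004),
                 class = "source_grid")
  lf <- build_lead_fields(h, g, sph)
  expect_lt(sqrt(sum(lf$L[, , 1]^2)), 1e-25)
  pos <- channel_positions(h)
  rad <- pos / sqrt(rowSums(pos^2))
  Bfree <- dipole_field_free(sph$centre, c(0, 1e-8, 0), pos)
  expect_lt(max(abs(rowSums(Bfree * rad))), 1e-25)
})
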