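# Shared fixtures and small independent oracles used across the suite.

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# straight cylinder of radius r and height h along +z, origin cap at z = 0
cylinder_fixture <- function(r = 1, h = 2, n_rings = 8, n_sides = 64) {
  make_tube(function(t) c(0, 0, h * t), r, n_rings = n_rings, n_sides = n_sides)
}

# quarter-circle tube: centerline on the circle of radius R in the xy-plane
quarter_tube_fixture <- function(R = 10, r = 1, n_rings = 64, n_sides = 64) {
  make_tube(
    function(t) c(R * cos(pi / 2 * t), R * sin(pi / 2 * t), 0), r,
    n_rings = n_rings, n_sides = n_sides
  )
}

# curved belly whose end tangents are parallel to the origin-insertion chord
# (caps perpendicular to the slicing axis, so no slice ever cuts a cap)
bump_tube_fixture <- function(L = 20, A = 3, r = 1, n_rings = 96, n_sides = 48) {
  make_tube(
    function(t) c(L * t, A * sin(pi * t)^2, 0), r,
    n_rings = n_rings, n_sides = n_sides
  )
}

# point-to-segment and point-to-polyline distances (centerline recovery)
dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  sqrt(sum((a + t * ab - p)^2))
}

dist_point_polyline <- function(p, P) {
  min(vapply(
    seq_len(nrow(P) - 1),
    function(k) dist_point_segment(p, P[k, ], P[k + 1, ]), 0
  ))
}

# independent continuum oracle for the quarter-circle tube: centroid of the
# exact planar section of the solid torus (radius R, tube radius r), clipped
# by the cap half-spaces, by dense 2D integration in the slice plane
quarter_tube_section_oracle <- function(t, R = 10, r = 1, n_grid = 1200) {
  o <- c(R, 0, 0)
  i <- c(0, R, 0)
  q <- o + t * (i - o)
  u <- (i - o) / sqrt(sum((i - o)^2))
  v1 <- c(1, 1, 0) / sqrt(2) # in-plane basis (plane normal is the chord)
  # centre the integration window where the arc pierces the plane
  phi_star <- optimize(
    function(phi) (sum((c(R * cos(phi), R * sin(phi), 0) - q) * u))^2,
    c(0, pi / 2)
  )$minimum
  a0 <- sum((c(R * cos(phi_star), R * sin(phi_star), 0) - q) * v1)
  a <- seq(a0 - 2.5 * r, a0 + 2.5 * r, length.out = 2 * n_grid + 1)
  b <- seq(-1.2 * r, 1.2 * r, length.out = n_grid)
  g <- expand.grid(a = a, b = b)
  x <- q[1] + g$a * v1[1]
  y <- q[2] + g$a * v1[2]
  z <- g$b
  rad <- sqrt(x^2 + y^2)
  inside <- ((rad - R)^2 + z^2 <= r^2) & y >= 0 & x >= 0
  c(mean(x[inside]), mean(y[inside]), mean(z[inside]))
}

# two-sided exact Mann-Whitney p by direct permutation enumeration,
# written against the definition (independent of the implementation)
mwu_brute_force <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- combn(n, nx)
  Ws <- apply(sets, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  list(
    W = W_obs,
    p = min(1, 2 * min(mean(Ws <= W_obs + 1e-9), mean(Ws >= W_obs - 1e-9)))
  )
}

# cube mesh missing one face (open surface with a 4-edge boundary)
open_cube_fixture <- function() {
  cube <- make_primitive("cube")
  poly_mesh(cube$vertices, cube$faces[-1], unit = cube$unit)
}

# two unit cubes stacked in z that share one quad face record: the four
# edges of the shared face are each used by three faces
shared_face_cubes_fixture <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), # bottom of cube A
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1), # shared layer
    c(0, 0, 2), c(1, 0, 2), c(1, 1, 2), c(0, 1, 2) # top of cube B
  )
  quad_ring <- function(a, b, c_, d, e, f, g, h) {
    list(c(a, b, f, e), c(b, c_, g, f), c(c_, d, h, g), c(d, a, e, h))
  }
  f <- c(
    list(c(4, 3, 2, 1)), # bottom of A
    quad_ring(1, 2, 3, 4, 5, 6, 7, 8), # sides of A
    list(c(5, 6, 7, 8)), # shared face (once)
    quad_ring(5, 6, 7, 8, 9, 10, 11, 12), # sides of B
    list(c(9, 10, 11, 12)) # top of B
  )
  poly_mesh(v, f, unit = "mm")
}

# plain cross product, for checking Heron areas independently
crossprod_oracle <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

# even-odd-rule point-in-polygon test (vectorised over px, py)
in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
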