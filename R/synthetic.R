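# Synthetic muscle-mesh generator.
#
# Produces closed meshes with analytic ground truth (centerline, volume,
# cap centroids) so every geometric operation can be tested without scan
# data: tubes around parametric centerlines (fusiform/curved bellies),
# exact primitives, and an oblique-capped prism reproducing the LoA
# centroid-drag ("kink") artifact near wide angled attachments.

signed_mesh_volume <- function(vertices, faces) {
  m <- poly_mesh(vertices, faces, unit = "mm")
  tri <- triangulate(m)
  V <- m$vertices
  A <- V[tri[, 1], , drop = FALSE]
  B <- V[tri[, 2], , drop = FALSE]
  C <- V[tri[, 3], , drop = FALSE]
  bc <- cbind(
    B[, 2] * C[, 3] - B[, 3] * C[, 2],
    B[, 3] * C[, 1] - B[, 1] * C[, 3],
    B[, 1] * C[, 2] - B[, 2] * C[, 1]
  )
  sum(rowSums(A * bc)) / 6
}

# flip winding if the signed volume says the surface faces inward
orient_outward <- function(vertices, faces) {
  if (signed_mesh_volume(vertices, faces) < 0) {
    faces <- lapply(faces, rev)
  }
  faces
}

#' Tube mesh around a parametric centerline
#'
#' Sweeps a circle of (possibly varying) radius along a centerline curve
#' using rotation-minimising (parallel-transport) frames, producing a
#' quad-strip tube with triangle-fan caps. The ground truth records the
#' centerline, the analytic volume (pi r^2 h for a straight constant-radius
#' cylinder, otherwise composite-Simpson integration of
#' pi r(t)^2 |c'(t)| dt), and the cap centroids with their face selections.
#'
#' @param centerline Function `t -> c(x, y, z)` for `t` in \[0, 1\].
#' @param radius Constant radius, or function `t -> r > 0`.
#' @param n_rings Number of rings along the tube (>= 2).
#' @param n_sides Number of vertices per ring (>= 8).
#' @param capped Close the tube with end caps (required for volume work).
#' @param name,unit Passed to [poly_mesh()].
#' @return List with `mesh` (a [poly_mesh()]) and `truth`: a list holding
#'   `centerline_samples`, `analytic_volume`, `cap_centroids` (`origin`,
#'   `insertion`) and `cap_selections`.
#' @export
make_tube <- function(centerline, radius, n_rings = 32, n_sides = 32,
                      capped = TRUE, name = "tube", unit = "mm") {
  if (n_rings < 2 || n_sides < 8) {
    stop("need n_rings >= 2 and n_sides >= 8", call. = FALSE)
  }
  rfun <- if (is.function(radius)) radius else function(t) radius
  tvals <- seq(0, 1, length.out = n_rings)
  centers <- t(vapply(tvals, centerline, numeric(3)))
  radii <- vapply(tvals, rfun, 0)
  if (any(radii <= 0)) stop("radius must be positive on [0,1]", call. = FALSE)

  # tangents by central differences on a fine sampling
  h <- 1e-6
  tangent <- function(t) {
    t0 <- max(0, t - h); t1 <- min(1, t + h)
    d <- (centerline(t1) - centerline(t0)) / (t1 - t0)
    d / sqrt(sum(d^2))
  }
  tangents <- t(vapply(tvals, tangent, numeric(3)))

  # curvature bound: the tube self-intersects where r * kappa >= 1
  ts <- seq(0, 1, length.out = 201)
  hh <- 1 / 400
  kap <- vapply(ts[c(-1, -length(ts))], function(t) {
    c0 <- centerline(t - hh); c1 <- centerline(t); c2 <- centerline(t + hh)
    d1 <- (c2 - c0) / (2 * hh)
    d2 <- (c2 - 2 * c1 + c0) / hh^2
    cr <- cross3(d1, d2)
    sqrt(sum(cr^2)) / max(sum(d1^2)^1.5, .Machine$double.eps)
  }, 0)
  if (max(kap * vapply(ts[c(-1, -length(ts))], rfun, 0)) >= 1) {
    stop("radius exceeds curvature bound: tube would self-intersect",
      call. = FALSE
    )
  }

  # parallel-transport frames: rotate the previous normal by the rotation
  # taking the previous tangent onto the current one (no twist)
  frames_u <- matrix(NA_real_, n_rings, 3)
  T0 <- tangents[1, ]
  a <- if (abs(T0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(a, T0); u <- u / sqrt(sum(u^2))
  frames_u[1, ] <- u
  for (j in 2:n_rings) {
    Tp <- tangents[j - 1, ]; Tc <- tangents[j, ]
    ax <- cross3(Tp, Tc)
    s <- sqrt(sum(ax^2)); cth <- sum(Tp * Tc)
    if (s > 1e-14) {
      ax <- ax / s
      # Rodrigues rotation of u about ax by the angle between tangents
      u <- u * cth + cross3(ax, u) * s + ax * sum(ax * u) * (1 - cth)
    }
    u <- u - sum(u * Tc) * Tc
    u <- u / sqrt(sum(u^2))
    frames_u[j, ] <- u
  }

  theta <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  verts <- matrix(NA_real_, n_rings * n_sides, 3)
  for (j in seq_len(n_rings)) {
    v <- cross3(tangents[j, ], frames_u[j, ])
    ring <- centers[rep(j, n_sides), ] +
      radii[j] * (outer(cos(theta), frames_u[j, ]) + outer(sin(theta), v))
    verts[(j - 1) * n_sides + seq_len(n_sides), ] <- ring
  }
  vid <- function(j, k) (j - 1L) * n_sides + ((k - 1L) %% n_sides) + 1L
  faces <- list()
  for (j in seq_len(n_rings - 1)) {
    for (k in seq_len(n_sides)) {
      faces[[length(faces) + 1]] <-
        c(vid(j, k), vid(j, k + 1), vid(j + 1, k + 1), vid(j + 1, k))
    }
  }
  n_side_faces <- length(faces)
  cap_sel <- NULL
  if (capped) {
    apex0 <- nrow(verts) + 1L
    apex1 <- nrow(verts) + 2L
    verts <- rbind(verts, centers[1, ], centers[n_rings, ])
    for (k in seq_len(n_sides)) { # origin cap
      faces[[length(faces) + 1]] <- c(apex0, vid(1, k + 1), vid(1, k))
    }
    for (k in seq_len(n_sides)) { # insertion cap
      faces[[length(faces) + 1]] <- c(apex1, vid(n_rings, k), vid(n_rings, k + 1))
    }
    cap_sel <- list(
      origin = n_side_faces + seq_len(n_sides),
      insertion = n_side_faces + n_sides + seq_len(n_sides)
    )
  }
  faces <- orient_outward(verts, faces)
  mesh <- poly_mesh(verts, faces, name = name, unit = unit)

  # analytic volume of the swept solid
  straight <- {
    chord <- centers[n_rings, ] - centers[1, ]
    cl <- sqrt(sum(chord^2))
    mid <- centerline(0.5)
    dev <- sqrt(sum((mid - (centers[1, ] + 0.5 * chord))^2))
    dev < 1e-9 * cl && sd(radii) < 1e-12 * mean(radii)
  }
  analytic_volume <- if (straight) {
    pi * radii[1]^2 * sqrt(sum((centers[n_rings, ] - centers[1, ])^2))
  } else {
    ns <- 10000 # composite Simpson
    tt <- seq(0, 1, length.out = ns + 1)
    speed <- vapply(tt, function(t) {
      t0 <- max(0, t - h); t1 <- min(1, t + h)
      sqrt(sum(((centerline(t1) - centerline(t0)) / (t1 - t0))^2))
    }, 0)
    f <- pi * vapply(tt, rfun, 0)^2 * speed
    (1 / ns) / 3 * (f[1] + f[ns + 1] +
      4 * sum(f[seq(2, ns, 2)]) + 2 * sum(f[seq(3, ns - 1, 2)]))
  }
  truth <- list(
    centerline = centerline,
    centerline_samples = t(vapply(seq(0, 1, length.out = 200), centerline, numeric(3))),
    analytic_volume = analytic_volume,
    cap_centroids = list(origin = centers[1, ], insertion = centers[n_rings, ]),
    cap_selections = if (capped) {
      list(
        origin = face_selection(mesh, cap_sel$origin),
        insertion = face_selection(mesh, cap_sel$insertion)
      )
    } else {
      NULL
    }
  )
  list(mesh = mesh, truth = truth)
}

#' Exact geometric primitives
#'
#' @param kind `"cube"`, `"icosphere"` or `"frustum"`.
#' @param edge Cube edge length.
#' @param radius Icosphere radius.
#' @param subdivision Icosphere subdivision level (0 = icosahedron).
#' @param r1,r2 Frustum base/top radii (`r2 = 0` gives a cone).
#' @param h Frustum height.
#' @param n_sides Frustum ring resolution.
#' @param unit Length unit tag.
#' @return A [poly_mesh()].
#' @export
make_primitive <- function(kind = c("cube", "icosphere", "frustum"),
                           edge = 1, radius = 1, subdivision = 3,
                           r1 = 1, r2 = 0.5, h = 1, n_sides = 64,
                           unit = "mm") {
  kind <- match.arg(kind)
  switch(kind,
    cube = make_cube(edge, unit),
    icosphere = make_icosphere(radius, subdivision, unit),
    frustum = make_frustum(r1, r2, h, n_sides, unit)
  )
}

make_cube <- function(edge = 1, unit = "mm") {
  if (edge <= 0) stop("edge must be positive", call. = FALSE)
  s <- edge / 2
  v <- rbind(
    c(-s, -s, -s), c(s, -s, -s), c(s, s, -s), c(-s, s, -s),
    c(-s, -s, s), c(s, -s, s), c(s, s, s), c(-s, s, s)
  )
  f <- list(
    c(4, 3, 2, 1), # bottom (-z)
    c(5, 6, 7, 8), # top (+z)
    c(1, 2, 6, 5), # -y
    c(3, 4, 8, 7), # +y
    c(2, 3, 7, 6), # +x
    c(4, 1, 5, 8) # -x
  )
  poly_mesh(v, orient_outward(v, f), name = "cube", unit = unit)
}

make_icosphere <- function(radius = 1, subdivision = 3, unit = "mm") {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (subdivision < 0 || subdivision > 6) {
    stop("subdivision must be between 0 and 6", call. = FALSE)
  }
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2)[1])
  f <- matrix(c(
    1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
    2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
    4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
    5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2
  ), ncol = 3, byrow = TRUE)
  for (lev in seq_len(subdivision)) {
    midcache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      midcache[[key]] <- idx
      idx
    }
    nf <- matrix(NA_integer_, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(4 * k - 3):(4 * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    f <- nf
  }
  v <- v * radius
  faces <- lapply(seq_len(nrow(f)), function(k) f[k, ])
  poly_mesh(v, orient_outward(v, faces), name = "icosphere", unit = unit)
}

make_frustum <- function(r1 = 1, r2 = 0.5, h = 1, n_sides = 64, unit = "mm") {
  if (r1 <= 0 || r2 < 0 || h <= 0) {
    stop("need r1 > 0, r2 >= 0, h > 0", call. = FALSE)
  }
  theta <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  ring1 <- cbind(r1 * cos(theta), r1 * sin(theta), 0)
  nxt <- function(k) (k %% n_sides) + 1L
  if (r2 > 0) {
    ring2 <- cbind(r2 * cos(theta), r2 * sin(theta), h)
    v <- rbind(ring1, ring2, c(0, 0, 0), c(0, 0, h))
    c1 <- 2L * n_sides + 1L; c2 <- 2L * n_sides + 2L
    faces <- c(
      lapply(seq_len(n_sides), function(k) {
        c(k, nxt(k), n_sides + nxt(k), n_sides + k)
      }),
      lapply(seq_len(n_sides), function(k) c(c1, nxt(k), k)),
      lapply(seq_len(n_sides), function(k) c(c2, n_sides + k, n_sides + nxt(k)))
    )
  } else {
    apex <- n_sides + 1L; c1 <- n_sides + 2L
    v <- rbind(ring1, c(0, 0, h), c(0, 0, 0))
    faces <- c(
      lapply(seq_len(n_sides), function(k) c(k, nxt(k), apex)),
      lapply(seq_len(n_sides), function(k) c(c1, nxt(k), k))
    )
  }
  poly_mesh(v, orient_outward(v, faces), name = "frustum", unit = unit)
}

#' Oblique-capped prism (LoA kink fixture)
#'
#' A closed rectangular prism along the x axis whose origin cap is tilted
#' by `cap_angle` degrees about the width (y) axis, emulating a muscle with
#' a wide attachment area angled to its long axis. Slicing such a muscle
#' perpendicular to the origin-insertion axis cuts obliquely through the
#' attachment region: cross-sections near the origin lose the part of the
#' prism on the far side of the cap plane, dragging their centroids toward
#' the side the cap leans (negative z here) — the kink artifact.
#'
#' @param length Prism length along x.
#' @param width Width along y.
#' @param thickness Thickness along z.
#' @param cap_angle Tilt of the origin cap in degrees, in \[0, 80).
#' @param unit Length unit tag.
#' @return List with `mesh` and `truth` (`centerline_samples` = the
#'   mid-thickness chord, `analytic_volume`, `cap_centroids`,
#'   `cap_selections`, and `lean_sign`, the sign of the expected near-cap
#'   centroid deviation in z).
#' @export
make_oblique_muscle <- function(length = 10, width = 4, thickness = 4,
                                cap_angle = 0, unit = "mm") {
  if (cap_angle < 0 || cap_angle >= 80) {
    stop("cap_angle must be in [0, 80) degrees", call. = FALSE)
  }
  s <- tan(cap_angle * pi / 180)
  Th <- thickness / 2
  W <- width / 2
  if (s * Th >= length / 2) {
    stop("cap_angle too steep for this length/thickness", call. = FALSE)
  }
  o1 <- c(s * Th, -W, Th); o2 <- c(s * Th, W, Th)
  o3 <- c(-s * Th, W, -Th); o4 <- c(-s * Th, -W, -Th)
  i1 <- c(length, -W, Th); i2 <- c(length, W, Th)
  i3 <- c(length, W, -Th); i4 <- c(length, -W, -Th)
  v <- rbind(o1, o2, o3, o4, i1, i2, i3, i4)
  rownames(v) <- NULL
  faces <- list(
    c(1, 2, 3, 4), # origin cap (tilted)
    c(5, 8, 7, 6), # insertion cap
    c(1, 5, 6, 2), # top z = +Th
    c(4, 3, 7, 8), # bottom z = -Th
    c(1, 4, 8, 5), # side y = -W
    c(2, 6, 7, 3) # side y = +W
  )
  faces <- orient_outward(v, faces)
  mesh <- poly_mesh(v, faces, name = "oblique_prism", unit = unit)
  truth <- list(
    centerline_samples = cbind(seq(0, length, length.out = 100), 0, 0),
    analytic_volume = length * width * thickness, # shear preserves volume
    cap_centroids = list(origin = c(0, 0, 0), insertion = c(length, 0, 0)),
    cap_selections = list(
      origin = face_selection(mesh, 1L),
      insertion = face_selection(mesh, 2L)
    ),
    cap_angle = cap_angle,
    lean_sign = if (cap_angle > 0) -1 else 0
  )
  list(mesh = mesh, truth = truth)
}

#' Analytic slice centroid of the oblique prism
#'
#' Independent ground truth for the kink fixture: the cross-section of the
#' prism at axis position `x = c` is the full width rectangle in y with z
#' restricted to `[-T/2, min(T/2, c / tan(angle))]`, so its centroid is
#' exactly `(c, 0, (-T/2 + min(T/2, c / tan(angle))) / 2)`.
#'
#' @param x Axis position(s) of the slice plane.
#' @param thickness,cap_angle As in [make_oblique_muscle()].
#' @return Matrix of exact slab centroids (one row per `x`).
#' @export
oblique_slice_centroid <- function(x, thickness, cap_angle) {
  Th <- thickness / 2
  s <- tan(cap_angle * pi / 180)
  zmax <- if (s == 0) rep(Th, length(x)) else pmin(Th, x / s)
  cbind(x, 0, (-Th + zmax) / 2)
}
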