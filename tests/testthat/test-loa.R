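test_that("slice planes are interior and evenly spaced", {
  p1 <- slice_planes(c(0, 0, 0), c(0, 0, 2), 1)
  expect_equal(p1[[1]]$point, c(0, 0, 1))
  expect_equal(p1[[1]]$normal, c(0, 0, 1))

  p3 <- slice_planes(c(0, 0, 0), c(0, 0, 2), 3)
  expect_equal(vapply(p3, function(p) p$point[3], 0), c(0.5, 1.0, 1.5))

  set.seed(13)
  o <- rnorm(3); i <- rnorm(3)
  p10 <- slice_planes(o, i, 10)
  pos <- vapply(p10, function(p) sum((p$point - o) * p$normal), 0)
  expect_lt(max(abs(diff(pos) - pos[1])), 1e-12)
  expect_error(slice_planes(c(1, 1, 1), c(1, 1, 1), 5), "degenerate axis")

  pe <- slice_planes(c(0, 0, 0), c(0, 0, 2), 3, include_endpoints = TRUE)
  expect_equal(vapply(pe, function(p) p$point[3], 0), c(0, 1, 2))
})

test_that("cross-sections recover analytic slice geometry", {
  cube <- make_primitive("cube") # spans [-0.5, 0.5]^3
  cs <- cross_section(cube, plane3(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(length(cs$loops), 1)
  expect_equal(cs$area, 1, tolerance = 1e-12)
  expect_equal(cs$centroid, c(0, 0, 0), tolerance = 1e-12)

  cyl <- cylinder_fixture(r = 1, h = 2, n_sides = 64)
  mid <- cross_section(cyl$mesh, plane3(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(length(mid$loops), 1)
  expect_lt(abs(mid$area - pi) / pi, 0.005)

  empty <- cross_section(cube, plane3(c(0, 0, 9), c(0, 0, 1)))
  expect_equal(length(empty$loops), 0)
  expect_equal(empty$area, 0)
  expect_error(section_centroid(empty), "no loop")
})

test_that("planes through vertices are handled deterministically", {
  cube <- make_primitive("cube")
  # z = 0.5 passes exactly through the top face vertices
  cs <- cross_section(cube, plane3(c(0, 0, 0.5), c(0, 0, 1)))
  cs2 <- cross_section(cube, plane3(c(0, 0, 0.5), c(0, 0, 1)))
  expect_identical(cs$area, cs2$area)
  expect_true(cs$area >= 0)
})

test_that("disjoint loops combine by area weighting", {
  # two boxes: footprint areas 1 at x = 0 and 3 at x = 10, both z in [0, 1]
  box <- function(cx, half) {
    v <- as.matrix(expand.grid(x = c(-half, half), y = c(-half, half), z = c(0, 1)))
    v[, 1] <- v[, 1] + cx
    v
  }
  v <- rbind(box(0, 0.5), box(10, sqrt(3) / 2))
  faces_for <- function(o) {
    lapply(list(
      c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
      c(3, 7, 8, 4), c(2, 4, 8, 6), c(1, 5, 7, 3)
    ), function(f) f + o)
  }
  m <- poly_mesh(v, c(faces_for(0L), faces_for(8L)))
  cs <- cross_section(m, plane3(c(0, 0, 0.5), c(0, 0, 1)))
  expect_equal(length(cs$loops), 2)
  expect_equal(sort(cs$loop_areas), c(1, 3), tolerance = 1e-9)
  expect_equal(section_centroid(cs), c(7.5, 0, 0.5), tolerance = 1e-9)
})

test_that("non-convex section centroids match rectangle decomposition", {
  # L-shaped prism: [0,2]x[0,1] plus [0,1]x[1,2], extruded in z
  xy <- rbind(
    c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2)
  )
  n <- nrow(xy)
  v <- rbind(cbind(xy, 0), cbind(xy, 1))
  side <- lapply(seq_len(n), function(k) {
    k2 <- k %% n + 1
    c(k, k2, n + k2, n + k)
  })
  m <- poly_mesh(v, c(list(rev(seq_len(n)), n + seq_len(n)), side))
  cs <- cross_section(m, plane3(c(0, 0, 0.5), c(0, 0, 1)))
  # two rectangles: 2x1 at (1, 0.5) and 1x1 at (0.5, 1.5); total area 3
  expect_equal(cs$area, 3, tolerance = 1e-9)
  expect_equal(
    section_centroid(cs)[1:2],
    c((2 * 1 + 1 * 0.5) / 3, (2 * 0.5 + 1 * 1.5) / 3),
    tolerance = 1e-9
  )
})

test_that("straight cylinder LoA lies on the axis", {
  cyl <- cylinder_fixture(r = 1, h = 2)
  o <- attachment_centroid(cyl$truth$cap_selections$origin)
  i <- attachment_centroid(cyl$truth$cap_selections$insertion)
  loa <- estimate_loa(cyl$mesh, o, i, n_slices = 10)
  expect_equal(nrow(loa$points), 12)
  expect_lt(max(abs(loa$points[, 1:2])), 1e-9)
  expect_equal(loa$arc_length, 2, tolerance = 1e-9)
})

test_that("curved tube slice centroids match the continuum section oracle", {
  qt <- quarter_tube_fixture()
  o <- attachment_centroid(qt$truth$cap_selections$origin)
  i <- attachment_centroid(qt$truth$cap_selections$insertion)
  loa <- estimate_loa(qt$mesh, o, i, n_slices = 20)
  np <- nrow(loa$points)
  cents <- loa$points[2:(np - 1), ]
  for (k in c(1, 2, 10)) {
    oracle <- quarter_tube_section_oracle(k / 21)
    expect_lt(max(abs(cents[k, ] - oracle)), 2e-3) # mesh discretisation
  }
  # frozen from the continuum oracle: max centroid-to-centerline distance is
  # about 2.1% of the tube radius at this resolution (end slices dominate)
  dev <- apply(cents, 1, function(p) {
    sqrt((sqrt(p[1]^2 + p[2]^2) - 10)^2 + p[3]^2)
  })
  expect_equal(max(dev), 0.0206, tolerance = 0.02)
})

test_that("centerline recovery improves as slices double on a curved belly", {
  bump <- bump_tube_fixture()
  o <- attachment_centroid(bump$truth$cap_selections$origin)
  i <- attachment_centroid(bump$truth$cap_selections$insertion)
  arc <- bump$truth$centerline_samples
  err <- vapply(c(5, 10, 20, 40), function(ns) {
    loa <- estimate_loa(bump$mesh, o, i, n_slices = ns)
    max(apply(arc, 1, dist_point_polyline, P = loa$points))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("oblique caps drag near-cap centroids as the slab oracle predicts", {
  for (ang in c(0, 30, 45, 60)) {
    ob <- make_oblique_muscle(10, 4, 4, cap_angle = ang)
    o <- attachment_centroid(ob$truth$cap_selections$origin)
    i <- attachment_centroid(ob$truth$cap_selections$insertion)
    loa <- estimate_loa(ob$mesh, o, i, n_slices = 20)
    np <- nrow(loa$points)
    cents <- loa$points[2:(np - 1), ]
    oracle <- oblique_slice_centroid(cents[, 1], 4, ang)
    expect_lt(max(abs(cents - oracle)), 1e-6 * 10)
    if (ang == 0) {
      expect_lt(max(abs(cents[, 3])), 1e-9 * 10)
    } else {
      nonzero <- cents[abs(cents[, 3]) > 1e-9 * 10, 3]
      expect_true(all(sign(nonzero) == ob$truth$lean_sign))
    }
  }
})

test_that("empty slices are skipped and a missing axis is an error", {
  cyl <- cylinder_fixture(r = 1, h = 2)
  # axis extends below the belly: some planes miss the mesh
  expect_warning(
    loa <- estimate_loa(cyl$mesh, c(0, 0, -0.8), c(0, 0, 2), n_slices = 10),
    "empty slice"
  )
  expect_lt(nrow(loa$points), 12)
  expect_error(
    suppressWarnings(
      estimate_loa(cyl$mesh, c(0, 0, -20), c(0, 0, 2), n_slices = 10)
    ),
    "axis misses"
  )
})

test_that("LoA pipeline is rigid-motion equivariant", {
  set.seed(17)
  qt <- quarter_tube_fixture(n_rings = 24, n_sides = 24)
  o <- attachment_centroid(qt$truth$cap_selections$origin)
  i <- attachment_centroid(qt$truth$cap_selections$insertion)
  base <- estimate_loa(qt$mesh, o, i, n_slices = 8)
  Rm <- random_rotation()
  tr <- rnorm(3, sd = 20)
  meshT <- transform_mesh(qt$mesh, Rm, tr)
  oT <- attachment_centroid(face_selection(meshT, qt$truth$cap_selections$origin$face_indices))
  iT <- attachment_centroid(face_selection(meshT, qt$truth$cap_selections$insertion$face_indices))
  moved <- estimate_loa(meshT, oT, iT, n_slices = 8)
  expected <- sweep(base$points %*% t(Rm), 2, tr, `+`)
  expect_lt(max(abs(moved$points - expected)), 1e-9)
  expect_lt(abs(moved$arc_length - base$arc_length), 1e-9)
})

test_that("smoothing preserves endpoints and reduces deviations", {
  # collinear path stays collinear
  pts <- cbind(seq(0, 10, length.out = 8), 0, 0)
  loa <- structure(
    list(points = pts, smoothed = NULL, arc_length = 10, unit = "mm"),
    class = "line_of_action"
  )
  sm <- smooth_loa(loa, n_samples = 50, smoothing = 0)
  expect_lt(max(abs(sm$smoothed[, 2:3])), 1e-9)
  expect_equal(sm$smoothed[1, ], pts[1, ])
  expect_equal(sm$smoothed[50, ], pts[8, ])

  # one perturbed interior point: smoothing shrinks the max deviation
  pts2 <- pts
  pts2[4, 2] <- 0.5
  loa2 <- structure(
    list(points = pts2, smoothed = NULL, arc_length = NA, unit = "mm"),
    class = "line_of_action"
  )
  sm2 <- smooth_loa(loa2, n_samples = 200, smoothing = 1.5)
  expect_lt(max(abs(sm2$smoothed[, 2])), 0.5)
  for (s in c(0, 0.5, 2, 10)) {
    smk <- smooth_loa(loa2, n_samples = 33, smoothing = s)
    expect_equal(smk$smoothed[1, ], pts2[1, ])
    expect_equal(smk$smoothed[33, ], pts2[8, ])
  }
  expect_error(smooth_loa(loa2, n_samples = 1), "n_samples")

  # 3-point path falls back to linear interpolation
  loa3 <- structure(
    list(
      points = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
      smoothed = NULL, arc_length = 2, unit = "mm"
    ),
    class = "line_of_action"
  )
  sm3 <- smooth_loa(loa3, n_samples = 21)
  expect_equal(arc_length(sm3, use_smoothed = TRUE), 2, tolerance = 1e-9)
})

test_that("arc length matches closed forms", {
  two <- structure(
    list(
      points = rbind(c(0, 0, 0), c(3, 4, 0)),
      smoothed = NULL, arc_length = 5, unit = "mm"
    ),
    class = "line_of_action"
  )
  expect_equal(arc_length(two), 5)
  ell <- structure(
    list(
      points = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
      smoothed = NULL, arc_length = 2, unit = "mm"
    ),
    class = "line_of_action"
  )
  expect_equal(arc_length(ell), 2)
  th <- seq(0, pi, length.out = 1000)
  semi <- structure(
    list(
      points = cbind(cos(th), sin(th), 0),
      smoothed = NULL, arc_length = NA, unit = "mm"
    ),
    class = "line_of_action"
  )
  expect_lt(abs(arc_length(semi) - pi) / pi, 0.001)
  # interpolating spline arc length stays within 0.1% of the raw polyline
  sm <- smooth_loa(semi, n_samples = 2000, smoothing = 0)
  expect_lt(
    abs(arc_length(sm, use_smoothed = TRUE) - arc_length(sm)) / arc_length(sm),
    0.001
  )
})

test_that("LoA exports round-trip and convert units", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 5, 2))
  loa <- structure(
    list(points = pts, smoothed = NULL, arc_length = NA, unit = "cm"),
    class = "line_of_action"
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  export_loa(loa, csv, format = "csv")
  expect_equal(nrow(read.csv(csv)), 3)
  expect_lt(max(abs(read_loa_csv(csv) - pts)), 1e-9)

  js <- withr::local_tempfile(fileext = ".json")
  export_loa(loa, js, format = "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$n_points, 3)
  expect_equal(parsed$unit, "cm")

  obj <- withr::local_tempfile(fileext = ".obj")
  export_loa(loa, obj, format = "obj_polyline")
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 3)
  expect_equal(lines[length(lines)], "l 1 2 3")

  osim <- withr::local_tempfile(fileext = ".xml")
  two <- structure(
    list(
      points = rbind(c(100, 0, 0), c(0, 50, 0)),
      smoothed = NULL, arc_length = NA, unit = "cm"
    ),
    class = "line_of_action"
  )
  export_loa(two, osim, format = "osim_pathpoints")
  xml <- readLines(osim)
  locs <- grep("<location>", xml, value = TRUE)
  expect_equal(length(locs), 2)
  expect_match(locs[1], "1 0 0") # 100 cm -> 1 m
  expect_match(locs[2], "0 0.5 0") # 50 cm -> 0.5 m
})
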