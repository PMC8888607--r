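# Line-of-action (LoA) estimation.
#
# The muscle belly mesh is sliced by planes perpendicular to the axis from
# the origin attachment centroid to the insertion attachment centroid. Each
# planar cross-section is a set of closed loops; its centroid is computed
# the same way as an attachment centroid (triangulate, weight by area).
# Threading the slice centroids from origin to insertion gives the LoA; a
# spline conversion smooths it and the arc length measures MTU length.

#' Construct a slicing plane
#'
#' @param point Length-3 point on the plane.
#' @param normal Length-3 normal vector (normalised internally).
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero", call. = FALSE)
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nn),
    class = "plane3"
  )
}

# orthonormal in-plane basis (u, v) with u x v = normal
plane_basis <- function(plane) {
  n <- plane$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(a, n)
  u <- u / sqrt(sum(u^2))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' Evenly spaced slicing planes along the origin-insertion axis
#'
#' Planes are placed at interior parameters t_i = i / (n_slices + 1) of the
#' origin-to-insertion segment so that no plane coincides with an attachment
#' cap; `include_endpoints = TRUE` switches to inclusive placement
#' t_i = (i - 1) / (n_slices - 1).
#'
#' @param origin,insertion Length-3 attachment centroid coordinates.
#' @param n_slices Number of slices (>= 1).
#' @param include_endpoints Place the first/last plane on the attachments.
#' @return List of [plane3()] objects with attribute `t` (axis parameters).
#' @export
slice_planes <- function(origin, insertion, n_slices, include_endpoints = FALSE) {
  origin <- as.numeric(origin)
  insertion <- as.numeric(insertion)
  axis <- insertion - origin
  if (sqrt(sum(axis^2)) == 0) {
    stop("degenerate axis: origin and insertion coincide", call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  t <- if (include_endpoints && n_slices >= 2) {
    (seq_len(n_slices) - 1) / (n_slices - 1)
  } else {
    seq_len(n_slices) / (n_slices + 1)
  }
  planes <- lapply(t, function(ti) plane3(origin + ti * axis, axis))
  attr(planes, "t") <- t
  planes
}

# signed distances of mesh vertices to a plane, with a deterministic
# offset perturbation when the plane passes (nearly) through vertices
plane_distances <- function(mesh, plane) {
  d <- as.numeric((mesh$vertices %*% plane$normal) -
    sum(plane$point * plane$normal))
  diag_len <- bbox_diagonal(mesh)
  tol <- 1e-12 * diag_len
  eps <- 1e-9 * diag_len
  k <- 0
  while (any(abs(d) < tol) && k < 40) {
    d <- d + eps
    eps <- eps * 2
    k <- k + 1
  }
  d
}

#' Planar cross-section of a closed mesh
#'
#' Intersects every triangle of the (triangulated) mesh with the plane and
#' chains the resulting segments into closed loops by shared endpoints.
#' Planes passing exactly through vertices are handled by a deterministic
#' perturbation of the plane offset along its normal. Loop areas and
#' centroids are computed by the shoelace formula in plane coordinates.
#'
#' @param mesh A closed [poly_mesh()].
#' @param plane A [plane3()].
#' @return A `cross_section` object: `plane`, `loops` (list of m x 3 point
#'   matrices, closure implied between last and first row), `loop_areas`,
#'   `area` (total) and `centroid` (area-weighted over loops, `NA` if empty).
#' @export
cross_section <- function(mesh, plane) {
  stopifnot(inherits(mesh, "poly_mesh"), inherits(plane, "plane3"))
  tri <- triangulate(mesh)
  V <- mesh$vertices
  d <- plane_distances(mesh, plane)
  d1 <- d[tri[, 1]]; d2 <- d[tri[, 2]]; d3 <- d[tri[, 3]]
  straddle <- which(!(pmin(d1, d2, d3) > 0 | pmax(d1, d2, d3) < 0))
  segs <- vector("list", length(straddle))
  for (si in seq_along(straddle)) {
    tr <- tri[straddle[si], ]
    dv <- d[tr]
    pts <- matrix(NA_real_, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      da <- dv[e[1]]; db <- dv[e[2]]
      if ((da > 0) != (db > 0)) {
        s <- da / (da - db)
        pts <- rbind(pts, V[tr[e[1]], ] + s * (V[tr[e[2]], ] - V[tr[e[1]], ]))
      }
    }
    segs[[si]] <- pts
  }
  segs <- segs[vapply(segs, nrow, 0L) == 2]
  loops <- chain_loops(segs, tol = 1e-9 * bbox_diagonal(mesh))
  basis <- plane_basis(plane)
  p0 <- plane$point
  geom <- lapply(loops, function(L) {
    rel <- sweep(L, 2, p0)
    xy <- cbind(rel %*% basis$u, rel %*% basis$v)
    polygon_area_centroid(xy)
  })
  areas <- vapply(geom, function(g) abs(g$area), 0)
  centroid <- if (length(loops) == 0 || sum(areas) == 0) {
    rep(NA_real_, 3)
  } else {
    cent2 <- t(vapply(geom, function(g) g$centroid, c(0, 0)))
    c2 <- colSums(cent2 * areas) / sum(areas)
    p0 + c2[1] * basis$u + c2[2] * basis$v
  }
  structure(
    list(
      plane = plane, loops = loops, loop_areas = areas,
      area = sum(areas), centroid = centroid
    ),
    class = "cross_section"
  )
}

# chain unordered 3D segments into closed loops by endpoint identity
chain_loops <- function(segs, tol) {
  if (length(segs) == 0) return(list())
  ends <- do.call(rbind, segs) # 2 rows per segment
  key <- apply(round(ends / tol), 1, paste, collapse = " ")
  nseg <- length(segs)
  seg_of <- rep(seq_len(nseg), each = 2)
  # adjacency: for each endpoint key, the (segment, end) pairs using it
  buckets <- split(seq_len(2 * nseg), key)
  if (any(vapply(buckets, length, 0L) %% 2 != 0)) {
    stop("open intersection chain: endpoint matching tolerance failed",
      call. = FALSE
    )
  }
  used <- rep(FALSE, nseg)
  loops <- list()
  partner <- function(row) if (row %% 2 == 1) row + 1L else row - 1L
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    loop_pts <- list(segs[[start]][1, ], segs[[start]][2, ])
    cur_row <- 2L * start # row index of the far endpoint
    repeat {
      k <- key[cur_row]
      cand <- setdiff(buckets[[k]], cur_row)
      cand <- cand[!used[seg_of[cand]]]
      if (length(cand) == 0) break
      nxt <- cand[1]
      sidx <- seg_of[nxt]
      used[sidx] <- TRUE
      other <- partner(nxt)
      loop_pts[[length(loop_pts) + 1]] <- ends[other, ]
      cur_row <- other
    }
    L <- do.call(rbind, loop_pts)
    # closed loop: last point returns to the first; drop the duplicate
    if (sum((L[1, ] - L[nrow(L), ])^2) > (3 * tol)^2 * 4) {
      stop("open intersection chain on a closed mesh", call. = FALSE)
    }
    L <- L[-nrow(L), , drop = FALSE]
    if (nrow(L) >= 3) loops[[length(loops) + 1]] <- L
  }
  loops
}

# signed shoelace area and centroid of a 2D polygon (rows = vertices,
# closure implied). The centroid formula is the area-weighted mean of the
# signed fan triangulation, valid for any simple polygon.
polygon_area_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  A <- sum(cr) / 2
  if (A == 0) {
    return(list(area = 0, centroid = colMeans(xy)))
  }
  cx <- sum((xy[, 1] + xy[j, 1]) * cr) / (6 * A)
  cy <- sum((xy[, 2] + xy[j, 2]) * cr) / (6 * A)
  list(area = A, centroid = c(cx, cy))
}

#' Centroid of a cross-section
#'
#' Area-weighted centroid over all loops of the section, computed in the
#' same fashion as the attachment centroid (triangle subdivision weighted by
#' area; realised through the equivalent shoelace formulation). Disjoint
#' loops combine by area weighting.
#'
#' @param section A [cross_section()].
#' @return Length-3 centroid coordinates.
#' @export
section_centroid <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (length(section$loops) == 0 || section$area <= 0) {
    stop("cross-section has no loop with positive area", call. = FALSE)
  }
  section$centroid
}

#' Estimate a muscle's line of action
#'
#' Slices the muscle mesh with `n_slices` planes perpendicular to the
#' origin-to-insertion axis, threads the area-weighted slice centroids into
#' a path anchored at the attachment centroids, and measures its length.
#' Slices where the plane misses the belly are skipped with a warning; if
#' more than half are empty the axis is judged to miss the muscle.
#'
#' By default disjoint loops in one slice combine by area weighting, which
#' reproduces the centroid drag ("kink") artifact near wide oblique
#' attachments; `nearest_loop = TRUE` instead keeps only the loop whose
#' centroid is nearest the origin-insertion chord.
#'
#' @param mesh Closed [poly_mesh()] of the muscle belly.
#' @param origin,insertion [attachment_centroid()] results (or length-3
#'   points) anchoring the path.
#' @param n_slices Number of slicing planes.
#' @param include_endpoints Passed to [slice_planes()].
#' @param nearest_loop Use only the loop nearest the chord in each slice.
#' @return A `line_of_action` object: `points` (m x 3, origin centroid,
#'   slice centroids in axis order, insertion centroid), `slice_t` (axis
#'   parameters of the retained slices), `smoothed` (`NULL` until
#'   [smooth_loa()]), `arc_length` and `unit`.
#' @export
estimate_loa <- function(mesh, origin, insertion, n_slices,
                         include_endpoints = FALSE, nearest_loop = FALSE) {
  o <- if (inherits(origin, "attachment_centroid")) origin$centroid else as.numeric(origin)
  i <- if (inherits(insertion, "attachment_centroid")) insertion$centroid else as.numeric(insertion)
  planes <- slice_planes(o, i, n_slices, include_endpoints)
  tvals <- attr(planes, "t")
  cents <- matrix(NA_real_, length(planes), 3)
  keep <- logical(length(planes))
  for (k in seq_along(planes)) {
    cs <- cross_section(mesh, planes[[k]])
    if (length(cs$loops) == 0 || cs$area <= 0) next
    keep[k] <- TRUE
    cents[k, ] <- if (nearest_loop && length(cs$loops) > 1) {
      nearest_loop_centroid(cs, o, i)
    } else {
      section_centroid(cs)
    }
  }
  n_empty <- sum(!keep)
  if (n_empty > length(planes) / 2) {
    stop("axis misses muscle: more than half of the slices are empty",
      call. = FALSE
    )
  }
  if (n_empty > 0) {
    warning(sprintf("%d empty slice(s) skipped", n_empty), call. = FALSE)
  }
  pts <- rbind(o, cents[keep, , drop = FALSE], i)
  rownames(pts) <- NULL
  loa <- structure(
    list(
      points = pts, slice_t = tvals[keep], smoothed = NULL,
      arc_length = polyline_length(pts), unit = mesh$unit
    ),
    class = "line_of_action"
  )
  loa
}

nearest_loop_centroid <- function(section, o, i) {
  axis <- (i - o) / sqrt(sum((i - o)^2))
  basis <- plane_basis(section$plane)
  p0 <- section$plane$point
  best <- NULL
  best_d <- Inf
  for (li in seq_along(section$loops)) {
    rel <- sweep(section$loops[[li]], 2, p0)
    xy <- cbind(rel %*% basis$u, rel %*% basis$v)
    g <- polygon_area_centroid(xy)
    cen <- p0 + g$centroid[1] * basis$u + g$centroid[2] * basis$v
    w <- cen - o
    d <- sqrt(sum((w - sum(w * axis) * axis)^2)) # distance to chord
    if (d < best_d) {
      best_d <- d
      best <- cen
    }
  }
  best
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' @export
print.line_of_action <- function(x, ...) {
  cat(sprintf(
    "<line_of_action> %d points, arc length %.6g %s%s\n",
    nrow(x$points), x$arc_length, x$unit,
    if (is.null(x$smoothed)) "" else sprintf(" (+ smoothed curve, %d samples)", nrow(x$smoothed))
  ))
  invisible(x)
}

#' Smooth a line of action into a spline curve
#'
#' Converts the threaded centroid path into a cubic spline curve sampled at
#' `n_samples` points, parameterised by cumulative chord length. With
#' `smoothing = 0` the spline interpolates every path point; larger values
#' fit a least-squares cubic B-spline with fewer degrees of freedom. The
#' first and last points (the attachment centroids) are preserved exactly
#' for any smoothing value. Paths with fewer than 4 points fall back to
#' linear interpolation.
#'
#' @param loa A [estimate_loa()] result.
#' @param n_samples Number of samples on the smoothed curve (>= 2).
#' @param smoothing Non-negative smoothing strength; 0 interpolates.
#' @return The `line_of_action` with its `smoothed` field populated.
#' @export
smooth_loa <- function(loa, n_samples = 100, smoothing = 0) {
  stopifnot(inherits(loa, "line_of_action"))
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (smoothing < 0) stop("smoothing must be >= 0", call. = FALSE)
  P <- loa$points
  n <- nrow(P)
  seglen <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  t <- c(0, cumsum(seglen))
  t <- t / t[n]
  tout <- seq(0, 1, length.out = n_samples)
  if (n < 4) {
    S <- vapply(1:3, function(j) approx(t, P[, j], xout = tout)$y,
      numeric(n_samples)
    )
  } else if (smoothing == 0) {
    S <- vapply(1:3, function(j) spline(t, P[, j], xout = tout, method = "natural")$y,
      numeric(n_samples)
    )
  } else {
    df <- max(4L, round(n / (1 + smoothing)))
    B <- splines::bs(t, df = df, intercept = TRUE)
    Bout <- predict(B, tout)
    S <- vapply(1:3, function(j) {
      beta <- qr.coef(qr(B), P[, j])
      beta[is.na(beta)] <- 0
      as.numeric(Bout %*% beta)
    }, numeric(n_samples))
    # pin the endpoints back onto the attachment centroids exactly
    res0 <- P[1, ] - S[1, ]
    res1 <- P[n, ] - S[n_samples, ]
    S <- S + outer(1 - tout, res0) + outer(tout, res1)
  }
  loa$smoothed <- unname(S)
  loa
}

#' Arc length of a line of action
#'
#' The polyline length of the raw centroid path, or of the smoothed curve;
#' in model units this is the muscle-tendon-unit (MTU) length from origin to
#' insertion.
#'
#' @param loa A `line_of_action`.
#' @param use_smoothed Measure the smoothed curve instead of the raw path.
#' @return Length in model units.
#' @export
arc_length <- function(loa, use_smoothed = FALSE) {
  stopifnot(inherits(loa, "line_of_action"))
  if (use_smoothed) {
    if (is.null(loa$smoothed)) stop("LoA has no smoothed curve; call smooth_loa()", call. = FALSE)
    polyline_length(loa$smoothed)
  } else {
    polyline_length(loa$points)
  }
}

#' Export a line of action
#'
#' Formats: `csv` (x,y,z rows), `json` (points, arc length, metadata),
#' `obj_polyline` (OBJ `v`/`l` records), and `osim_pathpoints` — an XML
#' fragment of sequential OpenSim PathPoint elements with locations
#' converted from the LoA's model unit to meters.
#'
#' @param loa A `line_of_action`.
#' @param path Output file path.
#' @param format One of `"csv"`, `"json"`, `"obj_polyline"`,
#'   `"osim_pathpoints"`.
#' @param use_smoothed Export the smoothed curve instead of the raw path.
#' @return `path`, invisibly.
#' @export
export_loa <- function(loa, path,
                       format = c("csv", "json", "obj_polyline", "osim_pathpoints"),
                       use_smoothed = FALSE) {
  stopifnot(inherits(loa, "line_of_action"))
  format <- match.arg(format)
  P <- if (use_smoothed) {
    if (is.null(loa$smoothed)) stop("LoA has no smoothed curve", call. = FALSE)
    loa$smoothed
  } else {
    loa$points
  }
  switch(format,
    csv = {
      df <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3])
      write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    json = {
      jsonlite::write_json(
        list(
          points = unname(split(P, row(P))),
          arc_length = polyline_length(P),
          unit = loa$unit,
          n_points = nrow(P)
        ),
        path, auto_unbox = TRUE, digits = NA
      )
    },
    obj_polyline = {
      writeLines(c(
        sprintf("v %.9g %.9g %.9g", P[, 1], P[, 2], P[, 3]),
        paste("l", paste(seq_len(nrow(P)), collapse = " "))
      ), path)
    },
    osim_pathpoints = {
      fac <- unit_length_factor(loa$unit)
      writeLines(c(
        "<PathPointSet>",
        "  <objects>",
        unlist(lapply(seq_len(nrow(P)), function(i) {
          c(
            sprintf('    <PathPoint name="p%d">', i),
            sprintf(
              "      <location> %.9g %.9g %.9g </location>",
              P[i, 1] * fac, P[i, 2] * fac, P[i, 3] * fac
            ),
            "    </PathPoint>"
          )
        })),
        "  </objects>",
        "</PathPointSet>"
      ), path)
    }
  )
  invisible(path)
}

#' Read a line-of-action CSV back into a point matrix
#'
#' @param path CSV written by [export_loa()].
#' @return Numeric matrix with columns x, y, z.
#' @export
read_loa_csv <- function(path) {
  df <- read.csv(path)
  as.matrix(df[, c("x", "y", "z")])
}
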