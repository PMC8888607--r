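# Polygonal mesh data model and core geometric measures.
#
# A poly_mesh stores vertices as an n x 3 numeric matrix and faces as a list
# of integer vectors (1-based vertex indices, counter-clockwise when viewed
# from outside). Faces may be arbitrary k-gons; triangulation is explicit.

VALID_UNITS <- c("mm", "cm", "m")

# cubic metres per model-unit^3
unit_volume_factor <- function(unit) {
  switch(match.arg(unit, VALID_UNITS),
    mm = 1e-9, cm = 1e-6, m = 1
  )
}

# metres per model unit
unit_length_factor <- function(unit) {
  switch(match.arg(unit, VALID_UNITS),
    mm = 1e-3, cm = 1e-2, m = 1
  )
}

#' Construct a polygonal mesh
#'
#' @param vertices Numeric matrix with one row per vertex and columns x, y, z.
#' @param faces List of integer vectors; each face lists >= 3 vertex indices
#'   (1-based) in counter-clockwise order seen from outside the surface.
#' @param name Mesh name.
#' @param unit Length unit of the model coordinates: `"mm"`, `"cm"` or `"m"`.
#' @param groups Optional character vector, one group label per face (as read
#'   from OBJ `g` records); `NA` for ungrouped faces.
#'
#' @return An object of class `poly_mesh`.
#' @export
poly_mesh <- function(vertices, faces, name = "mesh", unit = "mm",
                      groups = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3 || !is.numeric(vertices)) {
    stop("`vertices` must be a numeric matrix with 3 columns", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("all vertex coordinates must be finite", call. = FALSE)
  }
  if (nrow(vertices) == 0 || length(faces) == 0) {
    stop("mesh is empty: needs at least one vertex and one face", call. = FALSE)
  }
  unit <- match.arg(unit, VALID_UNITS)
  faces <- lapply(faces, function(f) as.integer(f))
  nv <- nrow(vertices)
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    if (length(f) < 3) {
      stop(sprintf("face %d has fewer than 3 vertices", i), call. = FALSE)
    }
    if (any(f < 1L) || any(f > nv)) {
      stop(sprintf("face %d references a vertex index out of range", i),
        call. = FALSE
      )
    }
    if (anyDuplicated(f)) {
      stop(sprintf("face %d repeats a vertex index", i), call. = FALSE)
    }
  }
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(faces))
    groups <- as.character(groups)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(
    list(
      name = name, unit = unit, vertices = vertices, faces = faces,
      groups = groups
    ),
    class = "poly_mesh"
  )
}

#' @export
print.poly_mesh <- function(x, ...) {
  cat(sprintf(
    "<poly_mesh> %s: %d vertices, %d faces [%s]\n",
    x$name, nrow(x$vertices), length(x$faces), x$unit
  ))
  invisible(x)
}

#' Select faces of a mesh as an attachment area
#'
#' A face selection marks the subset of mesh faces forming one muscle
#' attachment area (origin or insertion).
#'
#' @param mesh A [poly_mesh()].
#' @param face_indices Integer vector of face indices (1-based).
#' @return An object of class `face_selection`.
#' @export
face_selection <- function(mesh, face_indices) {
  stopifnot(inherits(mesh, "poly_mesh"))
  face_indices <- sort(unique(as.integer(face_indices)))
  if (length(face_indices) == 0) {
    stop("face selection is empty", call. = FALSE)
  }
  if (any(face_indices < 1L) || any(face_indices > length(mesh$faces))) {
    stop("face selection contains indices outside the mesh", call. = FALSE)
  }
  structure(list(mesh = mesh, face_indices = face_indices),
    class = "face_selection"
  )
}

#' Select faces by OBJ group name
#'
#' @param mesh A [poly_mesh()] read from an OBJ file with `g` groups.
#' @param group Group label.
#' @return A [face_selection()].
#' @export
face_selection_from_group <- function(mesh, group) {
  if (is.null(mesh$groups)) {
    stop("mesh carries no face groups", call. = FALSE)
  }
  idx <- which(mesh$groups == group)
  if (length(idx) == 0) {
    stop(sprintf("no faces in group '%s'", group), call. = FALSE)
  }
  face_selection(mesh, idx)
}

#' @export
print.face_selection <- function(x, ...) {
  cat(sprintf(
    "<face_selection> %d of %d faces of '%s'\n",
    length(x$face_indices), length(x$mesh$faces), x$mesh$name
  ))
  invisible(x)
}

squared_bbox_diagonal <- function(mesh) {
  rng <- apply(mesh$vertices, 2, range)
  sum((rng[2, ] - rng[1, ])^2)
}

bbox_diagonal <- function(mesh) sqrt(squared_bbox_diagonal(mesh))

cross3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

triangle_area_xp <- function(A, B, C) {
  0.5 * sqrt(sum(cross3(B - A, C - A)^2))
}

#' Triangulate mesh faces
#'
#' Splits every k-gon face into k - 2 triangles sharing the parent face's
#' orientation: quads are split along the (v1, v3) diagonal and larger
#' polygons are fanned from their first vertex. Triangles pass through
#' unchanged. Degenerate faces (zero area after triangulation, relative to
#' the mesh bounding box) are dropped with a warning rather than an error.
#'
#' @param mesh A [poly_mesh()].
#' @param selection Optional [face_selection()] restricting which faces are
#'   triangulated; defaults to all faces.
#' @return Integer matrix with three columns, one row per triangle, plus an
#'   attribute `face` giving the parent face index of each triangle.
#' @export
triangulate <- function(mesh, selection = NULL) {
  stopifnot(inherits(mesh, "poly_mesh"))
  idx <- if (is.null(selection)) {
    seq_along(mesh$faces)
  } else {
    stopifnot(identical(selection$mesh$vertices, mesh$vertices))
    selection$face_indices
  }
  area_tol2 <- 1e-12 * squared_bbox_diagonal(mesh) # on squared scale
  tris <- vector("list", length(idx))
  parents <- vector("list", length(idx))
  n_degenerate <- 0L
  V <- mesh$vertices
  for (k in seq_along(idx)) {
    fi <- idx[k]
    f <- mesh$faces[[fi]]
    m <- length(f)
    t_local <- if (m == 3) {
      matrix(f, ncol = 3)
    } else {
      # fan from the first vertex; for quads this is the (v1,v3) diagonal
      cbind(f[1], f[2:(m - 1)], f[3:m])
    }
    areas <- apply(t_local, 1, function(tr) {
      triangle_area_xp(V[tr[1], ], V[tr[2], ], V[tr[3], ])
    })
    keep <- areas^2 > area_tol2
    if (!all(keep)) n_degenerate <- n_degenerate + sum(!keep)
    tris[[k]] <- t_local[keep, , drop = FALSE]
    parents[[k]] <- rep(fi, sum(keep))
  }
  if (n_degenerate > 0) {
    warning(sprintf(
      "%d degenerate (zero-area) triangle(s) excluded from triangulation",
      n_degenerate
    ), call. = FALSE)
  }
  out <- do.call(rbind, tris)
  attr(out, "face") <- unlist(parents, use.names = FALSE)
  out
}

# undirected edge incidence table: how many faces use each edge
edge_use_counts <- function(mesh) {
  edges <- do.call(rbind, lapply(mesh$faces, function(f) {
    cbind(f, c(f[-1], f[1]))
  }))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  table(key)
}

#' Validate mesh topology
#'
#' Reports whether the surface is closed (watertight) and manifold. An edge
#' used by exactly one face is a boundary edge; an edge used by more than two
#' faces is non-manifold. A closed mesh has no boundary edges.
#'
#' @param mesh A [poly_mesh()].
#' @return A list of class `mesh_report` with elements `closed`,
#'   `boundary_edge_count`, `non_manifold_edge_count` and
#'   `negative_volume_flag` (the last set by [mesh_volume()], `FALSE` here).
#' @export
validate_mesh <- function(mesh) {
  counts <- edge_use_counts(mesh)
  boundary <- sum(counts == 1)
  nonmanifold <- sum(counts > 2)
  structure(
    list(
      closed = boundary == 0L,
      boundary_edge_count = as.integer(boundary),
      non_manifold_edge_count = as.integer(nonmanifold),
      negative_volume_flag = FALSE
    ),
    class = "mesh_report"
  )
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf(
    "<mesh_report> closed=%s boundary_edges=%d non_manifold_edges=%d\n",
    x$closed, x$boundary_edge_count, x$non_manifold_edge_count
  ))
  invisible(x)
}

#' Volume of a closed mesh
#'
#' Signed sum of origin-tetrahedron volumes over the triangulated faces
#' (the divergence-theorem volume). The mesh must be closed; a negative
#' signed sum indicates inward-facing winding and is corrected by taking
#' the absolute value, with attribute `negative_volume_flag` set.
#'
#' @param mesh A closed [poly_mesh()].
#' @return Volume in model units cubed, with attribute `negative_volume_flag`.
#' @export
mesh_volume <- function(mesh) {
  rep_ <- validate_mesh(mesh)
  if (!rep_$closed) {
    stop(sprintf(
      "mesh is not closed: %d boundary edge(s)", rep_$boundary_edge_count
    ), call. = FALSE)
  }
  if (rep_$non_manifold_edge_count > 0) {
    stop(sprintf(
      "mesh has %d non-manifold edge(s)", rep_$non_manifold_edge_count
    ), call. = FALSE)
  }
  tri <- triangulate(mesh)
  V <- mesh$vertices
  A <- V[tri[, 1], , drop = FALSE]
  B <- V[tri[, 2], , drop = FALSE]
  C <- V[tri[, 3], , drop = FALSE]
  # scalar triple product A . (B x C) per triangle
  bc <- cbind(
    B[, 2] * C[, 3] - B[, 3] * C[, 2],
    B[, 3] * C[, 1] - B[, 1] * C[, 3],
    B[, 1] * C[, 2] - B[, 2] * C[, 1]
  )
  signed <- sum(rowSums(A * bc)) / 6
  vol <- abs(signed)
  attr(vol, "negative_volume_flag") <- signed < 0
  vol
}

#' Surface area of a face selection
#'
#' Total area of the (triangulated) selected faces: the attachment area
#' weight used by the area-weighted centroid.
#'
#' @param selection A [face_selection()], or a whole [poly_mesh()] for the
#'   full surface area.
#' @return Area in model units squared.
#' @export
surface_area <- function(selection) {
  if (inherits(selection, "poly_mesh")) {
    selection <- face_selection(selection, seq_along(selection$faces))
  }
  stopifnot(inherits(selection, "face_selection"))
  mesh <- selection$mesh
  tri <- triangulate(mesh, selection)
  if (nrow(tri) == 0) stop("selection has no non-degenerate faces", call. = FALSE)
  V <- mesh$vertices
  sum(apply(tri, 1, function(tr) {
    triangle_area_xp(V[tr[1], ], V[tr[2], ], V[tr[3], ])
  }))
}

#' Rigidly transform a mesh
#'
#' @param mesh A [poly_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  out <- mesh
  dimnames(v) <- dimnames(mesh$vertices)
  out$vertices <- v
  out
}
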