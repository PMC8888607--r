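# Area-weighted attachment centroid.
#
# The attachment area of a muscle is marked as a set of mesh faces. Each
# face is triangulated; a triangle with vertices A, B, C and side lengths
# a = |BC|, b = |AC|, c = |AB| has semi-perimeter s = (a + b + c) / 2 and
# area w = sqrt(s (s-a) (s-b) (s-c)) (Heron's formula), and centroid
# (A + B + C) / 3. The attachment centroid is the area-weighted mean of the
# triangle centroids, C_A = sum(w_i C_i) / sum(w_i).

#' Triangle area by Heron's formula
#'
#' @param A,B,C Length-3 numeric vertex coordinates.
#' @return Non-negative area. Near-degenerate triangles whose Heron radicand
#'   dips below zero through floating point are clamped to area 0.
#' @export
heron_area <- function(A, B, C) {
  a <- sqrt(sum((B - C)^2))
  b <- sqrt(sum((A - C)^2))
  c <- sqrt(sum((A - B)^2))
  s <- (a + b + c) / 2
  rad <- s * (s - a) * (s - b) * (s - c)
  if (rad < 0) rad <- 0
  sqrt(rad)
}

#' Triangle centroid
#'
#' @param A,B,C Length-3 numeric vertex coordinates.
#' @return The vertex average `(A + B + C) / 3`.
#' @export
triangle_centroid <- function(A, B, C) {
  (A + B + C) / 3
}

#' Area-weighted centroid of weighted triangles
#'
#' @param centroids Numeric matrix, one triangle centroid per row.
#' @param weights Non-negative triangle areas, one per row of `centroids`.
#' @param n_vertices Optional count of vertices describing the attachment
#'   area, carried through for reporting.
#' @return An `attachment_centroid` object with fields `centroid` (length-3),
#'   `total_area` and `n_vertices`.
#' @export
area_weighted_centroid <- function(centroids, weights, n_vertices = NA_integer_) {
  centroids <- rbind(centroids)
  stopifnot(nrow(centroids) == length(weights), all(weights >= 0))
  W <- sum(weights)
  if (W <= 0) {
    stop("degenerate attachment: total area is zero", call. = FALSE)
  }
  CA <- colSums(centroids * weights) / W
  structure(
    list(
      centroid = unname(CA), total_area = W,
      n_vertices = as.integer(n_vertices)
    ),
    class = "attachment_centroid"
  )
}

#' @export
print.attachment_centroid <- function(x, ...) {
  cat(sprintf(
    "<attachment_centroid> C_A = (%.6g, %.6g, %.6g), W_A = %.6g, n = %s\n",
    x$centroid[1], x$centroid[2], x$centroid[3], x$total_area,
    ifelse(is.na(x$n_vertices), "?", x$n_vertices)
  ))
  invisible(x)
}

#' Attachment centroid of a face selection
#'
#' Triangulates the selected faces, computes each triangle's Heron area and
#' vertex-average centroid, and returns their area-weighted mean. The result
#' is independent of face order and, for planar selections, of the
#' triangulation split. For curved patches the centroid is the extrinsic
#' (embedding-space) mean and can lie off the surface.
#'
#' @param selection A [face_selection()].
#' @return An [area_weighted_centroid()] result.
#' @export
attachment_centroid <- function(selection) {
  stopifnot(inherits(selection, "face_selection"))
  mesh <- selection$mesh
  tri <- suppressWarnings(triangulate(mesh, selection))
  if (nrow(tri) == 0) {
    stop("degenerate attachment: no non-degenerate triangles", call. = FALSE)
  }
  V <- mesh$vertices
  w <- numeric(nrow(tri))
  cen <- matrix(NA_real_, nrow(tri), 3)
  for (i in seq_len(nrow(tri))) {
    A <- V[tri[i, 1], ]; B <- V[tri[i, 2], ]; C <- V[tri[i, 3], ]
    w[i] <- heron_area(A, B, C)
    cen[i, ] <- triangle_centroid(A, B, C)
  }
  nverts <- length(unique(unlist(mesh$faces[selection$face_indices])))
  area_weighted_centroid(cen, w, n_vertices = nverts)
}
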