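# Mesh file I/O: Wavefront OBJ (polygonal faces, "g" groups), STL
# (ASCII and binary read, ASCII write) and ASCII PLY.

detect_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "stl", "ply")) {
    stop(sprintf("cannot infer mesh format from extension '%s'", ext),
      call. = FALSE
    )
  }
  ext
}

#' Read a polygonal mesh from OBJ, STL or PLY
#'
#' OBJ and PLY keep their polygonal (non-pre-triangulated) faces and vertex
#' order; OBJ 1-based indices are used directly as the internal convention
#' and `g` group labels are kept per face so groups can act as named
#' attachment selections. STL yields triangles; its per-facet vertices are
#' welded at an absolute tolerance so shared corners become shared vertices.
#'
#' @param path File path.
#' @param format `"obj"`, `"stl"`, `"ply"`, or `"auto"` (from the extension).
#' @param unit Length unit tag to attach to the mesh.
#' @param weld_tol Absolute welding tolerance for STL vertices.
#' @return A [poly_mesh()].
#' @export
read_mesh <- function(path, format = "auto", unit = "mm", weld_tol = 1e-9) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read mesh: '%s' does not exist", path), call. = FALSE)
  }
  format <- match.arg(format, c("auto", "obj", "stl", "ply"))
  if (format == "auto") format <- detect_mesh_format(path)
  name <- tools::file_path_sans_ext(basename(path))
  switch(format,
    obj = read_obj(path, name, unit),
    stl = read_stl(path, name, unit, weld_tol),
    ply = read_ply(path, name, unit)
  )
}

read_obj <- function(path, name, unit) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines_idx <- which(startsWith(lines, "f "))
  if (length(vlines) == 0 || length(flines_idx) == 0) {
    stop(sprintf("'%s' contains no vertices or no faces", path), call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"),
    function(p) as.numeric(p[1:3])
  ))
  # track the active group ("g") for each face line
  glines_idx <- which(startsWith(lines, "g"))
  glabels <- trimws(sub("^g", "", lines[glines_idx]))
  glabels[glabels == ""] <- NA_character_
  face_group <- rep(NA_character_, length(flines_idx))
  if (length(glines_idx) > 0) {
    pos <- findInterval(flines_idx, glines_idx)
    face_group[pos > 0] <- glabels[pos[pos > 0]]
  }
  faces <- lapply(seq_along(flines_idx), function(k) {
    toks <- strsplit(sub("^f\\s+", "", lines[flines_idx[k]]), "\\s+")[[1]]
    # "v", "v/vt", "v/vt/vn", "v//vn" -> leading vertex index
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    if (anyNA(idx)) {
      stop(sprintf("unparseable face line %d in '%s'", k, path), call. = FALSE)
    }
    # negative OBJ indices are relative to the current vertex count
    idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
    if (any(idx < 1L) || any(idx > nrow(verts))) {
      stop(sprintf(
        "face %d of '%s' references a vertex index out of range", k, path
      ), call. = FALSE)
    }
    idx
  })
  poly_mesh(verts, faces,
    name = name, unit = unit,
    groups = if (any(!is.na(face_group))) face_group else NULL
  )
}

weld_vertices <- function(coords, tol) {
  # quantize to a grid of spacing tol; identical cells weld together
  key <- apply(round(coords / tol), 1, paste, collapse = " ")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = coords[first, , drop = FALSE], map = map)
}

read_stl <- function(path, name, unit, weld_tol) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  is_ascii <- grepl("^solid", rawToChar(header[1:5]))
  close(con)
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- lines[startsWith(lines, "vertex")]
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      stop(sprintf("'%s' is not a valid ASCII STL", path), call. = FALSE)
    }
    coords <- do.call(rbind, lapply(
      strsplit(sub("^vertex\\s+", "", vlines), "\\s+"),
      function(p) as.numeric(p[1:3])
    ))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
    }
  }
  w <- weld_vertices(coords, weld_tol)
  faces <- split(w$map, rep(seq_len(length(w$map) / 3), each = 3))
  poly_mesh(w$vertices, unname(faces), name = name, unit = unit)
}

read_ply <- function(path, name, unit) {
  lines <- readLines(path, warn = FALSE)
  end_hdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(end_hdr) || !grepl("^ply", lines[1])) {
    stop(sprintf("'%s' is not an ASCII PLY file", path), call. = FALSE)
  }
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("format ascii", hdr))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face counts", call. = FALSE)
  body <- trimws(lines[(end_hdr + 1):length(lines)])
  body <- body[nzchar(body)]
  verts <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
    function(p) as.numeric(p[1:3])
  ))
  faces <- lapply(strsplit(body[nv + seq_len(nf)], "\\s+"), function(p) {
    n <- as.integer(p[1])
    as.integer(p[2:(n + 1)]) + 1L # PLY is 0-based
  })
  poly_mesh(verts, faces, name = name, unit = unit)
}

#' Write a mesh to OBJ, STL or PLY
#'
#' OBJ is written with 1-based indices and per-face group records when the
#' mesh carries groups; STL forces triangulation (ASCII output); PLY keeps
#' polygonal faces (0-based indices per the format).
#'
#' @param mesh A [poly_mesh()].
#' @param path Output file path.
#' @param format `"obj"`, `"stl"`, `"ply"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto") {
  stopifnot(inherits(mesh, "poly_mesh"))
  format <- match.arg(format, c("auto", "obj", "stl", "ply"))
  if (format == "auto") format <- detect_mesh_format(path)
  V <- mesh$vertices
  lines <- switch(format,
    obj = {
      fl <- character(0)
      cur_group <- NA_character_
      for (i in seq_along(mesh$faces)) {
        g <- if (is.null(mesh$groups)) NA_character_ else mesh$groups[i]
        if (!is.na(g) && !identical(g, cur_group)) {
          fl <- c(fl, paste("g", g))
          cur_group <- g
        }
        fl <- c(fl, paste("f", paste(mesh$faces[[i]], collapse = " ")))
      }
      c(
        sprintf("# %s", mesh$name),
        sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
        fl
      )
    },
    stl = {
      tri <- triangulate(mesh)
      out <- c(sprintf("solid %s", mesh$name))
      for (i in seq_len(nrow(tri))) {
        A <- V[tri[i, 1], ]; B <- V[tri[i, 2], ]; C <- V[tri[i, 3], ]
        n <- cross3(B - A, C - A)
        nn <- sqrt(sum(n^2))
        if (nn > 0) n <- n / nn
        out <- c(
          out,
          sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
          "    outer loop",
          sprintf("      vertex %.9g %.9g %.9g", c(A[1], B[1], C[1]),
            c(A[2], B[2], C[2]), c(A[3], B[3], C[3])
          ),
          "    endloop",
          "  endfacet"
        )
      }
      c(out, sprintf("endsolid %s", mesh$name))
    },
    ply = {
      c(
        "ply", "format ascii 1.0",
        sprintf("element vertex %d", nrow(V)),
        "property float x", "property float y", "property float z",
        sprintf("element face %d", length(mesh$faces)),
        "property list uchar int vertex_indices",
        "end_header",
        sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
        vapply(mesh$faces, function(f) {
          paste(c(length(f), f - 1L), collapse = " ")
        }, "")
      )
    }
  )
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
      call. = FALSE
    )
  }
  invisible(path)
}

#' Read a face selection from a text file
#'
#' One face index per line, or an inclusive range `a-b`; indices in the file
#' are 0-based (the on-disk convention); `#` starts a comment.
#'
#' @param mesh The [poly_mesh()] the indices refer to.
#' @param path Selection file path.
#' @return A [face_selection()].
#' @export
read_face_selection <- function(mesh, path) {
  if (!file.exists(path)) {
    stop(sprintf("selection file '%s' does not exist", path), call. = FALSE)
  }
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  idx0 <- unlist(lapply(lines, function(ln) {
    if (grepl("^\\d+\\s*-\\s*\\d+$", ln)) {
      ab <- as.integer(strsplit(ln, "-")[[1]])
      seq(ab[1], ab[2])
    } else if (grepl("^\\d+$", ln)) {
      as.integer(ln)
    } else {
      stop(sprintf("unparseable selection line: '%s'", ln), call. = FALSE)
    }
  }))
  face_selection(mesh, idx0 + 1L)
}

#' Write a face selection to a text file (0-based indices)
#'
#' @param selection A [face_selection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_face_selection <- function(selection, path) {
  stopifnot(inherits(selection, "face_selection"))
  writeLines(as.character(selection$face_indices - 1L), path)
  invisible(path)
}
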