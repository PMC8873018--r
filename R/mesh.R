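#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` is the spatial substrate for vertex-wise analysis and
#' cluster formation. Vertex adjacency (two vertices are neighbours when
#' they share a triangle edge) and per-vertex areas (one third of the summed
#' areas of incident triangles, the usual barycentric area assignment) are
#' derived at construction time.
#'
#' Triangles are stored 1-based inside R (the language's native indexing);
#' the package's on-disk dialects (`triangle_text`, TSV maps) are 0-based.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices.
#' @param mask logical vector, one entry per vertex; `TRUE` = analyzed.
#'   Defaults to all `TRUE`.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `mask`, `areas` (mm^2) and `adjacency` (list of integer
#'   neighbour vectors).
#' @export
surface_mesh <- function(vertices, triangles, mask = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  nv <- nrow(vertices)
  if (nrow(triangles) > 0L) {
    bad <- which(triangles < 1L | triangles > nv, arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("triangle %d references vertex index %d outside 1..%d",
                   bad[1L, 1L], triangles[bad[1L, , drop = FALSE]], nv))
    }
    degen <- which(triangles[, 1L] == triangles[, 2L] |
                   triangles[, 1L] == triangles[, 3L] |
                   triangles[, 2L] == triangles[, 3L])
    if (length(degen)) {
      stop(sprintf("degenerate triangle %d (repeated vertex index)", degen[1L]))
    }
  }
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.logical(mask)
  if (length(mask) != nv) stop("mask length must equal vertex count")

  mesh <- list(vertices = vertices, triangles = triangles, mask = mask)
  mesh$areas <- .vertex_areas(vertices, triangles)
  mesh$adjacency <- .mesh_adjacency(nv, triangles)
  class(mesh) <- "surface_mesh"
  mesh
}

.vertex_areas <- function(vertices, triangles) {
  areas <- numeric(nrow(vertices))
  if (nrow(triangles) == 0L) return(areas)
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  third <- tri_area / 3
  for (k in 1:3) {
    acc <- tapply(third, triangles[, k], sum)
    idx <- as.integer(names(acc))
    areas[idx] <- areas[idx] + as.numeric(acc)
  }
  areas
}

.mesh_adjacency <- function(nv, triangles) {
  if (nrow(triangles) == 0L) return(rep(list(integer(0)), nv))
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(1L, 3L)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2L], factor(e[, 1L], levels = seq_len(nv)))
  unname(lapply(adj, function(x) sort(as.integer(x))))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %d masked-in\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$mask)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Replace the analysis mask of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param mask logical per-vertex vector, or path to a text file with one
#'   0/1 (or TRUE/FALSE) value per line.
#' @return the mesh with its mask replaced.
#' @export
set_mesh_mask <- function(mesh, mask) {
  if (is.character(mask) && length(mask) == 1L) {
    mask <- as.logical(as.numeric(readLines(mask)))
  }
  if (length(mask) != n_vertices(mesh)) stop("mask length mismatch")
  mesh$mask <- as.logical(mask)
  mesh
}

# ---------------------------------------------------------------------------
# File I/O: plain triangle_text dialect and FreeSurfer binary surfaces.

#' Read a surface mesh from disk
#'
#' Two dialects are supported: `triangle_text`, an ASCII format with
#' `v x y z` vertex lines followed by `f i j k` triangle lines holding
#' 0-based vertex indices; and `freesurfer_surface`, the FreeSurfer binary
#' triangle surface format (big-endian, magic 0xFFFFFE).
#'
#' @param path file to read.
#' @param format `"triangle_text"` or `"freesurfer_surface"`.
#' @return a [surface_mesh()] with an all-`TRUE` mask.
#' @export
load_mesh <- function(path, format = c("triangle_text", "freesurfer_surface")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "triangle_text") .read_triangle_text(path)
  else .read_fs_surface(path)
}

#' Write a surface mesh to disk
#'
#' @inheritParams load_mesh
#' @param mesh a `surface_mesh`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("triangle_text", "freesurfer_surface")) {
  format <- match.arg(format)
  if (format == "triangle_text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1L] - 1L,
                       mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L),
               con)
  } else {
    .write_fs_surface(mesh, path)
  }
  invisible(path)
}

.read_triangle_text <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vl <- startsWith(lines, "v ")
  fl <- startsWith(lines, "f ")
  if (any(!vl & !fl)) stop("unrecognized line in triangle_text file: ",
                           lines[which(!vl & !fl)[1L]])
  parse_num <- function(ls, prefix) {
    toks <- strsplit(sub(prefix, "", ls), "[[:space:]]+")
    m <- t(vapply(toks, function(t) as.numeric(t[nzchar(t)]), numeric(3)))
    if (anyNA(m)) stop("unparsable coordinates/indices in ", path)
    m
  }
  verts <- parse_num(lines[vl], "^v ")
  tris <- matrix(integer(0), 0L, 3L)
  if (any(fl)) {
    tris <- parse_num(lines[fl], "^f ")
    if (any(tris != round(tris))) stop("non-integer triangle index")
    tris <- matrix(as.integer(tris), ncol = 3L) + 1L  # file is 0-based
  }
  surface_mesh(verts, tris)
}

.read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  magic_val <- magic[1L] * 65536 + magic[2L] * 256 + magic[3L]
  if (magic_val != 16777214) {  # 0xFFFFFE, triangle file
    stop("not a FreeSurfer triangle surface (bad magic)")
  }
  # comment terminated by "\n\n" (some writers use "\n")
  cmt <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer surface header")
    cmt <- c(cmt, b)
    nc <- length(cmt)
    if (nc >= 2L && cmt[nc] == as.raw(10L) && cmt[nc - 1L] == as.raw(10L)) break
  }
  vnum <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  fnum <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  verts <- readBin(con, "numeric", n = 3L * vnum, size = 4L, endian = "big")
  tris <- readBin(con, "integer", n = 3L * fnum, size = 4L, endian = "big")
  surface_mesh(matrix(verts, ncol = 3L, byrow = TRUE),
               matrix(tris, ncol = 3L, byrow = TRUE) + 1L)
}

.write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeBin(charToRaw("created by surflmm\n\n"), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$triangles)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}
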