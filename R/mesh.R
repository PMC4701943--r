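#' Triangle mesh of a single dendritic spine
#'
#' Light container for a spine surface: an `n x 3` matrix of vertex
#' coordinates in micrometres and an `m x 3` integer matrix of 1-based
#' vertex indices, one row per triangle. Construction validates the
#' geometric invariants every downstream operation relies on: finite
#' coordinates, in-range indices, at least one face and no degenerate
#' (repeated-index) triangle.
#'
#' @param vertices numeric matrix (or data frame) with 3 columns, micrometre
#'   coordinates.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name identifier carried through to file writers.
#' @return An object of class `spine_mesh`: a list with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' tri <- spine_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
#' surface_area(tri)
#' @export
spine_mesh <- function(vertices, faces, name = "spine") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) abort("`vertices` must have 3 columns (x, y, z).")
  if (ncol(faces) != 3) abort("`faces` must have 3 columns of vertex indices.")
  if (nrow(faces) < 1) abort("empty mesh: at least one face is required.")
  if (!all(is.finite(vertices))) abort("non-finite vertex coordinate.")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    abort(sprintf("face index out of range [1, %d].", nrow(vertices)))
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen)) {
    abort(sprintf("degenerate face(s) with repeated vertex indices: %s",
                  paste(utils::head(which(degen), 5), collapse = ", ")))
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "spine_mesh")
}

#' @export
print.spine_mesh <- function(x, ...) {
  cat(sprintf("<spine_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# undirected edge keys "i:j" with i < j, one per face edge occurrence
.edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = ":")
}

#' Count boundary edges of a mesh
#'
#' A boundary edge belongs to exactly one triangle; a closed (watertight)
#' surface has none.
#'
#' @param mesh a [spine_mesh()].
#' @return Integer count of boundary edges.
#' @export
n_boundary_edges <- function(mesh) {
  tab <- table(.edge_keys(mesh$faces))
  sum(tab == 1L)
}

#' Is a mesh closed and consistently oriented?
#'
#' Watertight means every undirected edge is shared by exactly two triangles;
#' consistent orientation additionally requires each directed edge to appear
#' exactly once (adjacent triangles traverse their shared edge in opposite
#' directions).
#'
#' @inheritParams n_boundary_edges
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  und <- table(.edge_keys(f))
  if (!all(und == 2L)) return(FALSE)
  dir <- paste(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]), sep = ">")
  !anyDuplicated(dir)
}

# per-face unnormalised normals (cross products); rows are faces
.face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.median_edge_length <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  stats::median(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                              v[e[, 2], , drop = FALSE])^2)))
}

# rigid transform helper, used by tests and examples
#' Apply a rigid motion (rotation + translation) to a mesh
#'
#' @inheritParams n_boundary_edges
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric offset in micrometres.
#' @return The transformed `spine_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  spine_mesh(v, mesh$faces, mesh$name)
}
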