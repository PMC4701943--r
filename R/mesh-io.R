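#' Read a spine mesh from VRML 2.0, OBJ or PLY
#'
#' VRML support covers the `IndexedFaceSet` subset produced by Imaris surface
#' export: a `coord Coordinate { point [...] }` block plus a `coordIndex`
#' list terminated by `-1` markers. Materials and transforms are ignored.
#' OBJ reads `v`/`f` records (texture/normal references in `f` entries are
#' stripped); PLY reads the ascii dialect. Polygonal faces with more than
#' three vertices are fan-triangulated. Coordinates pass through unchanged
#' and are assumed to be micrometres.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"vrml"`, `"obj"`, `"ply"`. `"auto"` keys
#'   on the file extension (`.wrl`/`.vrml`, `.obj`, `.ply`).
#' @return A [spine_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "vrml", "obj", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      wrl = , vrml = "vrml", obj = "obj", ply = "ply",
      abort(sprintf("cannot infer mesh format from extension '.%s' (%s)",
                    ext, path)))
  }
  name <- tools::file_path_sans_ext(basename(path))
  switch(format,
         vrml = .read_vrml(path, name),
         obj  = .read_obj(path, name),
         ply  = .read_ply(path, name))
}

# fan-triangulate a polygon given as a vector of >= 3 vertex indices
.fan <- function(idx) {
  if (length(idx) < 3) return(NULL)
  cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
}

.extract_bracket <- function(text, keyword, path) {
  open <- regexpr(paste0(keyword, "\\s*\\["), text)
  if (open == -1) {
    abort(sprintf("VRML parse failure in %s: no '%s [' block found", path,
                  keyword))
  }
  start <- open + attr(open, "match.length")
  close <- regexpr("\\]", substr(text, start, nchar(text)))
  if (close == -1) {
    abort(sprintf("VRML parse failure in %s: unterminated '%s' block at offset %d",
                  path, keyword, as.integer(open)))
  }
  substr(text, start, start + close - 2)
}

.read_vrml <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  # strip comments, keep everything on one string for block extraction
  lines <- sub("#.*$", "", lines)
  # (the leading '#VRML V2.0 utf8' header is a comment and drops out here)
  text <- paste(lines, collapse = "\n")
  if (!grepl("IndexedFaceSet", text)) {
    abort(sprintf("VRML parse failure in %s: no IndexedFaceSet found", path))
  }
  pts <- .extract_bracket(text, "point", path)
  idx <- .extract_bracket(text, "coordIndex", path)
  xyz <- scan(text = gsub(",", " ", pts), what = double(), quiet = TRUE)
  if (length(xyz) == 0 || length(xyz) %% 3 != 0) {
    abort(sprintf("VRML parse failure in %s: point list length %d is not a multiple of 3",
                  path, length(xyz)))
  }
  vertices <- matrix(xyz, ncol = 3, byrow = TRUE)
  ids <- scan(text = gsub(",", " ", idx), what = integer(), quiet = TRUE)
  polys <- split(ids, cumsum(c(0, utils::head(ids, -1) == -1L)))
  faces <- do.call(rbind, lapply(polys, function(p) .fan(p[p != -1L] + 1L)))
  if (is.null(faces) || nrow(faces) == 0) {
    abort(sprintf("empty mesh: %s has no faces", path))
  }
  spine_mesh(vertices, faces, name)
}

.read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(flines) == 0) abort(sprintf("empty mesh: %s has no faces", path))
  verts <- t(vapply(strsplit(trimws(sub("^v", "", lines[vlines])), "\\s+"),
                    function(p) as.numeric(p[1:3]), double(3)))
  if (anyNA(verts)) {
    bad <- vlines[which(apply(is.na(verts), 1, any))[1]]
    abort(sprintf("OBJ parse failure in %s at line %d", path, bad))
  }
  faces <- do.call(rbind, lapply(flines, function(ln) {
    toks <- strsplit(trimws(sub("^f", "", lines[ln])), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", toks)))
    if (anyNA(idx)) abort(sprintf("OBJ parse failure in %s at line %d", path, ln))
    .fan(idx)
  }))
  spine_mesh(verts, faces, name)
}

.read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    abort(sprintf("PLY parse failure in %s at line 1: missing 'ply' magic", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort(sprintf("PLY parse failure in %s: no end_header", path))
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format binary", header))) {
    abort(sprintf("PLY parse failure in %s: binary PLY is not supported; re-export as ascii",
                  path))
  }
  elem <- grep("^element ", header, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(strsplit(elem, "\\s+"), `[`, "", 3)),
    vapply(strsplit(elem, "\\s+"), `[`, "", 2))
  nv <- counts[["vertex"]]
  nf <- counts[["face"]]
  if (is.null(nv) || is.null(nf)) {
    abort(sprintf("PLY parse failure in %s: need vertex and face elements", path))
  }
  # vertex property order, to locate x/y/z among possible extras (e.g. rgb)
  vstart <- grep("^element vertex", header)
  vend <- c(grep("^element ", header), end)
  vend <- min(vend[vend > vstart])
  vprops <- vapply(strsplit(grep("^property ",
                                 header[vstart:(vend - 1)], value = TRUE),
                            "\\s+"), function(p) p[length(p)], "")
  xyz_at <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz_at)) {
    abort(sprintf("PLY parse failure in %s: vertex element lacks x/y/z", path))
  }
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    abort(sprintf("PLY parse failure in %s: %d body lines, expected %d",
                  path, length(body), nv + nf))
  }
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(p) as.numeric(p[xyz_at]), double(3)))
  faces <- do.call(rbind, lapply(seq_len(nf), function(i) {
    p <- as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]])
    if (length(p) < p[1] + 1) {
      abort(sprintf("PLY parse failure in %s: short face record %d", path, i))
    }
    .fan(p[2:(p[1] + 1)] + 1L)
  }))
  if (is.null(faces)) abort(sprintf("empty mesh: %s has no faces", path))
  spine_mesh(verts, faces, name)
}

#' Write a spine mesh to VRML 2.0, OBJ or PLY
#'
#' Coordinates are written with 9 significant digits, so a write/read round
#' trip reproduces vertices to well under 1e-6 micrometres.
#'
#' @inheritParams read_mesh
#' @param mesh a [spine_mesh()].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vrml", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      wrl = , vrml = "vrml", obj = "obj", ply = "ply",
      abort(sprintf("cannot infer mesh format from '%s'", path)))
  }
  switch(format,
         vrml = .write_vrml(mesh, path),
         obj  = .write_obj(mesh, path),
         ply  = .write_ply(mesh, path, colors = NULL))
  invisible(path)
}

.num <- function(x) sprintf("%.9g", x)

.write_vrml <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#VRML V2.0 utf8",
    sprintf("# %s", mesh$name),
    "Shape {",
    "  geometry IndexedFaceSet {",
    "    coord Coordinate {",
    "      point ["), con)
  writeLines(sprintf("        %s %s %s,", .num(v[, 1]), .num(v[, 2]),
                     .num(v[, 3])), con)
  writeLines(c("      ]", "    }", "    coordIndex ["), con)
  writeLines(sprintf("      %d, %d, %d, -1,", f[, 1], f[, 2], f[, 3]), con)
  writeLines(c("    ]", "  }", "}"), con)
}

.write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("# %s", mesh$name),
               sprintf("v %s %s %s", .num(v[, 1]), .num(v[, 2]), .num(v[, 3])),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
             path)
}

.write_ply <- function(mesh, path, colors = NULL) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply", "format ascii 1.0", sprintf("comment %s", mesh$name),
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(colors)) {
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vlines <- if (is.null(colors)) {
    sprintf("%s %s %s", .num(v[, 1]), .num(v[, 2]), .num(v[, 3]))
  } else {
    sprintf("%s %s %s %d %d %d", .num(v[, 1]), .num(v[, 2]), .num(v[, 3]),
            colors[1], colors[2], colors[3])
  }
  writeLines(c(hdr, vlines, sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])),
             path)
}

#' Evaluate a named colormap at a score between 0 and 1
#'
#' @param score numeric vector of values in `[0, 1]`.
#' @param colormap `"blue_red"` (default; pure blue at 0, pure red at 1),
#'   `"viridis"`, or `"grey"`.
#' @return Integer matrix with columns red, green, blue in 0..255.
#' @export
colormap_rgb <- function(score, colormap = c("blue_red", "viridis", "grey")) {
  colormap <- match.arg(colormap)
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    abort("`score` must lie in [0, 1].")
  }
  ramp <- switch(colormap,
    blue_red = grDevices::colorRamp(c("blue", "red")),
    viridis  = grDevices::colorRamp(grDevices::hcl.colors(64, "viridis")),
    grey     = grDevices::colorRamp(c("black", "white")))
  rgb <- round(ramp(score))
  storage.mode(rgb) <- "integer"
  colnames(rgb) <- c("red", "green", "blue")
  rgb
}

#' Write a mesh colored by its similarity score
#'
#' File-based counterpart of on-screen score coloring: the whole spine is
#' painted with the colormap value at its score and written as an ascii PLY
#' with per-vertex `uchar` RGB.
#'
#' @inheritParams write_mesh
#' @param score scalar in `[0, 1]`.
#' @param colormap see [colormap_rgb()].
#' @return `path`, invisibly.
#' @export
write_colored_mesh <- function(mesh, score, path, colormap = "blue_red") {
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score) ||
      score < 0 || score > 1) {
    abort("`score` must be a single value in [0, 1].")
  }
  .write_ply(mesh, path, colors = colormap_rgb(score, colormap)[1, ])
  invisible(path)
}
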