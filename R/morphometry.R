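#' Total surface area of a spine mesh
#'
#' Sum of triangle areas, in square micrometres. Includes every triangle
#' (caps as well as lateral surface), matching the convention of total
#' surface measurements from segmentation software.
#'
#' @param mesh a [spine_mesh()].
#' @return Scalar area.
#' @export
surface_area <- function(mesh) {
  sum(sqrt(rowSums(.face_cross(mesh)^2))) / 2
}

#' Volume enclosed by a closed spine mesh
#'
#' Divergence-theorem volume: absolute value of the signed sum of
#' origin-anchored tetrahedra, one per face. Exact for any closed,
#' consistently oriented triangulation and independent of translation.
#'
#' @param mesh a closed [spine_mesh()].
#' @return Scalar volume in cubic micrometres.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_watertight(mesh)) {
    abort(sprintf("mesh '%s' is not watertight (%d boundary edges); volume is undefined",
                  mesh$name, n_boundary_edges(mesh)))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  signed <- rowSums(a * .face_cross(mesh)) / 6
  abs(sum(signed))
}

#' Spine axis and length from the edge-graph geodesic
#'
#' The spine tip is taken as the mesh point maximally geodesically distant
#' from the attachment, with geodesic distance approximated by shortest
#' paths on the edge graph. The axis is a centerline polyline obtained by
#' binning vertices by geodesic distance and taking bin centroids, so it
#' runs through the interior of the spine rather than along its surface;
#' spine length is the polyline arc length. The polyline starts at the
#' attachment point and ends at the tip vertex, so length is never below
#' the Euclidean attachment-tip distance.
#'
#' @param mesh a [spine_mesh()].
#' @param attachment length-3 point where the spine meets its dendrite
#'   (for synthetic fixtures, the base-disk center). Must lie within twice
#'   the median edge length of the mesh surface.
#' @param n_bins number of geodesic-distance bins for the centerline.
#' @return Object of class `spine_axis`: list with `points` (polyline
#'   matrix), `length` (micrometres), `attachment`, `tip`.
#' @export
spine_axis <- function(mesh, attachment, n_bins = 24) {
  attachment <- as.numeric(attachment)
  v <- mesh$vertices
  d2 <- sqrt(colSums((t(v) - attachment)^2))
  v0 <- which.min(d2)
  med <- .median_edge_length(mesh)
  if (d2[v0] > 2 * med) {
    abort(sprintf("attachment point is %.3g um from the mesh (limit %.3g): wrong spine or wrong point?",
                  d2[v0], 2 * med))
  }
  f <- mesh$faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]))
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  gd <- as.numeric(igraph::distances(g, v = v0, weights = w))
  tip <- which.max(gd)
  # centroid polyline: vertices binned by geodesic distance; distances are
  # quantized first so a symmetric vertex ring sitting on a bin boundary
  # (ubiquitous in tessellated solids) falls into one bin atomically
  tol <- gd[tip] * 1e-9
  gdq <- round(gd / tol) * tol
  br <- seq(0, gd[tip], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(gdq, br, rightmost.closed = TRUE), 1L), n_bins)
  cent <- t(vapply(seq_len(n_bins), function(b) {
    if (!any(bin == b)) return(c(NA_real_, NA_real_, NA_real_))
    colMeans(v[bin == b, , drop = FALSE])
  }, double(3)))
  pts <- rbind(attachment, cent[stats::complete.cases(cent), , drop = FALSE],
               v[tip, ])
  # drop consecutive near-duplicates so arc positions increase strictly
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  seglen <- sqrt(rowSums(diff(pts)^2))
  structure(list(points = unname(pts), length = sum(seglen),
                 attachment = attachment, tip = unname(v[tip, ])),
            class = "spine_axis")
}

#' @export
print.spine_axis <- function(x, ...) {
  cat(sprintf("<spine_axis: length %.4g um, %d polyline points>\n",
              x$length, nrow(x$points)))
  invisible(x)
}

# point and unit tangent at arc position s along a polyline
.axis_at <- function(axis, s) {
  pts <- axis$points
  seglen <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-12))
  i <- min(i, length(seglen))
  frac <- (s - cum[i]) / seglen[i]
  p <- pts[i, ] + frac * (pts[i + 1, ] - pts[i, ])
  # smoothed tangent over a window of the arc, robust to centroid wobble
  h <- max(axis$length / 16, 1e-6)
  pa <- .polyline_point(pts, cum, max(s - h, 0))
  pb <- .polyline_point(pts, cum, min(s + h, cum[length(cum)]))
  t <- pb - pa
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12) t <- pts[nrow(pts), ] - pts[1, ] else t <- t / nt
  list(point = p, tangent = t / sqrt(sum(t^2)))
}

.polyline_point <- function(pts, cum, s) {
  i <- max(which(cum <= s + 1e-12))
  i <- min(i, nrow(pts) - 1)
  frac <- if (cum[i + 1] > cum[i]) (s - cum[i]) / (cum[i + 1] - cum[i]) else 0
  pts[i, ] + frac * (pts[i + 1, ] - pts[i, ])
}

# intersect a closed mesh with the plane through `origin` with normal `normal`;
# returns list of loops, each a matrix of 2D in-plane coordinates
.plane_sections <- function(mesh, origin, normal) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric((v %*% normal) - sum(origin * normal))
  d[abs(d) < 1e-12] <- 1e-12  # nudge on-plane vertices to one side
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  mixed <- which((s1 | s2 | s3) & !(s1 & s2 & s3))
  if (!length(mixed)) return(list())
  # undirected edge key for an (i, j) crossing
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = ":")
  cross_pt <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  # per mixed triangle: the two crossing edges and their intersection points
  tri_edges <- vector("list", length(mixed))
  for (k in seq_along(mixed)) {
    tri <- f[mixed[k], ]
    sg <- d[tri] > 0
    pairs <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    crossing <- sg[c(1, 2, 3)] != sg[c(2, 3, 1)]
    pe <- pairs[crossing, , drop = FALSE]
    tri_edges[[k]] <- list(keys = ekey(pe[, 1], pe[, 2]),
                           pts = rbind(cross_pt(pe[1, 1], pe[1, 2]),
                                       cross_pt(pe[2, 1], pe[2, 2])))
  }
  # map edge key -> triangles (each interior crossing edge borders two)
  edge_map <- new.env(parent = emptyenv())
  for (k in seq_along(tri_edges)) {
    for (key in tri_edges[[k]]$keys) {
      edge_map[[key]] <- c(edge_map[[key]], k)
    }
  }
  used <- logical(length(mixed))
  loops <- list()
  for (start in seq_along(mixed)) {
    if (used[start]) next
    cur <- start
    enter_key <- tri_edges[[cur]]$keys[1]
    loop_pts <- NULL
    repeat {
      used[cur] <- TRUE
      te <- tri_edges[[cur]]
      exit_i <- if (te$keys[1] == enter_key) 2L else 1L
      loop_pts <- rbind(loop_pts, te$pts[exit_i, ])
      exit_key <- te$keys[exit_i]
      nbrs <- edge_map[[exit_key]]
      nxt <- nbrs[nbrs != cur]
      if (length(nxt) != 1 || used[nxt[1]]) break
      enter_key <- exit_key
      cur <- nxt[1]
    }
    if (!is.null(loop_pts) && nrow(loop_pts) >= 3) {
      loops[[length(loops) + 1]] <- loop_pts
    }
  }
  # project each loop into plane coordinates
  u <- .orthonormal(normal)
  lapply(loops, function(L) {
    rel <- sweep(L, 2, origin)
    cbind(rel %*% u$a, rel %*% u$b)
  })
}

.orthonormal <- function(n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- ref - sum(ref * n) * n
  a <- a / sqrt(sum(a^2))
  b <- c(n[2] * a[3] - n[3] * a[2],
         n[3] * a[1] - n[1] * a[3],
         n[1] * a[2] - n[2] * a[1])
  list(a = a, b = b)
}

.polygon_area2d <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.point_in_polygon <- function(pt, poly) {
  x <- poly[, 1] - pt[1]; y <- poly[, 2] - pt[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crossing <- ((y > 0) != (yn > 0)) & ((x * yn - xn * y) / (yn - y) > 0)
  sum(crossing) %% 2 == 1
}

#' Cross-section profile along the spine axis
#'
#' Cuts the mesh with planes perpendicular to the local axis direction at
#' `n_stations` arc positions (station midpoints, so end planes are never
#' tangential) and records the equivalent-circle diameter
#' `2 * sqrt(area / pi)` of the intersection loop containing the axis point
#' (nearest loop if centerline wobble puts the point just outside).
#' Stations with no usable loop are dropped; more than 20% dropped is an
#' error.
#'
#' @param mesh a closed [spine_mesh()].
#' @param axis a [spine_axis()] for the same mesh.
#' @param n_stations number of stations, at least 8.
#' @return Tibble of class `cross_section_profile` with columns `station`
#'   (arc position, micrometres) and `diameter`.
#' @export
cross_section_profile <- function(mesh, axis, n_stations = 32) {
  if (n_stations < 8) abort("`n_stations` must be at least 8.")
  L <- axis$length
  stations <- (seq_len(n_stations) - 0.5) * L / n_stations
  diam <- vapply(stations, function(s) {
    at <- .axis_at(axis, s)
    loops <- .plane_sections(mesh, at$point, at$tangent)
    if (!length(loops)) return(NA_real_)
    contains <- vapply(loops, function(p) .point_in_polygon(c(0, 0), p), TRUE)
    pick <- if (any(contains)) {
      which(contains)[which.max(vapply(loops[contains], .polygon_area2d, 1))]
    } else {
      which.min(vapply(loops, function(p) sum(colMeans(p)^2), 1))
    }
    a <- .polygon_area2d(loops[[pick]])
    if (a <= 0) NA_real_ else 2 * sqrt(a / pi)
  }, 1)
  ok <- !is.na(diam)
  if (mean(!ok) > 0.2) {
    abort(sprintf("profile error: no intersection loop at %d of %d stations",
                  sum(!ok), n_stations))
  }
  out <- tibble(station = stations[ok], diameter = diam[ok])
  class(out) <- c("cross_section_profile", class(out))
  attr(out, "axis_length") <- L
  out
}

#' Maximum equivalent diameter over a profile
#'
#' @param profile a [cross_section_profile()].
#' @return Scalar micrometre diameter.
#' @export
max_diameter <- function(profile) {
  if (nrow(profile) == 0) abort("empty cross-section profile.")
  max(profile$diameter)
}

#' Mean neck diameter from a profile
#'
#' The neck is the contiguous run of proximal stations (starting at the
#' attachment end) whose diameter stays below `neck_frac` times the profile
#' maximum. Returns `NA` when the first station already exceeds the
#' threshold, i.e. for neckless (stubby) spines.
#'
#' @inheritParams max_diameter
#' @param neck_frac fraction of the maximum diameter delimiting the neck.
#' @return Scalar diameter, or `NA` if no neck is detected.
#' @export
neck_mean_diameter <- function(profile, neck_frac = 0.7) {
  if (nrow(profile) == 0) abort("empty cross-section profile.")
  thr <- neck_frac * max(profile$diameter)
  below <- profile$diameter < thr
  if (!below[1]) return(NA_real_)
  run <- cumprod(below) == 1
  mean(profile$diameter[run])
}

#' Three-way spine classification
#'
#' Stubby when no neck is detectable; otherwise mushroom when the maximum
#' diameter reaches the smallest modelled head (0.43 micrometres by
#' default), else thin (small-headed protrusions and filopodia, excluded
#' from the biophysical model).
#'
#' @param max_diameter,neck_mean_diameter numeric vectors (micrometres);
#'   `NA` neck means no neck detected.
#' @param head_min_diameter smallest head diameter still counted as a
#'   mushroom head.
#' @return Character vector in `c("mushroom", "stubby", "thin")`.
#' @export
classify_spine <- function(max_diameter, neck_mean_diameter,
                           head_min_diameter = 0.43) {
  dplyr::case_when(
    is.na(neck_mean_diameter) ~ "stubby",
    max_diameter >= head_min_diameter ~ "mushroom",
    TRUE ~ "thin")
}

#' Full morphometry of one spine mesh
#'
#' Composes [enclosed_volume()], [surface_area()], [spine_axis()],
#' [cross_section_profile()], [max_diameter()], [neck_mean_diameter()] and
#' [classify_spine()] into the five morphological features plus class.
#'
#' @inheritParams spine_axis
#' @inheritParams cross_section_profile
#' @inheritParams neck_mean_diameter
#' @inheritParams classify_spine
#' @return One-row tibble with columns `volume`, `area`, `length`,
#'   `max_diameter`, `neck_mean_diameter`, `spine_class`.
#' @examples
#' fx <- make_cylinder_mesh(d = 1, L = 2, n_seg = 32)
#' spine_morphometry(fx$mesh, fx$attachment)
#' @export
spine_morphometry <- function(mesh, attachment, n_stations = 32,
                              neck_frac = 0.7, head_min_diameter = 0.43) {
  vol <- enclosed_volume(mesh)
  area <- surface_area(mesh)
  axis <- spine_axis(mesh, attachment)
  prof <- cross_section_profile(mesh, axis, n_stations)
  maxd <- max_diameter(prof)
  neckd <- neck_mean_diameter(prof, neck_frac)
  stopifnot(vol > 0, area > 0, axis$length > 0,
            is.na(neckd) || maxd >= neckd)
  tibble(volume = vol, area = area, length = axis$length,
         max_diameter = maxd, neck_mean_diameter = neckd,
         spine_class = classify_spine(maxd, neckd, head_min_diameter))
}

#' @rdname cross_section_profile
#' @param object a `cross_section_profile`.
#' @param ... ignored.
#' @method autoplot cross_section_profile
#' @export
autoplot.cross_section_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$station, y = .data$diameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "arc position along spine axis (µm)",
                  y = "equivalent diameter (µm)") +
    ggplot2::theme_minimal()
}
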