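#' Exact geometry of a regular-polygon prism section
#'
#' Closed-form area, perimeter and equivalent-circle diameter of the
#' regular n-gon inscribed in a circle of diameter `d`. Fixture ground
#' truth uses these faceted-solid formulas, not smooth-cylinder ones, so
#' mesh oracles are tolerance-free at any resolution; the smooth values are
#' recovered only in the `n_seg -> Inf` limit.
#'
#' @param d circumscribed diameter, micrometres.
#' @param n_seg number of polygon segments.
#' @return List with `area`, `perimeter`, `equiv_diameter`.
#' @export
polygon_section <- function(d, n_seg) {
  r <- d / 2
  area <- 0.5 * n_seg * r^2 * sin(2 * pi / n_seg)
  per <- 2 * n_seg * r * sin(pi / n_seg)
  list(area = area, perimeter = per, equiv_diameter = 2 * sqrt(area / pi))
}

# ring of n vertices at height z, circumscribed diameter d
.ring <- function(d, n, z) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind((d / 2) * cos(th), (d / 2) * sin(th), z)
}

# side faces between two rings of equal segment count; outward orientation
# for counterclockwise rings (viewed from +z) with lower ring first
.side_faces <- function(lo, hi, n) {
  k <- seq_len(n)
  k1 <- c(seq_len(n - 1) + 1, 1)  # next index around the ring
  rbind(cbind(lo + k - 1, lo + k1 - 1, hi + k1 - 1),
        cbind(lo + k - 1, hi + k1 - 1, hi + k - 1))
}

# cap fan around a center vertex; `up` chooses outward +z or -z normal
.cap_faces <- function(ring_start, center, n, up) {
  k <- seq_len(n)
  k1 <- c(seq_len(n - 1) + 1, 1)
  if (up) cbind(center, ring_start + k - 1, ring_start + k1 - 1)
  else    cbind(center, ring_start + k1 - 1, ring_start + k - 1)
}

.fixture <- function(mesh, attachment, truth, geometry) {
  stopifnot(is_watertight(mesh))
  structure(list(mesh = mesh, attachment = attachment, truth = truth,
                 geometry = geometry),
            class = "spine_fixture")
}

#' @export
print.spine_fixture <- function(x, ...) {
  cat(sprintf("<spine_fixture '%s' (%s): truth volume %.4g um3, length %.4g um>\n",
              x$mesh$name, x$truth$spine_class, x$truth$volume,
              x$truth$length))
  invisible(x)
}

#' Capped prism ("cylinder") fixture with analytic ground truth
#'
#' A closed regular-prism solid standing on the z = 0 plane, attachment at
#' the base center. The lateral wall is subdivided axially so interior
#' vertices exist for axis extraction. Ground truth is exact for the
#' faceted solid: `truth$volume = A_n * L`, `truth$area = P_n * L + 2 A_n`,
#' `truth$max_diameter` the equivalent diameter of the n-gon section.
#'
#' @param d,L diameter and length, micrometres (positive).
#' @param n_seg polygon segments, at least 8.
#' @param name mesh identifier.
#' @return A `spine_fixture`: list with `mesh`, `attachment`, `truth`
#'   (one-row tibble matching [spine_morphometry()] columns), `geometry`
#'   (a stubby [spine_geometry()]).
#' @export
make_cylinder_mesh <- function(d, L, n_seg = 64, name = "cylinder") {
  if (n_seg < 8) abort("`n_seg` must be at least 8.")
  stopifnot(d > 0, L > 0)
  n_ax <- max(2L, min(32L, ceiling(2 * L / d)))
  zs <- seq(0, L, length.out = n_ax + 1)
  verts <- do.call(rbind, lapply(zs, function(z) .ring(d, n_seg, z)))
  starts <- (seq_len(n_ax + 1) - 1) * n_seg + 1
  faces <- do.call(rbind, lapply(seq_len(n_ax), function(j) {
    .side_faces(starts[j], starts[j + 1], n_seg)
  }))
  c_bot <- nrow(verts) + 1L
  c_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, L))
  faces <- rbind(faces,
                 .cap_faces(starts[1], c_bot, n_seg, up = FALSE),
                 .cap_faces(starts[n_ax + 1], c_top, n_seg, up = TRUE))
  mesh <- spine_mesh(verts, faces, name)
  sec <- polygon_section(d, n_seg)
  truth <- tibble(volume = sec$area * L,
                  area = sec$perimeter * L + 2 * sec$area,
                  length = L,
                  max_diameter = sec$equiv_diameter,
                  neck_mean_diameter = NA_real_,
                  spine_class = "stubby")
  .fixture(mesh, c(0, 0, 0), truth,
           spine_geometry("stubby", diameter = d, length = L))
}

#' Stubby spine fixture
#'
#' Alias of [make_cylinder_mesh()]: stubby spines are single cylinders.
#'
#' @inheritParams make_cylinder_mesh
#' @return A `spine_fixture`.
#' @export
make_stubby_mesh <- function(d, L, n_seg = 64, name = "stubby") {
  make_cylinder_mesh(d, L, n_seg, name)
}

#' Mushroom spine fixture: welded neck and head prisms
#'
#' Two coaxial capped prisms (neck below, head above) sharing their
#' junction plane, joined by an annulus of triangles so the surface is a
#' single watertight solid. Attachment at the neck base center.
#'
#' Ground truth follows the profile-extraction contract: when the neck is
#' narrower than `neck_frac` times the head (`neck_d < neck_frac * head_d`)
#' the fixture reports the faceted neck diameter and a mushroom (or thin,
#' for sub-threshold heads) class; a wider neck is undetectable by the
#' proximal-run rule and the fixture honestly reports `NA` neck and class
#' stubby.
#'
#' @param head_d,head_l head prism diameter and length, micrometres.
#' @param neck_d,neck_l neck prism diameter and length, micrometres.
#' @param n_seg polygon segments, at least 8.
#' @param neck_frac neck-detection threshold used for the truth label.
#' @param head_min_diameter mushroom/thin head threshold for the truth
#'   label.
#' @param name mesh identifier.
#' @return A `spine_fixture`.
#' @export
make_mushroom_spine_mesh <- function(head_d, head_l, neck_d, neck_l,
                                     n_seg = 64, neck_frac = 0.7,
                                     head_min_diameter = 0.43,
                                     name = "mushroom") {
  if (n_seg < 8) abort("`n_seg` must be at least 8.")
  stopifnot(head_d > 0, head_l > 0, neck_d > 0, neck_l > 0)
  if (head_d <= neck_d) {
    abort("head diameter must exceed neck diameter for a mushroom fixture.")
  }
  n_ax_n <- max(2L, min(32L, ceiling(2 * neck_l / neck_d)))
  n_ax_h <- max(2L, min(32L, ceiling(2 * head_l / head_d)))
  zs_n <- seq(0, neck_l, length.out = n_ax_n + 1)
  zs_h <- seq(neck_l, neck_l + head_l, length.out = n_ax_h + 1)
  verts <- rbind(do.call(rbind, lapply(zs_n, function(z) .ring(neck_d, n_seg, z))),
                 do.call(rbind, lapply(zs_h, function(z) .ring(head_d, n_seg, z))))
  nstart <- (seq_len(n_ax_n + 1) - 1) * n_seg + 1
  hstart <- (n_ax_n + 1) * n_seg + (seq_len(n_ax_h + 1) - 1) * n_seg + 1
  faces <- rbind(
    do.call(rbind, lapply(seq_len(n_ax_n), function(j) {
      .side_faces(nstart[j], nstart[j + 1], n_seg)
    })),
    # annulus between neck top ring and head bottom ring (same z, same
    # angles): quads facing downward/outward
    .side_faces(nstart[n_ax_n + 1], hstart[1], n_seg),
    do.call(rbind, lapply(seq_len(n_ax_h), function(j) {
      .side_faces(hstart[j], hstart[j + 1], n_seg)
    })))
  c_bot <- nrow(verts) + 1L
  c_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, neck_l + head_l))
  faces <- rbind(faces,
                 .cap_faces(nstart[1], c_bot, n_seg, up = FALSE),
                 .cap_faces(hstart[n_ax_h + 1], c_top, n_seg, up = TRUE))
  mesh <- spine_mesh(verts, faces, name)
  sec_n <- polygon_section(neck_d, n_seg)
  sec_h <- polygon_section(head_d, n_seg)
  neck_detectable <- neck_d < neck_frac * head_d
  cls <- if (!neck_detectable) "stubby"
         else if (sec_h$equiv_diameter >= head_min_diameter) "mushroom"
         else "thin"
  truth <- tibble(
    volume = sec_n$area * neck_l + sec_h$area * head_l,
    area = sec_n$perimeter * neck_l + sec_h$perimeter * head_l +
      2 * sec_h$area,   # base cap + annulus + top cap = 2 * head section
    length = neck_l + head_l,
    max_diameter = sec_h$equiv_diameter,
    neck_mean_diameter = if (neck_detectable) sec_n$equiv_diameter else NA_real_,
    spine_class = cls)
  .fixture(mesh, c(0, 0, 0), truth,
           spine_geometry("mushroom", head_diameter = head_d,
                          head_length = head_l, neck_diameter = neck_d,
                          neck_length = neck_l))
}

#' Sample spine fixtures from the modelled dimension ranges
#'
#' Draws mushroom and stubby fixtures with dimensions uniform over the
#' modelled ranges (mushroom neck diameter 0.175-1 um and length
#' 0.38-4.37 um, head diameter and length 0.43-1.04 um; stubby diameter
#' 0.44-1.15 um and length 0.32-1.66 um). Mushroom neck diameters are
#' additionally capped at 0.6 x head diameter so every drawn fixture has a
#' profile-detectable neck.
#'
#' @param n number of fixtures.
#' @param seed RNG seed (single stream, reproducible).
#' @param n_seg polygon segments per fixture.
#' @param p_mushroom probability a draw is a mushroom (vs stubby).
#' @return List of `spine_fixture` objects.
#' @export
make_spine_fixtures <- function(n, seed = 1, n_seg = 64, p_mushroom = 0.6) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    if (runif(1) < p_mushroom) {
      head_d <- runif(1, 0.43, 1.04)
      make_mushroom_spine_mesh(
        head_d = head_d,
        head_l = runif(1, 0.43, 1.04),
        neck_d = runif(1, 0.175, min(1, 0.6 * head_d)),
        neck_l = runif(1, 0.38, 4.37),
        n_seg = n_seg, name = sprintf("fixture_%03d", i))
    } else {
      make_stubby_mesh(d = runif(1, 0.44, 1.15), L = runif(1, 0.32, 1.66),
                       n_seg = n_seg, name = sprintf("fixture_%03d", i))
    }
  })
}
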