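# uniform draw over a printed range, optionally concentrated around its
# midpoint (concentration = 1 reproduces the full range)
.runif_range <- function(n, lo, hi, concentration = 1) {
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2 * concentration
  runif(n, mid - half, mid + half)
}

# synthetic dendritic paths: positions are metadata, laid out so regions
# occupy distinct parts of space (apical trunk up +z, collaterals branching
# off it, basal dendrites in the lower hemisphere)
.spine_positions <- function(region) {
  n <- length(region)
  x <- y <- z <- numeric(n)
  am <- region == "apical_main"
  z[am] <- runif(sum(am), 0, 540)
  x[am] <- runif(sum(am), -3, 3); y[am] <- runif(sum(am), -3, 3)
  ac <- region == "apical_collateral"
  z0 <- runif(sum(ac), 50, 500)
  th <- runif(sum(ac), 0, 2 * pi); rr <- runif(sum(ac), 5, 120)
  x[ac] <- rr * cos(th); y[ac] <- rr * sin(th); z[ac] <- z0
  ba <- region == "basal"
  u <- runif(sum(ba), -1, -0.05); phi <- runif(sum(ba), 0, 2 * pi)
  rho <- runif(sum(ba), 5, 150); s <- sqrt(1 - u^2)
  x[ba] <- rho * s * cos(phi); y[ba] <- rho * s * sin(phi); z[ba] <- rho * u
  cbind(x = x, y = y, z = z)
}

#' Generate a synthetic per-spine feature table
#'
#' Emulates the shape of a reconstructed pyramidal neuron's spine dataset:
#' spines distributed over basal, main-apical and apical-collateral
#' regions (default proportions follow the relative dendritic lengths
#' 4263 : 540 : 3890 um), drawn from three morphological kinds, with
#' dimensions uniform over the modelled ranges per kind (mushroom neck
#' diameter 0.175-1 um and length 0.38-4.37 um, head diameter and length
#' 0.43-1.04 um; stubby diameter 0.44-1.15 um and length 0.32-1.66 um;
#' thin spines below the modelled head range). The five morphological
#' features come from the lumped-cylinder closed forms; the
#' membrane-potential peak is simulated per spine (missing for thin
#' spines, which the biophysical model excludes). Planted regional
#' multipliers are applied to features after the draw. Deterministic given
#' `seed` (single RNG stream).
#'
#' @param n_spines number of spines.
#' @param seed RNG seed.
#' @param region_proportions named numeric, must sum to 1.
#' @param kind_proportions named numeric over mushroom/stubby/thin.
#' @param planted_effects named list: region -> named feature multipliers,
#'   e.g. `list(apical_main = c(Volume = 2))`.
#' @param range_concentration in (0, 1]: 1 draws over each full printed
#'   range, smaller values concentrate draws around the range midpoint
#'   (used by the structured positive-control preset).
#' @param peaks simulate the `MembranePotentialPeak` feature (slower).
#' @param cable,synapse,config biophysical parameters for the peak.
#' @return Tibble with columns `id`, `x`, `y`, `z`, `region`,
#'   `spine_class`, `Volume`, `Area`, `Length`, `MaxDiameter`,
#'   `NeckMeanDiameter` and (with `peaks = TRUE`) `MembranePotentialPeak`.
#' @examples
#' tab <- generate_feature_dataset(n_spines = 20, seed = 7, peaks = FALSE)
#' dplyr::count(tab, region, spine_class)
#' @export
generate_feature_dataset <- function(n_spines = 1000, seed = 1,
                                     region_proportions = c(basal = 0.490,
                                                            apical_main = 0.062,
                                                            apical_collateral = 0.448),
                                     kind_proportions = c(mushroom = 0.5,
                                                          stubby = 0.3,
                                                          thin = 0.2),
                                     planted_effects = list(),
                                     range_concentration = 1,
                                     peaks = TRUE,
                                     cable = cable_params(),
                                     synapse = synapse_params(),
                                     config = sim_config()) {
  stopifnot(n_spines >= 1,
            abs(sum(region_proportions) - 1) < 1e-8,
            abs(sum(kind_proportions) - 1) < 1e-8,
            range_concentration > 0, range_concentration <= 1)
  set.seed(seed)
  f <- range_concentration
  region <- sample(names(region_proportions), n_spines, replace = TRUE,
                   prob = region_proportions)
  kind <- sample(names(kind_proportions), n_spines, replace = TRUE,
                 prob = kind_proportions)
  n <- n_spines
  head_d <- head_l <- neck_d <- neck_l <- rep(NA_real_, n)
  vol <- area <- len <- maxd <- neckd <- rep(NA_real_, n)

  mu <- kind == "mushroom"
  if (any(mu)) {
    head_d[mu] <- .runif_range(sum(mu), 0.43, 1.04, f)
    head_l[mu] <- .runif_range(sum(mu), 0.43, 1.04, f)
    # cap at 0.6 x head so the neck is always narrower than the head and
    # detectable by the profile rule; stays inside the 0.175-1 um range
    neck_d[mu] <- pmin(.runif_range(sum(mu), 0.175, 1, f), 0.6 * head_d[mu])
    neck_l[mu] <- .runif_range(sum(mu), 0.38, 4.37, f)
  }
  st <- kind == "stubby"
  if (any(st)) {
    head_d[st] <- .runif_range(sum(st), 0.44, 1.15, f)
    head_l[st] <- .runif_range(sum(st), 0.32, 1.66, f)
  }
  th <- kind == "thin"
  if (any(th)) {
    head_d[th] <- .runif_range(sum(th), 0.20, 0.42, f)
    head_l[th] <- .runif_range(sum(th), 0.20, 0.42, f)
    neck_d[th] <- pmin(.runif_range(sum(th), 0.10, 0.29, f), 0.6 * head_d[th])
    neck_l[th] <- .runif_range(sum(th), 0.50, 4.37, f)
  }

  two_cyl <- mu | th
  vol[two_cyl] <- pi / 4 * (head_d[two_cyl]^2 * head_l[two_cyl] +
                            neck_d[two_cyl]^2 * neck_l[two_cyl])
  area[two_cyl] <- pi * (head_d[two_cyl] * head_l[two_cyl] +
                         neck_d[two_cyl] * neck_l[two_cyl]) +
    pi / 2 * head_d[two_cyl]^2
  len[two_cyl] <- head_l[two_cyl] + neck_l[two_cyl]
  neckd[two_cyl] <- neck_d[two_cyl]

  vol[st] <- pi / 4 * head_d[st]^2 * head_l[st]
  area[st] <- pi * head_d[st] * head_l[st] + pi / 2 * head_d[st]^2
  len[st] <- head_l[st]
  maxd <- head_d

  pos <- .spine_positions(region)
  out <- tibble(id = sprintf("spine_%05d", seq_len(n)),
                x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                region = region, spine_class = kind,
                Volume = vol, Area = area, Length = len,
                MaxDiameter = maxd, NeckMeanDiameter = neckd)
  if (peaks) {
    geom_tab <- tibble(spine_class = kind, MaxDiameter = head_d,
                       NeckMeanDiameter = neck_d,
                       head_length = head_l, neck_length = neck_l)
    out$MembranePotentialPeak <- .peaks_from_dims(geom_tab, cable, synapse,
                                                  config)
  }
  for (reg in names(planted_effects)) {
    eff <- planted_effects[[reg]]
    rows <- out$region == reg
    for (feat in names(eff)) {
      out[[feat]][rows] <- out[[feat]][rows] * eff[[feat]]
    }
  }
  out
}

# peaks from the generating cylinder dimensions themselves (no morphometry
# round trip): thin spines are excluded from the model -> NA
.peaks_from_dims <- function(g, cable, synapse, config) {
  vapply(seq_len(nrow(g)), function(i) {
    if (g$spine_class[i] == "thin") return(NA_real_)
    geom <- if (g$spine_class[i] == "mushroom") {
      spine_geometry("mushroom", head_diameter = g$MaxDiameter[i],
                     head_length = g$head_length[i],
                     neck_diameter = g$NeckMeanDiameter[i],
                     neck_length = g$neck_length[i])
    } else {
      spine_geometry("stubby", diameter = g$MaxDiameter[i],
                     length = g$head_length[i])
    }
    membrane_potential_peak(geom, cable, synapse, config)
  }, 1)
}

#' Structured-neuron preset: planted apical-main enlargement
#'
#' Positive-control dataset for retrieval: the largest spines sit on the
#' main apical dendrite. Mushroom spines only, dimensions drawn from the
#' central 15% of each modelled range (so within-region volume spread is
#' small against the planted effect: the 75th/10th volume percentile ratio
#' is about 1.25), and apical-main Volume and Area multiplied by 2. With
#' this construction every doubled apical-main spine clears the top
#' volume quartile structurally, for any seed - which is exactly what a
#' planted-effect recovery control should guarantee. Region labels double
#' as ground-truth labels.
#'
#' @param n number of spines, at least 100.
#' @param seed RNG seed.
#' @param peaks simulate membrane-potential peaks (off by default; the
#'   recovery control is morphological).
#' @return Tibble as in [generate_feature_dataset()].
#' @export
generate_structured_neuron <- function(n = 1000, seed = 1, peaks = FALSE) {
  if (n < 100) abort("the structured preset needs n >= 100.")
  generate_feature_dataset(
    n_spines = n, seed = seed,
    kind_proportions = c(mushroom = 1, stubby = 0, thin = 0),
    planted_effects = list(apical_main = c(Volume = 2, Area = 2)),
    range_concentration = 0.15,
    peaks = peaks)
}

#' Write synthetic fixture meshes plus their ground-truth table
#'
#' Convenience for the command line: writes each fixture as both PLY and
#' VRML and one CSV of analytic truth values.
#'
#' @param dir output directory (created if needed).
#' @inheritParams make_spine_fixtures
#' @return Tibble of truth values, invisibly.
#' @export
write_fixture_set <- function(dir, n = 10, seed = 1, n_seg = 64) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- make_spine_fixtures(n, seed, n_seg)
  truth <- purrr::map_dfr(fixtures, function(fx) {
    write_mesh(fx$mesh, file.path(dir, paste0(fx$mesh$name, ".ply")))
    write_mesh(fx$mesh, file.path(dir, paste0(fx$mesh$name, ".wrl")))
    dplyr::mutate(fx$truth, id = fx$mesh$name, .before = 1)
  })
  readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(truth)
}
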