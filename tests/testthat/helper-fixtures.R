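# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit cube mesh, outward-oriented (12 triangles)
cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),        # bottom (z = 0), normal -z
             c(5, 6, 7), c(5, 7, 8),        # top (z = 1), normal +z
             c(1, 2, 6), c(1, 6, 5),        # y = 0
             c(2, 3, 7), c(2, 7, 6),        # x = 1
             c(3, 4, 8), c(3, 8, 7),        # y = 1
             c(4, 1, 5), c(4, 5, 8))        # x = 0
  spine_mesh(v, f, "cube")
}

# tetrahedron on the unit axes: volume 1/6
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  spine_mesh(v, f, "tetra")
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# a cross-section profile built directly (for the diameter-rule units)
profile_of <- function(diams, length = 1) {
  n <- base::length(diams)
  out <- tibble::tibble(station = (seq_len(n) - 0.5) * length / n,
                        diameter = diams)
  class(out) <- c("cross_section_profile", class(out))
  out
}

# independent high-accuracy reference: lsoda on the circuit ODEs
reference_head_peak <- function(circ, syn, tmax = 20) {
  comps <- circ$compartments
  n <- nrow(comps)
  Em <- circ$cable$Em
  gbar <- peak_synaptic_conductance(circ, syn)
  rhs <- function(t, V, p) {
    gs <- alpha_conductance(t - syn$onset, gbar, syn$tau_syn)
    dV <- numeric(n)
    for (i in seq_len(n)) {
      I <- comps$g_leak_S[i] * (Em - V[i])
      for (k in seq_len(nrow(circ$couplings))) {
        ii <- circ$couplings$i[k]
        jj <- circ$couplings$j[k]
        if (ii == i) I <- I + (V[jj] - V[i]) / circ$couplings$R_Ohm[k]
        if (jj == i) I <- I + (V[ii] - V[i]) / circ$couplings$R_Ohm[k]
      }
      if (i == circ$syn_comp) I <- I + gs * (syn$Esyn - V[i])
      dV[i] <- I / comps$C_F[i] * 1e-3   # mV per ms
    }
    list(dV)
  }
  out <- deSolve::lsoda(rep(Em, n), seq(0, tmax, by = 0.002), rhs, NULL,
                        rtol = 1e-11, atol = 1e-11)
  max(out[, 1 + circ$syn_comp]) - Em
}

# sample one lumped-cylinder geometry from the modelled ranges
sample_geometry <- function() {
  if (runif(1) < 0.6) {
    hd <- runif(1, 0.43, 1.04)
    spine_geometry("mushroom", head_diameter = hd,
                   head_length = runif(1, 0.43, 1.04),
                   neck_diameter = runif(1, 0.175, min(1, 0.9 * hd)),
                   neck_length = runif(1, 0.38, 4.37))
  } else {
    spine_geometry("stubby", diameter = runif(1, 0.44, 1.15),
                   length = runif(1, 0.32, 1.66))
  }
}

# brute-force query scoring, written independently of the package's
# vectorized implementation (plain loops over records)
brute_normalize <- function(vals) {
  ok <- !is.na(vals)
  lo <- min(vals[ok]); hi <- max(vals[ok])
  out <- rep(NA_real_, length(vals))
  out[ok] <- if (hi == lo) 0 else (vals[ok] - lo) / (hi - lo)
  out
}

brute_cell_distribution <- function(table, weights) {
  feats <- names(weights)
  norm <- lapply(feats, function(f) brute_normalize(table[[f]]))
  names(norm) <- feats
  raw <- rep(0, nrow(table))
  for (f in feats) raw <- raw + weights[[f]] * norm[[f]]
  keep <- !is.na(raw)
  r <- raw[keep]
  score <- if (sum(keep) == 1) 1 else
    (rank(r, ties.method = "average") - 1) / (sum(keep) - 1)
  stats::setNames(score, table$id[keep])
}

brute_spine_comparison <- function(table, weights, query_ids) {
  feats <- names(weights)
  norm <- lapply(feats, function(f) brute_normalize(table[[f]]))
  names(norm) <- feats
  qrows <- match(query_ids, table$id)
  out <- rep(NA_real_, nrow(table))
  for (i in seq_len(nrow(table))) {
    acc <- 0; wsum <- 0; ok <- TRUE
    for (f in feats) {
      cf <- mean(norm[[f]][qrows])
      fi <- norm[[f]][i]
      if (is.na(fi)) { ok <- FALSE; break }
      s <- 1 - abs(fi - cf)
      acc <- acc + abs(weights[[f]]) * (if (weights[[f]] > 0) s else 1 - s)
      wsum <- wsum + abs(weights[[f]])
    }
    if (ok) out[i] <- acc / wsum
  }
  stats::setNames(out[!is.na(out)], table$id[!is.na(out)])
}
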