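---
title: "Methods: spine morphometry, passive biophysics and retrieval in spinekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine morphometry, passive biophysics and retrieval in spinekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinekit)
```

spinekit is a headless toolkit for the morpho-functional analysis of
pyramidal-neuron dendritic spines: it derives per-spine morphology from
triangle meshes, attaches a model-based functional feature (the
membrane-potential peak an excitatory synapse would evoke in the spine
head), and ranks or filters spines by weighted similarity over those
features. This vignette documents the models, the numerical choices, and
the limits of what the synthetic test bed can show.

## Mesh morphometry

Five features are computed per spine mesh (micrometre units throughout):
volume, total surface area, length, maximum diameter and neck mean
diameter, plus a three-way class label (mushroom / stubby / thin).

**Volume and area.** Area is the plain sum of triangle areas, caps
included — the total-surface convention of segmentation exports. Volume is
the divergence-theorem sum of signed origin tetrahedra, which is exact for
any closed, consistently oriented triangulation; `enclosed_volume()`
refuses open meshes and reports the boundary-edge count instead of
returning a wrong number.

**Axis and length.** Segmentation tools export surfaces, not skeletons, so
the spine axis must be reconstructed. The tip is defined as the mesh point
maximally geodesically distant from the attachment point (the dendrite
contact, supplied externally; base-disk center for synthetic fixtures),
with geodesic distance approximated by shortest paths on the edge graph.
Vertices are then binned by geodesic distance (24 bins) and the polyline
through the bin centroids — attachment first, tip last — is the axis; spine
length is its arc length. Running through centroids keeps the axis in the
interior of curved spines, and ending at the tip guarantees length is
never below the Euclidean attachment–tip distance. Distances are quantized
at a 1e-9 relative tolerance before binning so that the symmetric vertex
rings of tessellated solids fall into one bin atomically; without this,
rings sitting exactly on a bin boundary split into asymmetric halves and
drag the axis off-center.

**Diameters.** At 32 stations (mid-positions, so no end plane is ever
tangential) the mesh is cut by the plane perpendicular to the local axis
direction; the intersection loop containing the axis point contributes an
equivalent-circle diameter `2 * sqrt(area / pi)`. The neck is the
contiguous proximal run of stations below 0.7 x the profile maximum; its
mean diameter is the neck mean diameter, and its absence defines a stubby
spine. The source measurements never specify how diameters were extracted
from meshes, so this planar-section construction is this package's own
choice: it is deterministic, resolution-stable, and consistent with the
lumped-cylinder abstraction the functional model uses downstream. The 0.7
threshold and the station count are configuration parameters
(`morphometry:` block), not constants.

**Classification.** Stubby if no neck is detected; otherwise mushroom if
the maximum diameter reaches 0.43 um — the smallest head the functional
model covers — else thin. Thin spines (small-headed protrusions and
filopodia) are excluded from the functional model and carry a missing
functional feature.

## Passive spine biophysics

Each spine is a chain of lumped cylinders attached to one parent dendrite
compartment (3 um diameter, 20 um length, sealed ends): mushroom spines
contribute a neck and a head compartment, stubby spines a single cylinder
that doubles as the head. Passive parameters default to Cm = 1 uF/cm2,
Ri = 100 Ohm.cm, Rm = 20,000 Ohm.cm2. Compartment areas use the lateral
surface only, the standard lumped-cylinder convention; axial coupling
between adjacent compartments is the symmetric mean of their end-to-end
resistances, with the child-resistance convention some simulators use
available as `coupling = "child_ra"`.

The synapse is a single alpha-conductance event on the head,
`g(t) = gbar (t/tau) exp(1 - t/tau)` with tau = 2 ms and reversal 0 mV
(excitatory glutamatergic input), with peak conductance set by an areal
density of 132 S/m2 over the head's lateral surface — larger heads receive
proportionally stronger synapses. The functional feature is the peak
depolarization from rest in the head. The resting potential is not fixed
by the source measurements; the default Em = -70 mV is the standard
cortical pyramidal value and is explicit configuration because the peak
scales with the driving force.

**Mapping morphometry to geometry.** The model needs a neck length, which
is not one of the five extracted features. The mapping used is: head
diameter = head length = maximum diameter (a head as tall as it is wide),
neck diameter = neck mean diameter, neck length = spine length minus head
length, flagged missing (with a warning) when that difference is not
positive. Stubby spines map to a single cylinder of their maximum diameter
and length.

**Integration.** The default step is 1 us with 50 ms simulated — far
beyond the 2 ms conductance peak, so the voltage peak is always captured;
`simulate_spine()` refuses durations under five synaptic time constants.
Two schemes are provided:

* `scheme = "matrix"` (default): exponential Euler on the full coupled
  system. With conductances frozen at the step midpoint the circuit is
  linear, and the step is propagated *exactly* via the eigendecomposition
  of the symmetrized system matrix. The only error source is freezing the
  slow alpha conductance, so agreement with an adaptive high-accuracy ODE
  solution (deSolve::lsoda, rtol 1e-11) is at the 1e-7 relative level,
  and halving the step changes peaks by less than 1e-6 relative.
* `scheme = "local"`: the classical per-compartment update
  (`exp_euler_step()`), each compartment relaxing toward its instantaneous
  steady state with neighbors held at start-of-step values. This is the
  textbook compartmental-simulator scheme, but spine compartments are tiny:
  their time constants (0.02–0.4 us for the modelled dimension ranges) sit
  far below a 1 us step, and the stale-neighbor splitting then biases head
  peaks by 2–38% depending on geometry (worst for stubby spines and short
  wide necks, i.e. the most strongly coupled circuits). It is kept for
  reference and step-level testing, not for production peaks.

A passive circuit with a single excitatory reversal confines every
voltage to `[Em, Esyn]`; both schemes preserve this bound by construction
(each update is a convex combination), and the test suite asserts it on
every run.

**Neck-length sensitivity.** For a fixed head, lengthening the neck both
isolates the head (raising the local IR contribution) and adds neck
membrane capacitance that loads the head during the 2 ms conductance
rise. For the modelled dimension ranges the capacitive loading dominates
slightly: the head peak declines smoothly by about 2% from the shortest
to the longest modelled neck. This is the model's genuine behavior — it
is reproduced by the independent ODE reference — even though one might
intuitively expect isolation to win.

## Retrieval engine

Queries operate on a per-spine feature table. Before any scoring, each
selected feature is min-max normalized over its non-missing values
(constant features map to zero; missing values stay missing and exclude a
spine from that query, listed separately rather than imputed).

* **Cell distribution**: the raw score is the weighted sum of normalized
  features, weights in `[-1, 1]` (positive seeks large values, negative
  small). The reported score is the rank percentile of the raw score —
  `(rank - 1) / (N - 1)` with average ranks on ties, defined as 1 for a
  single scored spine — because this mode reports each spine's relative
  position in the feature ranking. Raw values are retained in the output
  for transparency.
* **Spine comparison**: the query set's signature is the centroid of its
  normalized feature vectors (the aggregation rule for multi-spine query
  sets is this package's choice). Per feature, similarity is
  `1 - |fhat - c|`; negative weights flip the contribution to
  `|fhat - c|`; contributions average with weights `|w| / sum(|w|)`.
  This is the simplest form that keeps every score in `[0, 1]`, makes a
  singleton query retrieve itself at score 1 under positive weights, and
  makes negative weights exact complements.

Ranking sorts by descending score with ties broken lexicographically by
id, so results are order-deterministic. Score histograms use equal-width
bins on `[0, 1]` (right-closed last bin); the double-slider range filter
keeps `lo <= score <= hi` and its complement returns exactly the other
scored spines; display rescaling linearly remaps `[lo, hi]` onto the unit
interval with clipping, without touching the scores themselves.

## Synthetic data and what it can show

`make_cylinder_mesh()` / `make_mushroom_spine_mesh()` build closed prism
solids whose ground truth uses exact faceted-polygon formulas (area
`n r^2 sin(2 pi / n) / 2` per section, etc.), not smooth-cylinder
formulas, so mesh oracles are tolerance-free at any resolution; smooth
values are only asserted as tessellation limits. Mushroom fixtures weld
the neck and head prisms through an annulus into a single watertight
surface. When a requested neck is not narrower than 0.7 x the head, the
profile rule cannot see it, and the fixture honestly labels itself stubby
with a missing neck value rather than carrying an unmeasurable truth.

`generate_feature_dataset()` emulates the shape of a reconstructed human
pyramidal neuron's spine table: about 9,000 spines along 8,693 um of
dendrite, split 49% basal / 6% main apical / 45% apical collateral by
dendritic length (the default region proportions; the default table size
is 1,000 spines, a parameter). Spine kinds are drawn mushroom / stubby /
thin at 0.5 / 0.3 / 0.2 — an assumed mix, as the source measurements give
ranges but neither kind frequencies nor dimension distributions — and
dimensions are uniform over the modelled ranges per kind. Mushroom neck
diameters are capped at 0.6 x the head diameter so every generated
mushroom has a profile-detectable neck while staying inside the
0.175–1 um range. Features follow from the smooth lumped-cylinder closed
forms; the membrane-potential peak is simulated per spine (missing for
thin spines). Positions lay the regions out along simple synthetic
dendritic paths and are metadata only.

`generate_structured_neuron()` is a deliberately *clean positive control*
for planted-effect recovery, not a realistic neuron: mushroom spines
only, dimensions drawn from the central 15% of each modelled range, and
apical-main volumes and areas multiplied by 2. A feasibility analysis
fixed this design before any test was run: with full-range uniform draws
the 75th/10th volume percentile ratio is about 5 and a x2 planted effect
moves only ~53% of apical-main spines into the top quartile (and any
mixture containing thin spines caps recovery near 1 minus the thin
fraction, since between-kind volume separation dominates the planted
effect). With the concentrated mushroom-only design the ratio is about
1.25 < 2, so every doubled apical-main spine clears the top volume
quartile structurally, for any seed. Passing the recovery property
therefore certifies the retrieval engine's ranking arithmetic — which is
what the control is for — and says nothing about detectability of subtle
regional effects in real, broadly dispersed spine populations.

The same caveat applies to the mesh suite: synthetic prisms are convex,
coaxial and noise-free, so passing morphometry oracles certifies the
geometry pipeline's correctness, not its robustness to segmentation
noise, fused spines or non-tubular necks.

## Problem sizes and defaults

Test and acceptance runs use: fixtures at tessellation 64 (256 and 512
only in convergence checks), 20 sampled geometries for the
simulator-vs-ODE oracle at dt = 1 us over 50 ms, and 1,000-spine tables
for recovery properties — sizes chosen so the whole suite exercises every
claim in about a minute of compute while the statistical checks stay far
from their thresholds. All tunables live in one YAML config
(`inst/extdata/spinekit-config.yaml` documents the defaults): cable and
synapse parameters, integrator step and duration, coupling convention,
station count, neck threshold, head class threshold, and the CSV header
alias map for spreadsheet imports.

## Known limitations

* Passive membrane only: no active conductances, no synaptic trains or
  plasticity, one spine per circuit; interactions between co-active
  spines are out of scope.
* The axis construction assumes a single protrusion per mesh; a mesh
  containing two spines or a shaft fragment will produce one axis through
  whichever tip is geodesically farthest.
* VRML support is the `IndexedFaceSet` subset that surface-export
  pipelines produce; general VRML scenes (transforms, materials,
  prototypes) are ignored or rejected.
* Binary PLY is not read; meshes should be exported ascii.
* Real Imaris column layouts vary; the alias map defaults are
  best-effort and user-overridable in the config.
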