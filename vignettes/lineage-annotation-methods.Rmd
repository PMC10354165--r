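---
title: "Lineage annotation of a connectome: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage annotation of a connectome: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagecx)
```

## The problem

Insect brains are built from ~100 pairs of neuroblast stem cells, each of
which produces a *lineage* of sister neurons. Neurons of one lineage (or
hemilineage) run together in a tight, glia-ensheathed fiber bundle — the
lineage tract — from a soma cluster in the cortical rind into the neuropil.
In a synapse-resolution connectome these tracts are a developmental
fingerprint: if a neuron's skeleton can be reduced to its tract *backbone*,
and the entry points of the known bundles into the neuropil are annotated,
every neuron can be assigned to the lineage whose bundle its backbone runs
in. `lineagecx` implements that workflow for the large-field (tangential)
input network of the central complex (CX): backbone extraction, geometric
bundle assignment, the CX large-field catalog filter, and the synaptic
summaries used to describe the resulting lineage-structured circuits
(connection matrices, input fractions, T-bar counts, pairwise-strength
ECDFs, toroidal projections of the ellipsoid body, and domain-occupancy
tables).

All coordinates are nanometres internally. SWC files in micrometres or in
voxel units (e.g. an 8 nm isotropic EM grid) are rescaled on read.

## Backbone extraction

A neuron skeleton is a rooted tree of 3-D nodes. The tract backbone is
recovered by four rules applied in order:

1. **Twig pruning.** Terminal branches with fewer than `twig_node_max = 15`
   nodes (~120 nm at 8 nm node spacing) that carry no connector (T-bar or
   PSD mapped to a node within 250 nm) are removed. Pruning iterates to a
   fixpoint so that nested twigs do not survive; a single-pass variant
   would leave a twig whose own side-twig made it look internal.
2. **Fragmentation.** The pruned skeleton is cut at every branch point
   (undirected degree ≥ 3). Fragments are maximal unbranched paths; branch
   nodes are duplicated into each incident fragment so fragments partition
   the edge set.
3. **Selection.** Fragments longer than `large_fragment_min_len = 2500` nm
   are kept outright. Smaller fragments are kept only if longer than
   `small_fragment_min_len = 80` nm *and* carrying fewer connectors than
   `connector_density_max = 0.01` per nm of cable (i.e. fewer than 1% of
   the numerical value of the cable length in nm). Of these small
   survivors, any shorter than (largest fragment length) / 2.5 is
   discarded. The published phrasing of this relative-length rule is
   internally inconsistent (read literally it discards every non-largest
   fragment); we implement the ratio reading by default and expose the
   literal reading behind `backbone_params(relative_rule = "literal")`.
4. **Distal trimming.** Any non-largest fragment whose minimum
   node-to-point distance to *both* endpoints of the largest fragment
   exceeds `distal_trim_distance = 5000` nm is discarded. We apply this to
   all non-largest fragments, large or small; the rule's scope is not
   stated more precisely in the source description. Fragment-to-endpoint
   distance is the minimum over the fragment's nodes, not its centroid —
   a centroid rule would wrongly discard long fragments whose near end
   touches the tract.

Connector-to-node mapping uses the nearest node within 250 nm; connectors
with no node in range are ignored by the pruning rules. This radius is a
design choice (the source procedure is silent): it is large against the
8 nm node spacing and small against inter-tract distances.

Two properties are tested rather than assumed: the backbone node set is
always a subset of the input skeleton (no geometry is invented), and
raising the large-fragment threshold never adds fragments.

## Bundle assignment

Manual identification of glial-ensheathed bundles in EM images is replaced
by an annotation file: per lineage, an entry portal (a point and plane
normal where the tract enters the neuropil), seed fiber positions on that
plane, a capture radius, and optionally the soma-cluster centre.

Assignment computes, per bundle, the first crossing of the neuron's
backbone main path (largest fragment, ordered soma-side first) through the
bundle's portal plane, and the distance `d` from that crossing to the
nearest seed fiber. The bundle minimising `d` wins if `d` is within its
capture radius (method `PORTAL`). Backbones that cross no portal plane
fall back to the mean backbone-to-seed distance (method `TRAJECTORY`) —
the situation of tracts whose entry point lies outside the imaged volume.
Exact ties break by soma-to-cluster distance, then lexicographically.
Everything else is `UNASSIGNED` and retained in outputs rather than
dropped. The assignment score `exp(-d / capture_radius)` is a bounded
monotone confidence, 1 on the seed itself and `1/e` at the capture
boundary.

Hemilineage splitting, when requested, is a 1-D cut of the portal-crossing
positions along their widest principal direction, mirroring paired
dorsal/ventral tracts; the source workflow identifies such pairs visually
and gives no rule, so a two-group geometric split at the median is the
simplest faithful mechanisation.

## The CX large-field catalog filter

A neuron enters the catalog if it (1) has at least one connector in a CX
compartment (PB, EB, FB, NO, AB), (2) forms strictly more than 15 T-bars
plus PSDs in those compartments, and (3) makes at least one output
connection onto a single partner with strength strictly greater than 5
synapses, where connection strength is the summed synapse count of an
ordered neuron pair. Both bounds are strict: a neuron with exactly 15 CX
connectors, or whose strongest connection is exactly 5, is excluded. The
filter is idempotent by construction and is property-tested against an
independent brute-force reference on random toy catalogs.

## Synaptic summaries

The connector table holds one row per synaptic contact (`pre -> post`);
`kind` records whether the row's coordinates are the presynaptic T-bar or
the postsynaptic density, and aggregated rows carry an integer weight that
every downstream count sums. Conservation is an invariant, not a hope:
connection-matrix grand totals equal filtered connector weight sums,
input fractions sum to 1 whenever any synapse survives the region
exclusion, projections conserve point counts and weights exactly, and
density histograms conserve mass (out-of-range points are clamped into the
edge bins).

Choices worth stating:

* **Input fractions** (the sunburst sectors) count PSD-side synapses onto
  the target neurons, grouped by the targets' lineage, with the CX
  compartments excluded so only lateral inputs count. Whether such counts
  should use the targets' PSDs or the sources' T-bars is not specified in
  the source figures; PSD-side is the default and `count_side = "pre"`
  switches.
* **"Relative input strength"** shading normalises a connection matrix to
  its global maximum, and per-synapse shade weights divide a neuron's
  total upstream input by the maximum per-target total so weights stay in
  [0, 1].
* **ECDFs** of pairwise connection strength are right-continuous,
  `F(x) = #{strengths <= x} / N`.
* No significance machinery is attached: these are descriptive counts.

## Toroidal (EB) projection

The ellipsoid body is a torus; its annular domains differ in radial and
axial position but not azimuth. The circular projection therefore maps
each point to `u` (distance from the ring axis minus the ring radius) and
`v` (signed offset along the axis) and discards azimuth — collapsing all
cross sections onto one plane. The axis model is either fitted (centroid,
least-variance direction, mean axis distance; sign fixed toward a
reference direction so fits are deterministic) or supplied from
configuration; synthetic runs can use the generator's true axis to
isolate projection tests from fitting error. The exact display convention
of the original circular projection is not documented; this construction
reproduces its stated intent and is tested for azimuth invariance,
distance preservation (`u + R` equals the 3-D distance to the axis to
1e-9 relative error) and rotation equivariance of the fit.

The FB "layer index" of a neuron is the layer containing the plurality of
its output synapses, ties resolving to the lower layer. The topography
statistic is the Spearman rank correlation between each neuron's
dendritic (PSD) centroid coordinate along a configured anatomical axis
and its layer index, per lineage; lineages with fewer than 3 informative
neurons report `NA`. Anatomical axes are configuration-declared unit
vectors — the library never hardcodes a species' neuraxis.

## The synthetic generator

`generate_brain()` plants full ground truth so every stage is testable
without downloads. Its defaults are the study conditions, not tuning
knobs: 8 nm node spacing (so the 15-node twig threshold is ~120 nm),
lineage sizes drawn uniformly from 50–150 fibers when unspecified (the
typical tract fiber count), 100 nm lateral tract noise truncated at 3
sigma (fibers stay inside the glial bundle), a 400 nm capture radius, and
portal separations of at least 10 sigma in the shipped scenarios. Synapse
budgets are realised exactly — deterministic allocation, so acceptance
tolerances reflect only spatial randomness — with a Poisson mode behind a
flag. Twigs are attached at least `twig_node_max` nodes away from tract
ends (so a twig can never convert a tract terminus into a prunable
branch) and at least 600 nm away from the neuron's own synapses (so no
connector can map onto a twig node within the 250 nm mapping radius):
planted-backbone recovery is exact by construction, and the tests verify
that the construction actually delivers it.

Positions are drawn by rejection sampling against the full compartment
model, so a planted synapse always lies in its declared region even where
primitives overlap. The model is a miniature bilateral brain: an EB torus
with five annular domains, nine FB layer slabs, PB, three noduli, the
asymmetrical body, the tripartite bulb and the lateral compartments, with
bilateral structures mirrored across the x = 0 midline.

Three fixed scenarios cover the analyses:

* `generate_tract_scenario()` — bundles 1200 nm apart with no synapses;
  used for backbone recovery (200 neurons) and assignment accuracy
  (30 neurons per seed across 20 seeds).
* `generate_avp_scenario()` — two TuBu hemilineages converging on four ER
  subclasses with 100% planted source exclusivity (4200 TuBu synapses in
  the bulb, 2900 ER outputs in the EB domains).
* `generate_fb_scenario()` — five FB lineages, nine neurons each (one per
  output layer), receiving 20,000 lateral input synapses with planted
  fractions 28.6% / 23.2% / 22.3% for the three dominant lineages and a
  280 nm-per-layer posterior dendrite gradient (noise sigma 300 nm by
  default, 0 for the noiseless check). With one neuron per layer within
  each lineage, the noiseless Spearman correlation is exactly 1; tied
  layers across neurons would cap it below 1 through midranks, which is
  why the scenario plants distinct layers within a lineage.

What the generator does **not** emulate: realistic arbor morphology
(arbors are reduced to twigs; synapse positions are region-sampled rather
than arbor-attached), partner multiplicity statistics of real
connectomes, reconstruction noise such as broken or merged skeletons, and
nested region-of-interest hierarchies. Passing tests therefore
demonstrate the correctness of the rules and statistics under the planted
geometry — not robustness to segmentation artifacts, which on real data
is handled by the connector-aware pruning rules themselves.

## Problem sizes and numerics

The shipped test and acceptance workloads use 200 neurons for backbone
recovery, 1000 random trees (≤ 50 nodes) for oracle agreement, 20 seeds
by 30 neurons for assignment accuracy, and 20,000 synapses for the FB
fractions — sizes chosen so the planted effects dominate sampling noise
(multinomial error at n = 20,000 is ~0.3% against a 2% tolerance) while a
full run stays desk-scale. Degenerate inputs are defined, not crashed:
empty skeletons pass through, neurons whose fragments all fail the rules
yield an empty backbone with a warning, all-zero matrices normalise to
zeros with a warning, zero input totals yield `NA` fractions, and
collinear point clouds are rejected by the torus fit. Region membership
is boundary-inclusive with declared priority order, which makes every
boundary test deterministic.

## Limitations

Real catalogs need real bundle annotations: for a connectome volume the
portal/seed file must be digitised from anatomical landmarks, and
assignment quality depends on that annotation, not only on the geometry
code. The `TRAJECTORY` fallback is a crude surrogate for expert judgment
on truncated tracts; such neurons are better left `UNASSIGNED` unless an
explicit override is supplied. The hemilineage split assumes at most two
sub-bundles. The export adapter expects a flat region label per synapse;
nested ROI hierarchies must be flattened upstream.
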