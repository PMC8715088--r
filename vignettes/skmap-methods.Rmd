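---
title: "Methods: geodesic immunogold statistics on reconstructed membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodesic immunogold statistics on reconstructed membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`skmap` quantifies the 3D organization of immunogold particles — electron-dense
markers of a labeled membrane protein such as the SK2 channel — on segmented
FIB/SEM reconstructions of dendrites. This vignette documents the model
choices, parameters, and numerical decisions behind each stage, and what the
synthetic-scene tests do and do not establish about real data.

## The geometry substrate

The input is a label volume: a 3D integer grid in which each compartment
(pyramidal shaft, spine, interneuron shaft) carries one label and 0 is
background, with anisotropic acquisition spacing (typically 5 × 5 nm in-plane,
20 nm per milled section). All coordinates in the package are physical
(nanometres), with the center of the voxel at 0-based grid position
$(i, j, k)$ at $((i+0.5)\,dx,\ (j+0.5)\,dy,\ (k+0.5)\,dz)$. Particle tables
store nanometres, never pixels, so resampling the image grid never rewrites a
particle file.

Before surface work the volume is made isotropic by majority-vote block
reduction in the imaging plane only (default target 20 nm, matching the
section thickness; ties break to the lowest label so the operation is
deterministic). No z interpolation is performed: the 20-nm sections are taken
as-is. Majority voting preserves thin structures (spine necks) better than
strided subsampling; a compartment smaller than the target grid can still
vanish, and the function warns when a label is lost. Frames whose size is not
a multiple of the reduction factor are padded with background.

## The membrane as a graph

A compartment's surface is represented as a **boundary-voxel graph**, not a
triangle mesh:

- **nodes** are the compartment's boundary voxels — those with at least one of
  their 6 face-neighbors outside the compartment — positioned at voxel
  centers, each weighted by its exposed-face area (faces × spacing²);
- **edges** connect boundary voxels within the 26-neighborhood, weighted by
  the Euclidean distance between centers (s, s√2 or s√3 for spacing s).

The 6-exposure / 26-adjacency pairing is the standard digital-topology
combination. Geodesic distances are exact Dijkstra shortest paths on this
graph (multi-source where several sources are involved). The representation
is deterministic and directly checkable against brute-force shortest-path
oracles, which the test suite does on surfaces of up to 500 nodes with a
hand-rolled Floyd–Warshall implementation.

Two known biases follow from the raster representation and are accepted
rather than corrected:

- **Chamfer inflation.** Graph geodesics overestimate true surface distance
  direction-dependently, by up to ~8% in the worst direction of a flat sheet.
  Because the observed pattern and every Monte-Carlo replicate are measured
  with the *same* metric, the randomization comparison is unaffected; only
  absolute distances (NND means, profile bin positions) carry the bias. A
  flat-sheet test pins the mean inflation below 8%.
- **Face-count area bias.** Summed exposed-face area overestimates the true
  (smooth) area of a curved surface by a shape-dependent factor; for a
  rasterized sphere the ratio against $4\pi r^2$ falls in roughly 1.2–1.8.
  Face-count area is used only as a *relative* weight (sampling nodes
  proportionally to exposed area approximates uniformity over the continuous
  membrane, since boundary voxels expose 1–5 faces) — never as a reported
  absolute area in the statistics.

## Particle assignment and localization

Each particle is assigned the label of its containing voxel; particles
falling in background are rescued to the nearest labeled voxel within the
contact radius (ties: closer voxel center, then lower label id), otherwise
reported unassigned. A particle is **plasma-membrane-bound** iff its distance
to the nearest surface node of its compartment is at most
`pm_contact_radius`, else intracellular.

`pm_contact_radius` defaults to **20 nm — one isotropic voxel**. The
underlying biological criterion (particle touching the inner membrane
leaflet) is visual; 20 nm matches both the z-resolution of the data and the
physical scale of a silver-enhanced gold particle, and makes "contact" mean
"within one voxel of the boundary" on the analysis grid. The radius is
configurable, and classification is monotone in it (growing the radius can
only move particles intracellular → PM), which the tests assert. PM particles
keep their nearest surface node as their projection for all geodesic work.

## Nearest-neighbor distances and the randomness test

For $n \ge 2$ PM particles projected to surface nodes, the per-particle NND
is the geodesic distance to the closest other particle; the mean and sample
SD summarize the pattern. Randomness is tested against a Monte-Carlo null
that mirrors the experimental logic of re-drawing the same number of
particles on the same membrane:

- each of `reps = 100` replicates draws $n$ *distinct* surface nodes with
  probability proportional to node area and recomputes the mean NND;
- the z score is $(\text{observed} - \bar{m}_{null}) / s_{null}$;
- the empirical p uses the add-one estimator
  $p = (1 + \#\{m_{null} \le m_{obs}\}) / (reps + 1)$, one-sided toward
  clustering, so the smallest attainable p at 100 replicates is $1/101$.

With a single replicate no null SD exists; the result is flagged degenerate
and z is reported absent. On surfaces of ≤ 4000 nodes the implementation
precomputes the full node-to-node distance matrix once and evaluates
replicates by indexing; larger surfaces use multi-source Dijkstra from the
union of sampled nodes. Both paths are exact and give identical results (a
test asserts this), and a `dist_full` argument lets calibration studies reuse
one matrix across many calls.

Calibration is part of the acceptance suite: across 500 independent patterns
drawn from the null itself the test rejects at α = 0.05 at a rate within
0.05 ± 0.02, and across 20 clustered patterns (10 parents × 5 offspring,
30-nm spread) it detects clustering in at least 90%.

## Cluster calling

Particles are grouped by single linkage: connected components of the graph
joining pairs whose geodesic distance is at most the threshold. Groups of
≥ 3 particles are clusters; groups of 1–2 are scattered. The published rule
wording ("closer than the average NND and two times its standard deviation")
is ambiguous between mean + 2 SD and mean − 2 SD; the default is
**mean + 2 SD** with a `minus2sd` switch, because for clustered data the SD
of NNDs typically exceeds half the mean, making mean − 2 SD negative and the
rule vacuous. The chosen rule is recorded in every run manifest. Merging is
monotone in the threshold (tested), and the output is always a partition of
the input particles.

## Distance-to-synapse profiles

Synapse patches arrive as a second label volume sharing the frame plus a
metadata table typing each patch (asymmetric/symmetric — the EM morphology
proxies for excitatory/inhibitory). Patch voxels are mapped to surface
nodes; a patch's **edge** is its nodes adjacent in the surface graph to at
least one node outside that patch. Each PM particle's distance is the
geodesic distance to the nearest edge node over all patches of the requested
type; particles inside a patch get 0. Distances are binned in 60-nm bins to
a 660-nm limit — exactly 11 bins; measuring to the patch *edge* (not
centroid) follows the convention of reporting distances from the edge of the
synaptic specialization.

The natural denominator for the normalized profile is not obvious (all
analyzed particles vs particles inside the limit); the profile reports both
(`prop_all`, `prop_within`) and treats the within-limit version as the
normalized profile, alongside the within/beyond counts. On a uniformly
covered flat sheet with a disk patch the binned proportions track the
analytic annulus-area fractions; the acceptance test bounds the per-bin
deviation at 0.05, a budget covering the chamfer inflation and the
half-voxel uncertainty of the rasterized patch edge.

## Density tables and comparative statistics

Per-compartment records carry PM/intracellular counts, volume (voxel count ×
voxel volume), densities (gold/µm³) and PM percentages. The totals row sums
counts and volumes but reports densities as the **mean ± SEM of per-compartment
densities** — the convention that makes a published per-dendrite table's
total reproducible — with pooled (summed count / summed volume) densities
attached as an attribute, so both conventions are available. Spine-level
group statistics weight per spine, shaft-level ones per dendrite, matching
how such tables mix the two.

Comparative statistics are deliberately plain base-R: one-way ANOVA with
Bonferroni-adjusted pairwise contrasts computed from the pooled within-group
variance ($p_{adj} = \min(1, m\,p_{raw})$), two-sided Mann-Whitney for spine
volumes (immunopositive vs immunonegative), Pearson correlation for spine
volume vs particle count, and two-sample Kolmogorov–Smirnov for distribution
comparisons. Constant responses are flagged degenerate (detected with a
scale-aware variance threshold rather than an exact zero test, since `aov`
on constants leaves floating-point noise) instead of producing spurious
p-values.

## The synthetic scene generator

`build_scene()` rasterizes a capped-cylinder shaft along a gently curved
(sinusoidal, 150-nm amplitude) axis, with spines as sphere heads on
cylindrical necks at non-overlapping random attachment sites, an asymmetric
synapse patch on every spine head pole, and symmetric patches on the shaft;
interneuron scenes are spineless with both patch types on the shaft.
Defaults mimic the scale of reconstructed CA1 dendrites: shaft radius
0.5 µm and length 4 µm (volume ≈ 3.1 µm³), spine head radius 150 nm (volume
≈ 0.014 µm³), neck 200 × 60 nm, patch radius 100 nm, at 20-nm isotropic
spacing. Spine-neck dimensions are conventions — published reconstructions
describe them only qualitatively — and are fully parameterized.

Surface particles follow either complete spatial randomness
(area-weighted over boundary nodes, count Poisson in the requested
intensity) or a Thomas-like parent–offspring process with **geodesic**
Gaussian offspring spread (default 10 parents × 5 offspring, σ = 30 nm),
which produces cluster sizes in the 3–8 range that cluster calling should
recover. Sampled nodes are jittered uniformly within their voxel, so a PM
particle stays within $\sqrt{3}\,s/2 \approx 17$ nm of its node — inside the
20-nm contact radius by construction. Intracellular particles are a Poisson
draw over the *deep interior* (voxels whose entire 26-neighborhood shares
the label), guaranteeing more than one voxel of clearance from every
boundary node, so the generated ground truth is exactly recoverable by the
classifier. Everything is deterministic given the seed (`withr::with_seed`;
the pipeline fans a single run seed into fixed per-stage substreams).

What the generator does **not** emulate: image noise and silver-grain
rendering (particle coordinates are inputs, not detections), axons/boutons
and neuropil packing, spine-neck/head shape diversity, antibody penetration
gradients, and segmentation error. Passing tests therefore validate the
*analysis* — classification, geodesics, null calibration, accounting — on
idealized geometry; they do not validate tracing quality or detection on
real micrographs.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: oracle
comparisons use a rasterized 100-nm sphere (~400 nodes, under the 500-node
brute-force budget); type-I calibration runs 500 trials of a 100-replicate
test on that sphere via one precomputed distance matrix; power uses a 300-nm
sphere (~2300 nodes) and 20 pattern redraws; pipeline tests use a reduced
spiny scene (2-µm shaft, 3 spines). The statistical conclusions these check
(exactness of geodesics, null calibration, power at the default clustered
parameters, ground-truth recovery) are scale-free properties of the method;
the full-size default scene exercises the same code paths through the CLI.

## Known limitations

- Geodesics live on the boundary-voxel graph: absolute distances carry the
  chamfer bias above, and sub-voxel particle positions are projected to node
  centers before any geodesic work.
- Surfaces of disconnected compartment fragments yield infinite
  between-fragment distances; NND and profiles treat unreachable pairs as
  beyond any finite limit.
- The cluster threshold inherits the sampling variability of the NND mean
  and SD; at very small n the plus-2-SD threshold is unstable.
- Density totals assume the supplied compartment volumes are correct;
  rounding in externally supplied tables propagates into recomputed
  densities at the second decimal.
- The profile's equal-width binning reports proportions, not intensities;
  it does not correct for the available membrane area per distance band
  (no Ripley-type edge correction), matching the descriptive convention it
  reproduces.
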