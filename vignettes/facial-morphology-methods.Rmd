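---
title: "Dissecting 3D facial morphology: methods and design notes"
author: "faceMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting 3D facial morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceMorph)
```

# Overview

`faceMorph` implements a two-track dissection of three-dimensional facial
morphology into quantitative phenotypes, together with the population
statistics used to ask whether regional subpopulations differ in those
phenotypes.

The *landmark track* starts from 26 Farkas-convention soft-tissue landmarks
placed twice on each facial surface, averages the two landmarking
replicates, aligns all configurations by generalized Procrustes analysis
(GPA) **without scaling**, and derives ten phenotype families per
individual: the 78 aligned point coordinates, 26 mean and 26 Gaussian
landmark curvatures, 325 Euclidean, 325 Manhattan and 325 surface geodesic
distances (all landmark pairs), 32 Farkas-style proportion indices, 7800
angles (three vertex angles for each of the 2600 landmark triples), 2600
Heron triangle areas, and convex-hull volumes and surface areas of 10
facial regions.

The *computer-aided track* works on dense surfaces in template
correspondence: per-vertex displacement fields in the GPA consensus frame,
an RV-coefficient similarity of vertex covariation, recursive two-way
spectral clustering into a 7-level hierarchy of 127 facial segments, and
per-segment phenotypes — principal-component scores retained by parallel
analysis, surface areas, and Moran's I spatial autocorrelation of the z
coordinate, mean curvature and Gaussian curvature.

The statistics layer screens every phenotype against an ordered regional
coding by Spearman correlation under Bonferroni control (classifying
phenotypes as *heterogeneous* or *homogeneous* across regions), checks
design balance by chi-square, separates groups by PLS-DA with VIP variable
selection, quantifies explained variance by PERMANOVA, and removes linear
age effects by regression.

Because cohort-scale raw data of this kind are generally not deposited, the
package includes a fully synthetic face-population generator with known
regional structure; every downstream stage is tested against it and against
closed-form geometric oracles.

# The synthetic population generator

`buildTemplate()` constructs a procedural face-like surface — a
half-ellipsoid head patch 140 mm wide, 180 mm tall and about 50 mm deep,
with a Gaussian nose ridge, two eye depressions, a mouth groove and a chin
bulge — triangulated over a regular grid masked to an ellipse. The grid is
symmetric in x, so bilateral landmark pairs mirror exactly. The default
resolution (61 points across) yields roughly 2,900 vertices; this keeps a
whole simulated population and its dense similarity matrix comfortably in
memory while leaving every segment of a 7-level hierarchy with tens of
vertices. The template is procedural rather than an artist mesh so the
repository stays asset-free and the resolution is a parameter, not a fact
about a file.

`populationModel()` describes the study conditions:

* **Regions.** Three groups ordered north to south. Eight of the 78
  landmark coordinates (10%) carry a *gradient*: a mean displacement of
  +delta in the northernmost region grading linearly to -delta in the
  southernmost (deltas of 1.0–1.5 mm; nose projection and height, face
  height, bilateral face and nose widths). Gradient deltas are balanced
  across axes and sides so that Procrustes centring leaks almost nothing
  into unaffected coordinates.
* **Individual variation.** Isotropic Gaussian displacement of every
  landmark coordinate, SD 1 mm — the scale of within-population soft-tissue
  variability at well-defined landmarks.
* **Landmarking noise.** Each of the two replicates adds independent
  per-landmark noise, SD 0.5 mm by default; a per-landmark SD table mimics
  the practical fact that lateral points (zygion) are far harder to place
  than the nose tip.
* **Covariates.** Small linear drifts give the age adjustment and the
  sex-balance chi-square something real to work on: males get a slightly
  longer lower face and wider jaw, age adds a mild soft-tissue descent at
  the mouth corners (0.02 mm/yr). Both default effects can be zeroed.
* **Meshes.** Each individual's surface is the template warped by a
  Gaussian radial-basis interpolant that passes exactly through the
  individual's true landmarks (bandwidth 30 mm), so mesh-level phenotypes
  (curvatures, geodesics, segment areas) covary with the landmark effects.

What the generator deliberately does **not** emulate: photorealistic
anatomy, texture, asymmetry structure, non-Gaussian population tails,
correlated landmarking error, or any real population's facial statistics.
Passing tests demonstrate that the *pipeline* measures what it claims to
measure under known truth — not that any particular real population
behaves this way.

# Alignment and reliability

GPA follows the standard iterative scheme: centre every configuration,
rotate each onto the current consensus by the SVD (Kabsch) solution
constrained to det(R) = +1 (faces must never mirror), update the consensus,
and repeat until the consensus RMS change falls below 1e-8 mm (at most 100
iterations; the consensus is initialised from the first configuration).
Scaling is deliberately omitted so face-size differences remain part of
every distance, area and volume phenotype. Centroid sizes are verified
unchanged by alignment, and the summed squared distance to the consensus is
non-increasing across iterations.

Landmarking reproducibility is summarised per landmark and axis as the SD
across individuals of the signed replicate difference, computed in the raw
scanner frame (landmarking happens before any alignment; aligning first
would mix axes). With isotropic replicate noise of SD sigma this statistic
estimates sigma*sqrt(2), which the tests recover. The conventional 1 mm
threshold separates "moderate or high" from "low" reproducibility. An
alternative definition (deviation of each replicate from the replicate
mean) differs only by the factor sqrt(2)/2 and can be derived from the same
table.

Reliability of derived traits uses the two-way mixed-effects consistency
ICC, from the mean squares directly: ICC(3,1) = (MS_S - MS_E) / (MS_S +
(k-1) MS_E), with exact F-distribution confidence bounds, and the common
0.5 / 0.75 / 0.9 bands for qualitative labels.

# Landmark phenotypes: numerical choices

**Curvatures.** Principal curvatures come from a local quadric (Monge
patch) fit: the vertex normal is the area-weighted average of incident face
normals, oriented away from the mesh centroid; neighbours within a 10 mm
edge-connected radius (at least 6 required) are projected into the tangent
frame; and z = ax^2 + bxy + cy^2 + dx + ey is fitted by least squares. The
principal curvatures of the fitted patch are signed so that convex regions
(the nose tip) have positive mean curvature; a sphere of radius r yields MC
= 1/r and GC = 1/r^2, which the tests verify within 5%, and a saddle yields
negative GC. Curvatures are computed on the surface as given; no smoothing
is applied by default.

**Geodesics.** On-surface distances solve the unit-speed Eikonal equation
by fast marching over the triangulation: the classic two-point triangle
update in Gram-matrix form with a causality check, falling back to edge
updates where the characteristic leaves the triangle (obtuse corners), then
a small number of Gauss–Seidel relaxation sweeps that repair any
fallback-induced overestimates. Landmarks snap to their nearest mesh vertex
(tolerance 2 mm); the 26 single-source solves give all 325 pairs,
symmetrised by averaging the two directions. An edge-graph Dijkstra bound
is kept in the test suite as an independent oracle (any edge path is a
surface path, so Dijkstra can never be shorter than the true geodesic);
flat sheets reproduce chords within 1% and spheres reproduce great-circle
arcs within 2%.

**Manhattan distances** are the only axis-dependent family, so they are
always computed in the GPA consensus frame; this makes them well-defined
and deterministic but, unlike every other family, not invariant to rigid
motion of the raw input (the tests assert both facts).

**Proportion indices** express the smaller of two Euclidean distances as a
percentage of the larger, so values lie in (0, 100]. The shipped battery of
32 indices covers face, orbit, nose, mouth and profile proportions;
published index sets vary between studies, so the battery is data, not
code, and fully overridable.

**Hull phenotypes.** Region volumes and surface areas use the convex hull
of each region's landmarks. Point sets here are tiny (4–10 points), so the
hull is found by supporting-plane enumeration with coplanar facets merged
through their planar 2D hull; coplanar regions report volume 0 with a
warning. Ten default regions (nose, cheeks, chin, mouth, lips, eye span,
jaw, midface) are shipped as overridable data for the same reason as the
indices.

# Segmentation track: design decisions

**Correspondence.** Synthetic meshes are template warps, so they are in
dense correspondence by construction. For external data the package
requires externally registered meshes (same vertex count and order) and
says so in its errors; dense nonrigid registration is a prerequisite, not a
feature.

**Similarity.** The covariation similarity of two vertices is the RV
coefficient between their n x 3 displacement matrices across individuals —
a scale-free generalisation of squared correlation to multivariate blocks,
in [0, 1]. Zero-variance vertices get similarity 0 with a warning.

**Spectral splitting.** Each segment splits by the sign of the Fiedler
vector of the symmetric normalized Laplacian of its similarity submatrix.
The leading eigenvector of D^-1/2 W D^-1/2 is known analytically (sqrt of
the degrees), so the Fiedler vector comes from deflated power iteration
with a deterministic start (small segments use a dense eigendecomposition).
Zero entries of the Fiedler vector join the smaller side. A minimum segment
size (default 10 vertices) stops a branch rather than produce unstable
micro-segments; stopped branches carry their segment forward so every level
remains a complete partition, and the count is then below 2^L - 1 with a
warning. Run to 7 levels with the guard disabled, the hierarchy always
contains 127 segments.

**Parallel analysis.** Per-segment PCA retains components whose covariance
eigenvalue exceeds the 95th percentile of the matching rank's eigenvalues
over column-permuted null datasets (default 100 permutations, seeded;
fewer than 20 is refused). Permutation preserves each column's values, so
the null keeps per-variable variances while destroying covariance.
Retention stops at the first failing rank. Score signs are fixed by making
each component's largest-magnitude loading positive, which makes runs
bit-reproducible under a fixed seed.

**Moran's I.** Spatial weights are k = 8 nearest neighbours on each
segment's (x, y) vertex locations, symmetrised by union and then
row-standardised; attributes are the z coordinate, mean curvature and
Gaussian curvature per vertex. The statistic follows the classic
normalisation with null mean -1/(n-1); the tests check the permutation
null mean, the sign on smooth gradients versus checkerboards, affine
invariance in the attribute, and agreement with an independent
implementation (`ape::Moran.I`).

# Statistics layer

The regional screen correlates each phenotype with the ordinal region
coding (north = 1 < central = 2 < south = 3) by Spearman rho with
average-rank ties and a two-sided t-approximation p-value; a
Kruskal–Wallis mode is available when no ordering should be assumed. The
Bonferroni threshold is alpha divided by the number of phenotypes actually
tested. Significant phenotypes are labelled heterogeneous, the rest
homogeneous. Family-wise error under the global null and power against
injected monotone effects are both verified by simulation in the test
suite.

PLS-DA is NIPALS PLS2 on autoscaled phenotypes against centred one-hot
group indicators. The component count is selected by cross-validated Q2
(default 7 folds, seeded): components are added while Q2 improves by at
least 0.01. VIP scores use the standard weighting of per-component
explained Y-variance and satisfy sum(VIP^2) = number of variables exactly;
VIP > 1 is the conventional selection rule. Autoscaling (not just
centring) mirrors the behaviour of the commercial software that popularised
VIP screening and is switchable.

PERMANOVA partitions the Gower-centred squared-distance matrix by group,
reporting pseudo-F, R^2 and a permutation p with the +1 convention (so the
smallest attainable p at 999 permutations is 0.001). The default distance
is Euclidean on standardised phenotypes. The univariate Euclidean case
reduces exactly to one-way ANOVA, and the implementation is
cross-validated against `vegan::adonis2` in the tests.

Age adjustment replaces each phenotype by its least-squares residual on
age with the mean added back — an orthogonal projection, hence idempotent,
and exactly orthogonal to age.

# Problem sizes and reproducibility

All stochastic stages take explicit seeds and are bit-reproducible from
(configuration, seed). The test suite runs the full pipeline at desk
scale: reliability laws at 500–2,000 observations, calibration suites at
200 replicate simulations, segmentation populations of 60 individuals, and
one end-to-end study of 300 individuals (100 per region) through
extraction, segmentation (50 parallel-analysis permutations) and
screening, which recovers the 8 injected gradient coordinates and flags no
unaffected point coordinate. These sizes were chosen as the smallest at
which the calibration targets have comfortable statistical margins.

# Known limitations

* Internal vertex indices are 1-based (R convention); OBJ files are
  1-based and PLY files 0-based on disk, converted at the I/O boundary.
* The fast-marching solver is first order; its error grows with triangle
  anisotropy. The relaxation sweeps mitigate but do not eliminate this.
* The warp is an exact interpolant; with the default 30 mm bandwidth the
  26-landmark kernel system is smooth but ill-conditioned enough that a
  single-landmark displacement does not stay strictly local (the kernel
  decay property is exact only for well-separated centres, and is tested
  that way). Simulated faces are smooth warps, which is what the
  segmentation track assumes.
* Landmark-only external datasets can use the whole landmark track, but
  the segmentation track requires dense correspondence the package does
  not itself compute.
* The Spearman screen's t-approximation is accurate at the tested sizes
  (30+ per group); for very small groups an exact permutation p would be
  preferable.
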