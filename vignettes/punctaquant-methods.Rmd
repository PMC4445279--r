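---
title: "PunctaQuant: models, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PunctaQuant: models, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PunctaQuant quantifies synaptic puncta in two-channel 3D confocal stacks.
This vignette is the package's own account of the underlying models, the
parameters that matter, what the synthetic benchmark does and does not
show, and the design decisions taken where more than one reading was
defensible. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and its assumptions

The input is a deconvolved laser-scanning confocal stack with a synaptic
marker channel (bright, roughly Gaussian puncta) and a neuronal morphology
channel (a bright tube-like structure), on an anisotropic grid — the
reference geometry is 80 × 80 × 400 nm voxels, so a punctum spans several
pixels in xy but only a few slices in z. The method assumes:

* puncta are local intensity maxima a small classifier can recognize from
  a 9 × 9 × 3 neighborhood;
* background is dark relative to puncta, but contrast may vary regionally
  (stitching seams), which is why thresholds are local, not global;
* artifacts (dim marker-like spots off the neuron) exist and are removed
  by morphology-channel proximity, not by intensity alone;
* adjacent puncta may fuse into one connected component ("clump") whose
  member centers the detector marks individually.

Coordinates are 0-based voxel triples (x, y, z) with z the slice index;
every box "a × b × c" means extent a in x, b in y, c in z centered on a
voxel. Distances in 3D scale z differences by dz/dx (5 at the reference
geometry). Whether image coordinates start at 0 or 1 is a convention, not
something the method constrains; 0-based was fixed once and is used in all
CSV artifacts.

## Robust adaptive thresholding (RATS)

Each slice is recursively divided into a quadtree (integer midpoints, the
larger half first, down to `minDepth` levels unless a region edge would
drop below `leafletSize`). A region's threshold is the gradient-weighted
intensity mean

$$T = \frac{\sum G_{x,y}^2 \, I_{x,y}}{\sum G_{x,y}^2},$$

with $G$ the Sobel gradient magnitude (mirror border extension). On an
ideal two-sided step the gradient mass is symmetric and $T$ is the step
midpoint; the formula is shift- and scale-equivariant, which the test
suite asserts directly.

**Validity rule.** A region is only allowed to keep its own threshold when
its gradient mass is clearly above what noise alone produces:
$\sum G^2 > (s \cdot m)^2 \, n_\mathrm{edge}$, where $m$ = `minNoise` (an
intensity-scale noise estimate), $s$ = `scalingFactor`, and
$n_\mathrm{edge}$ counts gradient-bearing pixels. Invalid regions inherit
the nearest valid ancestor; the root falls back to the global formula over
the slice, or the slice median when the slice has no gradient at all.
Leaflet thresholds sit at region centers and are bilinearly interpolated
to every pixel (clamped beyond the outermost centers); foreground is
strict (`intensity > threshold`), so constant slices give empty masks.
The exact validity test of the original formulation is not fixed by the
method description; this rule was chosen because it makes `minNoise` a
per-pixel noise amplitude and is easy to reason about: for additive noise
of sd $\sigma$, the squared Sobel magnitude averages about $24\sigma^2$
per pixel for iid noise and much less for spatially correlated noise, so
any `minNoise` a factor above $\sigma\sqrt{24}/s$ keeps signal-free
regions invalid.

**Pseudo-3D and the reference slice.** Full 3D interpolation is avoided;
the stack is thresholded slice by slice with one shared parameter set. Two
readings of "anchored on a reference slice" exist: recompute the field per
slice, or apply the middle slice's field everywhere. `ratsMask()` defaults
to per-slice recomputation and exposes `applyReferenceField`;
`pipelineConfig()` turns the option on. The reason is measurable:
boundary slices of a confocal stack are typically dark and signal-free,
and a per-slice threshold there collapses toward the noise floor —
on the benchmark scene, signal-free boundary slices went from 23–26%
foreground (per-slice) to the 1–4% of signal slices (reference field).
Over-detection on empty slices is exactly what anchoring to the brightest
slice prevents.

**Two parameterizations.** Candidate generation needs a mask guaranteed to
contain every true peak, so the *over-mask* halves `minNoise`; the
*seg-mask* uses the nominal value. Benchmark defaults: `leafletSize = 16`
(a 5-level quadtree on 256-px slices), `scalingFactor = 3`, and
`minNoise = 40` = 2 × the scene noise sd for the synapse channel. The
morphology channel uses `minNoise = 80`: its background is near zero, and
clipping at zero concentrates gradient energy into sparse spikes while
zeroing it elsewhere, which shrinks the $n_\mathrm{edge}$-scaled floor —
only the strong membrane edge should define local thresholds there. The
morphology foreground additionally drops connected components below 8
voxels, the same small-object noise rule used after synapse segmentation,
so isolated noise speckles cannot validate stray markers.

## The anisotropic Haar descriptor

Each z slice of a 9 × 9 × 3 ROI is mirror-padded to 16 × 16 and decomposed
with the orthonormal 2D Haar transform to 2 levels; the feature vector is
the weighted sum of the per-slice coefficient vectors with weights
(1, 2, 1)/4 — middle slice heaviest, matching the z-resolution disparity.
Summing (not concatenating) across z keeps the descriptor length at
$16^2 = 256$ and makes it symmetric under z flips. The full padded
coefficient set is used rather than a sub-band selection: it is
deterministic, complete, and linear in the input, and the choice is
isolated behind `haarConfig()` should a selection prove preferable.
Additional descriptors can be registered at run time
(`registerFeatureExtractor`); a deliberately weak `mean_intensity`
baseline ships for chain comparisons.

## The windowed-momentum MLP

A single hidden layer of sigmoid units (default 16) with a sigmoid output,
trained by full-batch backpropagation on the mean squared error with the
update

$$\Delta w(t) = -\eta \nabla E(t) + \alpha \cdot
\mathrm{mean}\big(\Delta w(t-1), \ldots, \Delta w(t-W)\big),$$

which for $W = 1$ reduces exactly to classical momentum (a regression test
asserts the equality against an independent re-implementation). Features
are standardized per dimension with training-set constants stored in the
model; weights start uniform in $\pm 1/\sqrt{\text{fan-in}}$ under a fixed
seed, so training is deterministic. Defaults: $\eta = 0.05$,
$\alpha = 0.9$, $W = 5$, 500 epochs, early stop when the MSE falls below
$10^{-4}$. A score strictly above 0.5 is positive; exactly 0.5 is
negative. Chains (extractors + classifier) are ranked by stratified k-fold
cross-validation with pooled accuracy; SVM and random-forest classifiers
can be plugged in behind the same interface, but only the MLP is part of
the method.

## Detection

Candidates are voxels that are foreground in the over-mask and equal to
the maximum of their 7 × 7 × 5 neighborhood (clipped at borders); within a
26-connected plateau of equal maxima only the smallest (z, y, x) voxel
survives — the method does not specify plateau handling, and this
tie-break makes the output deterministic. Each candidate's ROI is
classified; positives are refined by iterative mean shift (window
9 × 9 × 3, mirror-padded, tolerance 0.5 voxel, max 20 iterations) and then
merged whenever two centers are closer than
`mergeFraction × expectedSizeXy` (defaults 0.5 × 7 = 3.5 anisotropy-scaled
voxels): the globally closest pair merges first into its score-weighted
centroid, ties broken by smallest (z, y, x), which makes merging
order-independent. One consequence of the greedy rule worth noting: three
collinear markers spaced just under the merge radius collapse to *two*
markers, not one — after the first merge the centroid sits farther than
the radius from the third marker.

## Clump splitting

After seg-mask segmentation, 26-connected components (objects under 8
voxels discarded as noise) holding two or more markers are split on their
xy maximum intensity projection. The contour is traced (Moore
neighborhood, clockwise, starting at the topmost-then-leftmost pixel —
any closed ordering works for the concavity sums; this one is canonical),
and each contour point i gets

$$C(i) = \sum_{k = i-1}^{i+1} w_k,$$

with $w_k$ the foreground count in the 5 × 5 window at point k (clipped at
the image border: windows must not hallucinate foreground). The cut for a
target marker M1 walks anchors A in decreasing $C$; partners B are tried
in decreasing split energy

$$E(\{i, j\}) = \frac{C(i)\,C(j)}{d(i, j)},$$

and the first Bresenham chord whose removal leaves M1 8-disconnected from
every other marker wins (so the returned pair maximizes E among valid
pairs for that anchor). M1 itself is the pool member with maximal summed
3D distance to the rest — peeling extremes first keeps cuts natural on
elongated clumps. Voxels follow the side of their projection pixel; chord
pixels go to the side of the nearer marker (ties to M1). When no chord
separates (e.g. markers coincide in projection), the remainder stays
together flagged `unsplittable`. Children always partition the parent
exactly, which the acceptance suite asserts on dumbbell and triple-blob
fixtures.

**What splitting changes.** Splitting produces per-synapse voxel supports:
counts, sizes, and per-child centroids (`quantifyObjects()`). The
*positions* reported for detections remain the mean-shifted markers. This
was a measured decision: a mean-shifted marker is already a local
center-of-mass estimate sitting on a punctum peak, and replacing it by the
whole-child centroid (geometric or intensity-weighted — both were tried)
moves the center off-peak precisely when a child still contains a second,
undetected punctum. On the benchmark, centroid replacement lost matches
and never gained any, so the after-splitting marker set equals the model
output in position, with markers of split clumps flagged `split`.

## Co-localization and evaluation

A detected center is kept iff any morphology-foreground voxel lies in its
centered 9 × 9 × 5 box; kept markers gain status `validated`, and the
filter is idempotent. Evaluation matches detections to reference centers
one-to-one inside a 7 × 7 × 5 box, pairing globally closest
(anisotropy-scaled) first — one-to-one is stricter than per-marker
counting and cannot double-count a reference. Precision, recall and
$F = 2PR/(P+R)$ are reported in percent to 2 decimals (half-up rounding),
and region reports append an unweighted per-region average row.

## The synthetic benchmark

`generateScene()` emulates, with known ground truth, the image properties
the detector must survive: anisotropic Gaussian puncta (σ = 1.6 voxels in
xy, 0.8 in z, truncated at 3σ rounded up to whole voxels; peaks uniform in
150–255 on a 16-bit-compatible integer scale), fused clumps (members
spaced 1.0–1.5 × σxy apart so their blobs merge into one component), dim
artifacts at 0.3 × peak planted at least 8 voxels off the neuron, a smooth
additive background gradient, additive Gaussian noise, and a branched
random-walk tube as morphology. The default scene is 256 × 256 × 16
voxels with 150 synapses, 30% clumped, 10 artifacts, and noise sd 20
(10% of the median peak), seed 42 — sized so the full pipeline runs in
seconds to minutes on one CPU. Synapse seats keep a minimum
anisotropy-scaled spacing of 10 voxels between groups, a realistic packing
for receptor puncta along a neurite at this pixel size.

Two generator choices deserve explanation:

* **Noise is spatially correlated** (xy Gaussian smoothing with σ = 2,
  marginal sd rescaled to exactly the nominal value). Deconvolved,
  frame-averaged confocal stacks have smooth noise; iid pixel noise would
  put ~24σ² of squared Sobel energy into every flat region, more than any
  gradient-weighted threshold scheme can rise above, and is not what the
  target data look like.
* **The morphology channel has its own, lower noise** (sd 8, ~5% of the
  tube intensity): membrane markers are imaged at high SNR and the channel
  serves only as a binary structure reference.

What passing the synthetic benchmark does *not* show about real data: the
scene has no intracellular-transport artifacts on the neuron itself, no
stitching discontinuities (the background varies smoothly), a single blob
shape shared by all puncta, and clump members so close (≤ 2.4 voxels) that
they never form separate intensity maxima — on real stacks, clump members
are typically farther apart and the marker-guided split recovers them as
separate detections, whereas here clumps are bounded by the candidate
stage. Benchmark recall is therefore structurally capped near
(150 − ~25)/150 ≈ 0.83, and the after-splitting F equals the model-output
F on this benchmark (splitting refines supports, not positions).

Training ROIs are sampled 25 + 25 by default: positives on true centers;
negatives from artifact centers (up to 20%), ring positions 3–6 xy voxels
off a center, and bright background spots (a random voxel snapped to the
brightest voxel of its 5 × 5 × 3 window — the detector will only ever see
background at local maxima, and an annotator tags distractor-like spots,
not arbitrary dark voxels). Every negative keeps at least 3 xy voxels from
every true center.

## Numerical choices and degenerate inputs

* ROI and mean-shift windows mirror-reflect at borders (no edge
  repetition: index −1 maps to 1), avoiding artificial dark rims in
  features.
* Quadtree splits at integer midpoints, larger first half; plateau,
  merge-order, component-renumbering and matching ties all break by
  smallest (z, y, x); equal-accuracy chains keep declaration order.
* All-zero mean-shift windows leave the marker unchanged; empty masks give
  empty marker sets; constant slices give empty foreground; an empty
  marker CSV is a header-only file that round-trips.
* Marker CSVs store coordinates exactly and scores at full double
  precision; models serialize to a single JSON file (weights, chain,
  standardization constants).
* All randomness (scene, ROI sampling, weight initialization, fold
  assignment) flows from explicit seeds; identical seeds give
  bit-identical scenes and byte-identical pipeline marker CSVs.

## Test problem sizes

The unit suite works on constructed fixtures (dumbbells, triple blobs,
steps, random 20 × 20 × 8 volumes against brute-force oracles) and small
96 × 96 × 8 scenes with 15 synapses; the acceptance suite additionally
runs the full 256 × 256 × 16 benchmark once. The whole suite completes in
well under a minute per scene-bearing file on one CPU.

## Known limitations

* The splitting recursion is quadratic in contour length per anchor; it is
  intended for punctum-scale clumps (tens of pixels across), not
  field-scale segmentation masks.
* The MLP is a fixed-architecture binary classifier; it does not estimate
  uncertainty beyond its sigmoid score.
* The RATS validity rule is a documented stand-in for an unspecified
  original; `minNoise` must be chosen per channel with the noise model in
  mind (see above), and grossly misestimated values degrade the masks.
* Co-localization is purely geometric; intensity-correlation measures are
  out of scope.
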