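# PunctaQuant

Learning-guided detection and quantification of synaptic puncta in
anisotropic two-channel 3D confocal stacks.

Counting synapses in confocal images of single neurons — for example
GABA-receptor puncta on the axon terminals and dendrites of fly lobula plate
tangential cells — is still largely done by hand. Automation is hard for
specific reasons: stacks are large and anisotropic (xy pixels around 80 nm,
z steps around 400 nm), staining artifacts mimic dim puncta, regional
contrast varies across stitched images, and neighbouring synapses fuse into
clumps that intensity thresholding cannot separate. PunctaQuant implements a
detection pipeline built around a small trained classifier and
marker-guided clump splitting, together with a seeded synthetic scene
generator so that every stage can be benchmarked against known ground
truth.

## Method

The pipeline runs these stages on the synapse channel:

1. **Adaptive thresholding (RATS).** Each slice is divided into a quadtree
   of regions; a region's threshold is the gradient-weighted intensity mean

   `T = Σ (G²ₓᵧ · Iₓᵧ) / Σ G²ₓᵧ`

   with `G` the Sobel gradient magnitude. Regions whose gradient mass does
   not clear a noise floor defer to their parent; leaflet thresholds are
   bilinearly interpolated to every pixel. The stack is processed
   slice-wise ("pseudo-3D"), anchored on a reference (middle) slice. A
   permissive *over-mask* supports candidate generation; the nominal
   *seg-mask* supports object segmentation.
2. **Candidate generation.** Masked 3D local maxima in a 7×7×5 search
   locality.
3. **Classification.** A 9×9×3 ROI around each candidate is described by an
   anisotropic 3D Haar descriptor (orthonormal 2D Haar coefficients of each
   xy plane, summed across z with the middle slice weighted heavier) and
   classified by a single-hidden-layer perceptron trained with windowed
   momentum (`Δw(t) = −η∇E(t) + α·mean(Δw(t−1)…Δw(t−W))`) on a few dozen
   annotated ROIs. Chains of extractor + classifier are compared by
   stratified 5-fold cross-validation.
4. **Refinement.** Iterative mean shift to the local center of mass, then
   merging of centers closer than half the expected synapse diameter.
5. **Clump splitting.** 26-connected components (< 8 voxels discarded as
   noise) containing two or more markers are split on their xy maximum
   intensity projection: contour points get a concavity score
   `C(i) = w(i−1) + w(i) + w(i+1)` (`w` = foreground count in the 5×5
   window), and the cut chord `{i, j}` maximizes the split energy
   `E = C(i)·C(j) / d(i, j)` among chords that isolate the targeted marker,
   recursing until each child holds one marker.
6. **Co-localization.** Detected centers lacking morphology-channel
   foreground within a 9×9×5 box are discarded as staining artifacts.
7. **Evaluation.** Precision / recall against reference centers by
   one-to-one proximity matching in a 7×7×5 box, combined as
   `F = 2PR / (P + R)`.

## Worked example

```r
library(PunctaQuant)

# the default benchmark: a 256 x 256 x 16 two-channel scene with 150
# synapses (30% fused into clumps) and 10 off-neuron artifacts, a model
# trained on 25 positive + 25 negative sampled ROIs, and the full pipeline
res <- runBenchmark(seed = 1)

res$cvAccuracy                 # 5-fold CV accuracy of the haar3d+mlp chain
#> [1] 1
res$evaluation$model$f         # model-output F-measure vs ground truth (%)
#> [1] 88.0597
res$evaluation$validated$f     # after splitting + co-localization (%)
#> [1] 88.0597
res$quantification$count       # objects within the 8..1000 voxel range
#> [1] 119
round(res$quantification$mean, 1)  # mean punctum size (voxels)
#> [1] 26.4
```

The model output finds 118 of the 150 planted synapses with no false
positives (precision 100%, recall 78.7%); the unrecovered ones are almost
all clump members whose blobs are too fused to form separate intensity
maxima. Co-localization removes every planted off-neuron artifact while
keeping all true detections.

Individual stages are exported (`ratsMask`, `localMaxima`,
`classifyCandidates`, `meanShiftRefine`, `mergeClose`,
`connectedComponents26`, `splitObjects`, `colocalizeFilter`,
`regionReport`, …) and a thin command-line front end with `simulate`,
`train`, `detect`, `split`, `validate`, `evaluate` and `run` subcommands is
installed under `inst/scripts/punctaquant`. See the methods vignette
(`vignettes/punctaquant-methods.Rmd`) for the models, parameter choices and
their rationale.

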