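---
title: "Quantifying DNA bridging in fluid-AFM height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA bridging in fluid-AFM height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nucleoid-associated proteins (NAPs) such as GapR of *Caulobacter crescentus*
compact and organise the bacterial chromosome. One proposed mechanism is DNA
*bridging*: a protein holding two duplex segments together. In fluid atomic
force microscopy (AFM), a bridge shows up as a *junction* — a crossing of two
DNA paths whose surface height exceeds that of a single duplex, and exceeds
it further when a protein sits at the crossing. Short DNA fragments
(1 kbp, contour length 1000 bp × 0.34 nm/bp = 340 nm) deposited at a few
molecules per square micrometre give fields in which individual molecules,
their crossings, and the height at each crossing can all be measured.

`afmbridge` implements the full quantification workflow — per-scanline
background flattening, height-threshold particle segmentation, skeleton-graph
molecule tracing, junction detection and classification, junction-height
statistics, and density-stratified comparisons — together with a
ground-truthed synthetic scene generator, so that every stage of the analysis
can be validated against known truth without any external data.

# The synthetic scene model

## Chains

Surface-equilibrated DNA is modelled as a two-dimensional worm-like chain:
a polyline of equal segments (default 2 nm) whose successive turning angles
are independent zero-mean Gaussians with variance `segment_length / lp`,
where `lp` is the persistence length (default 50 nm, the accepted value for
double-stranded DNA). Under this convention the tangent correlation decays
as `exp(-s / (2 lp))` along the contour — the 2-D closed form the test suite
checks by Monte-Carlo. The contour length is exactly `n_bp * 0.34` nm; the
requested segment length is adjusted to the nearest divisor so this holds to
machine precision.

## Scenes and forced junctions

`place_molecules()` scatters chains with uniform positions and orientations
over a square field (default 1 × 1 μm, the scan size). Junctions can be
forced with configurable probabilities:

* *intramolecular*: the distal part of a chain is regrown steered toward one
  of its earlier vertices, and one segment is placed passing exactly through
  that vertex — a guaranteed self-crossing with all segment lengths
  preserved;
* *intermolecular*: a chain is translated so one of its vertices coincides
  with a vertex of an earlier chain.

Ground truth is then established *independently of the forcing*: an
all-pairs segment-intersection sweep finds every crossing of the final
polylines (forced or natural), crossings of the same chain pair within the
capture radius (two segment lengths) merge into one junction, and junctions
outside the field are discarded. Each junction is flagged protein-bound with
probability `p_protein`. The test suite re-derives these counts with an
independent brute-force oracle.

Sample densities follow the two imaging regimes used for density-stratified
comparisons: *low* coverage at 4–7 and *high* at 8–15 molecules/μm².

## Rendering

`render_height_map()` inverts the imaging process pixel by pixel:

* base height `h_dna * exp(-d² / (2 tip_sigma²))`, with `d` the distance to
  the nearest chain segment — a Gaussian surrogate for tip convolution
  (default `h_dna` = 1.0 nm, `tip_sigma` = 3 nm);
* `h_overlap_add` (default 0.86 nm) wherever the pixel lies within
  `tip_sigma` of **two distinct duplex passes** — two different chains, or
  two parts of the same chain more than 20 nm apart along the contour. This
  makes steep crossings and extended shallow-angle overlaps alike sit about
  one duplex height above free DNA;
* `h_protein_add` (default 0.50 nm) within `tip_sigma` of a protein-bound
  junction;
* a random per-scanline polynomial background (orders 0–2, coefficient scale
  0.3 nm) and i.i.d. Gaussian pixel noise (0.08 nm).

The defaults are chosen so a bare crossing reads 0.86 nm and a
protein-occupied one 1.36 nm above free DNA — the two junction classes the
analysis must separate — and so rendered fields resemble published fluid-AFM
scans of DNA in the 0–2.8 nm display range. The scan raster defaults to
512 px over 1 μm; the pixel count is a conventional acquisition setting, not
a physical constant, and everything downstream reads the pixel size from the
map itself.

Condition presets map the three experimental samples to generator settings:
`dna` (no protein: junctions occur but none are bound), `gapr` (frequent
bridging, every junction bound), and `mutant` (a DNA-binding-deficient
variant: near-baseline junction frequency with residual occupancy 0.18,
which puts the expected junction height excess at
0.86 + 0.18 × 0.50 ≈ 0.95 nm).

What the generator does **not** emulate: tip asymmetry and double-tip
artifacts, scars and streaks, drift shear, molecule-surface interactions
that perturb the 2-D WLC statistics, and protein aggregates on the
substrate. Passing recovery tests therefore demonstrates that the analysis
is correct *under the stated imaging model*, not that it is robust to every
artifact of real scans.

# The analysis pipeline

## Flattening

AFM raster images carry per-scanline background (piezo drift, line-to-line
offsets). `flatten_scanlines()` fits and subtracts a polynomial of order 0,
1 or 2 per image row; `flatten_image()` applies the three orders
sequentially, the common practice. Because molecules would bias a naive
least-squares fit, the fit is iterated (default 3 times) with one-sided
masking: pixels whose residual exceeds `mask_k` (default 3) robust sigmas
(MAD × 1.4826) are treated as foreground and excluded from the next fit.
Scanlines with fewer unmasked pixels than coefficients fall back to order 0
with a warning. The output minus the input is, per row, exactly a polynomial
of the requested order — a property the tests assert directly.

## Segmentation

The original workflow selected a height cutoff by eye such that over 90% of
molecules were captured. The package substitutes a reproducible rule:
threshold at the background median plus `k` = 3 robust sigmas (the
background dominates by area, so whole-image robust statistics estimate it
well). Supra-threshold pixels are labelled by 8-connected components
(diagonal moves connect, keeping thin diagonal rasters intact), and
components below 30 px are discarded as specks. A ground-truth molecule
counts as *captured* when at least half of its rasterised centerline pixels
fall in some labelled component; on default synthetic fields the automatic
threshold captures essentially all molecules, comfortably above the 90%
criterion.

## Tracing

Each component is thinned to a one-pixel skeleton (Zhang–Suen, topology
preserving). Skeleton pixels with ≥3 neighbours become branch nodes
(touching branch pixels merge; nearby branch nodes within `r_merge` = 4 px
merge again at junction level, since a pixelated X typically thins into two
degree-3 nodes), degree-1 pixels are endpoints, and maximal node-free pixel
paths are edges. Dead-end edges shorter than 6 px are pruned and the graph
re-simplified — thinned images of noisy, several-pixel-wide ribbons sprout
short spurious hairs, and pruning them is standard filament-tracing
practice. The segmentation mask itself is built from a lightly smoothed copy
of the image (Gaussian, σ = 1 px) for the same reason; *all heights are
measured on the unsmoothed map*.

**Contour length** is measured by walking every skeleton pixel of the
component (greedy nearest-unvisited walk) and summing chords spanning three
pixels. The chord metric is exact on straight axial and diagonal paths —
where it coincides with the classical 1 px / √2 px step metric — while
suppressing two known biases: the staircase inflation of step counting on
oblique curves, and the shortcuts a naive graph path takes where tight folds
of a molecule touch in the raster. On noise-free rendered 1-kbp molecules
the traced mean is within about 2% of 340 nm; the residual bias comes from
thinning's retraction of rounded ribbon ends and its smoothing of
sub-resolution wiggles.

**Junction detection** is height-based: skeleton pixels whose height exceeds
the component's own median skeleton height by `min_height_excess` = 0.4 nm
(about half a duplex height, five times the pixel noise) mark overlap
regions; connected clusters of ≥2 such pixels each count as one junction,
located at the cluster's highest pixel. This is deliberately not "one
junction per branch node": where two ribbons merely run close enough to
merge laterally the skeleton branches but nothing is elevated (not a
junction), and where two molecules overlap at a shallow angle the elevation
extends along a stretch whose branch nodes sit at the merge ends (one
junction, found by its elevation). Branch nodes remain available via
`detect_junctions()` and supply the reported junction degree.

**Junction height difference** reproduces the arrow-vs-asterisk comparison:
the same local feature height — the maximum within `window_r` = 3 px — is
read at the junction and at free-DNA reference points (skeleton pixels
farther than `excl_r` = 8 px from every junction; up to 40 evenly
subsampled), and the difference of the junction reading and the median free
reading is returned. Reading *both* sides with the identical local-max
statistic makes the noise-extremum bias of a windowed maximum cancel; an
asymmetric estimator (max at the junction, plain median on free DNA) would
overestimate by roughly the expected maximum of a handful of noise draws,
~0.1 nm at the default noise level. Recovery tests confirm the matched
estimator is unbiased within 2 SEM at n = 30 junctions. Junctions whose
component retains fewer than 20 free-DNA pixels are skipped with a warning.

**Classification** is component-level, using endpoint count and total
length against the nominal molecule length `L0` (340 nm) with relative
tolerance 0.25: two endpoints at ~`L0` → intramolecular; three or four
endpoints at ~`2 L0` → intermolecular; closed loops → intramolecular;
anything else ambiguous. Components touching the image border are flagged
clipped and excluded from classification (only whole molecules are
classified); an ambiguous component contributes `round(L / L0)` molecules
to counts, an intermolecular one contributes two.

## Statistics

`summarize_sample()` pools molecules and junctions per condition: counts by
type, the percentage of molecules with at least one junction, and the mean ±
SEM height difference (SEM uses the n−1 standard deviation). Summaries carry
their sufficient statistics so `merge_summaries()` recomputes pooled values
exactly rather than averaging. Junctions are pooled across images, matching
the original analysis; per-image aggregation can be built from the per-image
tables if clustering is a concern. Condition comparisons use the unpaired
equal-variance Student's t test (`unpaired_t_test()`, cross-checked against
`stats::t.test` and an exact permutation oracle), with the significance
threshold reported at 0.001 and no multiple-testing correction — the
comparisons are few and pre-planned. `density_fold_change()` forms the
ratio of intermolecular junction percentages (high/low density) and of
intramolecular percentages (low/high).

# Numerical choices and degenerate inputs

* All randomness is seeded; scene assembly and rendering each consume one
  seeded stream, and the pipeline derives per-image seeds as
  `(seed * 1000 + i) mod (2^31 - 1)`. Two runs of the same configuration are
  byte-identical.
* A zero-noise, zero-background map has robust sigma 0: the automatic
  threshold degenerates to the background median (0), which still captures
  every molecule but labels the whole field; explicit thresholds are the
  right tool for synthetic noise-free maps.
* Constant scanlines (MAD = 0) keep all pixels unmasked during flattening;
  scanlines narrower than the polynomial order fall back to order 0.
* The t test's degenerate contract: identical constant samples give
  t = 0, p = 1; constant samples with different means give an infinite
  statistic and p = 0, flagged.
* Zhang–Suen thinning applies its two sub-iterations in a fixed direction
  order, so a 90° image rotation can move one borderline junction region in
  or out; counts are stable to ±1 under rotation.
* TIFF export rescales heights to [0, 1] (the writer's storage range) and
  records offset/scale plus the pixel size in a JSON sidecar; reading
  restores nm values to float32 precision. The ASCII format (`%.17g`)
  round-trips bit-identically and is the reference format. A map without
  its sidecar is refused — silently assuming a pixel size would corrupt
  every nm-valued quantity downstream.

# Problem sizes used in validation

The packaged tests and the acceptance script run at the study's native
scale: 1 × 1 μm fields at 512 px with 8–12 molecules for segmentation and
junction-count recovery (20 fields), 256 px two-molecule fields for the
junction-height ensembles (30 junctions per arm), 10⁴ chains for the
tangent-correlation check, and a two-condition demo run at 256 px for the
determinism contract. These sizes make the whole suite run in a few minutes
on one CPU while keeping every statistical check at useful power.

# Known limitations

* Merged multi-molecule clusters are classified, not split; a watershed
  separation of touching molecules is out of scope.
* Crossing topology (which strand passes over) is not resolved, and
  persistence length is not estimated from traces.
* The intra/inter classification trusts skeleton length; molecules whose
  folds overlap extensively are under-measured and land in the ambiguous
  class.
* Real-data effects outside the imaging model (tip artifacts, aggregates,
  drift) are untested by construction; apply the pipeline to real scans
  with those caveats in mind.
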