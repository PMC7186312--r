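---
title: "Quantifying collagen fiber organization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen fiber organization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibretrace)
```

Fibrillar collagen remodels around tumors in characteristic patterns:
fibers running perpendicular to a tumor boundary mark an invasion-permissive
phenotype, while dense parallel alignment signals stiffened, reorganized
stroma. Second harmonic generation (SHG) microscopy images collagen
label-free, and the quantities of interest are orientational: the mean
fiber angle, the alignment coefficient, and fiber-level geometry (length,
width, straightness). `fibretrace` computes these with two complementary
analysis modes plus the supporting machinery — boundary-relative angle
analysis, ROI tools, a ground-truth synthetic generator, and a
deterministic batch runner. This vignette explains the models, the tunable
parameters, and the design decisions that were genuinely open.

## Angle conventions and directional statistics

All orientations are *axial*: a fiber at 10° and one at 190° are the same
fiber. Angles live in [0°, 180°), measured counterclockwise (as displayed)
from the +x (column) axis, with the image row axis pointing down. Every
statistic doubles the angles first — the standard treatment of axial data —
so the sample `{0°, 90°}` is maximally dispersed, as it should be for
undirected orientations.

On the doubled circle we compute the usual circular moments. The
**alignment coefficient** is the resultant vector length
$R = \lvert \tfrac{1}{W}\sum_k w_k e^{2 i \theta_k}\rvert \in [0, 1]$:
0 for isotropic orientations, 1 for perfect parallel alignment. The
circular variance is $1 - R$, the circular standard deviation
$\sqrt{-2 \ln R}$ (reported in axial degrees), and skewness/kurtosis follow
Fisher's circular definitions from the second trigonometric moment. The
median is the sample angle minimizing mean axial deviation, ties resolved
toward the smaller angle. Weights default to 1; curvelet-mode statistics
weight angles by coefficient magnitude (strong coefficients mark strong
edges) and fiber-mode statistics weight by fiber length, matching how an
annotator would weight long fibers. Empty samples yield a *flagged*
summary (`undefined = TRUE`) rather than an error, so a blank image cannot
abort a batch.

## The curvelet transform

Curvelets are needle-shaped, oriented multiscale elements supported on
frequency wedges, with parabolic scaling (length $2^{-j/2}$, width
$2^{-j}$). Because a smooth edge is sparsely represented by the few
curvelets aligned with it, the largest coefficients of a curvelet
transform read off local fiber orientations directly, with no thresholding
or denoising step — band selection does both implicitly.

`fdct()` tiles the frequency plane with windows whose *squares sum to one
exactly*: a low-pass block at the coarsest scale, dyadic coronae split
into angular wedges in between, and an isotropic fine ring at the highest
frequencies (which holds pixel-scale noise and is excluded from analysis,
as is the low-frequency background block). Radial knots sit at
$\rho_j = 0.48 \cdot 2^{\,j-J}$ in normalized frequency; each corona rises
and falls over exactly one octave on each side of its center, and each
wedge spans one wedge spacing to either side of its central direction,
with complementary $C^\infty$ rise/fall steps. Each wedge band is then
extracted on the rectangular frequency block bounding its support and
inverse-transformed with a unitary FFT. Two consequences are exact rather
than approximate, and the test suite asserts them at 1e-6 where they hold
at ~1e-15:

* **Tight frame.** Coefficient energy equals image energy, and
  `ifdct(fdct(x))` reproduces `x` to floating-point rounding.
* **Conjugate symmetry.** Antipodal wedges of a real image carry complex
  conjugate coefficients; the antipodal block is indexed as the exact
  negation of its partner, so the symmetry is exact.

Coefficient `(k1, k2)` of a block of size $L_1 \times L_2$ sits at image
position $(k_1 N_1/L_1,\; k_2 N_2/L_2)$ — the regular spatial lattice of
that wedge — and its ridge orientation is perpendicular to the wedge's
central frequency direction. This pyramid is more oversampled than
decimated-wedge implementations (blocks are not subsampled), which only
means `keep_fraction` counts against a larger coefficient total; the kept
curvelets concentrate on the same edges.

Defaults: `n_scales = ceil(log2(min(dim)) - 3)` (at least 3) and 16 wedges
at the second-coarsest scale, doubling every second scale — at 512×512 the
analysis scale carries 32 wedges, i.e. 5.625° axial half-width, which sets
the angular quantization of curvelet mode.

## Curvelet mode

The pipeline is: transform → keep the second-finest scale → keep the
`keep_fraction` largest magnitudes (default 0.35%, ties broken
lexicographically for determinism) → attach image-space geometry → group
curvelets within `group_radius_px` (default 10 px; the packaged validation
uses 8 px). "Group the adjacent curvelets within a given radius" is
realized as single-linkage connected components — the transitive closure
of the pairwise-distance relation — because it is the unique
deterministic, order-independent reading of adjacency-within-a-radius.
Groups are numbered by their smallest member position, so shuffling the
input changes nothing. Each group's representative is the
magnitude-weighted centroid and magnitude-weighted axial mean of its
members.

One behavioral note follows directly from single linkage: raising
`keep_fraction` adds curvelets that can *bridge* two existing groups into
one, so the number of groups is not monotone in the kept fraction (the
number of grouped curvelets is).

Per-group features: nearest-neighbor distance, local density (neighbor
counts within 16/32/48/64 px), and local alignment (alignment coefficient
of the group and its 4/8/16 nearest neighbors). The ladders are
config-exposed; the values are round numbers spanning one to a few fiber
lengths at typical SHG pixel sizes. `local_alignment_map()` tiles the
image and assigns each square the alignment of the groups inside it
(empty squares are 0).

## Individual-fiber mode

The tracer works on the Euclidean distance transform of the binarized
image (foreground strictly above `background_threshold`, default 60 — the
validation setting):

1. **Nucleation.** Pixels whose distance value is the strict maximum of
   an 11×11 box (`nucleation_box_radius` 5) and exceeds
   `nucleation_distance_threshold` (2 px) seed the tracer. Plateau ties
   are broken by a seeded multiplicative jitter below 1e-6 — large enough
   to order equal values deterministically, far too small to reorder
   distinct ones.
2. **Extension.** From each nucleation point, one branch per local
   maximum point (LMP) on the surface of the box whose half-width is the
   tip's distance value. At each step, LMPs below
   `lmp_distance_threshold` (1.5 px) are ignored, near-duplicate LMPs
   closer than `lmp_min_separation` (3 px) collapse to the larger one,
   candidates opposing the tip direction (negative dot product) are
   discarded to prevent backtracking, and the most aligned candidate is
   taken. The tip direction carries memory:
   `new = normalize(0.5 * old + 0.5 * step)`. A branch ends when no
   admissible LMP remains, at the image edge, or on reaching another
   nucleation point — in which case it snaps to that point and records
   it.
3. **Linking.** A branch to nucleation point *b* and its mirror traced
   from *b* back describe the same path, so only one of each mirror pair
   enters the pool. Nucleation points are then visited in id order; at
   each point, the incident chain ends whose directions (computed over
   `tip_spacing` = 3 vertices) continue most nearly straight are linked
   first, as long as the deviation stays within `link_angle_threshold`
   (30°), and a merged chain keeps linking at its other ends. This chains
   branches through interior nucleation points into full-length fibers.
   Unlinked branches become single-branch fibers; fibers shorter than
   `min_fiber_length` (30 px) are dropped.

Per-vertex radius is the distance value at the vertex; fiber width is
twice the mean radius, straightness is end-to-end distance over contour
length, and the angle is the axial angle of the end-to-end vector. Two
biases are inherent and documented rather than corrected: tips are
truncated where the distance falls below the LMP threshold (total
extracted length ≤ true length), and noise pixels attached to fibers
fatten the foreground (extracted width ≥ stamped width on noisy images).
The tests assert the directions, not magnitudes. Gaps in intensity are
not bridged: a fiber interrupted by a dropout is reported as two fibers.

Everything downstream of the seeded jitter is deterministic, and each
image in a batch derives its RNG stream from the job seed and the image
file name, so parallel and sequential batch runs are byte-identical.

## Synthetic fiber generator

The generator is the package's validation oracle: it produces images with
per-fiber ground truth under user-specified distributions.

**Properties.** Length, starting width and straightness are drawn from
Gaussian, uniform or piecewise-linear distributions. A Gaussian with
`sd = 0` is allowed as a point mass — the packaged validation presets pin
length 60 px, width 5 px and straightness 1 (straight preset) or 0.92
(curvy preset) exactly, with 30 fibers per 512×512 image, mean angle 90°,
alignment 0.2, edge buffer 10 px and Poisson noise level 50.

**Directions.** Drawn from an axial von Mises distribution whose
concentration solves $A_1(\kappa) = I_1(\kappa)/I_0(\kappa) = \rho$, then
calibrated: deviations are scaled about the sample mean direction (the
scale factor found by root-finding on the sample resultant) and the
sample is recentered, so each image's fiber population has *exactly* the
requested mean angle and alignment. The alternative — matching the
targets only in expectation — was rejected because the sample resultant
of 30 i.i.d. draws is biased upward
($E[\hat R] \approx \sqrt{\rho^2 + (1-\rho^2)/n} \approx 0.27$ for
$\rho = 0.2$), which would make per-image alignment systematically
overshoot the nominal value and defeat the generator's purpose as a
ground-truth instrument. Targets below 0.02 fall back to uniform draws
(a zero sample resultant is not reachable by scaling).

**Paths.** `bridge_path()` places `n = round(length / segment_length)`
segments of *exact* length between endpoints separated by
`straightness × n × segment_length`. The midpoint of a gap of $m$
segments is sampled uniformly from the intersection of the two regions
reachable from its endpoints — a disk of radius $\lceil m/2\rceil L$ /
$\lfloor m/2\rfloor L$ for two or more steps, a circle of radius $L$ for
exactly one — and the construction recurses. Exact-length segments make
the stored ground truth exact by construction: contour length is
$nL$, and straightness is the chord/contour ratio. A taut chord
degenerates every intersection to a point and yields the exactly
collinear path.

**Smoothing.** Three methods, applied in the order bubble → swap →
spline, each preserving the endpoints exactly. Bubble sweeps the path and
swaps adjacent segment *displacement vectors* when the swap reduces the
turning angle at the affected joints (a monotone-turning path is a fixed
point); swap performs `rate × n` random transpositions. Both permute the
segment multiset, so contour length, chord and angle are untouched.
Spline fits interpolating cubics (chord-length parameterization) and
resamples to `ratio ×` the point count, which perturbs contour length by
well under 1% at the default ratio 2. Ground truth is measured from the
final vertices, so the stored table is always self-consistent with the
stored geometry.

**Rendering.** Segments are stamped as lines dilated to their per-segment
width (foreground 255 on 0). The degradations — rescale, mean-pool
downsample, Gaussian blur, noise, distance filter, threshold,
normalize — apply in that order, each only if enabled. The default noise
model replaces each pixel by a Poisson draw with mean
`intensity + noise_level` (clipped to [0, 255]), so the background mean
equals the configured noise level, mimicking photon counting; additive
Gaussian noise is available as an alternative. With noise level 50 about
7% of background pixels cross the validation threshold of 60, but only as
isolated specks whose distance values stay below the nucleation and LMP
thresholds — which is why those defaults coexist.

**Unprinted defaults**, chosen once as realistic for SHG collagen:
segment length 4 px (15 segments across a 60 px fiber) and width change
0.2 px per segment. The width walk is a reflected random walk with a
0.5 px floor; at 0.2 px per step it wanders roughly ±0.8 px (±15%) over a
60 px fiber, the mild tapering seen in real fibers. (A 0.5 px step was
considered and rejected: it produces ±30% width excursions on a 5 px
fiber, which neither looks like collagen nor leaves a usable medial
ridge.) The generator does not model fiber–fiber interactions: crossings
are independent overlaps, and densely crossing mats are exactly where the
tracer's joint-resolution errors concentrate — passing tests on generator
images bound algorithmic error, not biological segmentation difficulty.

## Boundary-relative angles and ROIs

A binary boundary mask is traced into ordered outlines (Moore neighbor
tracing, components largest-first). Each object associates with its
nearest outline point (ties toward the smaller outline index); the local
tangent is the principal axis of the outline points within ±5 indices
(window exposed — the principal axis is robust to staircase pixelation
where a two-point difference is not); and the relative angle is the axial
difference between object and tangent, folded into [0°, 90°]. Objects
farther than `max_distance` (default 150 px, the packaged boundary
analysis setting) are `excluded-too-far`; objects whose center pixel is
foreground in the mask are `excluded-inside`. The heatmap flags tiles
containing at least one measured object above the 60° cutoff — the
perpendicular-fiber signature used to screen for invasion-permissive
regions.

ROIs are rectangles (0-based, half-open — the convention is stated so
files interchange bit-exactly; a shim imports 1-based CSVs), polygons
(point-in-polygon containment), or masks. Intensity statistics partition
the image exactly into outline (ROI pixels with a 4-neighbor outside),
inside, and outside.

## Numerical choices and degenerate inputs

* Thresholding keeps `ceil(keep_fraction × N)` coefficients so a positive
  fraction never returns zero curvelets; exact-zero coefficients are
  never returned, so a blank image yields an empty table and a flagged
  summary.
* All tie-breaks (coefficient ties, LMP plateaus, linking candidates,
  component ordering) are lexicographic on (row, col) or index, making
  every stage reproducible across platforms.
* Distance-transform plateaus are ordered by seeded jitter with relative
  magnitude < 1e-6.
* The von Mises concentration is inverted with exponentially scaled
  Bessel ratios, stable to κ ≈ 10⁴; the direction-calibration root is
  bracketed on a fine grid before refinement because the sample resultant
  oscillates in the scale factor for small n.
* An all-background image is a valid input everywhere: empty distance
  map, empty fiber table, flagged statistics.

## Problem sizes used by the packaged checks

The test suite and the reproduction script run the full validation at 20
images of 512×512 with 30 fibers (the generator's preset conditions),
which gives the t-tests comfortable power while keeping a complete run in
a few minutes of a single CPU; frame properties are checked at 64–256 px
where they are size-independent identities. On these runs, fiber-mode
orientation and alignment center on the generator targets (90°, 0.2),
while curvelet-mode alignment sits near 0.27 — biased *upward*, because
~20 curvelet groups per image inflate the sample resultant exactly as the
small-n analysis above predicts. That direction is asserted by the
acceptance test. Curvelet-mode orientation is unbiased; its per-image
spread is wider than fiber mode's (wedge quantization plus noise-edge
curvelets), which is the expected trade for not segmenting fibers at all.

## Known limitations

* Fiber widths are measured from one medial radius; on noisy images the
  estimate is biased high, and joints/ends bias total length low.
* Intensity dropouts split fibers; no gap bridging.
* The curvelet pyramid is undecimated, so memory per image is a few times
  the image size times the wedge count at the analyzed scale.
* Boundary masks are inputs: registration/segmentation of bright-field
  images to produce them is out of scope.
* Alignment calibration is exact at the population level per image;
  extraction noise, not the generator, sets the residual spread of
  measured alignment.
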