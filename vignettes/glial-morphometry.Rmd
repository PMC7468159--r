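---
title: "Quantifying glial morphology with gliamorph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial morphology with gliamorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

# The measurement problem

Microglia and astrocytes change shape when they change state: reactive
microglia retract and thicken their processes and elongate their somata,
while astrocytes can either hypertrophy or, as reported in some autism
models, retract processes in specific hippocampal subfields. Quantifying
such changes from immunofluorescence (IBA-1 for microglia, GFAP for
astrocytes) requires turning a 2-D confocal field into a handful of
per-cell numbers: cell density, number of primary branches, number of
branch points, total branch length, cell radius, cell area, soma area and
soma eccentricity. `gliamorph` implements that measurement chain as a
reproducible, scriptable pipeline, together with a synthetic-image
generator whose ground truth is known in closed form, so that every stage
of the chain can be validated quantitatively rather than by eye.

# The pipeline

## Segmentation by intensity quantiles

Somata are the brightest structures in a glial stain. Two thresholds are
taken as empirical quantiles of the whole field's intensity distribution
(linear-interpolation convention, `stats::quantile` type 7, documented
because quantile conventions differ between tools):

* the **soma threshold** (default fraction 0.995) isolates somata;
* the **background threshold** (default fraction 0.90) separates all
  labelled signal - somata plus processes - from background.

Pixels at or above the soma threshold are grouped into 8-connected
components; components smaller than `minSizePx` (default 150 px, within
the conventional 100-200 px window for a 20x acquisition at
0.415 µm/px, where a ~50 µm² soma covers ~290 px) are discarded.
Components touching the field border are flagged: they are counted for
density but excluded from morphology by default, since their shape is
truncated. Labels are assigned in raster-scan order so repeated runs are
bit-identical.

The quantile fractions are deliberately explicit configuration rather
than interactive adjustment. `sweepSomaQuantiles()` reports the detection
count across candidate fractions; a plateau in that curve is the operating
point an experimenter would otherwise find by hand. Two caveats discovered
during validation are worth stating. First, on noisy data the background
threshold should sit at least 3-4 noise standard deviations above the
background level: lower settings sprinkle single-pixel specks through the
mask which, when they touch a process, add spurious short side-branches.
Second, the detection count is only guaranteed monotone in the soma
quantile once the threshold has cleared the process intensity band - below
that, raising the threshold can split merged components and the count can
transiently rise.

## Soma shape

Soma area is the pixel count times the squared pixel size. Eccentricity
comes from the second-central-moment ellipse of the pixel coordinates:
with eigenvalues $\lambda_1 \ge \lambda_2$ of the coordinate covariance,

$$e = \sqrt{1 - \lambda_2 / \lambda_1},$$

which is 0 for a disc and approaches 1 for a line-like region, matching
the convention of common region-properties implementations. A one-pixel
region has no defined ellipse; it is reported as 0 and flagged.

## Process tracing

The foreground mask is regularized (a one-pixel-radius morphological
closing smooths noise-ragged boundaries, then enclosed holes are filled so
the skeleton cannot loop around single-pixel dropouts) and thinned to a
unit-width skeleton with the Guo-Hall two-subiteration algorithm. Guo-Hall
was chosen over Zhang-Suen after direct comparison: Zhang-Suen leaves
two-pixel staircase residue on oblique strokes, which fabricates
degree-3 pixels and corrupts branch-point counts.

Every foreground pixel is assigned to the soma it reaches *through the
mask* by geodesic propagation (`EBImage::propagate` with uniform cost), so
a skeleton strand connecting two somata is split at the geodesic midline
and both cells are flagged ambiguous rather than silently attributed.
Skeleton pixels inside the soma region - dilated by a small margin
(`somaMarginUm`, default 0.5 µm) so that the radial spokes thinning drives
across the soma boundary are not mistaken for junctions - are excluded
from all process measurements.

The per-cell skeleton becomes a graph: vertices are skeleton pixels, edges
connect 8-neighbours with weights of one pixel size (orthogonal) or
$\sqrt{2}$ pixel sizes (diagonal), and diagonal edges that merely shortcut
an orthogonal two-step are dropped so staircases are not double-connected.
Terminal spurs shorter than `pruneLenUm` (default 2 µm) are removed
iteratively, as are whole components shorter than the pruning length
(these are almost always noise specks touching the soma margin). Then:

* **primary branches** = clusters of mutually adjacent anchor pixels
  (skeleton pixels touching the soma margin);
* **branch points** = clusters of degree-$\ge$3 vertices, with junction
  pixels within 1.5 µm geodesic distance merged into one (a single
  anatomical bifurcation at a shallow angle thins into two junction
  pixels a couple of pixels apart; the merge radius must stay well below
  the shortest real inter-junction distance, which the generator keeps at
  5 µm or more);
* **total branch length** = sum of edge weights;
* **cell radius** = maximum Euclidean distance from the soma centroid to
  any skeleton pixel (a mask-based hull-like alternative is available via
  `cellRadiusFrom = "mask"`); a process-free cell falls back to the soma
  region's own radius and is flagged;
* **cell area** = pixel area of all foreground assigned to the cell. The
  mask reading (rather than a convex hull) is used because published
  astrocyte cell areas of ~170-310 µm² at 35 µm radii are far below any
  hull area, so the original measure must have been mask-based.

Cell density is the retained-cell count over the field area in mm².

## Statistics

Group comparisons mirror the normality-gated convention of glial
morphometry tables, with the animal as the sampling unit (per-animal
means, typically n = 5-6 per genotype):

1. each group is tested for normality with the Kolmogorov-Smirnov test
   using the Dallal-Wilkinson p-value approximation for estimated
   parameters (the "Lilliefors correction"); the approximation is accurate
   for p <= 0.1 and switches to the Stephens modified-statistic form
   above that, with results clipped to [0, 1];
2. if both groups pass (p > 0.05), a two-tailed pooled-variance Student
   t-test is used (Welch is available but never the default, matching the
   stated "Student's t-test" convention);
3. otherwise a two-tailed Mann-Whitney U test: exact by full enumeration
   of all $\binom{n_x+n_y}{n_x}$ group assignments when
   $n_x + n_y \le 12$ (ties handled naturally; the two-tailed p doubles
   the smaller tail, capped at 1), and the tie-corrected,
   continuity-corrected normal approximation above that. The branch used
   is recorded in the result.

`summaryTTest()` recomputes t from printed mean ± SEM rows
($t = (m_1 - m_2)/\sqrt{SEM_1^2 + SEM_2^2}$, $df = n_1 + n_2 - 2$). For
equal group sizes this is algebraically identical to the pooled t on raw
data; for unequal sizes it is the usual approximation. Because published
SEMs are rounded to 1-2 digits, recomputed p-values can differ from
printed ones in the second decimal (e.g. a printed 0.018 recomputes to
~0.022); the package treats these as cross-checks, never as equalities.

Groups smaller than four cannot be normality-tested; they fall back to the
t-test with a warning. Zero-variance samples are declared non-normal and
flagged. No multiple-testing correction is applied across the ~8
parameters × 2 regions - matching the reporting convention of this kind of
table - and every report carries a footnote stating the implied
family-wise error.

## Densitometry

Western-blot band intensities are divided by the same lane's β-actin
(loading-control) intensity; within each blot group (blot × target ×
region) every ratio is expressed as a percentage of the wild-type mean
ratio, so the wild-type group mean is 100 exactly by construction - an
identity the tests assert to machine precision on arbitrary admissible
tables. Genotypes are compared on the percentages with the pooled t-test.

# The synthetic generator

Because no raw micrographs are distributed with studies of this kind, the
package ships a generator (`renderField`, `makeGroupDataset`) that
emulates a 20x confocal field: a 424.26 µm square (area 0.1800 mm²) at
0.415 µm/px (1022 px side). The square-field reading deserves a note: the
imaged area is sometimes quoted as "424 µm²", but at the reported cell
densities (~20-95 cells/mm²) a literal 424 µm² field would contain ~0.004
cells; a 424 µm × 424 µm square reproduces the reported per-field counts
(4 cells → 22.2 cells/mm², the microglial scale), so the square reading is
used throughout.

Each cell is an ellipse soma (semi-axes $a \ge b$; area $\pi ab$;
eccentricity $\sqrt{1-(b/a)^2}$) plus recursive bifurcating polyline trees
of straight segments growing outward from the soma boundary, rasterized at
constant stroke width (default 1.2 µm), blurred by an isotropic Gaussian
PSF and overlaid with additive Gaussian noise clipped at zero. Ground
truth - primary-branch count, bifurcation count, summed segment length,
maximal vertex distance, $\pi ab$, $\sqrt{1-(b/a)^2}$ - is derived from
the specification in closed form, never from the raster, so it is
invariant to noise, blur and seed by construction (and tested to be).

Preset regimes follow the published hippocampal values: microglia with
~48 µm² somata, eccentricity ~0.79, 4 primary branches, ~5 branch points,
~150 µm total branch length, ~4 cells per field; astrocytes with 5-6
primaries, ~6 branch points, ~170-200 µm, ~12 cells per field. A mutant
group is derived from the wild-type regime by multiplicative factors (for
example total-branch-length factor 96.8/167 ≈ 0.58 for the astrocyte
retraction regime, density factor 38.7/22.6 ≈ 1.71 for the microglial
density regime). The animal is the sampling unit: each animal carries a
lognormal random effect (default CV 0.12, chosen so that group-level SEMs
are in the ~5-10 % of mean range typical of the published tables) shared
by its fields; per-field counts are Poisson around the regime density;
individual cells jitter lognormally (CV 0.10).

The generator deliberately enforces geometric separations - primary
directions near-evenly spaced with bounded jitter, child branches
diverging by 0.30-0.50 rad, segment lengths of at least 5 µm, cells placed
on a jittered grid so footprints cannot intersect - because exact
branch-point recovery is only a well-posed target when distinct junctions
are resolvable at the pixel size. What the generator does **not** emulate:
crossing or touching processes of neighbouring cells (real astrocyte
territories tile far more tightly), intensity inhomogeneity along
processes, uneven illumination, out-of-focus light from other z-planes,
anisotropic PSFs, or multi-channel context stains. Passing the recovery
tests therefore demonstrates that the measurement chain is correct and
unbiased on resolvable, well-separated cells - not that it would segment
heavily overlapping tissue, where threshold choice and the
geodesic-splitting heuristic dominate real-world accuracy.

# Numerical choices and edge cases

* **Quantile convention** type 7 (linear interpolation), documented above.
* **Connectivity** 8-connected components and skeleton adjacency.
* **Degenerate thresholds** (constant image): flagged; soma detection
  returns no objects rather than an all-true mask.
* **Skeleton length bias**: an 8-connected digital path overestimates the
  length of oblique straight lines by up to ~8 % (at ~20-30° from an
  axis) with the $1/\sqrt 2$ step weighting; averaged over the random
  branch angles of whole cells the measured totals land within a few
  percent of truth (the acceptance checks bound the per-cell error at
  10 %). No angle-dependent calibration factor is applied, keeping the
  step weights exactly $1$ and $\sqrt 2$ pixel sizes.
* **Rotation behaviour**: lengths and counts are stable under 90°
  rotations only up to thinning asymmetry (the Guo-Hall subiterations
  have a directional preference); empirically the length varies by
  ~0.5 %, and the tests assert 1 % rather than exact equality. Arbitrary
  analytic rotations of the generating spec reproduce lengths within
  0.5 % as well.
* **Noise robustness limit**: at process SNR ~5 and a background
  threshold 3.5 SD above background, the probability that noise cuts a
  process stroke across its full width (losing the distal sub-tree)
  is of order 1 % per field; the optional `denoiseSigmaPx` pre-smoothing
  removes this failure mode at the cost of requiring threshold fractions
  appropriate to the smoothed histogram.
* **16-bit TIFF I/O**: intensities are stored as value/65535, so integer
  intensities up to 65535 round-trip exactly and reruns are
  byte-identical (checksummed in the manifest).
* **CSV precision**: pipeline tables are written with 17 significant
  digits and a leading comment line carrying the configuration hash, so
  write-read round-trips preserve doubles exactly and every output is
  traceable to its configuration.

# Problem sizes used by the test-suite

The packaged tests validate the full chain on one 1022² px field of 10
cells per noise condition, exhaustive Mann-Whitney enumeration up to 6 per
group, 2000 Gaussian replicates for the normality-gate calibration, 1000
null replicates for the gated comparison's false-positive rate, and 200
replicate synthetic blots for the densitometry recovery; these sizes give
the Monte-Carlo assertions standard errors several times smaller than
their tolerance bands while keeping the default suite quick to run.

# Known limitations

* 2-D only; no z-stacks, no Sholl analysis, no fractal dimension - only
  the eight published parameters.
* The geodesic split of shared skeleton components is a heuristic; in
  dense tissue a watershed- or learning-based instance segmentation would
  be needed.
* `cellAreaUm2` ground truth in the generator (soma area + length ×
  width) slightly overstates the rasterized union at junction overlaps;
  it is exact enough for regime-level checks but is not used in the
  strict recovery assertions.
* The Dallal-Wilkinson approximation is an approximation; for n < 4 the
  normality gate cannot run at all and the pipeline falls back to the
  t-test with a warning, a convention the user should be aware of when
  groups are tiny.
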