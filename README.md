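# gliamorph

Quantitative morphometry of microglia and astrocytes in 2-D fluorescence
micrographs, for neuroscientists who need the standard eight per-cell
parameters — cell density, number of primary branches, number of branch
points, total branch length, cell radius, cell area, soma area and soma
eccentricity — from IBA-1 / GFAP-stained confocal fields, plus the
matching statistical layer (normality-gated two-group tests) and
Western-blot densitometry normalization.

## What it computes

**Segmentation.** Somata are detected as 8-connected components of pixels
above an empirical intensity quantile of the field (type-7 convention),
filtered at a minimum size (default 150 px, i.e. the conventional
100–200 px window at 0.415 µm/px where a ~50 µm² soma spans ~290 px). A
lower background quantile yields the soma-plus-process foreground mask.
Soma eccentricity comes from the second-central-moment ellipse: with
covariance eigenvalues λ₁ ≥ λ₂,

    e = sqrt(1 − λ₂/λ₁)        (0 = disc, → 1 = line-like)

**Tracing.** The foreground mask is thinned to a unit-width skeleton
(Guo–Hall), each pixel is assigned to the soma it reaches through the mask
(geodesic propagation; strands touching two somata are split at the
geodesic midline and flagged), terminal spurs shorter than 2 µm are
pruned, and the per-cell skeleton graph gives: primary branches (skeleton
strands crossing the soma boundary), branch points (degree-≥3 vertices,
nearby junction pixels merged), total branch length (orthogonal steps ×
pixel size, diagonal steps × √2 pixel size), and cell radius (maximal
centroid-to-skeleton distance). Cell density is cells per mm² of field.

**Statistics.** Each per-animal sample is gated through the
Kolmogorov–Smirnov normality test with the Dallal–Wilkinson (Lilliefors)
p-approximation; both groups normal → two-tailed pooled Student t,
otherwise two-tailed Mann–Whitney U (exact by full enumeration for
n₁ + n₂ ≤ 12). `summaryTTest()` cross-checks printed mean ± SEM rows via
t = (m₁ − m₂)/√(SEM₁² + SEM₂²). Densitometry lanes are normalized to the
per-blot β-actin ratio and expressed as percent of the wild-type blot
mean (wild-type mean = 100 exactly).

**Synthetic truth.** Because studies of this kind rarely deposit raw
images, the package generates 20× confocal-like fields (424 µm square =
0.18 mm², 0.415 µm/px) of branched glial cells — ellipse somata with
recursive bifurcating process trees — whose ground truth (soma area πab,
eccentricity √(1−(b/a)²), segment-sum branch length, bifurcation counts,
vertex-max radius) is known in closed form, so the whole measurement
chain is validated against analytic truth at the published microglial and
astrocytic regimes.

## Worked example

Simulate a small field of four astrocyte-regime cells with moderate noise
(process SNR 5.5), measure it, and compare with the planted truth:

```r
library(gliamorph)
set.seed(1)
reg   <- morphRegime("astrocyte", noiseSd = 200, psfSigmaUm = 0.3)
specs <- placeCells(4, reg, 212)                 # jittered-grid placement
fl    <- renderField(specs, fieldSideUm = 212, pixelSizeUm = 0.415, seed = 2)
px    <- fieldPixels(fl$image)
mf    <- measureField(fl$image,
                      somaQuantile       = 1 - mean(px >= 2750),
                      backgroundQuantile = 1 - mean(px >= 1100),
                      minSizePx = 150)
mf$cells
#>   label somaAreaUm2 somaEccentricity nPrimary nBranchPoints totalLengthUm cellRadiusUm
#> 1     1       43.06             0.82        5             5        168.90        27.56
#> 2     2       50.46             0.80        5             6        161.02        30.47
#> 3     3       43.92             0.83        5             5        161.63        26.77
#> 4     4       49.60             0.83        4             6        165.21        35.27
mf$summary
#>   nDetected nBorder nMorphology fieldAreaMm2 density
#> 1         4       0           4         0.04   88.95
```

All four somata are found (density 88.95 cells/mm² = 4 / 0.045 mm²), and
matching rows to the planted truth (`fl$cells`, by soma centroid) shows
the branch and junction counts recovered exactly, total branch length
within ~3 % (e.g. 168.90 µm measured vs 168.72 µm planted), soma
eccentricity within ~0.02 and cell radius within ~2 %.

The statistical layer reproduces published-table arithmetic from summary
rows; for a total-branch-length contrast of 167 ± 15 vs 96.8 ± 13 µm
(n = 5 animals per group):

```r
summaryTTest(167, 15, 5, 96.8, 13, 5)
#> 	Two-sample t-test from summary statistics
#>
#> data:  summaries
#> t = 3.5366, df = 8, p-value = 0.007658
```

A command-line front end wrapping the same functions lives at
`inst/cli/gliamorph.R` (`simulate`, `measure`, `compare`, `densitometry`
subcommands; YAML config in, TIFF/CSV/JSON out, checksummed manifests).

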