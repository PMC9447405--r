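---
title: "Models and methods behind fluorspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorspot)
```

# The measurement problem

A fluorescence microarray scan is a raster image containing a lattice
of printed spots; each spot's fluorescence, relative to its local
background, is the assay readout. Real scans complicate this in three
ways that drive every design choice in this package: the background is
spatially non-uniform (illumination and washing gradients), the
faintest spots of a dilution series sit only a few grey levels above
that background, and printed spots are not perfect discs. The pipeline
therefore never uses a single image-wide segmentation: it partitions
the image into a user-declared grid of cells, one spot per cell, and
solves a small two-class problem inside each cell.

# Pipeline model

**Greyscale reduction.** Colour scans are reduced to luminance with the
classic weights $g = 0.3R + 0.59G + 0.11B$, computed in floating point
and rounded half-up. These weights form a convex combination, so the
grey value always lies between the channel minimum and maximum; the
operation is idempotent on grey input. 16-bit input is processed
natively; `rescaleTo8bit()` is an explicit opt-in min–max reduction for
workflows standardized on 8-bit analysis.

**Gridding.** The usable region (image minus optional margins) is
partitioned into `nRows × nCols` cells: base height
$\lfloor H/n \rfloor$, with the remainder pixels assigned one each to
the trailing rows (and likewise for columns). This integer rule was
chosen over fractional boundaries because it is exactly conservative —
the cells tile the region with no gap or overlap, which the tests
assert pixel-by-pixel — and deterministic across platforms. No
automatic grid registration or rotation correction is attempted: the
grid declaration is the user's job, and mis-declared grids fail loudly.

**Thresholding.** Inside each cell the pixels are summarized by a
256-bin histogram (16-bit data is binned into 256 equal-width bins, a
deliberate mirroring of the 8-bit analysis domain) and split by Otsu's
criterion: the threshold $t^*$ maximizes the between-class variance
$\sigma_B^2(t) = \omega_0\omega_1(\mu_0-\mu_1)^2$. Three conventions
are fixed once and used everywhere: pixels strictly above the threshold
are foreground; ties in $\sigma_B^2$ are resolved toward the smallest
threshold; a single-occupied-bin histogram is *degenerate* and yields
`NA` rather than an arbitrary split. Five classic comparators (mean,
isodata, triangle, li, yen — spanning the clustering, statistical and
entropy families) share the same interface and conventions so that
method comparisons differ only in the criterion. The suite exists to
demonstrate *why* Otsu is the production method, not to reproduce any
external tool bit-for-bit.

**Local vs global.** `binarizeGlobal()` computes one threshold from the
whole-image histogram. On a background gradient whose span exceeds the
faintest spot amplitudes, that threshold necessarily sits above those
spots in the darker regions — the canonical failure mode, which
`countDetections()` makes quantitative (the tests construct exactly
this regime and count the losses). `binarizeLocal()` computes one
threshold per cell and is the default throughout.

**Detection limit.** A histogram criterion will happily split *pure
noise* into two "classes" roughly $1.6\sigma$ apart, so thresholding
alone cannot declare a cell empty. Two guards do: a minimum foreground
area (`minArea`, default 4 pixels) against isolated speckle, and a
local contrast limit — the foreground–background mean difference must
exceed `minContrast` (default 3) standard deviations of the cell's
background pixels. The $3\sigma$ rule is the conventional analytical
detection limit; because both sides of the inequality scale with the
noise level, noise-only cells are rejected at any noise amplitude,
while a spot is accepted once its amplitude exceeds roughly three times
the local background sd.

**Quantification.** Per cell: the background estimate is the *median*
of background-labelled pixels (robust to the spot's share of the cell
and to bright outliers; mean available via `bgStat`), and
`net_intensity = max(0, mean(foreground) − background)`. The
integrated alternative `fg_sum = max(0, Σ foreground − bg·area)` is
reported alongside, since some laboratories calibrate on integrated
rather than mean intensity; the default is documented, not claimed to
match any particular interactive tool. Median-subtracted means make net
intensity invariant under constant illumination offsets, which the
tests assert to within one grey level. QC flags: `empty` (no accepted
foreground — equivalently `fg_area = 0` and `net_intensity = 0`),
`saturated` (≥ 1% of foreground at the bit-depth maximum),
`edge_clipped` (foreground touching the cell border).

# Validation statistics

Pipeline output is validated against a reference by rank correlation,
since the relationship between two instruments' intensity scales is
monotone but not necessarily linear. On tie-free data
$r = 1 - 6\sum d_i^2 / (N(N^2-1))$ with $d_i$ the per-pair rank
difference; with ties (replicate spots share true amplitudes; empty
spots share zeros) average ranks are assigned and $r$ is the Pearson
correlation of the rank vectors — the two definitions coincide exactly
when ties are absent, which the tests check to $10^{-12}$. Significance
uses the two-sided t-approximation
$t = r\sqrt{(N-2)/(1-r^2)}$ on $N-2$ df; its type-I error is
empirically calibrated (10,000 null replicates at $N = 20$ fall within
$5\% \pm 1\%$). An exact small-sample p-value is available via
`pMethod = "exact"`. $|r| = 1$ returns $p = 0$ by convention. The
linear calibration reports OLS slope, intercept and
$R^2 = 1 - SS_{res}/SS_{tot}$. Group comparisons default to the
Mann–Whitney test (exact for small tie-free samples) with Welch's
t-test as an option; the choice of test is this package's own, made
because intensity distributions near the detection limit are
asymmetric.

# The synthetic generator

`renderArray()` exists so that every stage — and every end-to-end
claim — runs against known ground truth. It emulates a scanner image
as: background field (uniform, linear gradient, or quadratic bowl) +
one spot per cell (disc, ellipse, or irregular star-convex blob whose
outline is a low-order Fourier perturbation of a circle) with a
Gaussian-blurred edge profile + i.i.d. Gaussian pixel noise, rounded
and clipped to bit depth. All randomness flows from a single seed;
rendering is bit-identical for a fixed spec.

Key defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `cellSize` | 40 px | a typical spot-pitch at scanner resolution; not derived from any real scan |
| `spotRadiusRange` | 8–12 px | spot fills ~¼–½ of the cell width |
| `psfSigma` | 0.8 px | sub-pixel edge spread of a focused scanner; see below |
| `noiseSigma` | 2 (gradient array: 3) | faintest spots stay ≥ 3σ above background |
| background gradient | 40 grey levels | exceeds the faintest amplitudes, forcing the global-threshold failure |
| amplitude map | $a = 0.9\,(2^b{-}1)\,c/(c+K)$ | see below |

**Edge blur.** The mean-over-mask measurement carries a deterministic
negative bias from a spot's blurred skirt: the mask admits partially
lit edge pixels that dilute the foreground mean. The bias grows with
`psfSigma` (about 7% of amplitude at 0.8 px for blob spots, 12% at
1.5 px). The default of 0.8 px keeps simulated measurements within the
10% accuracy the quantification contract targets while still exercising
soft edges; `psfSigma = 0` renders hard-edged spots, the limit in which
noise-free disc recovery is exact to rounding (the self-consistency
test uses exactly this limit, because under *any* nonzero blur exact
recovery is impossible by construction for a mean-over-mask statistic).

**Amplitude–concentration link.** A strictly proportional map with a
hard saturation cap cannot serve the 31-condition dilution layout: any
gain that keeps the faintest condition (0.78 µg/mL) detectable drives
the top concentrations of the strongest series into the cap, creating
ties that break the generator's strict-monotonicity contract. The
saturating binding-curve map $a = 0.9\,(2^b-1)\,c/(c+K)$ with
$K = 25$ µg/mL (panel preset: $K = 100$ ng/mL) is strictly monotone,
bounded by the same 90% ceiling, and is the physically natural model
for fluorescence immunoassay response.

**Built-in study conditions.** `gradientArraySpec()` (7 × 10 spots,
amplitudes evenly spanning 15–220 grey levels scattered over the grid,
gradient 40, noise 3) is the local-vs-global showcase: nine spot
amplitudes lie below the gradient span. `cd14PanelSpec()` (ten
conditions × five replicates: a six-step standard series plus two high
"LN-like" and two low "HC-like" serum levels, uniform background,
noise 2) exercises replicate structure and two-group contrasts.
`defaultAntigenLayout()` enumerates the 31 antigen/dilution conditions
(six analytes × five 2-fold dilutions + PBS negative control) on a
4 × 8 grid.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real scans: optical vignetting, scanner line
noise and its spatial correlation, print-needle comet tails and
doughnut spots, grid rotation or keystone distortion, and inter-field
(subarray) effects. Results on real images also depend on the user
declaring the grid correctly, which synthetic layouts guarantee by
construction.

# Numerical choices and degenerate inputs

* Rounding is half-up (`floor(x + 0.5)`) everywhere an intensity is
  re-quantized; R's banker's rounding would make results depend on
  parity.
* Thresholds are reported on the source intensity scale; for 16-bit
  histograms that is the upper edge of the chosen 256-wide bin, so the
  foreground rule `value > threshold` is exact in both depths.
* Constant images/cells are degenerate: global mode warns and returns
  all-background; local mode flags the cell `empty`. An all-foreground
  mask falls back to the minimum cell intensity as background, with a
  warning.
* A 1 × 1 grid makes local mode pixel-identical to global mode, which
  ties the two code paths together in the tests.
* Problem sizes used by the test and acceptance experiments (70-spot
  and 50-spot arrays, 200-histogram oracle sweeps, 10,000-replicate
  null calibration) were chosen as the smallest sizes at which the
  studied effects are unambiguous.

# Known limitations

Background is estimated per cell, so background structure *within* a
cell (sharper than the grid pitch) biases the median. The skirt bias
described above means absolute net intensities run a few percent below
true amplitudes under soft focus — rank-based validation is unaffected,
which is precisely why Spearman correlation is the primary validation
statistic. No inter-spot normalization, morphological cleanup, or
spot-shape metrics are attempted; they are downstream of this package's
contract.
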