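---
title: "Morphometry of developing pulp fibroblasts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of developing pulp fibroblasts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During tooth development the mesenchymal core of the tooth germ (the dental
papilla, later the dental pulp) is populated by fibroblasts whose shape
evolves from star-like in the cap stage to almost fusiform in the late bell
stage. The change is obvious to a trained histologist but hard to express
numerically. `pulpmorph` implements a complete quantitative workflow for
this question: segment fibroblasts in stained micrographs, measure each
cell's area $A$ (µm²), perimeter $P$ (µm) and form factor

$$FF = \frac{4\pi A}{P^2},$$

summarise cases (tooth germs) and groups (developmental stages), and
quantify *similarity within a stage* and *distance between stages* with a
mean-value-scaled relative-distance (RD) statistic. Because the original
histological material is not distributable, the package ships a synthetic
study generator that renders segmentable images of star-like and fusiform
cells with exact polygonal ground truth, so the whole pipeline is testable
end to end.

The study design mirrored throughout is: 3 groups (I = cap, II = early
bell, III = late bell) × 5 cases per group × 5 RGB images per case;
measured records accumulate per case, then exactly 100 records per case are
sampled at random, giving 500-cell group vectors.

## The relative-distance statistic

For a set $E = \{e_1,\dots,e_n\}$ of positive values with mean $M(E)$,
define the transformation $\bar e_i = (e_i - M(E))/M(E)$ and

$$RD_E(e_i) = |\bar e_i| = \frac{|e_i - M(E)|}{M(E)}, \qquad
  RD(e_i, e_j) = |\bar e_i - \bar e_j| = \frac{|e_i - e_j|}{M(E)}.$$

Scaling by $M(E)$ makes both quantities invariant under a uniform rescaling
of the inputs, so the statistic compares *relative* morphology regardless
of absolute cell size. This invariance, the zero-sum property of the
$\bar e_i$, symmetry, and the triangle inequality are all property-tested.

*Intragroup* use: $E$ holds the five case means of one group for one
parameter; a case is deemed similar to its group when $RD_E < 10\%$
(strictly; the threshold is configurable, and 10% is intended as a
realistic bound for when a human observer would accept two cell
populations as similar). *Intergroup* use: $E$ holds the three group means;
$RD(\mathrm{gI},\mathrm{gII})$ and $RD(\mathrm{gII},\mathrm{gIII})$ measure
stage separation, and their ratio says how many times closer early bell is
to late bell than to cap. The ratio is only informative for $FF$: the
size parameters $A$ and $P$ grow at every stage transition and their RDs do
not separate the two pairs strongly, which the test suite checks on
synthetic studies.

A complementary procedure compares the per-group regression lines of $P$ on
$A$ at a fixed area (default $A = 30$ µm², a region dense with measurements
in every stage): the proximity ratio
$|P_{II}(30)-P_I(30)| / |P_{III}(30)-P_{II}(30)|$.

## Segmentation and measurement

Images are RGB, 8-bit per channel. Segmentation is deliberately simple and
transparent, as in classical interactive morphometry systems:

1. optional per-channel linear percentile stretch (1st–99th percentile to
   0–255) — off by default in synthetic mode, where the colour model is
   fixed and the default thresholds are calibrated to the unstretched
   colours; intended for real micrographs;
2. per-channel inclusive thresholds (`threshold_spec`): a pixel is
   foreground when all three channels lie within bounds;
3. scrap removal: 8-connected components below `min_area_px` (default 20
   px) are deleted as debris;
4. connected-component labelling (8-connected foreground, 4-connected
   background), with labels ordered deterministically by each region's
   first pixel in a row-major scan so record order is reproducible.

Area is pure pixel counting times the squared calibration; there is no
sub-pixel boundary correction, matching field-feature semantics of region
measurements. The perimeter estimator deserves more words, because naive
digital perimeters are substantially biased.

### Perimeter estimation

The default estimator (`perimeter_simplified`) traces the region's crack
boundary — the closed polygon of inter-pixel edges, so a $10\times10$ px
square has perimeter exactly 40 px and a single pixel 4 px — and then
simplifies that polygon with the Ramer–Douglas–Peucker algorithm at a
tolerance of 1.3 px before summing edge lengths. Simplification removes the
quantisation staircase: chords replace stair runs, recovering the length of
the underlying smooth contour. The tolerance was fixed once by calibrating
against analytic shapes: below ~0.71 px, diagonal staircases cannot
collapse and discs read ~20% long; at 1.0–1.3 px, discs of radius ≥ 40 px
measure within ~1% and rendered star/fusiform populations within ~0.5%,
with axis-aligned rectangles still exact. A weighted 8-neighbour chain code
(isothetic steps 1, diagonal steps √2) was considered and rejected: its
known bias on smooth contours is about +5% and cannot reach the accuracy
targeted here; the raw crack length (`perimeter_crack`, bias up to $4/\pi$)
is retained as an explicit, documented alternative, and the estimator is a
single swappable function argument throughout. Values $FF > 1$, possible
for tiny regions under digital measurement error, are flagged rather than
clipped.

Boundary tracing keeps the foreground on its right and resolves saddle
corners with a left-turn preference, which keeps diagonally-touching pixels
on a single boundary (consistent with 8-connected foreground). Interior
holes are not traced; synthetic cells are solid by construction.

## Statistics

Per-case sampling (`sample_records`) is uniform without replacement and
unstratified across the case's images — whether the original workflow
stratified by image is unknowable, and uniform sampling is the simpler
assumption. Descriptive statistics use the $n-1$ sample standard
deviation. Histograms use 20 fixed-width classes starting at 0 (widths
3.5 µm² for $A$, 7 µm for $P$, 0.05 for $FF$; all three parameters are
positive, and the published ranges fit these 20 classes), half-open bins
with the last upper edge closed, and an out-of-range count so totals are
conserved. The Gaussian overlay is the normal density with the sample mean
and SD scaled to the count scale ($n\,\times$ class width).

Between-group inference uses classical one-way ANOVA plus two-sample
t-tests; Welch's unequal-variance form is the default because the
equal-variance assumption is typically slightly violated for these vectors.
Pairwise tests are reported uncorrected, matching the descriptive role they
play here; significance tiers are $p \le 0.05 / 0.01 / 0.001$. Both tests
delegate to the standard R implementations and are verified in the test
suite against the definitional formulas computed independently.

## The synthetic-data generator

The generator's job is to produce studies with the statistical structure
the analysis assumes, at the published group parameters, not to imitate
histology visually.

**Distributions.** Per cell, $(A, FF)$ is drawn from a bivariate normal —
Gaussian overlays fit the published histograms well, which motivates the
normal family — truncated to the group's observed ranges, with means and
SDs from the published group rows (defaults: $A$ means 17.733 / 25.187 /
32.788 µm², $FF$ means 0.289 / 0.134 / 0.104 for groups I / II / III).
Truncation at the observed extremes matters: an unbounded lower $FF$ tail
would generate perimeter outliers (via $P = \sqrt{4\pi A/FF}$) far outside
anything measured. Because truncation shifts means, the pre-truncation
centres are adjusted by quadrature-based moment matching so the truncated
means equal the targets exactly.

**Correlation.** $A$ and $FF$ are negatively correlated (default
$\rho = -0.75$): within a stage, larger cells are the more elongated ones.
This is what makes $P$ grow quasilinearly with $A$; with independent draws
the per-group Pearson correlation of $P$ on $A$ would be only ~0.6–0.75,
irreconcilable with the reported 0.88–0.91. $\rho = -0.75$ reproduces that
range (simulation gives $r \approx 0.87$ per group) and was fixed once on
that basis.

**Perimeter.** $P = \sqrt{4\pi A / FF}$, the relation implied by
$FF = 4\pi A/P^2$. (An occasionally-quoted inline form $P = 4\pi A/FF$
omits the square root and is dimensionally inconsistent; the square-root
form is used throughout.)

**Shapes.** Cap-stage cells are stars with radial profile
$r(\theta) = R(1 + a\cos k\theta)$, $k$ drawn from 5–7 (escalated when a
very low target $FF$ requires it) and $a$ solved numerically so the
contour's analytic form factor equals the drawn $FF$; $a \ge 1$ is rejected
(self-intersection risk), with 0.95 as the practical cap. Bell-stage cells
are ellipses whose aspect ratio is solved the same way, capped at 60 and
jointly constrained by a 1.3 px minimum half-width and the image extent for
rasterisation stability; the caps touch only the extreme low-$FF$ tail.
Contours are 128-vertex polygons (more for many-lobed stars), which keeps
the polygonal discretisation error of $FF$ below 0.5%; the polygon itself
is the ground truth, and its shoelace area and edge-length perimeter
satisfy $ff = 4\pi A/P^2$ to machine precision by construction.

**Rendering.** Cells are rasterised exactly (a pixel centre is tested
against the polygon's angular sector chords), painted with a foreground
colour distribution over a background distribution, with additive Gaussian
pixel noise (defaults: purple cells on a pink background, ~6σ from the
default threshold bounds, so noise-free separation is essentially exact).
Placement draws centre and orientation by rejection sampling, requiring the
1-px-dilated footprint to be disjoint from all previous cells so segmented
regions stay separate under 8-connectivity; cells are placed in decreasing
order of spatial extent, which keeps rejection reliable for the long
fusiform cells, and placement fails loudly after 200 retries rather than
degrade the scene. Overlapping-cell scenes, nuclei, extracellular-matrix
texture and realistic stain variation are explicitly out of scope, so
passing tests demonstrate pipeline correctness on idealised colour images,
not robustness to real histological variability.

**Scale.** The default study is 3 × 5 × 5 images of 448 × 448 px at
0.25 µm/px with 24 cells per image (120 records per case; the original
study accumulated 500–700 per case). These sizes were chosen so a complete
generate–segment–measure–analyse cycle stays fast enough to run several
times in a test suite while the sampled design (100 records per case, 500
per group) matches the published one. The calibration default of 0.25
µm/px keeps the smallest cap cells near 10 px equivalent radius; at coarser
calibrations digital measurement error starts to dominate small-cell form
factors. Everything — study layout, cell counts, noise, seeds — lives in
`study_config()`.

**Determinism.** One master seed drives generation and sampling through
derived child seeds; identical configuration and seed reproduce every
table and CSV byte-for-byte, and all seeded helpers restore the caller's
RNG state.

## Known limitations

- The published RD values 29.45% ($A$, gI–gII), 88.29% and 16.57% ($FF$)
  are not exactly recoverable from the rounded table means (recomputation
  gives ≈29.54%, 88.24%, 17.08%); the originals were evidently computed
  from unrounded means. The package reports what the inputs imply.
- One published intragroup maximum ("3.74% for case 1", group II
  perimeter) conflicts with its own table, where case 5 holds 3.7% and
  case 1 holds 0.2%; the implementation reports the true argmax.
- On synthetic studies the regression-line proximity ratio is an unstable
  statistic: the group II and III lines intersect near the default
  evaluation area, so the denominator $|P_{III}(30) - P_{II}(30)|$ is
  within sampling noise of zero and the ratio fluctuates over an order of
  magnitude across seeds. The concordance between the proximity ratio and
  the $FF$ RD ratio is therefore asserted only on the published regression
  equations, where both procedures agree within 3%; the $FF$ RD ratio
  itself is the stable quantity and is checked on synthetic studies as a
  seed-averaged value.
- The exact preprocessing and threshold values of the original
  interactive system are not recoverable; only the contract (a binary mask
  of fibroblast regions) is reproduced, and segmentation parameters are
  fully configurable.
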