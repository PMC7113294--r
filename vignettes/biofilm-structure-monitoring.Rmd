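---
title: "Quantifying biofilm structure from OCT C-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm structure from OCT C-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octbiofilm)
```

## The measurement problem

Optical coherence tomography (OCT) images biofilms non-invasively at
mesoscopic scale: a C-scan is a stack of depth profiles (A-scans) assembled
into a 3D intensity volume over a flow channel, with the biofilm growing on
the bottom surface (the substratum). Automated monitoring rigs scan many
flow cells repeatedly over days; what a biologist or process engineer
actually wants from each scan is a handful of structural numbers — how much
of the surface is covered, how thick the film is, how porous it is, how
rough the bulk–biofilm interface looks — and trustworthy statistics of
those numbers across replicate flow cells.

`octbiofilm` implements that computation chain: raster preprocessing of the
volumes, the structural parameters, the positioning-accuracy statistics
that establish whether repeated scans of the same spot are comparable at
all, Grubbs-based replicate summaries, and a synthetic phantom generator
with exactly known ground truth so the whole pipeline can be validated
without an instrument.

## Coordinate and unit conventions

Volumes are arrays indexed `(z, y, x)` with `z = 1` at the substratum and z
increasing toward the bulk; every thickness-like formula in the package is
defined from the substratum upward, which is why the TIFF reader reverses
page order by default (`flip_z = TRUE`) — OCT probes scan from above. All
internal lengths are µm; mm appear only at the user-facing boundary (crop
extents, fields of view).

The axial voxel height deserves care. Devices specify axial sampling in
air; inside a medium of refractive index $n$ the effective height is

$$\Delta z = \Delta z_{air} / n .$$

A `voxel_spec` stores `dz_air` and `n` and *derives* the effective value
(`dz_eff()`), so the correction cannot silently be applied twice. For a
water-like medium ($n = 1.33$) and the 2.793 µm in-air sampling used as the
generator default, the effective height is 2.1 µm. Whether a vendor's
quoted axial figure is optical resolution or digital voxel pitch is
ambiguous in practice, so the in-air spacing is always user-supplied
(config or JSON sidecar) and TIFF resolution tags are only checked against
it (a >1% disagreement warns and is otherwise ignored — vendor tags are
unreliable).

## Preprocessing

The raster chain deliberately mirrors the Fiji-style workflow that
established these parameters, down to its integer semantics:

* **Disc mean filter** (default radius 2 px): arithmetic mean over the
  raster disc (center distance ≤ radius, 13 pixels at r = 2), rounded
  half-up to the nearest integer, borders replicated. Volumes are filtered
  slice-wise in the xy-plane; the axial direction is never mixed in.
* **Binarization**: `value >= threshold` is foreground. A `dark_target`
  flag thresholds the complemented image instead, which is what the
  calibration-target workflow needs (a printed disc is darker than paper).
  The exported `binarize()` defaults to bright-foreground polarity: the
  volumetric biomass pipeline is the common path, and a generic
  thresholder that silently inverts is the kind of trap this package tries
  to remove. `detect_target()` switches the polarity itself.
* **Three-class labeling**: biofilm 150, voids 50, background 0. A zero
  voxel is a void when it lies strictly below the topmost biomass voxel of
  its own A-scan column ("under the roof"). This column rule is simple,
  deterministic, and exactly invertible (relabeling the extracted biomass
  mask reproduces the labels). A stricter 3D-enclosure alternative is
  available as `void_mode = "floodfill"`, which only counts cavities
  unreachable from the bulk through zero voxels by 6-connectivity; it is
  not the default because side-open channels under overhangs are
  legitimately "within the structure" in the column sense and the flood
  fill is considerably more expensive.
* **Maximum intensity projection** along z gives the plan view used for
  coverage and texture.

## Structural parameters

For a binarized volume with $N$ A-scan columns and effective voxel height
$\Delta z$:

* **Local thickness** of column $i$: $L_{F,i} = \left(\sum_z b_{i,z}\right)
  \Delta z / 255$ with $b \in \{0, 255\}$ — i.e. the biomass voxel count
  times $\Delta z$. Internal voids do not add thickness under this sum
  rule. The alternative reading (height of the topmost interface) is
  exposed as `thickness_mode = "interface"`; the sum rule is the default
  because the division by 255 only makes sense for summed binary values.
* **Mean biofilm thickness**: $\bar L_F = \frac{1}{N} \sum_i L_{F,i}$,
  biomass-free columns included as zero.
* **Substratum coverage**: share of MIP pixels with value ≥ 1,
  $SC = 100 \cdot A_{biofilm} / (A_{biofilm} + A_{background})$.
* **Intrinsic porosity**: $\Phi_{intrinsic} = 100 \cdot A_{voids} /
  (A_{biofilm} + A_{voids})$, background excluded — appending empty bulk
  above the film changes nothing. Undefined (NA, blank CSV cell) when the
  volume holds neither biomass nor voids.
* **Global porosity**: non-biomass share of all voxels beneath the
  bulk–biofilm interface, $100 \cdot (V_{below} - V_{biofilm}) /
  V_{below}$ with $V_{below}$ the per-column interface height summed over
  columns. Identical to 0 for solid films; NA when no biomass. Under the
  column void rule every sub-interface non-biomass voxel is labeled void,
  so global and intrinsic porosity coincide exactly there; the two
  measures separate under floodfill labeling, where side-open spaces
  count only toward the global figure.
* **Height map**: per column, (1-based topmost biomass index) ×
  $\Delta z$; 0 where empty. Mean thickness never exceeds mean height, and
  equals it exactly for void-free volumes — a useful internal consistency
  check, asserted in the tests.
* **Textural entropy**: Shannon entropy, natural logarithm, of the
  co-occurrence probability table of the grayscale MIP,
  $TE = -\sum_{a,b} p(a,b) \ln p(a,b)$ over nonzero entries, default
  offset (0, 1), optionally averaged over the four standard offsets. A
  homogeneous image gives exactly 0 nats. TE is computed on the *filtered
  grayscale* MIP, not the binary one: on a binarized image the table
  degenerates to at most four entries (TE ≤ ln 4 ≈ 1.39), while grayscale
  interfaces produce the 2–5 nat range typical of developing biofilms.
  Native 256 gray levels are used by default, with optional binning.

The biomass binarization threshold for OCT volumes defaults to ≥ 1 on the
filtered 8-bit data (every nonzero voxel is biomass, matching the coverage
definition). Real OCT data carries speckle and detector noise, so
`structure_report(threshold = ...)` accepts any 8-bit value; for the
synthetic recovery studies below, half the phantom's biomass intensity is
used (90 against 180) — the midpoint maximizes the margin against both
false biomass and erosion.

## Positioning accuracy

Structural time series are only meaningful when the scanner returns to the
same spot: the stage error must stay below the lateral optical resolution
(8 µm for the system class this targets). The evaluation protocol images a
printed red disc (1 mm diameter) with a fixed microscope (1600 × 1200 px,
6.7 × 5.0 mm field of view), repeatedly, and measures the scatter of the
detected disc center:

1. mean filter (r = 2) → 8-bit grayscale (Rec. 601 luminance) → binarize
   at threshold 120 with dark polarity;
2. 8-connectivity connected components; components outside 25%–400% of the
   nominal disc area are discarded (dust and print artifacts); the largest
   survivor is the target, with a warning if a second component comes
   within 10% of its size;
3. the unweighted centroid of the component, in 0-based pixel coordinates
   scaled by the pixel size, is the center of mass (CoM);
4. per-axis deviations from the series mean, $\Delta x_i = x_i - \bar x$,
   $\Delta y_i = y_i - \bar y$, summarize positioning error. They sum to
   zero by construction; their SD, quartiles and the 1.5·IQR outlier
   fences (quartiles by linear interpolation, `quantile` type 7) are
   reported, plus the fraction of movements within a tolerance.
   `accuracy_report()` declares a pass when at least 75% of movements are
   within tolerance on both axes.

## The synthetic phantom generator

The generator stands in for instrument and cultivation. Colonies are
hemi-ellipsoidal caps seeded on the substratum by a Poisson process and
grown at fixed lateral/vertical rates; merging colonies union their masks;
growth clips at the channel height. Internal voids are small random
ellipsoids carved strictly below each column's interface voxel, so carving
never changes the topography — which is what makes the ground truth exact:
coverage, thickness and void fraction are obtained by direct voxel counting
on the noise-free mask, never through the analysis pipeline. Additive
Gaussian noise (clipped to 0..255) is applied last.

Default parameters were chosen once to emulate the monitoring scenario the
package targets: 450 µm channel, 8 × 8 µm lateral / 2.1 µm effective axial
voxels over 7 × 5 mm, 1 colony/mm²/day, 100 µm/day lateral and 35 µm/day
vertical growth (near-full coverage and ≈ 200 µm mean thickness by day 6),
void fraction 0.15, noise sd 8, biomass intensity 180. What the phantom
does *not* emulate: OCT speckle statistics (noise is Gaussian, not
multiplicative), detachment/sloughing, optical shadowing under dense
biomass, and refraction artifacts. Passing recovery tests therefore
demonstrates that the *computation* is faithful on geometrically realistic
structures — not that segmentation of real OCT volumes is solved; on real
data the binarization threshold remains the user's scientific choice.

Target images are rendered at the native microscope geometry with an
anti-aliased disc at a known sub-pixel center. Dust specks are placed away
from the disc (at least one speck diameter clear of its rim) — attached
dust is indistinguishable from the target by construction, and the
artifact-exclusion contract (CoM shift < 0.5 px) is only well-defined for
separate particles.

## Replicate statistics

Per parameter and day, outliers among flow cells are identified by the
two-sided Grubbs test, $G = \max_i |x_i - \bar x| / s$, with the critical
value from the closed-form t-quantile expression

$$G_{crit} = \frac{n-1}{\sqrt n} \sqrt{\frac{t^2_{1-\alpha/(2n),\,n-2}}
{n - 2 + t^2_{1-\alpha/(2n),\,n-2}}}$$

applied iteratively until no outlier remains, capped at $\lceil n/4
\rceil$ removals so a small sample cannot be stripped to nothing.
Zero-variance samples contain no outlier by definition; days with fewer
than three values are summarized but flagged unreliable. Survivor means,
medians (even counts: mean of the central pair) and sample SDs (n − 1)
feed the heat-map tables; outliers are annotated `o`, missing cells stay
blank, and the CSV uses 17-significant-digit formatting so the value
matrix round-trips exactly.

The statistical point of running 24 flow cells instead of 2 is
operationalized as a property: the SD of a parameter's estimated mean
shrinks as $1/\sqrt n$, verified across n ∈ {2, 6, 24} in the tests.

## Numerical choices and edge cases

* Rounding is half-up (`floor(x + 0.5)`), matching 8-bit raster practice.
* Thresholding is `>=` everywhere.
* Undefined parameters (porosity of an empty channel) are NA markers, not
  errors; they serialize as blank CSV cells and propagate through
  summaries via NA-aware statistics.
* Crops use the floor rule `floor(extent/spacing)` per axis and refuse
  requests beyond the available extent, naming the offending axis.
* 16-bit TIFF input is min-max rescaled to 8-bit before anything else — all
  thresholds in this workflow are on the 8-bit scale.
* Connected components use 8-connectivity (union-find, two-pass, in C++);
  the mean filter is also compiled — a 1600 × 1200 frame filters in tens of
  milliseconds, which keeps hundred-image positioning series interactive.

## Problem sizes used in the validation suite

The test and acceptance studies run on deliberately reduced grids, chosen
as the package's own validation conditions: recovery studies on 1–1.2 mm
fields at 15 µm lateral / 10–15 µm axial pitch (volumes around
45 × 80 × 80 voxels), oracle-equivalence sweeps on random volumes up to
16³, and positioning series of 100 full-resolution (1600 × 1200) target
images. On the recovery grids the pipeline reproduces ground-truth
coverage within ±2 points, mean thickness within one voxel height, and
intrinsic porosity within ±5 points for constructed void fractions up to
0.4. On the very coarse CLI demo grid (day-1 colonies only ~5 voxels in
radius) the r = 2 disc filter erodes up to ~3 coverage points — a raster
effect worth remembering when analyzing low-magnification scans of young,
small colonies.

## Known limitations

* The column void rule counts side-open channels under overhangs as voids;
  the floodfill mode counts only sealed cavities. Real biofilm porosity
  lies somewhere between these definitions.
* Textural entropy depends on gray-level binning and offset; values are
  comparable only within a fixed configuration (the defaults are recorded
  in every report's parameter attribute).
* The global-porosity definition fixes one of several reasonable envelope
  conventions (everything beneath the topmost biomass voxel per column).
* No refraction/dispersion correction beyond the axial scaling, no
  speckle modeling, no acquisition control.
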