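---
title: "Measuring retinal entity volumes from OCT B-scan annotations: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal entity volumes from OCT B-scan annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octvol)
```

## The measurement model

An OCT raster acquisition is an ordered stack of parallel B-scans separated
by a fixed inter-scan distance $\Delta$ (mm). An observer traces the
perimeter of the entity of interest — the retina between two reference
lines, a foveal cavity, a schitic space — on every B-scan where it appears,
and each tracing is a closed planar polygon whose area $A_i$ (mm²) the
calliper reports. The volume estimate treats each B-scan as a slab of
thickness $\Delta$:

$$ \hat V = \sum_i A_i \, \Delta . $$

This is a Riemann sum of the true cross-sectional area function $A(y)$
along the raster axis; for a smooth body it converges to
$V = \int A(y)\,dy$ as $\Delta \to 0$. `entity_volume()` implements the sum
exactly as stated (the total is bit-identical to
`sum(per_scan$area) * scan_spacing`), with polygon areas from the shoelace
formula

$$ A = \tfrac12 \Big| \sum_i (x_i z_{i+1} - x_{i+1} z_i) \Big| , $$

which is orientation-independent and exact for simple polygons.

**Slab convention.** The formula does not say whether a scan's slab extends
forward, backward, or symmetrically. We centre the slab on the scan
(midpoint rule): for symmetric entities this minimises the discretisation
error, and the midpoint rule's error for our phantoms is $O(\Delta^{3/2})$
(limited by the square-root behaviour of $A(y)$ at the entity's lateral
extremes, not by interior smoothness). The raster's alignment relative to
the entity (`grid_phase`) is an explicit phantom parameter so this error
band can be measured rather than assumed; validation uses a phase of
$0.37\,\Delta$ to avoid the artificial superconvergence a perfectly
centre-aligned grid produces for symmetric shapes.

**Circle-restricted (foveal) variant.** Retinal volume in a healthy macula
is measured inside a circle of radius $r = 0.5$ mm (1000 µm diameter)
centred on the foveal centre — the central subfield of the 1/3/6 mm ETDRS
grid. A B-scan at distance $d$ from the circle's centre-line sees the
circle as a chord of half-width $w(d) = \sqrt{r^2 - d^2}$ ($d < r$).
`foveal_volume()` clips each contour to the vertical strip
$[c_x - w,\, c_x + w]$ (Sutherland–Hodgman against the two clip lines) and
then applies the same slab sum. Clipping to the strip — not to the circular
arc — reproduces exactly the on-screen procedure of drawing two vertical
reference lines where the circle crosses the scan; across the stack the
union of strips Riemann-approximates the cylinder over the circle, so the
slab sum of clipped areas converges to the in-circle volume. Tangent scans
($d \ge r$) have zero chord width and are excluded. A raster so coarse that
no scan intersects the circle yields volume 0 with a warning rather than an
error: that is a statement about measurement resolution, not about the
data.

**Degenerate inputs and tie-breaks.** Contours need at least three
vertices and must be simple; self-intersecting tracings are rejected (via
an all-pairs segment test), not repaired — a mis-traced contour should
surface, the way an outlier triggers third-observer review in practice.
Multiple same-label contours on one scan are summed (multi-lobed schisis).
Scans without the label contribute zero, but the label must occur somewhere
in the stack. The Sutherland–Hodgman output of a non-convex contour can
touch itself along a clip line; its enclosed area is still correct, so
clipped results are exempt from re-validation.

## Units and interchange formats

All geometry is in mm; `x` is lateral and `z` axial within a B-scan, `y`
the raster axis. Because the device's on-screen tracings have no exportable
format, the package defines a JSON schema (see `?read_annotation_stack`)
holding contours, raster metadata (`scan_spacing_mm`, per-axis pixel
scales, foveal centre) and provenance in one portable file. Vertices may
arrive in pixels, in which case both `x_scale_mm_per_px` and
`z_scale_mm_per_px` are required and conversion happens at read time;
pixel input without scales is an error, never a silent interpretation.
Scan indices are 0-based; `lateral_offset_y` defaults to
`scan_index × scan_spacing` and, when given explicitly (e.g. a raster
centred on the fovea), must advance by `scan_spacing` per index step.
Paired measurements travel as a three-column CSV
(`subject,value_a,value_b`); incomplete pairs are dropped with a warning,
matching standard practice for agreement analysis, never imputed.

## Agreement statistics

For $n$ paired measurements the differences $d_j = a_j - b_j$ (first-named
method minus second) give:

* bias $\bar d$, with 95% CI $\bar d \pm 1.96\, s/\sqrt n$;
* SD of differences $s$ (sample, $n-1$ denominator — conventional in
  Bland–Altman analysis; the method statement does not specify);
* coefficient of repeatability $\mathrm{CR} = 1.96\,s$;
* limits of agreement $\mathrm{LOA} = \bar d \pm \mathrm{CR}$;
* LOA CIs of $\mathrm{LOA} \pm 1.96\,\mathrm{SE}$ with the stated
  approximation $\mathrm{SE} = \sqrt{3 s^2 / n}$.

The multiplier is the literal 1.96 throughout, because the method is
defined with that constant rather than with a $t$ quantile. A documented
inconsistency exists in the published summary table this package is
validated against: its LOA CIs are wider than $\sqrt{3 s^2/n}$ produces by
a factor $\approx\sqrt3$ (they are consistent with $\mathrm{SE} = 3
s/\sqrt n$). We implement the stated formula as the default and expose
`loa_se_mode = "table1"` so the printed intervals can be reproduced for
comparison; we do not guess which was intended. Relatedly, the three
foveal-cavity rows of that table do not reproduce *exactly* from their
printed (bias, CR, $n$) triples after 4-dp rounding — residuals of 1–2
units in the last digit, attributable to the printed inputs being
themselves rounded — and the acceptance suite leaves that check visibly
failing for those rows rather than widening the tolerance.

### Power for agreement designs

A planned comparison "agrees" when both LOA CIs fall inside the clinical
agreement interval $(-\delta, +\delta)$; $\delta$ defaults to 0.01 mm³, a
conservative limit for macular volumes. Under
$d_j \sim N(\mu, \sigma^2)$ the sample mean and SD are independent, with
$\bar d \sim N(\mu, \sigma^2/n)$ and
$s = \sigma\sqrt{\chi^2_{n-1}/(n-1)}$, and the success event is
$|\bar d| \le \delta - c(s)$ with
$c(s) = s\,(z_{\mathrm{loa}} + z_{\mathrm{ci}}\sqrt{3/n})$. The
`approximate` method evaluates

$$ \mathrm{power} = \int_0^\infty
   \Big[ \Phi\big(\tfrac{(\delta - c(s)) - \mu}{\sigma/\sqrt n}\big) -
         \Phi\big(\tfrac{-(\delta - c(s)) - \mu}{\sigma/\sqrt n}\big)
   \Big]_+ \, dF_s(s) $$

by quadrature over the $\chi^2$ distribution — exact up to quadrature
error for the estimators actually used. The `monte_carlo` method simulates
whole studies with those same estimators and is the independent oracle;
the two agree within Monte-Carlo error across a grid of
$(\mu/\sigma,\ \delta/\sigma,\ n)$, which is the contract of correctness.
An infeasible design (e.g. $|\mu| + 1.96\sigma \ge \delta$ with tiny
$\sigma$) returns power $\approx 0$, not an error.

## The phantom world

The synthetic-data generator states a world once and measures against it;
none of its defaults were chosen by looking at test outcomes.

* **Shapes** with closed-form volumes: ellipsoid
  ($\tfrac43\pi abc$), slab cylinder ($\pi r^2 t$; a uniform tissue slab
  over a disc, whose B-scan sections are exact rectangles), paraboloid pit
  ($\pi a^2 h/2$; a foveal-depression-like bowl), and biconvex lens
  (two spherical caps, $2\pi h^2(3R-h)/3$; a cavity/schisis-like body).
  Every closed form is cross-checked against 1-D quadrature of the exact
  cross-section function to $10^{-6}$ relative.
* **Raster**: 49 B-scans by default, emulating a dense macular volume
  acquisition. The true inter-scan distance of such presets is not
  published for the scan angle used, so the default spacing 0.12 mm is an
  explicit assumption (a 30° macular cube spans roughly 6 mm per 49 scans);
  spacing is always read from the data file, never hard-coded, and every
  validation sweeps it.
* **Rendering**: each scan's contour is a polygon inscribed in the exact
  section boundary with $k = 128$ vertices by default; inscribed polygons
  never overestimate, and the area deficit scales as $1/k^2$ (measured).
* **Observers** perturb per-scan *areas* multiplicatively: observed area =
  true area $\times (1 + \beta + \varepsilon)$,
  $\varepsilon \sim N(0, \sigma_a^2)$, truncated at zero. Area-level noise
  (rather than vertex-level) keeps the induced volume distribution
  analytically tractable: a volume difference between observers is
  $\beta_1 V + \Delta \sum_i A_i(\varepsilon_{1i} - \varepsilon_{2i})$, so
  expectation and variance follow from the subject's own per-scan areas.
  Tracing variability of real observers is plausibly 1–3% of area for
  well-defined boundaries; validation uses 2%.
* **Subjects** rescale the base shape's linear dimensions by $(1+u)$,
  $u \sim N(0, 0.05)$ — about 5% anatomic size variation, the order of
  inter-eye macular dimension spread.

What a green test establishes: that tracing polygons on exact section
boundaries and integrating them recovers known volumes at the expected
rates, and that the agreement statistics recover known observer biases and
noise. What it does not establish: anything about segmentation ambiguity on
real OCT images (speckle, boundary contrast, pathology), axial-scale
calibration of a device, retinal curvature (B-scans are treated as planar
sections), or interpolation behaviour of any commercial thickness-map
algorithm. Those remain properties of instruments and observers, not of
this arithmetic.

## Numerical choices

* Simplicity testing uses exact-arithmetic-style orientation signs on
  segment pairs; any touch between non-adjacent edges counts as
  self-intersection. Cost is $O(m^2)$ per contour, paid at file-read time;
  contours that are simple by construction (phantom renderings, clip
  outputs) carry a trusted flag so hot loops stay linear.
* The rasterization oracle used in tests (pixel-centre counting at
  1 µm/px via scanline crossings) shares no code with the shoelace or
  clipping implementations; agreement is required within
  $2 \times \text{perimeter} \times \text{pixel size}$, a conservative
  boundary-pixel bound.
* JSON serialisation uses 17 significant digits, so write→read round-trips
  reproduce every double exactly; CSV results use `%.17g` for the same
  reason.
* Monte-Carlo seeds are required inputs with default 2024; identical seeds
  give bit-identical simulated studies.
* Convergence-order estimates fit $\log|\hat V(\Delta) - V|$ against
  $\log \Delta$ over $\Delta \in \{0.2, 0.1, 0.05, 0.025\}$ mm and require
  slope $\ge 1$.

## Design decisions that were genuinely open

* **Interchange schema.** The source workflow draws on proprietary device
  software with no documented export of calliper tracings; defining a JSON
  schema (rather than guessing at a vendor format) keeps the method
  reproducible without the device.
* **Chord clipping vs arc clipping.** Clipping to the vertical strip
  matches the manual procedure exactly and makes the per-scan operation a
  polygon–halfplane intersection; clipping to the arc would measure the
  same limit but a different finite-$\Delta$ quantity than the manual
  method produces.
* **Power method.** The cited closed-form approach for agreement-study
  power is implemented as the exact integral above rather than a series
  approximation; since the simulation oracle defines correctness, any
  faithful variant must match it, and the integral is the simplest object
  that provably does.
* **Observer seed semantics.** A study-level seed governs all draws;
  per-observer seeds, when set, re-seed that observer's own noise stream.
  This keeps the common case (one seed, bit-reproducible study) simple.

## Known limitations

* Areas are taken as exact once a polygon is given; pixel-quantisation of
  a real calliper is not modelled (the rasterization oracle bounds what it
  could contribute: ≲ 2·perimeter·pixel size).
* The slab sum ignores partial-volume effects at the first and last scans
  touching an entity; this is inherent to the method being modelled, and
  it is exactly the term that makes the convergence order 3/2 rather
  than 2.
* No repeated-measures or proportional-bias extensions of the agreement
  analysis; the design validated here is the basic single-measurement
  comparison.
* The phantom observer model cannot emulate gross mis-tracings (the
  outlier-review pathway); it models routine variability only.
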