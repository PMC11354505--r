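# octvol

Volumetry of arbitrary retinal entities from manual contour annotations on
OCT B-scan rasters, with the full agreement-statistics toolkit needed to
validate such measurements.

## The problem

Commercial OCT software automates volume measurement only for the whole
retina or for single segmented layers. Entities that matter clinically in
vitreoretinal disease — the foveal cavity (FC) of a degenerative lamellar
macular hole, the schitic space (FS) under an epiretinal membrane, intra- or
sub-retinal fluid pockets — cannot be volumetrised automatically. A simple
manual alternative works with any raster acquisition: trace the perimeter of
the entity on every B-scan where it appears, let the calliper report each
cross-sectional area, and integrate across the raster:

```
V [mm^3] = Σ area_i [mm^2] × Δ [mm]
```

where Δ is the distance between consecutive B-scans. For retinal volume in
eyes with a normal foveal profile, measurement is restricted to the central
1000-µm-diameter circle around the fovea (the central ETDRS subfield): each
B-scan inside the circle sees it as a chord, and the traced contour is
clipped to the vertical strip between the two chord borders before its area
enters the sum.

`octvol` implements this method (shoelace polygon areas, analytic chord
clipping, Riemann slab summation) together with the statistics used to
validate it: Bland–Altman bias with 95% CI, coefficient of repeatability
(CR = 1.96·SD of differences), limits of agreement (LOA = bias ± CR) with
CIs (SE = √(3s²/n)), and power for agreement studies (probability that both
LOA CIs fall inside a clinical agreement limit δ, default 0.01 mm³).
Because no clinical data ship with the package, an analytic phantom module
generates annotation stacks from shapes with closed-form volumes
(ellipsoid, slab cylinder, paraboloid pit, biconvex lens) and simulates
noisy observers, so every pipeline stage is testable against ground truth.

## Worked example

```r
library(octvol)

# a lens-shaped schisis phantom, 49-scan raster at 0.12 mm spacing
sp <- phantom_spec("lens", list(h = 0.2, R = 0.5), label = "FS")
analytic_volume(sp)
#> [1] 0.1089085

stack <- render_stack(sp)
v <- entity_volume(stack, "FS")
v$total_volume
#> [1] 0.108897
```

The measured 0.108897 mm³ differs from the analytic 0.1089085 mm³ by the
polygon inscription error plus the finite 0.12-mm slab width; both vanish
under refinement (tested to order ≥ 1 in Δ and 1/k² in vertex count).

```r
# two simulated observers, 2% area noise, observer 1 biased +1%
study <- simulate_observers(sp, observer_model(0.01, 0.02),
                            observer_model(0, 0.02),
                            n_subjects = 30, seed = 2024)
bland_altman(study$comparisons$obs1_vs_obs2)
#> <agreement_result Obs 1-Obs 2, n = 30>
#>   bias 0.0010 mm^3 (95% CI 0.0005 to 0.0015)
#>   CR   0.0028 mm^3
#>   LOA  -0.0018 (95% CI -0.0026 to -0.0009)
#>        0.0038 (95% CI 0.0029 to 0.0047)

# was n = 30 enough to show agreement within 0.01 mm^3?
agreement_power(bias = 0.001, sd = 0.0028 / 1.96, delta = 0.01, n = 30)$power
#> [1] 1
```

The bias recovers observer 1's +1% of the ~0.106 mm³ mean true volume, and
with this little variability a 30-pair study demonstrates agreement within
δ = 0.01 mm³ essentially always (a noisier design, e.g. SD of differences
0.0035 mm³, drops the power to 0.51).

A command-line interface wraps the same operations
(`inst/cli/octvol`; see `?octvol_main`):

```sh
octvol simulate --shape lens --params h=0.2,R=0.5 --out stack.json
octvol measure --input stack.json --label entity --out volume.csv
octvol agreement --pairs pairs.csv --out ba.json
octvol power --bias 0 --sd 0.003 --delta 0.01 --n 30 --out power.json
```

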