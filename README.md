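# fibremech

Multi-modal damage metrology for single keratin (hair) fibers.

Repeated chemical treatment — bleaching and permanent dyeing in particular —
damages hair fibers at several length scales at once: the exposed edges of
the cuticle scales erode, the cuticle surface roughens, the fiber's contact
mechanics and tensile response stiffen, and the protein/water chemistry
shifts. Each effect is visible to a different instrument. `fibremech` is an
R package for scientists who quantify such damage as a *dose-response* over
treatment cycles, combining four standard measurement modalities into one
tested pipeline:

| Modality | Raw data | Extracted features |
|---|---|---|
| AFM topography | height grid (nm) with pixel size | cuticle step height; areal roughness Sa, Sz at two window sizes |
| AFM force spectroscopy | approach/retract force–distance curves | contact stiffness, adhesion (pull-off), attraction (snap-in) |
| Tensile test | strain vs force, fiber diameter | elastic modulus, yield stress, fracture stress and strain |
| ATR FT-IR | wavenumber vs transmittance (%T) | dip depths of the amide I/II/III/B, lipid, water, cysteic acid and NH₂ bands |

## The quantities at the core

* **Cuticle step height.** A line profile across the cuticle staircase is
  segmented into terraces by change-point detection (binary segmentation
  minimizing within-segment variance with a noise-scaled penalty); each step
  is the difference of flanking terrace medians, robust to edge rounding and
  debris.
* **Areal roughness.** After least-squares plane flattening,
  `Sa = mean |z − mean(z)|` and `Sz = max(z) − min(z)` over the sampled
  area. Computed on the full (step-spanning) field and on a small
  single-terrace window, which separate step erosion from surface
  roughening.
* **Force–distance features.** After linear baseline correction from the
  non-contact segment: attraction = |min force| of the approach branch
  (snap-in dip), adhesion = |min force| of the retract branch (pull-off
  dip), stiffness = least-squares slope of the repulsive contact region
  (raw force vs piezo displacement, bounded by the cantilever constant `k`
  through the series-spring relation `s = k·k_s/(k + k_s)`; the corrected
  sample stiffness `k_s` is also reported).
* **Tensile features.** Engineering stress `σ = F/A`, `A = π(d/2)²`; a
  continuous three-piece linear fit with free slopes and shared breakpoints
  segments the record into pre-yield / yield / post-yield; the elastic
  modulus is the pre-yield slope, the yield stress the highest pre-yield
  stress, and fracture is the last recorded sample.
* **Band quantification.** Band intensity is the transmittance dip depth
  below a local linear baseline through the window endpoints (deeper dip =
  stronger absorption); a band is "present" when its depth clears 3× a
  robust noise estimate.
* **Group statistics.** The fiber is the experimental unit: per-fiber values
  are averaged first, then groups are summarized as mean ± SEM and compared
  to the control group by two-tailed pooled-variance Student's t-tests with
  inclusive significance stars (\*p ≤ 0.05, \*\*p ≤ 0.01, \*\*\*p ≤ 0.001,
  \*\*\*\*p ≤ 0.0001).

Because raw per-fiber instrument data for dyeing studies are generally not
public, the package ships a first-class synthetic-data generator
(`gen_topography()`, `gen_fd_curve()`, `gen_tensile_curve()`,
`gen_spectrum()`, `gen_cohort()`) with known ground truth per dye-cycle
group, so every analyzer is validated by parameter recovery.

## Worked example

Simulate the default six-group cohort (dye cycles 0, 1, 3, 5, 7, 10; 25
fibers per group), analyze every fiber, and produce the dose-response
report:

```r
library(fibremech)

root <- tempfile("cohort")
simulate_cohort(root, seed = 1, n_fibers = 25)   # writes files + manifest.csv
an  <- analyze_cohort(root)                      # 150 fibers, 4 modalities each
rep <- report_cohort(an)

rep$tables$stiffness
#>   group  n      mean          sem  pct_change            t            p stars
#> 1     0 25 0.1628643 6.556000e-05  0.00000000    0.0000000 1.000000e+00    ns
#> 2     1 25 0.1629533 7.132223e-05  0.05462728   -0.9183726 3.630157e-01    ns
#> 3     3 25 0.1630443 5.920007e-05  0.11052401   -2.0377847 4.710335e-02     *
#> 4     5 25 0.1581757 6.733104e-05 -2.87883031   49.8910516 5.112762e-43  ****
#> 5     7 25 0.1695808 6.669557e-05  4.12399664  -71.8173145 1.641441e-50  ****
#> 6    10 25 0.1793115 6.425131e-05 10.09873553 -179.1732759 1.723736e-69  ****
```

Reading the table: the control-group contact stiffness is ~0.163 nN/nm
(below the 0.2 nN/nm cantilever constant, as a raw contact slope must be);
it is essentially unchanged through three dye cycles (a +0.1 % difference
that happens to graze p = 0.05), dips by ~3 % at five, and rises by ~4 %
after seven and ~10 % after ten cycles — each dyed group compared to
control by a pooled t-test, with `pct_change` the percent change of the
group mean. The same structure is produced per metric
(`rep$tables$step_height`, `$attraction`, `$elastic_modulus`,
`$water_depth`, ...), and `rep$recovery` holds the truth-vs-estimate table
(configured generator truth, estimated group mean, relative error) — in
this run every recovered metric is within 3 % of its configured truth.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fibremech.R run --root /tmp/cohort --out /tmp/report --seed 1
```

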