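---
title: "Methods: models, estimators and design choices in fibremech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in fibremech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibremech)
```

`fibremech` quantifies cumulative damage to single keratin fibers across
four measurement modalities and reports it as a dose-response over treatment
(dye-cycle) groups. This vignette is the package's account of the underlying
models, the estimators and their numerical behavior, the synthetic-data
generator that every analyzer is validated against, and the design choices
made where the methodology was genuinely open.

## 1. What the synthetic cohort emulates

Raw per-fiber instrument data for repeated-dyeing studies are not publicly
available, so the package treats parameter recovery on synthetic data as its
primary form of validation. The generator produces, per fiber:

* **Topography** — a height grid built as tilt plane + cuticle staircase +
  correlated Gaussian roughness + optional debris bumps. The staircase runs
  along the column (fast-scan) axis: terraces of fixed length (default
  3.5 µm, a typical exposed-scale length) separated by rises drawn from
  `Normal(step_height_mean, step_height_sd²)`. The roughness field is white
  Gaussian noise smoothed to a configurable correlation length (default
  0.3 µm) and rescaled to an exact standard deviation; a single-scale
  roughness is all that Sa/Sz estimation needs to be exercised. Debris
  appears as Poisson-scattered Gaussian bumps, emulating residual
  endocuticle fragments on dyed fibers.
* **Force–distance curves** — per branch: a zero-force non-contact baseline,
  a snap-in dip to `−attraction_depth` at the contact point, then a linear
  repulsive rise whose slope is the series-spring combination
  `s = k·k_s/(k+k_s)` of the cantilever constant `k` (default 0.2 nN/nm)
  and sample stiffness `k_s`, up to the setpoint (default 8 nN, within the
  ≤ 10 nN contact-mode regime); the retract branch follows the same contact
  line down to `−adhesion_depth` before pull-off. One sign/axis convention
  is fixed repo-wide: displacement in nm increases toward the sample,
  repulsive force is positive.
* **Tensile records** — a three-region stress–strain model on an equally
  spaced strain grid: Hookean pre-yield slope `E` up to the yield strain, a
  near-flat yield plateau, then a post-yield slope up to the fracture
  strain, where the record simply ends (the instrument stops at break). The
  plateau slope is fixed at 2 % of `E` rather than zero, so segmentation is
  tested against *near*-flat, not degenerate, regions — the yield region of
  keratin shows minimal but nonzero hardening while the α-helices unfold.
* **Spectra** — transmittance `100 + slope·(ν−ν_min) − Σ Gaussian dips +
  noise`, clipped below at 0 %T, on a 400–4000 cm⁻¹ grid at 4 cm⁻¹
  resolution. The default keratin band set places dips for amide I (1650),
  amide II (1520), amide III (1245), amide B (3066), lipid (3135), the broad
  water band (3277), the weak cysteic acid band (1035.9) and — in dyed-like
  spectra only — the NH₂ scissoring band at 1575 cm⁻¹.

**Noise defaults** are 0.02 nN (force), 2 MPa (stress), 0.3 %T
(transmittance) and a 5–15 nm roughness field on the topography: small
enough that recovery within the stated tolerances is expected, large enough
that estimators cannot cheat by reading single samples. Every generator is
a pure function of (truth, geometry, seed): fixed seeds give bit-identical
output, and with all noise terms at zero the data equal the closed-form
model exactly, which the tests assert pointwise.

**The default cohort** has groups at 0, 1, 3, 5, 7 and 10 dye cycles with
25 fibers each (typical published cohorts characterize 20–30 fibers per
group; 25 is the midpoint). Group truths follow the observed dose-response
pattern for this kind of treatment: control step height 430.2 nm dropping
to 343.3 nm after one dye (−20 %) then partially recovering while staying
below control; small-area roughness rising monotonically (6 → 14 nm);
contact slope 0.163 nN/nm, flat through three cycles, −3 % at five, +4 % at
seven, +10 % at ten; attraction 0.591 nN reduced by 38–43 % (1–5 cycles)
and 50–51 % (7–10); adhesion rising from five cycles; elastic modulus
3000 MPa rising to +190 % at ten cycles with a dip at seven; fracture
strain 0.47 (control) vs ≥ 0.52 (dyed); water-band depth reduced by 40 %
after one dye and 52 % from five dyes on; cysteic-acid depth halved from
three dyes; NH₂ present in every dyed group. Within a group, fibers differ
only through measurement noise and the per-fiber staircase draw — real
cohorts add genuine fiber-to-fiber biological variance, so real-data group
SEMs will be larger and significance weaker than in simulation. That, plus
idealized band shapes (pure Gaussians on a linear background) and the
absence of instrument drift or piezo hysteresis, delimits what passing
recovery tests can claim about real data: they validate the estimators,
not the instrument model.

**Simulation problem sizes.** Cohort images default to 128 × 128 px over
15 × 15 µm — enough for ~4 terraces and > 25 px per terrace — with FD
curves at 400 points/branch, tensile records at 500 points and spectra at
the instrument's native 901 points. These sizes keep a full 150-fiber
cohort round trip in well under a minute while leaving every estimator's
sampling error far below its acceptance tolerance.

## 2. Topography metrology

**Flattening** subtracts a least-squares polynomial surface of total degree
0, 1 or 2; order 1 (the mean plane) is the default for roughness, matching
the mean-plane definition of Sa. Flattening is idempotent and exactly
annihilates surfaces of its own degree. Note that plane flattening removes
the *average* slope of a staircase — jump discontinuities survive, but
terrace-median differences do not (each is reduced by
`slope × terrace_length`, which for a staircase's own mean slope equals one
full step height). Step detection therefore operates on **unflattened**
profiles: the residual within-terrace tilt (1–2 nm/µm in the default
cohort, i.e. a few nm per terrace) biases the median difference by well
under 1 % of a 400 nm step, whereas detrending first would destroy the
signal. This is why `detect_steps()` does not detrend by default.

**Step detection** segments a line profile into terraces by binary
change-point segmentation minimizing within-segment variance. The penalty
for an additional change point is `3·σ²·log n` with σ estimated robustly
from first differences (`mad(diff(y))/√2`), plus an absolute floor so
noiseless terraces are never split on rounding error. Adjacent segments are
merged while their median difference is below `min_height`; each surviving
boundary whose flanking terraces are at least `min_terrace` long becomes a
step event, with height = difference of flanking terrace medians (robust to
edge rounding and debris spikes) and direction rise/fall. On noiseless
staircases, recovery is exact; at 5 nm noise, group-mean bias is below 2 %.

**Roughness.** `Sa = mean |z − mean(z)|`, `Sz = max(z) − min(z)` over the
full sampled area, after flattening. Sz here is the *areal* peak-to-valley
convention; a profile-wise alternative (maximum over rows of per-row
ranges) is exposed via `sz_mode = "profile"` since the terse phrase
"peak-to-valley height of the profile" admits both readings. The two-scale
analysis mimics practice: a 15 × 15 µm window spans several scale edges, so
its Sa/Sz track step height, while a 3 × 3 µm window on a single cuticle
surface isolates surface roughening. Because a mid-image 3 × 3 window will
usually straddle a step, the pipeline places the small window with
`flattest_crop()`: it slides the window along the fast-scan axis and keeps
the placement with minimal flattened peak-to-valley range — the automated
equivalent of an operator choosing a scan area on a cuticle surface, away
from scale edges. The selection-by-minimum introduces a small downward bias
in the small-area Sa (it picks the quietest window), which is shared by all
groups and leaves the dose-response ordering intact.

Baseline/flattening treatment is the one step where commercial AFM software
pipelines differ silently; both the flatten order and the small-window
placement are therefore explicit, configurable parameters.

## 3. Force–distance analysis

`baseline_correct()` fits a line to the quarter of approach points farthest
from the surface and subtracts it from both branches; constant offsets and
linear baseline tilt are thereby absorbed, and the far-segment residual
provides the robust noise scale used everywhere else. A far-segment slope
above a quarter of the cantilever constant means no non-contact region
exists (fully-in-contact curve) and is an error.

Attraction and adhesion are the magnitudes of the deepest negative
excursions of the approach and retract branch respectively — branch
independence is asserted as a property test. A dip counts as *detected*
when it passes 4× the baseline noise: the statistic is a minimum over a
whole branch of hundreds of samples, so a 3σ rule would flag pure noise in
roughly a third of dip-free branches, while 4σ keeps false detections near
1 % without affecting any reported magnitude.

The contact point is the first displacement after the snap-in minimum where
force crosses +3σ — a deterministic rule chosen because the literature
rarely defines one. Stiffness is the least-squares slope of force vs piezo
displacement over the upper 70 % of the contact region (`fit_fraction`),
reported **raw**, i.e. not compliance-corrected: a raw contact slope is
bounded above by the cantilever constant, which is exactly the regime in
which a 0.163 nN/nm hair-surface value sits under a 0.2 nN/nm lever. The
series-spring inversion `k_s = k·s/(k−s)` is reported alongside as
`sample_stiffness`. Whether published stiffness values derive from approach
or retract contact data is usually unstated; the default here is the
approach branch, and the retract branch is available to the caller.

## 4. Tensile analysis

Stress is engineering stress `σ = F/A` with a circular cross-section from
the fiber diameter; strain is stored as a fraction and rendered as percent
in reports. Gram-force inputs convert at 1 gf = 9.80665 mN; subtracting the
instrument's 2 gf gauge pre-tension is supported but **off** by default,
since published stress values rarely state whether the pre-tension is
included.

Segmentation fits a continuous three-piece linear model (free slopes,
shared breakpoints) by exhaustive search on a 30-point breakpoint grid
followed by deterministic coordinate-descent refinement down to the strain
grid spacing, with a final snap of the breakpoints to the nearest sample.
No random initialization is involved, so results are exactly reproducible.
Degeneracy is declared — and the whole record treated as pre-yield — when a
single line explains the record as well as three (F-test at p > 10⁻³), or
when the middle slope is not the smallest of the three; a valid yield
plateau must be the flattest region.

Features: elastic modulus = least-squares slope over the pre-yield segment;
yield stress = maximum stress within pre-yield; fracture stress/strain =
the last recorded sample. For real traces whose loggers keep recording
after the break, an optional terminal-drop detector (> 50 % fall from the
running maximum) truncates the record first; it is off by default because
synthetic records end exactly at fracture. On noiseless three-piece curves
with on-grid breakpoints, recovery of breakpoints and modulus is exact; at
the default 2 MPa noise, modulus bias stays below 2 % and breakpoint error
below 0.01 strain (median).

## 5. FT-IR band quantification

Band intensity is measured as the transmittance dip depth below a local
linear baseline through the quantification-window endpoints. Published
analyses often report raw "transmittance" changes whose normalization is
unstated; depth-below-local-baseline is the reproducible surrogate, and the
sign relationship is stated explicitly wherever depths are reported:
**a larger depth means stronger absorption**, so a band whose transmittance
"increases" in the raw-%T sense has *lost* depth here. No absorbance
(−log T) conversion or ATR penetration-depth correction is applied; the
analysis stays in %T as acquired.

Two numerical choices matter. First, a width-3 moving average is applied
before baseline anchoring and peak picking (default on). The depth is a
maximum statistic over the window samples; unsmoothed, its extreme-value
inflation makes a 3σ presence rule fire on noise alone in a few percent of
empty windows, while after smoothing the same 3σ rule yields measured
false-positive and false-negative rates of ~0.3 % at the default noise.
The smoothing attenuates narrow-band depths by a few percent; the
noiseless-model reference depths recorded in the cohort manifest are
computed with the identical estimator, so truth and estimate remain
commensurable. Second, the window endpoints themselves serve as baseline
anchors — averaging *inward* from the endpoints was rejected because narrow
windows (e.g. the 1560–1590 cm⁻¹ NH₂ window) would then anchor the baseline
on the band's own shoulders and cancel the depth being measured.

The default eight-band table uses the standard keratin windows (amide I
1600–1690, amide II 1480–1575, amide III 1229–1301, amide B 3030–3100,
lipid 3110–3160, water 3180–3370, cysteic acid 1020–1060, NH₂ 1560–1590
cm⁻¹). Weak bands — cysteic acid and NH₂, a few times the noise floor — are
treated as *detection* targets (present/absent), not depth-recovery
targets: at those depths the max-statistic bias of the depth estimator is
an irreducible 10–20 %, so the recovery table tracks the strong bands
(amide I, water) and the detection rates validate the weak ones.

## 6. Statistics and reporting

The experimental unit is the fiber: repeated events within a fiber (e.g.
several steps on one profile) are averaged first, and all group statistics
run over per-fiber values — published error bars rarely state their unit,
and fiber-level inference is the conservative choice. Groups are summarized
as mean ± SEM (`sd/√n`, n−1 denominator) and compared to the control group
(dye count 0) by two-tailed **pooled-variance** Student's t-tests
(`df = n₁+n₂−2`) — the classic test that matches the "Student's t-test"
naming convention — with Welch's variant behind a flag. Stars follow the
inclusive thresholds \*p ≤ 0.05 through \*\*\*\*p ≤ 0.0001; exact-threshold
p-values earn the star. Zero-variance degeneracies are defined rather than
left to error: equal means give t = 0, p = 1; unequal means give p = 0 with
a degeneracy flag. No multiple-testing correction is applied by default
(matching field practice for these dose-response panels); a Bonferroni
option would be a one-line wrapper over the returned p-values.

`dose_response_report()` emits one table per metric (group, n, mean, SEM,
percent change vs control, t, p, stars) and, when a generator manifest is
available, a truth-vs-estimate recovery table whose absolute relative
errors stay below 10 % for every metric and group at the default noise —
in practice below ~4 %.

## 7. Known limitations

* No tip-shape deconvolution, scan-line artifact removal or multi-scan
  stitching; topography inputs are assumed already calibrated in nm.
* No contact-mechanics (Hertz/DMT/JKR) modulus fitting — stiffness is a
  slope, deliberately, and the series-spring inversion is the only
  mechanical correction applied.
* No α→β keratin transition modeling; the tensile region names are
  descriptive labels on a piecewise-linear fit.
* No secondary-structure deconvolution of amide I, no H–D exchange
  analysis, and no S–S band quantification (508–516 cm⁻¹ is typically not
  observable in these spectra).
* Group differences in the generator enter only through truth parameters;
  dye chemistry, diffusion and melanin are out of scope.
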