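---
title: "Evaluating synthetic CT for MRI-only adaptive radiotherapy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic CT for MRI-only adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctqa)
```

## The problem

In MRI-guided online adaptive radiotherapy the electron-density map used for
dose calculation is, in current practice, a planning CT deformably registered
to the daily MRI (a "deformed CT", dCT). MRI-only workflows replace it with a
synthetic CT (sCT) generated from the MRI itself. Before an sCT algorithm can
carry clinical dose calculation, its output has to be compared against the
dCT it would replace — geometrically, in Hounsfield units, and dosimetrically,
in the dose distributions that result when the same plan is recalculated on
each map. `sctqa` implements that evaluation pipeline: it does not generate
synthetic CTs and it does not calculate dose; it quantifies agreement between
two HU volumes and between two sets of per-fraction dose grids.

## The evaluation pipeline

For each case the pipeline is:

1. **Volume of interest.** Both CT volumes are thresholded at > −950 HU,
   intersected with the delineated body structure, and the three outermost
   axial slices at each cranial/caudal end are discarded
   (`threshold_body_mask()`, `build_voi()`). The threshold removes background
   and field-of-view edge artefacts that the delineated body outline does not
   reliably exclude; the slice trim removes the sCT blur at the volume ends
   (limited MRI coverage, convolutional padding).
2. **Air-pocket compensation.** Bowel gas moves between the imaging sessions
   the two volumes derive from; that anatomical mismatch is not the sCT
   algorithm's error. Within the VOI, voxels that read as gas in the dCT
   (< −500 HU) but as tissue in the sCT (> −200 HU) are overwritten with
   water (0 HU) in a copy of the dCT (`overwrite_air_pockets()`).
3. **HU agreement.** Mean error ME = mean(dCT − sCT), mean absolute error,
   MAE in 20-HU bins from −1000 to 1500 HU indexed by the reference value,
   and Dice overlap of threshold tissue masks — bone > 150 HU, fat in
   (−100, −20) HU, lung < −700 HU — inside the body outline
   (`mean_error()`, `mean_absolute_error()`, `binned_mae()`, `tissue_dice()`).
4. **Dosimetry.** Per-fraction dose grids calculated on each map are
   accumulated voxel-wise, in physical dose and in biologically effective
   dose BED = d·(1 + d/(α/β)) applied per fraction before summation.
   DVH points (D2%, D50%, D98%, Dmean, Dx cc, ...) are read per structure and
   differences reported relative to the dCT-based value, signed so that a
   higher dCT-based dose is positive (`accumulate_dose()`, `accumulate_bed()`,
   `dvh_point()`, `relative_difference()`).
5. **Gamma analysis.** Local 3D gamma of the accumulated physical doses at
   1%/1 mm, 2%/2 mm and 3%/3 mm with voxels below 10% of the reference
   maximum excluded from map and denominator (`gamma_map()`, `pass_rate()`).

`evaluate_case()` runs all of it and returns one tidy row per metric;
`summarize_cases()` reduces a cohort to mean, sample SD, min and max.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| body threshold | −950 (strict >) | HU | separates patient from background air without clipping lung |
| slice trim | 3 per end | slices | sCT edge blur affects the outermost slices |
| air-pocket rule | dCT < −500 and sCT > −200 → 0 | HU | gas-vs-tissue disagreement attributable to anatomy change |
| tissue thresholds | bone > 150, fat (−100, −20), lung < −700 | HU | ICRU-46 electron densities (1.2, 0.93–0.98, 0.26) through the default calibration curve |
| MAE bins | width 20, range [−1000, 1500) | HU | resolves tissue-dependent error structure |
| α/β | 10 targets, 3 OARs | Gy | standard generic fractionation sensitivities; per-structure overrides supported |
| gamma criteria | 1%/1, 2%/2, 3%/3 | %, mm | clinical QA conventions, local normalization |
| gamma exclusion | 0.10 of reference max | — | low-dose voxels carry no clinical meaning under local normalization |
| gamma lattice | step dta/10, radius 3·dta | mm | sub-voxel search resolution vs cost; see below |

All inequalities at thresholds are strict; boundary values are untouched.
Tissue thresholds are stored in HU, not recomputed from electron density at
run time, so replacing the calibration curve can never silently move a mask
threshold.

### The calibration curve

Vendor calibration curves are not published. The default curve pins nodes at
(−1000, 0.0), (−740, 0.26), (−100, 0.93), (−20, 0.98), (0, 1.0), (150, 1.2),
(1500, 2.0) so that every tissue electron density used for mask provenance
maps exactly onto the corresponding HU threshold — internal consistency was
preferred over guessing an unpublished curve, and the cited fat/lung
electron-density intervals are not exactly collinear with any single-slope
curve anyway. The curve is monotone piecewise-linear, user-replaceable from a
two-column text or JSON file (`read_calibration_curve()`), and the two
conversion directions are exact inverses wherever the curve is strictly
increasing.

## Numerical choices

**DVH read-off.** Dv% is the minimum dose to the hottest v% of the structure
volume. Sorted descending, each voxel is anchored at its cumulative-volume
midpoint and doses are interpolated linearly between midpoints (clamped to
max/min beyond the first/last midpoint); a no-interpolation step read-off
ships as `method = "step"` and the two agree within one voxel's dose
increment. On a 100-voxel equal-volume ramp of 1..100 Gy the interpolating
convention gives D50% = 50.5 Gy. Absolute-volume requests larger than the
structure are clamped with a warning.

**BED order.** BED is computed per fraction and then summed — never from the
accumulated physical dose. The two differ whenever fractional doses vary
(2 Gy + 8 Gy at α/β = 10: 16.8 Gy vs 20 Gy) and the test suite asserts that
difference.

**Gamma search.** The minimization runs over an axis-aligned lattice in mm
(default step dta/10) clipped to a sphere (default radius 3·dta) around each
reference voxel, with the evaluated dose trilinearly interpolated. The
production engine precomputes per-offset interpolation weights, sorts offsets
by distance and stops a voxel's scan once the pure distance term exceeds the
running minimum — an exact lower-bound rule, verified against a deliberately
independent brute-force transcription of the definition
(`method = "exhaustive"`) and, on tiny grids, against a pure-R oracle in the
test suite. A search radius of at least dta never changes pass/fail status:
an agreeing voxel's minimizer lies within dta by construction.

**Discrete gamma and criteria ordering.** In the continuum, loosening the
criteria can only raise the pass rate. The discrete estimator inherits that
guarantee only when the compared criteria share one evaluation lattice
(shared `step_mm`, radii at least each dta): the search sets then nest, and
the finer criterion's minimizer certifies agreement under the looser one.
With the default per-criterion lattices (step = dta/10) the ordering holds up
to discretization error; near steep dose gradients the coarser lattice of a
looser criterion can miss a sharp minimum, and we have observed rare
sub-0.1-percentage-point inversions on random phantoms. Cross-criteria
comparisons in the package's own checks therefore use a shared lattice.

**Empty masks.** Dice of two empty masks is reported not-applicable (`NA`),
never 0 or 100; empty-vs-non-empty is 0. The lung Dice is reported only when
both lung masks exceed 100 voxels, operationalizing "no lung tissue in
pelvic volumes" without a hard anatomy switch.

**Pass-rate boundary.** A voxel at gamma exactly 1 agrees by definition; the
pass count uses a 1e-9 guard so boundary voxels are not lost to
floating-point noise.

## The phantom generator

Clinical image pairs behind this kind of evaluation are generally not
shareable, so the package carries a fully synthetic case generator
(`phantom_spec()`, `generate_case()`) whose defaults encode the study
conditions the pipeline is meant for: an abdominal stereotactic course of
5 × 10 Gy (the modal prescription pattern among the emulated treatment
sites), HU noise of 60 HU SD and a 20 HU smooth bias field (global MAE near
50 HU, ME within roughly ±15 HU), 30% dropout of small bone elements
(ribs missing from the sCT), cranio-caudal edge blur, and an
evaluated-basis dose scale of 0.99 with an optional localized 2%-of-max
perturbation (DVH differences of about 1%).

Two deliberate modelling choices:

* **Air pockets carry partial-volume intensities** (−600 ± 30 HU, clamped
  below −520 HU). Pure −1000 HU gas would fall outside the > −950 HU body
  masks and hence outside the VOI, where the overwrite rule (by design
  restricted to the VOI) could never reach it; at 1.5–3 mm voxels real bowel
  gas reads well above −1000 HU anyway. Pockets of the three categories
  (reference-only, evaluated-only, shared) are mutually disjoint and placed
  clear of the trimmed end slices, so the ground-truth mismatch set is exact.
* **Dose is analytic** — crossing anisotropic Gaussian beams scaled so the
  target median dose equals the prescription — not transport-based. The
  evaluation is agnostic to how doses arose, and analytic doses give
  closed-form checks (a 0.99 dose scale must appear as exactly +1.0% at
  every DVH point).

Every injected parameter is recoverable downstream and the generator is
bit-reproducible under its seed. What the phantom does **not** emulate:
MRI contrast and artefacts, CT beam hardening, realistic bone topology,
transport effects of the magnetic field on dose, or registration error
beyond small smooth displacement fields. Passing tests demonstrate that the
*evaluation machinery* is correct under controlled conditions, not that any
particular sCT algorithm is clinically acceptable.

## Problem sizes used in the package's own checks

The default phantom grid is 20 × 48 × 48 voxels at 3 × 1.5 × 1.5 mm —
coarse relative to clinical grids but large enough that every mask, bin and
structure is well populated. The gamma search-vs-oracle equivalence runs on
twenty-one 16³ random dose pairs, one at the production-default 0.1 mm
lattice and twenty at 0.2 mm, all three clinical criteria each, on a shared
lattice for the ordering check (see above). The end-to-end reproducibility
check runs three seeded cases through generate → evaluate → summarize and
compares against a golden snapshot created from the first verified run.

## Known limitations

* Volumes are consumed as NIfTI (plus in-memory arrays); DICOM RT Dose /
  RT Structure Set import is not implemented.
* Displacement fields are applied, never estimated; dose warping is plain
  resampling without Jacobian energy correction.
* Structure masks are warped nearest-neighbour, which can erode single-voxel
  structures under large deformations.
* BED is the only radiobiological model offered; no EQD2, no repair
  half-times.
* The gamma engine is CPU-only and single-threaded; grids beyond ~10⁷ voxels
  at the default lattice will be slow.

## A worked example

```{r example, eval = FALSE}
library(sctqa)

case <- generate_case(phantom_spec(seed = 7))
rows <- evaluate_case(case, evaluation_config(), case_id = "demo")
subset(rows, metric %in% c("ME", "MAE") | metric == "gamma_pass_pct")

# cohort of three cases
cohort <- do.call(rbind, lapply(1:3, function(i)
  evaluate_case(generate_case(phantom_spec(seed = i)),
                case_id = sprintf("case%d", i))))
summarize_cases(cohort)
```
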