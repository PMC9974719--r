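---
title: "ASL-guided dose painting: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASL-guided dose painting: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslboost)
```

## The problem

Non-enhancing low-grade gliomas show no contrast enhancement on CE-T1
MRI; the visible lesion is the T2-Flair hyperintensity, which mixes true
tumor with edema. Irradiating the whole hyperintensity uniformly limits how
far the dose can be escalated, yet recurrence concentrates where the tumor
is most active. Arterial spin labeling (ASL) perfusion MRI localizes a
hyper-perfused subvolume inside the lesion without contrast agents, and that
subvolume is a natural target for a simultaneous integrated boost (SIB):
escalate dose where perfusion is elevated, keep the standard prescription
elsewhere, and hold every organ at risk (OAR) under its limit.

`aslboost` implements this analysis end to end as testable code: a seeded
digital head phantom stands in for patient images, CBF quantification and
threshold segmentation produce the boost target, margin expansion builds the
clinical target cascade, a simplified dose model simulates the competing
plans, and DVH metrics quantify what the boost costs and buys.

## CBF quantification

Single-delay pseudo-continuous ASL gives a closed-form cerebral blood flow
estimate per voxel:

$$\mathrm{CBF} \;=\; \frac{6000\,\lambda\,
(\mathrm{SI}_{\mathrm{control}}-\mathrm{SI}_{\mathrm{label}})\,
e^{\mathrm{PLD}/T_{1,\mathrm{blood}}}}
{2\,\alpha\,T_{1,\mathrm{blood}}\,\mathrm{SI}_{\mathrm{PD}}\,
\bigl(1-e^{-\tau/T_{1,\mathrm{blood}}}\bigr)}
\quad[\mathrm{ml}/100\,\mathrm{g}/\mathrm{min}]$$

with defaults $\lambda = 0.9$ ml/g, $T_{1,\mathrm{blood}} = 1.65$ s,
$\alpha = 0.85$, $\tau = 1.5$ s, $\mathrm{PLD} = 2.025$ s. The factor 6000
converts ml/g/s to the customary ml/100 g/min. All times are carried
internally in seconds; `asl_parameters(..., time_unit = "ms")` accepts the
millisecond values consoles print, and a plausibility guard rejects a
$T_{1,\mathrm{blood}}$ outside 0.5–3 s after conversion, so a unit mistake
fails loudly instead of silently scaling CBF by $10^3$. With the defaults
the scalar coefficient multiplying the normalized difference signal is
$\approx 1.10003 \times 10^4$.

Noise-driven negative CBF voxels are kept by default: clamping at zero
biases every region mean upward, and region means are exactly what the
relative-CBF reference uses. A `clamp_negative` flag exists for display
purposes. Voxels whose proton-density signal falls below $10^{-9}$ of the
in-mask median are reported and masked out rather than propagated as
infinities.

The package quantifies one (already averaged) control/label pair. Clinical
acquisitions average many pairs before quantification; whether averaging
happens before or after the closed form is immaterial for the mean (the
model is linear in the difference signal), so the single-pair convention is
the simpler faithful choice.

## The relative-CBF reference and segmentation

Absolute CBF varies across subjects; the segmentation therefore uses
relative CBF: each voxel divided by the mean CBF of a reference region. For
a unilateral lesion the reference is the lesion mask mirrored across the
mid-sagittal plane intersected with gray matter (contralateral mirrored
gray matter). The mid-sagittal plane is taken as the grid's central
x-plane; correcting real-data head tilt by registration is out of scope
here, which is one reason the phantom generates perfectly aligned anatomy.
For a midline lesion the mirror would overlap the lesion itself, so a
configured insula-analog gray-matter region serves as reference instead.

GTV-ASL is the set of GTV voxels with rCBF **strictly greater than 1.4**.
The strict inequality is deliberate (a `strict = FALSE` flag supports
sensitivity checks), the threshold is applied to the raw rCBF map (no
pre-smoothing), and no connected-component or minimum-volume filtering is
applied: the clinical workflow's manual radiologist edit is not
reproducible, so the automatic rule is kept pure. An empty GTV-ASL is not
an error — the dose-painting plans then degenerate to the conventional
plan, mirroring the clinical fallback, and the condition is flagged in the
run's warnings.

## Target-volume cascade

From GTV and GTV-ASL the cascade is pure geometry:

* CTV = GTV + 10 mm (microscopic spread), PTV = CTV + 5 mm (setup margin),
  PTV-ASL = GTV-ASL + 3 mm;
* GTV-SUB = GTV ∖ GTV-ASL and PTV-SUB = PTV ∖ PTV-ASL.

Margins are physical distances: a voxel joins the expansion when its centre
lies within the margin (Euclidean, in mm, honoring anisotropic spacing) of
some mask-voxel centre. The implementation computes an exact Euclidean
distance transform (a separable lower-envelope algorithm in C++) and
thresholds it, which the test suite checks against a brute-force all-pairs
oracle on small grids. Voxel-centre-to-voxel-centre distance is the
convention for every reported volume. CTV and PTV are clipped to the body
mask by default (`margin_policy(clip_to = ...)`), the usual external-beam
convention.

## The dose model

The commercial optimizer and dose engine are deliberately replaced by an
explicit, simple model — the largest gap between this package and the
clinical workflow, and worth stating loudly: the package reproduces the
*metric definitions, prescription logic and feasibility rules* of
SIB dose painting, not the output of a clinical IMRT optimizer.

`simulate_plan()` works in four steps:

1. **Aperture painting.** The prescription is painted uniformly on the
   target expanded by `aperture_margin_sigma × penumbra_sigma_mm` (default
   3σ = 15 mm). The margin emulates the boundary fluence enhancement an
   optimizer uses to carry the prescription to the target surface; without
   it the blurred field sags over the entire outer centimetre of the PTV.
2. **Penumbra.** The painted field is convolved with an isotropic Gaussian
   (`penumbra_sigma_mm`, default 5 mm), the model of lateral scatter and
   beam penumbra. σ = 0 is the exact box-dose limit, useful for tests.
3. **Plans 2–3 are built on plan 1.** The plan-1 field is normalized so the
   mean PTV dose equals the baseline prescription; the boost increment is
   painted on the PTV-ASL aperture with amplitude chosen so the mean
   PTV-ASL dose reaches `baseline × (1 + escalation)`; the sum is then
   renormalized multiplicatively to the PTV-ASL mean. This mirrors the
   clinical sequence (the painted plans are derived from the approved
   conventional plan) and keeps the final multiplicative normalization
   within a fraction of a percent of unity.
4. **Cap and coverage trim.** Plans 1–2 cap every voxel at 110% of its
   structure-local prescription (boost inside PTV-ASL, baseline elsewhere)
   and re-verify the normalization to within 0.5%, iterating cap and
   renormalization (at most 20 fixed-point steps); plan 3 applies no cap.
   Finally the dose is scaled up within the 0.5% normalization tolerance
   until the baseline prescription covers `coverage_goal` (default 95%) of
   the PTV, and the cap is re-applied.

The coverage trim deserves its own paragraph, because it resolves a real
tension rather than hiding one. After mean-dose normalization, coverage at
the full prescription equals the fraction of PTV voxels above the PTV's own
mean — a scale-invariant property of the dose *shape*. Any Gaussian-blurred
field has a radially graded rim deficit, and for a 5 mm penumbra on a
~40 mm PTV that shape property tops out well below a 95% coverage goal no
matter how generous the aperture. Clinical optimizers face the same
trade-off and resolve it by letting the normalization point float slightly;
the model does the same, explicitly and boundedly: the trim never moves the
normalization residual beyond the 0.5% tolerance that the normalization
contract itself grants, and the cap is re-applied afterwards so the cap
contract stays exact to $10^{-6}$ Gy.

One consequence of the cap rule is worth noting: a *global* 110%-of-baseline
cap (exposed as `cap_reference = "baseline"`) is mathematically
incompatible with an escalation above 10%, since the boost prescription
itself would exceed the cap. The structure-local reading (the default) is
therefore the only one consistent with a 20% boost; `simulate_plan()`
diagnoses the infeasible combination with an explicit error.

Field-angle machinery has no analog in a kernel model and is out of scope.
Dose is computed and evaluated on the phantom grid (2 mm by default; the
clinical planning grid is 2.5 mm); `resample_volume()` provides trilinear
resampling when a different dose-grid spacing is wanted.

## DVH conventions

All plan metrics come from cumulative DVHs with 0.1 Gy bins:

* **Voxel counting.** A voxel is wholly in or out of a structure; no
  sub-voxel partial-volume weighting. Absolute metrics on small structures
  (the 0.16 cc lenses) are sensitive to this and should be read with the
  voxel volume in mind.
* **Dx% interpolation.** Linear between cumulative bin edges, ties broken
  toward the higher dose (the reported value is a dose the hottest x% is
  guaranteed to receive), and results clamped to the observed dose range so
  uniform-dose identities are exact. A sorting oracle reproduces every
  reported dose point within one bin in the tests.
* **D0.1cc** is `dose_at_volume(0.1 cc / structure volume)`; structures
  smaller than 0.1 cc return their minimum dose with a warning.
* **Dmax** is the maximum in-mask voxel dose, with no near-maximum
  smoothing — that is what the constraint table means by it.
* **CI and HI.** $CI = V_{t,ref}^2/(V_t\,V_{ref})$ at the baseline
  prescription isodose by default (configurable to 95% of it);
  $HI = (D_{2\%}-D_{98\%})/D_{50\%}$ computed per structure, with the PTV's
  HI reported as the plan's headline value.
* The paper-style bin width is unknown, so one bin width of tolerance is
  attached wherever dose points are compared.

## The phantom: what it emulates and what it does not

The default phantom is a 128×128×96 grid at 2 mm isotropic (fine enough to
resolve the lenses; the spacing, shape and every radius are configurable):
a spherical brain (r = 80 mm) with a gray-matter shell over white matter, a
25 mm edema-like GTV in the left hemisphere containing a 10 mm
hyper-perfused core placed off-centre (real hyper-perfused subvolumes abut
the edema boundary, and an off-centre core lets the boost visibly perturb
the conformity of the painted plans), the cranial OARs (brain stem,
eyeballs, lenses, optic nerves, chiasm) as analytic solids, and an
insula-analog reference region. Ground-truth CBF is 60 (gray), 25 (white),
30 (edema) and 120 (core) ml/100 g/min — the core's rCBF of 2.0 clears the
1.4 threshold, edema's 0.5 does not. Published values for gray and white
matter motivate the tissue levels; the edema and core levels are plausible
choices, not literature constants, because absolute CBF in these
compartments is patient-specific.

ASL signals are generated by inverting the quantification equation —
`asl_pd` is constant per tissue, the control-minus-label difference is set
voxelwise to `truth_cbf × pd / K` — so with `noise_sd = 0` quantification
reproduces the ground truth to floating point, which the tests assert at
$10^{-6}$ ml/100 g/min. Gaussian noise (default SD 0.5 signal units,
per-voxel CBF noise ≈ 8 ml/100 g/min, plausible for an averaged series) is
added independently to control and label; a single noise knob emulates the
multi-excitation averaging of a clinical acquisition. All randomness flows
from one seed, and identical configurations are bit-identical.

What the phantom does **not** emulate: MR physics (coil sensitivity, EPI
distortion, background suppression), motion, partial-volume mixtures,
anatomical asymmetry, and — importantly for the dosimetric numbers — the
clinical proximity of OARs to the target. In the default geometry the brain
stem sits ~56 mm from the GTV centre, so its D0.1cc is far below both the
54 Gy limit and the ~50 Gy values seen when a real tumor abuts the
brainstem. Passing tests therefore demonstrate that the pipeline's rules
and metrics behave correctly, not that any particular patient's plan is
feasible.

Structures are rasterized by voxel-centre inclusion of analytic solids, so
every analytic volume is an exact oracle for its mask (the discretization
error shrinks with spacing, which a test checks across two resolutions).

## Problem sizes and runtime

The default end-to-end run (1.57 M voxels, three plans) takes a few seconds
on one core: the distance transform is exact and linear-time, and the
Gaussian is applied as three kernel-matrix products. Unit tests use a
coarser 3 mm phantom of the same anatomy; the full-resolution default is
exercised in the acceptance tests and by `scripts/acceptance.R`.

## Interface choices

The package's interface is its functions — `run_pipeline()` for the whole
analysis, the per-stage operations for everything else — plus NIfTI, CSV
and JSON artifacts written by `run_pipeline()` when an output directory is
set, and YAML/JSON configuration via `read_run_config()` with
argument-level overrides. A shell entry point would only wrap
`run_pipeline()` in argument parsing; `scripts/acceptance.R` shows the
pattern for anyone who wants one.

## Known limitations

* The Gaussian-penumbra model has no beams, no fluence optimization, no
  heterogeneity corrections; OAR-proximity trade-offs that drive real plan
  quality are absent.
* No DICOM/DICOM-RT support; NIfTI only, axis-aligned affines only.
* No cohort statistics: the pipeline analyses one synthetic patient per
  run; comparing many runs is left to the caller.
* No radiobiology (EQD2/BED, TCP/NTCP): all comparisons are physical dose.
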