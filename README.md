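# aslboost

Simulation and evaluation of **ASL-guided simultaneous integrated boost
(SIB) dose painting** for brain radiotherapy, with non-enhancing low-grade
glioma as the motivating setting.

Non-enhancing low-grade gliomas are visible as a T2-Flair hyperintensity
(the GTV) that mixes tumor and edema, which makes uniform dose escalation
costly. Arterial spin labeling (ASL) perfusion MRI identifies a
hyper-perfused subvolume inside the GTV — the region most likely to drive
recurrence — that can receive a selective boost while the rest of the
target keeps the standard prescription. `aslboost` implements that analysis
as a reusable, fully tested pipeline operating on synthetic patients:

1. **Phantom** (`generate_phantom`): seeded digital head with
   gray/white matter, an edema-like GTV containing a hyper-perfused core,
   the cranial OARs, and noisy ASL control/label/PD signal volumes
   generated by inverting the quantification model.
2. **CBF quantification** (`compute_cbf`): closed-form single-delay ASL
   model,

   CBF = 6000 λ (SI_control − SI_label) e^(PLD/T1b) /
   [2 α T1b SI_PD (1 − e^(−τ/T1b))]   [ml/100 g/min],

   with λ = 0.9 ml/g, T1b = 1.65 s, α = 0.85, τ = 1.5 s, PLD = 2.025 s by
   default.
3. **Segmentation** (`relative_cbf`, `mirror_reference`,
   `segment_hyperperfusion`): relative CBF against contralateral mirrored
   gray matter (or an insula reference for midline lesions); GTV-ASL =
   GTV voxels with rCBF > 1.4.
4. **Target cascade** (`build_structure_cascade`): CTV = GTV + 10 mm,
   PTV = CTV + 5 mm, PTV-ASL = GTV-ASL + 3 mm, PTV-SUB = PTV ∖ PTV-ASL,
   using an exact anisotropic Euclidean distance transform.
5. **Plan simulation** (`simulate_plan`): a Gaussian-penumbra stand-in for
   the clinical optimizer produces three plans — conventional (plan 1),
   dose-painted with the 110% maximum-dose cap (plan 2), and dose-painted
   without it (plan 3); escalation 10–20% above the 45–60 Gy baseline,
   normalization to the mean dose of PTV (plan 1) or PTV-ASL (plans 2–3).
6. **Evaluation** (`compute_dvh`, `evaluate_plans`): D2%, D98%, D50%,
   Dmean, Dmax, D0.1cc, coverage, conformity index
   CI = V²_t,ref / (V_t · V_ref) and homogeneity index
   HI = (D2% − D98%) / D50%, plus OAR constraint verdicts (brain stem
   D0.1cc ≤ 54 Gy, eyeball Dmax < 45 Gy, lens Dmax < 10 Gy, optic
   nerve/chiasm Dmax ≤ 55 Gy).

See `vignettes/aslboost-methods.Rmd` for the models, conventions and the
design decisions behind the simplified dose model.

## Worked example

```r
library(aslboost)
result <- run_pipeline(run_config(scenario = "unilateral", seed = 17))
print(result)
```

```
<pipeline_result> unilateral scenario, seed 17
  PTV 252.8 cc, PTV-ASL 8.7 cc (ratio 3.4%)
Plan quality summary
  plan    CI     HI ptv_coverage Dmax
 plan1 0.951 0.0025        0.951 60.1
 plan2 0.907 0.1949        0.950 72.0
 plan3 0.907 0.1949        0.950 72.0
```

Reading the output: the hyper-perfused planning volume is a small fraction
of the PTV, so the 20% boost (72 Gy inside PTV-ASL on a 60 Gy baseline)
is delivered while all three plans still cover ≥ 95% of the PTV at the
baseline prescription. The painted plans pay for the boost with conformity
(CI drops from 0.951 to 0.907) and homogeneity (HI rises from 0.0025 to
0.19) — the expected signature of SIB dose painting. The per-structure
table (printed below the summary) shows plan 2's PTV-ASL at
D2% = D98% = Dmean = 72.0 Gy versus 60.1 Gy in plan 1, the PTV-SUB capped
at 66 Gy (110% of baseline) in plan 2 but reaching 72 Gy in the uncapped
plan 3, and every OAR far below its limit in this phantom geometry.

Setting `output_dir` in `run_config()` additionally writes every volume and
mask as NIfTI, the report tables as CSV, and a JSON manifest with
checksums, timings and warnings.

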