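# lungsurf

Quantitative mapping of instilled surfactant distribution in
contrast-enhanced UTE lung MRI.

## The problem

Exogenous surfactant, administered through a thin tracheal catheter, only
works where it arrives: in the alveolated periphery of the lung, not
pooled in the central airways. When the surfactant solution is mixed with
a small volume of a gadolinium-based contrast agent, 3D ultra-short echo
time (UTE) MRI localizes it at millimetre resolution, and the agent's
relaxivity turns signal into concentration. `lungsurf` is for imaging
scientists who want that full quantification chain -- from raw
multi-flip-angle magnitude volumes to regional distribution metrics -- as
tested, composable R functions, validated against a digital thorax
phantom with known ground truth.

## The model

The spoiled gradient-echo (UTE) signal at flip angle α, repetition time
TR and longitudinal relaxation time T₁ is

    S = A · sin α · (1 − E₁) / (1 − cos α · E₁),   E₁ = exp(−TR/T₁)

with A a scanner scale constant. The pipeline:

1. **Calibration** — fit (A, R₁pre) to the mean ROI signals of the
   pre-administration series at four flip angles (5°, 8°, 16°, 25°;
   TR = 3.7 ms), taken in a distal lung region free of solution
   (`fit_pre_calibration()`);
2. **R₁ mapping** — invert the 25° post-administration volume pixel-wise
   with the calibrated A (`r1_post_map()`);
3. **Concentration** — C = (R₁post − R₁pre)/r₁ with
   r₁ = 3 mM⁻¹s⁻¹ per Gd³⁺ ion (`concentration_map()`); mM × mL gives
   the voxel Gd amount in µmol (`gd_amount()`);
4. **Regions** — a voxel-wise partition into total lung volume (TLV),
   peripheral (PER) and central (CER) enhanced regions, ingested from
   external masks (`ingest_labels()`) or produced by a transparent
   threshold-plus-morphology fallback segmenter (`fallback_segment()`);
5. **Metrics** — the peripheral distribution fraction
   PDF = 100·Q(PER)/(Q(PER)+Q(CER)), the peripheral volume fraction
   PVF = 100·V(PER)/V(TLV), slice-wise quantity/area profiles along
   anatomical axes, maximum intensity projections, and per-specimen /
   cohort summary tables (`specimen_report()`, `run_cohort()`).

The digital thorax phantom (`phantom_spec()`, `build_phantom()`) renders
two ellipsoidal lungs, a four-generation airway tree with enhancing inner
wall shells, and dorsally pooled peripheral blobs into multi-flip-angle
UTE volumes with known concentration, labels and noise — the test
substrate for every stage. See the methods vignette
(`vignettes/lungsurf-methods.Rmd`) for the assumptions and parameter
rationale.

## Worked example

Build a default phantom (SNR 50) and run the full pipeline against its
ground-truth labels:

```r
library(lungsurf)
params <- acquisition_params()
ds <- build_phantom(phantom_spec(seed = 42), params)
run <- run_specimen(dataset = ds, specimen = "demo")
print(run$calibration)
print(run$report)
```

```
pre-administration calibration: A = 99.9958, R1_pre = 1.25 s^-1 (T1 = 800.1 ms)
  relative RMS residual 0.000269; ROI voxels: 96437
specimen report demo
  enhanced volume 34.0 mL; mean T1_post 105.7 ms; mean C 2.94 mM
  Gd amount 100.0 umol; PDF 84.0%; PVF 32.5%
  volumes: TLV 92.7, PER 30.1, CER 3.9 mL
```

The calibration recovers the phantom's tissue relaxation rate
(R₁pre = 1.25 s⁻¹, i.e. T₁ = 800 ms) and scale constant (A = 100) from
the noisy flip-angle series; the integrated Gd amount matches the 100
µmol the phantom instilled, and the distribution metrics (PDF 84.0%,
PVF 32.5%) hit the generator's targets. The `analysis/` directory chains
this over a six-specimen cohort:

```sh
Rscript analysis/01_build_phantom_cohort.R   # render the cohort (targets per specimen)
Rscript analysis/02_quantify_specimens.R     # calibration -> R1 -> concentration -> amounts
Rscript analysis/03_segment_fallback.R       # fallback segmenter vs ground truth (Dice)
Rscript analysis/04_distribution_profiles.R  # cohort tables, profiles, MIPs
```

Tables land under `results/`; bulky volume artifacts under `scratch/`.

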