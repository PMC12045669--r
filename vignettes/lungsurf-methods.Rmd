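---
title: "Quantitative mapping of instilled surfactant distribution in lung MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative mapping of instilled surfactant distribution in lung MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Exogenous surfactant, delivered through a thin tracheal catheter, is the
cornerstone therapy for infant respiratory distress syndrome. Whether the
instilled solution actually reaches the alveolated periphery of the lung --
rather than pooling in the large airways -- is exactly the question an
imaging read-out should answer. When the surfactant is mixed with a small
volume of a gadolinium-based contrast agent, contrast-enhanced ultra-short
echo time (UTE) MRI can localize the solution in three dimensions at
millimetre resolution, and, through the agent's relaxivity, turn signal
into concentration.

`lungsurf` implements that quantification chain end to end, together with
a parametric digital thorax phantom that provides ground truth for every
stage. The package is organized as a set of composable functions under
`R/` plus a sequence of narrative analysis drivers under `analysis/` that
build a six-specimen phantom cohort and tabulate its regional distribution
metrics; the drivers are ordinary `Rscript` files, which is the natural
interface for an analysis of this kind, so no separate shell command is
provided.

## Signal model

The acquisition is a steady-state spoiled gradient-echo (UTE) sequence.
Its signal amplitude as a function of flip angle $\alpha$, repetition time
$TR$ and longitudinal relaxation time $T_1$ is

$$S = A\,\sin\alpha\;\frac{1 - E_1}{1 - \cos\alpha\,E_1},
\qquad E_1 = e^{-TR/T_1},$$

with $A$ a scale constant collecting the instrumentation gain and the
equilibrium magnetization. The echo time of the sequence (~0.1 ms) is
short enough that $T_2^*$ decay between excitation and readout is
neglected: the echo time is stored in `acquisition_params()` for
provenance but enters no equation. Flip angles are degrees at every
interface and radians only internally.

For fixed $\alpha$, $TR$ and a calibrated $A$, the model inverts in closed
form,

$$E_1 = \frac{A\sin\alpha - S}{A\sin\alpha - S\cos\alpha},
\qquad T_1 = \frac{-TR}{\ln E_1},$$

valid for $0 < S < A\sin\alpha$. `ute_signal()` and
`invert_signal_to_t1()` implement the pair; a property test checks the
round trip to a relative error below $10^{-10}$ over randomized
$(A, \alpha, TR, T_1)$ grids.

Two numerical policies guard the inversion on real (noisy) maps:

* **Out-of-domain voxels.** Magnitude noise guarantees that some voxels
  exceed the model ceiling $A\sin\alpha$. At map level these become `NA`
  with a running count (`invalid_voxel_count`), never an exception; the
  scalar interface raises an error instead, so programming mistakes are
  not silently absorbed.
* **Near-zero signal.** $S \to 0^+$ drives $T_1 \to \infty$; values above
  a cap (`t1_max`, default 5000 ms) are clamped there and counted. The cap
  only matters in background regions that the analysis mask normally
  excludes.

## Calibration and concentration mapping

The pre-administration relaxation rate is estimated at ROI level, not per
voxel: the mean signal of an ROI in a distal, solution-free lung region is
taken at each of the four flip angles (5, 8, 16, 25 degrees; TR = 3.7 ms),
and `fit_pre_calibration()` jointly fits $(A, R_{1,\mathrm{pre}})$.
The fit starts from the classic variable-flip-angle linearization --
$S/\sin\alpha$ regressed on $S/\tan\alpha$ has slope $E_1$ and intercept
$A(1-E_1)$ -- and is refined by Levenberg-Marquardt least squares on the
signal equation itself. On noiseless input the linearized solve is already
exact, which the tests exploit as an oracle; with two angles it reduces to
the algebraic two-point solution. Estimating $A$ from the same
solution-free ROI and the same fit is the minimal self-consistent reading
of a protocol that calibrates both quantities in enhancement-free distal
lung; a per-voxel pre-administration $T_1$ map is deliberately out of
scope.

The post-administration volume (25 degrees, the angle with the highest
enhancement contrast) is inverted pixel-wise with the calibrated $A$
(`r1_post_map()`), and concentration follows from the relaxivity
relation

$$C = \frac{R_{1,\mathrm{post}} - R_{1,\mathrm{pre}}}{r_1},$$

with $r_1 = 3\ \mathrm{mM^{-1}s^{-1}}$ per Gd$^{3+}$ ion by default
(`concentration_map()`). Noise makes scattered negative concentrations
inevitable; the policy is to keep the raw map, clamp negatives to zero for
amount integration and distribution metrics, and always report the
clamped count. Since concentration is in mM and voxel volume in mL, the
voxel amount $C \times v$ is in micromoles directly; `gd_amount()` sums it
per region.

## Regions and metrics

The grid is partitioned into background, un-enhanced lung ("TLV-only"),
the peripheral enhanced region (PER) and the central enhanced region
(CER), one integer label per voxel, so PER and CER are disjoint by
construction and the total lung volume (TLV) is the union of the three
lung labels. Externally produced label maps are first-class inputs
(`ingest_labels()`), and when only a lung mask, an enhanced mask and a PER
mask are available, CER is built as the complement of PER within the
enhanced set (`region_labels_from_masks()`).

The two distribution metrics are

* **PDF** (peripheral distribution fraction):
  $100\,Q_\mathrm{PER} / (Q_\mathrm{PER} + Q_\mathrm{CER})$, the
  peripheral share of the enhanced Gd amount;
* **PVF** (peripheral volume fraction):
  $100\,V_\mathrm{PER} / V_\mathrm{TLV}$, a pure volume ratio.

Cohort summaries (`summarize_cohort()`, `run_cohort()`) report mean,
sample SD with the $n-1$ denominator (the standard choice at $n = 6$;
the source tables do not state their convention) and CoV = SD/mean.
The cohort PVF is computed as a mean of per-specimen ratios, not a ratio
of summed volumes -- the two differ by several percentage points and only
the former matches the reference tables. Slice profiles
(`slice_profile()`) sum concentration-times-volume per slice along an
anatomical axis, so a quantity profile sums exactly to the region amount
(a conservation property tested to $10^{-10}$ relative); area profiles
report the in-plane mask area per slice, the most direct reading of
"surface per coronal slice". Projections (`mip_render()`) are per-ray
maxima. All of these address axes by anatomical name (right-left,
ventral-dorsal, cranial-caudal) through the axis mapping carried by every
volume, never by raw array index, so a supine "ventral-to-dorsal" profile
is orientation-safe by construction.

## The fallback segmenter

The reference route to the partition is an external mask (manual
delineation or a trained network); the package does not reimplement or
wrap any learning framework. For phantom-driven runs a transparent
fallback (`fallback_segment()`) stands in:

1. enhanced = lung voxels with voxel-wise signal enhancement
   $(S_\mathrm{post} - S_\mathrm{pre})/S_\mathrm{pre}$ above a threshold
   (default 1.0, i.e. a 100% signal increase), minus small connected
   components (default < 20 voxels);
2. CER = the part of the enhanced set reachable from the trachea seed
   through tubes of local radius at least `central_radius_mm` (default
   1 mm), implemented as morphological opening by a metric ball followed
   by 6-connected components from the seed;
3. PER = the remaining enhanced voxels; TLV is the supplied lung mask.

All defaults are declared conventions of this package -- no operator
protocol or intensity threshold exists to copy. The segmenter is
deterministic, invariant to global intensity rescaling (the enhancement
ratio cancels any common gain), and achieves Dice overlap above 0.95
for both PER and CER against phantom truth at SNR 50; the systematic CER
misses are the solution-free tracheal core and sub-radius terminal
branches, both understood consequences of the construction. Connected
components run on the 6-neighbourhood voxel graph via `igraph`;
morphology is implemented by array shifts over the metric-ball offset
set, which handles anisotropic spacing exactly.

## The digital thorax phantom

`phantom_spec()` describes a parametric thorax; `build_geometry()`,
`assign_concentration()` and `render_mri()` (or `build_phantom()` in one
call) produce a dataset with ground truth. Defaults are chosen once to
emulate the ex vivo leporine study conditions:

| parameter | default | why |
|---|---|---|
| grid, spacing | 144 x 144 x 110 at 0.78 x 0.78 x 1.0 mm | acquisition geometry |
| airway generations | 4 | generations resolvable in the segmented central region |
| trachea radius / length | 3.2 mm / 34 mm, shrink 0.78 / 0.76 per generation | CER volume near the 4.75 mL cohort mean |
| lung semi-axes | (16, 21, 32) mm, right x1.05, left x0.95 | TLV near the 91 mL cohort mean, right lung larger |
| total instilled Gd | 100 umol | the delivered dose of the instillation recipe |
| target PDF / PVF | 84% / 32.5% | cohort means of the reference tables |
| dorsal gradient strength | 1.5 | dependent-region pooling of a supine subject |
| right-lung fraction | 0.6 | right-dominant distribution in most specimens |
| wall shell | 2 mm | enhancement observed on inner airway walls, < 2 mm thick |
| tissue T1 / scale | 800 ms / 100 | declared convention for degassed ex vivo lung (no printed value exists) |
| background T1 / scale | 300 ms / 25 | gel-like chamber medium, weak but measurable signal |
| noise | Gaussian, SD set for SNR 50 over PER | see below |

The airway tree is deterministic (no RNG): each generation bifurcates at
38 degrees in alternating lateral/ventral planes with a mild pull toward
the host lung's center. Only blob seeding and rendered noise are random,
drawn from one seeded generator passed explicitly; the same seed gives a
bit-identical dataset, and re-rendering fixed geometry under a different
seed changes only the noise. Peripheral blobs (radius 2-5 mm) are seeded
with probability proportional to $1 + g\,t_\mathrm{dorsal}$, filled per
lung to exact per-side voxel targets so the right lung holds exactly the
configured fraction of the peripheral volume, and kept clear of the
airway tree so the two enhanced regions remain topologically separable.
The last blob is trimmed deterministically, making the truth PVF exact to
voxel rounding.

Concentration is assigned as weights normalized to the target amounts:
the peripheral fraction of the instilled amount over PER with the linear
ventral-to-dorsal weighting (a zero gradient gives an exactly uniform
field), the remainder over the airway wall shells, then rescaled so the
field integrates exactly to the instilled amount -- conservation is by
construction, and survives grid refinement trivially. Rendering applies
$R_{1,\mathrm{post}} = R_{1,\mathrm{pre}} + r_1 C$ per voxel and the
forward signal equation per flip angle.

**Noise model.** Zero-mean Gaussian noise is added to the magnitude
volumes and floored at zero -- not Rician noise; no characterization of
the scanner noise exists to fit, and at the working SNR the two are close
except in air. The SNR is referenced to the mean noiseless
post-administration signal over PER (default 50). The background medium
is given enough proton density that its signal sits several noise SDs
above zero, so the zero floor does not distort a background noise ROI and
`roi_snr()` (mean over a signal ROI divided by the SD over a noise ROI --
itself a declared convention, since no SNR estimator is specified
anywhere) reproduces the configured SNR.

**What the phantom does not emulate** -- and hence what passing tests do
not show about real data: B1/flip-angle inhomogeneity, slice-profile and
$T_2^*$ effects, partial-volume mixing at region boundaries, motion,
radial k-space reconstruction artifacts, realistic instillation fluid
dynamics (blobs are spheres, not acini), perfusion-driven contrast
clearance, and tissue-class heterogeneity beyond a two-class proton
density. The phantom validates the quantification arithmetic and the
pipeline's invariances, not the physiology.

## Problem sizes and verification

The test suite exercises the full default grid (144 x 144 x 110, about
2.3 million voxels) for the end-to-end recovery and segmentation checks --
noiseless recovery of the instilled amount to well below 2%, and recovery
within 10% (amount) and 3 percentage points (PDF) at SNR 50 across five
seeds -- and a same-extent, coarser 96 x 96 x 76 grid for unit and
property tests, a deliberate scaling choice that keeps the suite quick
without changing the physical conditions. The cohort statistics of the
reference tables are recomputed exactly from the shipped per-specimen
CSVs. `scripts/acceptance.R` re-derives all headline numbers from scratch
against the installed package.

## Known limitations

* $R_{1,\mathrm{pre}}$ is a single ROI-level scalar; spatial variation of
  the pre-administration relaxation rate biases concentrations locally.
* The concentration scale inherits the plasma relaxivity value; in lung
  tissue the effective relaxivity may differ, making absolute amounts
  less certain than relative distributions (the ~6% cohort spread of the
  recovered amount around the instilled dose in the reference data is
  consistent with that).
* The fallback segmenter is a geometric proxy: on real images with
  partial-volume boundaries and airway-wall ambiguity its Dice scores
  would be far below the phantom's.
* `read_volume()` trusts the stored array orientation (plus an explicit
  override) rather than interpreting NIfTI orientation codes; data from
  other conventions must be reoriented on ingestion.
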