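---
title: "Methods: simulating and analysing inversion-time effects in pulsed ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing inversion-time effects in pulsed ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In pulsed arterial spin labeling (PASL), blood water is magnetically
labeled in the neck and imaged after an inversion time TI. The choice of
TI trades signal-to-noise (label decays at the blood T1) against
completeness of delivery (tissue with arterial transit time ATT longer
than TI has received no label at all). Because ATT varies across the
brain — short near the proximal arterial territories (PTA: basal ganglia,
insular and perisylvian cortex), long in the distal territories (DTA:
parietal and occipital cortex) and longest in the watershed zones between
arterial territories — the TI does not bias CBF maps globally but
*regionally*: a short TI (~1500 ms) inflates PTA estimates through
intravascular label still sitting in arteries and deflates DTA estimates
whose bolus has not arrived, while a longer TI (~2000 ms) reverses both
effects. `asltilab` packages a fully synthetic, ground-truth-controlled
version of that comparison: a digital phantom cohort, a closed-form
forward signal model, standard-formula quantification, and the
VOI/voxel-wise Z-score and nonparametric statistical battery used to
detect the region-dependent effect.

# Signal model

The forward model is the single-compartment plug-flow bolus with
QUIPSS-II-style bolus truncation at TI1 and decay at the blood T1. For a
voxel with perfusion $f$ (ml/min/100 g) and transit time $\Delta t$ (ms):

$$
\Delta M(TI) =
\begin{cases}
0 & TI < \Delta t\\[2pt]
2\alpha M_{0b}\dfrac{f}{6000\lambda}\,(TI-\Delta t)\,e^{-TI/T_{1b}} &
 \Delta t \le TI < \Delta t + TI_1\\[6pt]
2\alpha M_{0b}\dfrac{f}{6000\lambda}\,TI_1\,e^{-TI/T_{1b}} &
 TI \ge \Delta t + TI_1
\end{cases}
$$

with durations converted to seconds inside the formula. Assumptions: no
outflow, no exchange-driven change of relaxation (all label decays at
$T_{1b}$), a rectangular bolus, a single TI for the whole volume (no
per-slice timing), and ideal background suppression (static tissue is
nulled without attenuating $\Delta M$). `tissue_delta_m()` implements the
closed form; the test suite checks it against numeric integration of the
underlying bolus kernel to below 1e-6 relative error.

Intravascular contamination is modelled as a boxcar: the labeled bolus
occupies the voxel's arterial compartment (volume fraction `abv`) during
$[\Delta t, \Delta t + TI_1)$ and has cleared afterwards
(`arterial_delta_m()`). The voxel's ATT value serves as both the tissue
and arterial transit time. The clearance threshold is what makes the
mechanism TI-dependent: with $\Delta t \approx 900$ ms and
$TI_1 = 700$ ms, the arteries are still full at TI 1500 but empty at TI
2020.

Quantification (`quantify_cbf()`) inverts the plateau branch — the
standard PASL formula

$$
CBF = \frac{6000\,\lambda\,\Delta M\, e^{TI/T_{1b}}}{2\,\alpha\,TI_1\,M_{0b}},
$$

which is exact when the bolus is fully delivered and attributes *all*
difference signal to perfusion. Applied at TI 1500 to a DTA voxel with
ATT 1800 ms it returns 0 regardless of true perfusion; applied to a PTA
voxel it converts the arterial boxcar into a CBF surcharge of
$6000\lambda\,abv/TI_1$ — about 77 ml/min/100 g at the default
`abv = 0.01`. These two failure modes *are* the phenomenon under study,
so they are deliberately left uncorrected.

$M_{0b}$ is estimated per acquisition from three non-suppressed
calibration images by a saturation-recovery fit
$M(ti) = M_{0t}(1 - e^{-ti/T_{1t}})$ on the grey-matter median signal,
scaled by the partition coefficient (`estimate_m0_blood()`). A global
reference-region fit was chosen over voxelwise calibration for
determinism and robustness at three time points.

## Constants

| constant | default | unit | why |
|---|---|---|---|
| `ti1` (bolus duration) | 700 | ms | the study protocol's QUIPSS-II value |
| `lambda_bp` | 0.9 | ml/g | consensus whole-brain partition coefficient |
| `alpha` | 0.98 | — | PASL labeling efficiency recommendation |
| `t1b` | 1650 | ms | arterial blood T1 at 3 T |
| `m0b` | 1000 | signal units | arbitrary simulation scale |
| calibration TIs/TRs | 1000/1990/4000, 1270/2270/4270 | ms | protocol values |

All are config-overridable and logged with every CBF map
(`constants_used`).

# The phantom

`generate_phantom()` builds a zoned axial stack (default 32 x 32 x 10
voxels): a CSF core, deep nuclei (basal ganglia on the middle slices),
a white-matter annulus, and a cortical ribbon parcellated by polar angle
into 7 VOIs per hemisphere (frontal, parietal, temporal, occipital,
insular, temporomesial, cingulate; labels 1-14), plus basal ganglia (15)
and supratentorial white matter (16). The geometry is synthetic on
purpose — it replaces an anatomical atlas with a label scheme of the same
cardinality and territory semantics, giving exact ground truth with no
external data. Anatomical realism, partial-volume mixtures and lesions
are non-goals.

Territory structure encodes the transit-time physiology:

* **PTA** — basal ganglia, insular cortex, and the innermost
  (perisylvian) shell of the frontal, temporal, temporomesial and
  cingulate VOIs; short ATT (default 900 ± 50 ms across subjects) and
  arterial blood volume `abv_pta` (default 0.01).
* **DTA** — parietal and occipital cortex and white matter; long ATT
  (1800 ± 75 ms).
* **Watershed** — the remainder of the mixed VOIs; the longest ATT
  (1900 ± 75 ms). Giving the watershed its own, longer distribution
  follows the physiology (border zones have the longest transit times)
  and is also what makes the cortical CBF distribution three-levelled;
  with only two levels the voxel-wise Z-score of any distal VOI would be
  the scale-invariant constant $-\sqrt{w/(1-w)}$ at *both* TIs and no
  Z-score effect could exist.

Within-territory voxel jitter (ATT sd 25 ms, CBF sd 5 ml/min/100 g) and
across-subject draws (GM CBF 60 ± 6, WM 25 ± 3 ml/min/100 g) are
truncated Gaussians — the simplest distributions with controllable
moments. All draws come from a deterministic stream keyed by
`(seed, subject)`, so identical configurations reproduce bit-identical
cohorts.

## The mixed-VOI fraction

Frontal and temporal (and temporomesial/cingulate) VOIs mix both
territories so that their regional means show no TI effect — the
"averaged-out" null. The PTA fraction that balances the two opposing
biases follows from the kinetic model: per PTA voxel the TI-2020-minus-
TI-1500 difference is
$d_P = f(\Delta t_{P}-TI+TI_1)/TI_1 - 6000\lambda\,abv/TI_1 \approx -69$
ml/min/100 g at the defaults, per watershed voxel
$d_W = f\,\mathbb{E}[(2020-\Delta t_W)_+]/TI_1 \approx +10$. The balance
$p^* = d_W/(d_W - d_P) \approx 0.13$ sets the default `mixed_pta_frac`.
The band is assigned per VOI by radius ranking, so every mixed VOI gets
the configured fraction exactly (up to one voxel). This derivation is
part of the generator's design — the phantom is *constructed* to express
a null there, mirroring how real frontal/temporal VOIs straddle both
territories.

## Covariates and their regime

`cohort_config()` couples ATT to subject covariates: sedated subjects get
`sedation_att_shift` added, and age contributes
`age_att_slope * (age - mean age)`. How a longer ATT changes the
TI-dependent variation $d = CBF_{2020} - CBF_{1500}$ is *regime
dependent*: $d(\Delta t)$ rises on $(TI-TI_1, 2020-TI_1)$, is flat, then
falls for $\Delta t > 1500$. In the reference cohort (DTA ATT 1800 ms,
past the peak) a longer ATT *shrinks* the distal variation; the
sign pattern in which younger/sedated (longer-ATT) subjects show
*larger* distal variations and deeper proximal contamination requires
baseline ATT below the short TI — which is also where the arterial
clearance threshold ($\Delta t + TI_1$ vs 1500 ms) drives the proximal
sign. `covariate_cohort_config()` therefore uses ATT 820 ± 40 (PTA) and
1250 ± 60 ms (DTA), where the model produces negative age correlations
in distal VOIs and positive in proximal ones. Users studying covariates
should be aware that outside this regime the correlations legitimately
invert.

# Regional and voxel-wise analysis

* `regional_table()` intersects each cortical VOI with the grey-matter
  segmentation (the white-matter VOI with white matter) before averaging,
  and reports the cortical Z-score
  $Z_{VOI} = (CBF_{VOI} - \overline{CBF}_{cortex})/\sigma_{cortex}$,
  where the cortex reference is the voxel-weighted union of the 14
  cortical VOIs. Empty intersections raise a classed warning and drop the
  VOI rather than failing silently.
* `z_map()` is the voxel-wise counterpart over the grey-matter mask; by
  construction in-mask values have mean 0 and sd 1.
* `subtraction_map()` and `across_subjects_sum()` reproduce the
  subtraction-map analysis: per-subject difference maps are binarized at
  *strict* sign (exact zeros count in neither direction — the threshold
  had to be fixed somewhere, and strict sign is the only choice that
  keeps the positive and negative counts disjoint) and summed across
  subjects. All subjects share one grid, so the resampling step of a
  real common-space analysis reduces to identity; the operation accepts
  a resampling hook to keep the pipeline shape.

Both Z formulas use the population (n-denominator) standard deviation by
default; the convention is switchable (`sd_type = "sample"`) and recorded
in the study log, since nothing pins it down externally and the paired
test is invariant to the choice in all but borderline cases.

# Statistics

The battery is deliberately nonparametric and paired within subject:

* `wilcoxon_signed_rank()` — zero differences dropped; for up to 15
  non-zero pairs the two-sided p comes from full enumeration of all
  $2^n$ sign assignments of the midranks (exact under ties, unlike the
  textbook null tables); beyond that a normal approximation with
  tie-corrected variance and continuity correction. With 5-subject
  scan-rescan cohorts the smallest achievable two-sided p is
  $2/2^5 = 0.0625$, so that design can never produce a false positive at
  0.05 — matching its role as a stability control.
* `benjamini_hochberg()` — the literal step-up adjustment, applied within
  one family per analysis block (CBF comparisons; Z-score comparisons;
  sedation; scan-rescan), since each block is interpreted as its own
  set of hypotheses.
* `mann_whitney_u()` — exact enumeration up to 12 pooled observations,
  tie-corrected normal approximation above.
* `dagostino_pearson()` — the K² omnibus (transformed skewness +
  kurtosis), undefined below n = 8; implemented from the standard
  formulas as no installed package provides it.
* `pearson_with_category()` — correlation, regression slope and R², with
  the conventional |rho| bins (0.2/0.4/0.6/0.8).

Tests verify every exact path against independent full-enumeration
oracles, BH against `p.adjust` and a literal step-up loop, and the K²
test by simulation (type-I error ≈ 5% under the null, near-complete
power against an exponential alternative at n = 200).

# Numerical choices and degenerate inputs

* Truncations: ATT and CBF draws are clamped at 0; `abv` is validated
  into [0, 0.05].
* The saturation-recovery fit uses `nls` (port algorithm) with positive
  bounds; degenerate designs (fewer than 2 distinct time points) and fit
  failures raise distinct classed errors.
* Negative CBF from noise is retained in maps and regional means —
  clipping would bias the paired differences.
* All-zero difference vectors return a flagged degenerate p = 1 instead
  of erroring, so noiseless null designs flow through the pipeline.
* Exact-test tail comparisons use a 1e-9 slack on the rank statistic to
  absorb floating-point ties from midranks.
* Enumeration cutoffs (15 signed-rank, 12 Mann-Whitney) keep the exact
  path at or below a few hundred thousand evaluated assignments.

# Problem sizes

The packaged analyses run on the default 32 x 32 x 10 grid with 8
label/control pairs and 3 calibration volumes per acquisition;
12-subject two-TI cohorts and 20-replicate batteries complete in about a
minute each on one core. The module tests use a 16 x 16 x 6 grid. These
sizes were chosen so the full battery is comfortably interactive while
keeping every VOI populated with tens to hundreds of voxels.

# What passing tests do and do not show

The phantom expresses the territory physiology with exact ground truth,
pre-aligned grids, ideal background suppression, Gaussian noise, and no
motion, drift, slice-timing or partial-volume effects. Reproducing the
direction pattern here shows that the *pipeline* — model, quantification,
Z-scores, testing scheme — faithfully transmits a transit-time/arterial
contamination contrast into the published statistical signature. It does
not validate magnitudes on real scanners, nor the registration and
motion-correction steps a clinical pipeline needs (both are explicitly
out of scope), and real paediatric ATT/CBF distributions are broader and
spatially smoother than the zoned phantom. Scan-rescan behaviour is
similarly idealized: its null holds by exact-test granularity plus
noise-only differences, not because physiological session effects were
modelled.
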