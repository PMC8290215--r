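---
title: "Amino-acid PET target volumes for glioma radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid PET target volumes for glioma radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminopet)
```

## The problem

Radiotherapy of glioblastoma is planned on contrast-enhanced T1 MRI: the
gross tumor volume (GTV) is the enhancing lesion plus resection cavity, the
clinical target volume (CTV) adds a 20 mm margin for microscopic spread
clipped at anatomical barriers, and the planning target volume (PTV) adds a
3–5 mm setup margin. Contrast enhancement marks blood–brain-barrier
breakdown, not tumor cells; amino-acid-analog PET tracers such as
¹⁸F-FDOPA accumulate in infiltrating tumor with low normal-brain
background, and the tracer-avid *biological target volume* (BTV) routinely
extends beyond the enhancement. This package quantifies that mismatch: it
segments BTVs by tumor-to-normal (T/N) uptake thresholds, builds the
CTV/PTV, and measures how far and how much of the BTV lies outside the
GTV, whether the standard plan's 95% isodose still covers it, and where
recurrences fall relative to each volume.

All computations operate on co-registered 3D scalar volumes and binary
masks on a common voxel grid. Co-registration is asserted, never computed:
shape, spacing and origin must match exactly, and mixed geometries are
rejected rather than silently resampled (registration and resampling
policy belong to the treatment-planning system, not to this analysis).

## SUV and decay correction

Tissue activity concentration $c$ (kBq/mL) is normalized by the
body-weight method with tissue density 1 g/mL:

$$\mathrm{SUV}(v) = \frac{c(v)}{A_\mathrm{acq} / (w \cdot 1000\,\mathrm{mL})},$$

where $w$ is the patient weight in kg and $A_\mathrm{acq}$ the injected
activity decay-corrected from injection to acquisition time,
$A_\mathrm{acq} = A_\mathrm{inj}\, 2^{-\Delta t / T_{1/2}}$. The decay
factor `decay_factor(dt, half_life)` $= 2^{\Delta t/T_{1/2}}$ uses the
¹⁸F half-life of 109.77 min by default. Correcting the injected activity
before the SUV division is the standard SUV-bw convention; it matters
whenever the uptake period differs between scans.

The normal reference is read from a 1-cm-diameter spherical ROI in the
contralateral white matter at the level of the centrum semiovale. A voxel
belongs to a sphere ROI iff its *center* lies within the radius (boundary
inclusive) — a deterministic rule that the test oracles reproduce
exactly. The reference statistic is the ROI **mean**: guidelines normalize
tumor uptake to mean background, and while some threshold literature
quotes "T/N SUVmax", the max of a homogeneous white-matter ROI is a noise
statistic; `relative_brain_signal()` exposes mean/median/max for
sensitivity analyses.

## BTV segmentation

With threshold ratio $t$ and normal reference $N$,

$$\mathrm{BTV}_t = \{\, v \in \mathrm{brain} : \mathrm{SUV}(v) \ge t\,N \,\}
  \setminus \bigcup \mathrm{exclusions}.$$

The comparison is inclusive (≥) so tie voxels are handled
deterministically. The clinical ratios for high-grade glioma FDOPA
delineation are $t = 1.7$ and $t = 2.0$; both are package defaults and any
list of ratios is accepted. Because the basal ganglia physiologically
accumulate FDOPA at tumor-like levels, an anatomical exclusion mask is
subtracted; in pipeline runs the exclusion is dilated by the PSF FWHM,
since scanner smoothing spreads ganglia signal a few mm beyond the
anatomical boundary and the un-dilated mask would leave an avid rim that
thresholds as tumor. Nesting ($\mathrm{BTV}_{2.0} \subseteq
\mathrm{BTV}_{1.7}$) and invariance under global intensity rescaling
follow from the definition and are enforced as tests.

`keep_components()` offers 26-connected component filtering (all /
largest / touching a seed). The default is **all**: the clinical
delineation procedure this emulates does not document island removal, so
none is applied unless asked for. Ties for the largest component break to
the first component in column-major encounter order.

## Margins

`expand_margin()` is Euclidean-distance expansion via an exact distance
transform (Felzenszwalb–Huttenlocher, applied separably with the physical
spacing of each axis), not structuring-element dilation — so anisotropic
grids are correct by construction and the margin is a true distance in
mm. The expanded set is every voxel of the bound, outside all barriers,
whose center lies within the margin (inclusive) of the nearest mask voxel
center. Barriers are *clipping* masks: their voxels are removed, but
regions behind them remain reachable, matching common planning-system
behaviour; a geodesic variant that models shadowing is deliberately out
of scope. `build_targets()` composes CTV = GTV ⊕ 20 mm (barriers, bound)
and PTV = CTV ⊕ 3 mm (bound only — setup error does not respect
anatomy). The 3 mm default is the lower end of the recommended 3–5 mm
band and is overridable.

## Concordance metrics

* **Surface voxels**: mask voxels with at least one of six face
  neighbours outside the mask (voxels beyond the grid count as outside).
* **Directed HD95** `hd95_directed(source, target)`: the 95th percentile
  of distances from each source surface voxel to the nearest target
  surface voxel, linearly interpolated between order statistics
  (`quantile type 7`, the common default of evaluation toolkits). The
  statistic is directed — GTV→BTV here — and is not symmetrized.
* **Supplementary-volume distances** `svc_distances(gtv, btv)`: over the
  voxels of BTV∖GTV, the max and mean distance to the GTV surface.
  Distances are measured from supplementary *voxels* (not only their
  surface) so the mean reflects how far the added volume extends; both
  are 0 when BTV ⊆ GTV.
* **Overlap decomposition**: within = BTV∩GTV, outside = BTV∖GTV, all
  from integer voxel counts; `total_cc` is defined as the sum of the two
  parts so the conservation identity holds to the last bit in floating
  point.
* **Dose coverage**: the fraction of structure voxels receiving at least
  `iso_fraction × prescription` (inclusive), default the 95% level of
  60 Gy, i.e. 57 Gy.
* **Recurrence analysis**: per reference structure, the fraction of
  recurrence voxels outside it.

On masks up to 20³ voxels every distance operation is tested against an
all-pairs brute-force oracle to 10⁻⁹ mm; the distance-transform path is
exact, not approximate.

## Cross-acquisition harmonization

When the same patient is scanned on two systems (e.g. PET/MR followed by
PET/CT roughly an hour later), absolute SUVs differ by decay and by
scanner calibration. Normalizing each structure's signal to the
contralateral-brain mean cancels any global multiplicative factor — the
decay factor included, since numerator and denominator share it; the test
suite asserts this cancellation explicitly. The decay computation is
therefore retained for reporting absolute signal deviation against the
acquisition gap, not for the ratio. Agreement between paired
brain-normalized signals is summarized by Pearson r (Spearman available),
with a Fisher-z 95% CI; inputs with zero variance raise a defined error
rather than returning NaN.

## The digital phantom

`phantom_spec()` / `generate_phantom()` build the synthetic patient all
tests run against: a brain-shaped ellipsoid of uniform white-matter
uptake (SUV 1.0), two high-uptake basal-ganglia spheres (T/N 2.2 —
FDOPA's striatal uptake is tumor-like), and a radially symmetric tumor
whose contrast-enhancement radius (the GTV) is smaller than its
tracer-avid infiltration radius — the phenomenon the concordance metrics
measure. Profiles are analytic (`step`, `radial_linear`,
`radial_gaussian`), so the iso-contour radius of any T/N ratio is closed
form; for the linear profile with peak $p$ and infiltration radius $R$,
the ratio-$t$ contour sits at $R(p-t)/(p-1)$ — e.g. 13 mm for $p=3$,
$R=20$ mm, $t=1.7$. That closed form is the ground truth for
parameter-recovery tests: noiseless segmentation must reproduce it
voxel-exactly (Dice 1.0), and under the scanner-like degradation used
throughout (4 mm FWHM Gaussian PSF, then 5% multiplicative Gaussian
noise, seeded) Dice ≥ 0.90 at 2 mm voxels.

The dose model is geometric: prescription inside the PTV, linear falloff
over a configurable distance outside (default 20 mm). Coverage metrics
need a plausible field, not a physics simulation. Optional recurrence
blobs are placed by bisection along an oblique ray from the deepest
interior point of a reference structure so that the fraction of blob
voxels outside the reference matches a designed value to within one
voxel; the achieved fraction is recorded in the ground truth. The ray is
slightly oblique to the grid axes so that no whole plane of voxels
crosses the boundary at once.

What the phantom does **not** emulate: anatomical heterogeneity (sulci,
ventricles, edema), irregular tumor shapes, reconstruction artifacts,
spatially correlated noise, registration error between modalities, and
observer variability in GTV delineation. Passing tests therefore
demonstrate correctness of the computational pipeline under known ground
truth, not clinical accuracy on patient images.

Default problem sizes were chosen as a desk-scale compromise: 128³ voxels
at 2 mm isotropic for cohort runs, 64³ at 2 mm for routine tests, and
72–80³ at 1 mm only where analytic accuracy is asserted (iso-contour
volume within 5%, margin ball volume within 3%).

## Numerical choices

* Voxel indices are 1-based in R; a voxel's value represents its center;
  all distances are physical mm from the spacing. Origin is the physical
  coordinate of the first voxel center.
* Inclusive comparisons throughout (threshold ≥, margin ≤, isodose ≥):
  every boundary tie is resolved the same way in the implementation, the
  analytic truth and the oracles.
* NIfTI-1 headers store voxel sizes as float32; the JSON sidecar written
  next to every volume carries float64 spacing and origin (plus the unit
  tag and mask role, which NIfTI cannot carry at all) and wins on read,
  making write→read round trips bit-exact.
* Units are explicit tags (`SUV`, `activity_kBq_per_mL`, `Gy`,
  `arbitrary`); operations declare what they need and reject mismatches,
  so an activity map can never be thresholded as if it were SUV.
* Degenerate inputs raise errors with explicit messages (empty masks
  where a surface or distance is undefined, zero-variance correlation,
  infeasible recurrence geometry); an empty segmented BTV is reported
  with zero volume, zero SVC distances and undefined (NA) HD95 rather
  than an error, since a sub-threshold tumor is a legitimate finding.

## Known limitations

Barrier clipping is non-geodesic (see above). HD95 point sets are surface
voxel centers on both sides; sub-voxel surface models (marching cubes)
would shift distances by fractions of a voxel. The phantom's recurrence
placement assumes the reference structure is thick enough to contain the
blob for small designed outside-fractions and errors otherwise. The
harmonization module correlates whatever paired samples the caller pools;
it does not model within-patient correlation across structures.
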