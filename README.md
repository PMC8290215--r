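# aminopet

Amino-acid PET biological target volumes for glioma radiotherapy
planning: segmentation, margin construction, and concordance analysis.

## What it does

Contrast-enhanced T1 MRI defines the gross tumor volume (GTV) that
glioblastoma radiotherapy is planned on, but enhancement marks
blood–brain-barrier breakdown rather than tumor cells. Amino-acid-analog
PET tracers (¹⁸F-FDOPA and relatives) accumulate in infiltrating tumor
with low normal-brain background, and the tracer-avid *biological target
volume* (BTV) typically extends beyond the enhancement. `aminopet` is an
R package for quantifying that mismatch on co-registered voxel grids:

* **SUV quantification** — body-weight SUV
  `SUV = c / (A_acq / (w·1000 mL))` with physical decay correction
  `2^(Δt/T½)` (¹⁸F: T½ = 109.77 min), and 1-cm spherical ROIs for the
  tumor and contralateral white-matter reference.
* **BTV segmentation** — `BTV_t = {v ∈ brain : SUV(v) ≥ t·N}` minus
  anatomical exclusions (basal ganglia), at the clinical tumor-to-normal
  ratios t = 1.7 and 2.0; 26-connected component filtering on request.
* **Margins** — CTV = GTV ⊕ 20 mm clipped at anatomical barriers,
  PTV = CTV ⊕ 3–5 mm, via an exact anisotropic Euclidean distance
  transform.
* **Concordance metrics** — directed 95th-percentile Hausdorff distance
  HD95(GTV→BTV), supplementary-volume (BTV∖GTV) max/mean distances,
  within/outside volume decomposition, isodose coverage
  (95% of prescription), and recurrence-overlap fractions.
* **Harmonization** — brain-normalized relative signals that cancel
  scanner scale and decay factors between paired acquisitions
  (PET/MR vs PET/CT), compared by Pearson/Spearman correlation.
* **Digital phantom** — a synthetic patient (brain ellipsoid, hot basal
  ganglia, radial tumor profile with closed-form iso-contours, dose
  field, designed recurrences) providing exact ground truth for every
  pipeline stage.

Volumes and masks are read and written as NIfTI with a JSON sidecar
carrying the unit tag, structure role and float64 geometry.

## Worked example

Generate a digital patient whose tracer-avid region (20 mm) extends
beyond its enhancing core (9 mm), then run the full per-case analysis at
T/N 1.7 and 2.0:

```r
library(aminopet)

spec <- phantom_spec(recurrence = list(radius_mm = 8,
                                       designed_outside_fraction = 0.3,
                                       vs = "GTV"))
res <- run_phantom_case(spec, case_id = "demo")
print(res)
#> <case_result> demo  GTV 2.98 cc
#>  threshold gtv_cc btv_cc within_cc outside_cc outside_fraction hd95_mm
#>        1.7  2.976  8.704     2.976      5.728        0.6580882       4
#>        2.0  2.976  3.928     2.808      1.120        0.2851324       2
#>  svc_max_mm svc_mean_mm covered_fraction
#>           6    3.227534                1
#>           4    2.209617                1
#> recurrence outside fractions:
#>    GTV    PTV BTV1.7   BTV2
#> 0.2996 0.0000 0.0187 0.2210
```

Reading the output: the BTV at T/N 1.7 is 8.70 cc of which 5.73 cc
(65.8%) lies outside the 2.98 cc GTV, reaching at most 6 mm beyond its
surface (mean 3.2 mm); the GTV surface sits within 4 mm of the BTV
surface at the 95th percentile. The tighter T/N 2.0 threshold yields a
smaller BTV with 28.5% outside. Both BTVs are fully covered
(`covered_fraction = 1`) by the 95% isodose of the 60 Gy plan built from
the PTV — the standard margin recipe absorbs the PET-defined extension.
The recurrence blob was designed with 30% of its volume outside the GTV
and is reported at 29.96% (voxelization), entirely inside the PTV.

Cohort aggregation mirrors per-patient reporting:

```r
cases <- lapply(1:5, function(i)
  run_phantom_case(phantom_spec(seed = i), case_id = paste0("case", i)))
summarize_cohort(cases)      # mean / min / max per metric and threshold
write_case_csv(cases, "cohort.csv")
```

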