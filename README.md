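# pcdquant

Phantom-based calibration and correction for two-material decomposition in
photon-counting detector CT (PCD-CT).

## The problem

Spectral CT quantifies contrast materials (iodine in water-equivalent
tissue, iron in liver-equivalent tissue) by two-material decomposition in
image space: each voxel's paired low/high-energy CT numbers (LE, HE) are
projected onto the *material line* of slope DER (the dual-energy ratio,
LE = DER · HE) along a line parallel to the *water line* (LE = HE). The
concentration-map (CM) value of a voxel is the weighted blend of the two
projected components,

    CM_measured = (DER·w + 1 − w) · (LE − HE) / (DER − 1),

with `w` a vendor weighting factor, and concentration follows as
`C = CM / α` with `α` in HU per mg/mL.

In practice the base material does not read identically in the two energy
channels: residual scanner-calibration tolerances leave a mismatch
`Δ_base = HE_base − LE_base` of a few HU, and the DER itself drifts with
tube voltage, dose and patient size. Both biases propagate into the
concentration estimate and dominate at low, clinically relevant
concentrations. The correction implemented here is

    CM_corrected = (DER·w + 1 − w) · (LE − HE + Δ_base) / (DER − 1),

with `Δ_base`, DER and `α` measured per scan configuration from a phantom
with rods of known concentration (three ordinary least-squares fits), then
averaged per material and tube voltage into site-specific "mean method"
parameters `Δ_base,avg`, `DER_avg`, `α_avg`:

    C = (1/α_avg) · ( CM_measured + (DER_avg·w + 1 − w) · Δ_base,avg / (DER_avg − 1) ).

The package covers the whole workflow for medical physicists running this
QA: circular-ROI extraction from paired low/high-energy images (NIfTI or a
raw-array fixture format), the calibration fits and their aggregation,
corrected/uncorrected quantification with relative errors, and a synthetic
spectral abdomen phantom generator with known ground truth so everything is
testable without scanner time.

## Worked example

Simulate one phantom configuration (six iodine rods, 0.5–15 mg/mL, 120 kV,
10 HU image noise), calibrate it, and quantify the rods:

```r
library(pcdquant)

spec <- phantom_spec("iodine", kv = "120", dose_pct = 100, seed = 7)
g    <- generate_phantom(spec)
tab  <- extract_measurements(g$pair, g$manifest$rods, area_cm2 = 2)
(rec <- calibrate_configuration(tab, w = 0.5))
#> Calibration record: iodine, 120 kV, 100% dose, fat ring no (6 rods)
#>   delta_base =   -4.358 HU   (LE_base -2.331, HE_base -6.689)
#>   DER        =   2.0942
#>   alpha      =  19.4509 HU per mg/mL   (w = 0.50)

params <- aggregate_mean_method(list(rec))
out <- quantify_with_mean_method(tab, params)
round(out[c("concentration_mg_ml", "concentration_corrected",
            "error_corrected_pct", "error_uncorrected_pct")], 3)
#>  concentration_mg_ml concentration_corrected error_corrected_pct error_uncorrected_pct
#>                  0.5                   0.536               7.290                70.650
#>                  1.0                   1.070               6.987                38.667
#>                  2.0                   1.901              -4.963                10.877
#>                  5.0                   4.976              -0.471                 5.865
#>                 10.0                  10.004               0.039                 3.207
#>                 15.0                  15.013               0.084                 2.196
```

The generator injected `Δ_base = −5` HU and `DER = 2.10`; the calibration
recovers them from the noisy images (−4.36 HU, 2.094). Ignoring the
mismatch biases every rod by a fixed CM offset, so the *uncorrected*
relative error explodes at low concentration (71% at 0.5 mg/mL) while the
corrected estimate stays within a few percent — the whole point of the
method.

A realistic per-configuration parameter table measured on a clinical
PCD-CT is bundled:

```r
mean_method_table(aggregate_study(example_calibration_table()))
```

## Command-line workflow

The four protocol steps are exposed as commands (`inst/cli/pcdquant`):

```sh
pcdquant simulate  --config run.yaml   # synthetic 12-configuration study
pcdquant calibrate --config run.yaml   # ROI extraction + three fits per configuration
pcdquant aggregate --config run.yaml   # per-kV mean-method parameters (report ± SD)
pcdquant quantify  --config run.yaml   # corrected vs uncorrected concentrations
```

`calibrate` also accepts a pre-made ROI measurement CSV (columns
`material,kv,dose_pct,fat_ring,concentration_mg_ml,le_hu,he_hu`) for
centers that measure ROIs in vendor software.

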