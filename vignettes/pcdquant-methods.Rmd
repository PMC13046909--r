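---
title: "Phantom-based correction of two-material decomposition: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based correction of two-material decomposition: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdquant)
```

## The decomposition model

Image-space two-material decomposition treats every voxel's paired
low/high-energy CT numbers $(HE, LE)$ as a mixture of a base material
(water- or liver-equivalent tissue) and a contrast material (iodine or
iron). In the $(HE, LE)$ plane, voxels containing only base material of
varying density fall on the *water line* $LE = HE$; voxels containing only
contrast material fall on the *material line* $LE = DER \cdot HE$, where
the dual-energy ratio $DER > 1$ is the material's low-to-high-energy
response ratio. A mixed voxel is projected onto the material line along a
direction parallel to the water line; the intersection
$(HE_{CM}, LE_{CM})$ is its contrast-material component:

$$HE_{CM} = \frac{LE - HE}{DER - 1}, \qquad LE_{CM} = DER \cdot HE_{CM}.$$

The concentration-map (CM) value blends the two components with a vendor
weighting factor $w \in [0, 1]$,

$$CM_{measured} = w\,LE_{CM} + (1-w)\,HE_{CM}
  = (DER\,w + 1 - w)\,\frac{LE - HE}{DER - 1},$$

and concentration follows as $C = CM/\alpha$ with $\alpha$ in HU per
mg/mL.

Two systematic errors corrupt this on a real scanner. First, the base
material does not read identically in the two channels: calibration
tolerances of a few HU per channel leave a mismatch
$\Delta_{base} = HE_{base} - LE_{base}$ that enters the difference
$LE - HE$ as a constant offset, hence a constant CM bias whose *relative*
effect grows as $1/C$. Second, the effective DER varies with tube voltage,
dose and patient habitus. The correction adds the mismatch back inside the
difference,

$$CM_{corrected} = (DER\,w + 1 - w)\,\frac{LE - HE + \Delta_{base}}{DER - 1}
  = CM_{measured} + (DER\,w + 1 - w)\,\frac{\Delta_{base}}{DER - 1},$$

which by construction maps a pure base-material voxel
$(HE_{base}, LE_{base})$ to exactly zero.

Model assumptions: the two channels are co-registered; rod attenuation is
linear in concentration over the calibrated range; a single $(DER,
\Delta_{base}, \alpha)$ triple describes a whole scan configuration.

## Calibration: three least-squares fits

For one scan configuration with rods of known concentrations $C_i$ and
measured ROI means $(LE_i, HE_i)$:

1. **Base intercepts.** OLS of $LE_i$ on $C_i$ and of $HE_i$ on $C_i$; the
   y-intercepts are $LE_{base}$ and $HE_{base}$, and
   $\Delta_{base} = HE_{base} - LE_{base}$.
2. **DER.** OLS of $LE_i$ on $HE_i$ with a free intercept; the slope is
   the DER. Along a rod series only the contrast concentration varies, so
   the points move parallel to the material line and base offsets land in
   the intercept, not the slope.
3. **$\alpha$.** Compute $CM_{corrected,i}$ with the just-fitted
   $\Delta_{base}$ and DER, then OLS of $CM_{corrected,i}$ on $C_i$; the
   slope is $\alpha$. The intercept is kept as a QC diagnostic — it should
   be near zero once $\Delta_{base}$ is corrected for.

The **mean method** averages $\Delta_{base}$, DER and $\alpha$ across all
configurations of one material and tube voltage (dose levels and fat-ring
states pooled), reporting sample standard deviations, and plugs
$\Delta_{base,avg}$, $DER_{avg}$, $\alpha_{avg}$ into the corrected
conversion. Per-rod accuracy is reported as the signed relative error
$(C_{est} - C_{true})/C_{true} \cdot 100\%$, undefined (and withheld) for
rods with $C_{true} = 0$.

## Design decisions

Several choices were genuinely open; the package settles them as follows.

* **Sign of $\Delta_{base}$** is $HE_{base} - LE_{base}$: the unique sign
  for which the corrected CM of a pure base-material voxel is exactly
  zero, which is the stated purpose of the correction. Base materials that
  read higher at low energy therefore get negative $\Delta_{base}$.
* **DER fit orientation.** The material line is defined as
  $LE = DER \cdot HE$ with $DER > 1$, so the fit regresses low-energy on
  high-energy HU and reports the slope. (The opposite orientation would
  yield $1/DER < 1$, inconsistent with every tabulated value.)
* **$\alpha$ fit orientation.** Since $C = CM/\alpha$ and iodine's
  $\alpha$ is ~20–27 HU per mg/mL, $\alpha$ must be the slope of CM
  against concentration, not the reverse.
* **Free intercepts everywhere.** Base offsets make a forced-zero DER fit
  wrong; the $\alpha$-fit intercept is diagnostic. Fits are unweighted
  OLS — no noise- or ROI-size weighting.
* **Weighting factor $w$.** Vendor-specific and not publicly documented;
  it defaults to 0.5 and is a required, recorded parameter. The factor
  $(DER\,w + 1 - w)$ scales $CM_{measured}$, the $\Delta_{base}$ offset
  and the fitted $\alpha$ identically, so the end-to-end concentration is
  invariant to $w$ whenever $\alpha$ is fitted with the same $w$: exactly
  so per configuration, and for the mean method exactly whenever the
  per-configuration DER fits coincide (to first order otherwise, since
  averaging $\alpha_i \propto DER_i w + 1 - w$ over configurations mixes
  slightly different scale factors). The test suite asserts the exact
  cases for $w \in \{0, 0.3, 0.5, 1\}$.
* **Aggregation conventions.** Arithmetic mean and *sample* SD
  ($n-1$ denominator); grouping key is (material, tube voltage); a
  single-configuration group reports SD 0. Report tables round to two
  decimals; all computations keep full precision.
* **Sign preservation.** Negative CM values and concentrations are
  returned as-is; clipping for display is left to callers.

## Numerical choices

* Division guard: $|DER - 1| < 10^{-6}$ (or $DER \le 1$) raises an error
  instead of returning infinities; $\alpha \le 0$ and $w \notin [0,1]$ are
  likewise rejected.
* Units are fixed throughout: HU for CT numbers, mg/mL for concentrations,
  mm for geometry — no implicit rescaling.
* ROI pixel selection uses the deterministic pixel-center-in-circle rule,
  identical for both energy channels, so a brute-force per-pixel oracle
  reproduces it exactly. ROI centers are specified in mm (origin at the
  first-pixel center), so ROI definitions survive resampling.
* On 3-D volumes the ROI mean is computed per slice and averaged with
  equal weights over the requested slice range; the default is the single
  central slice.

## The synthetic phantom: what it does and does not emulate

`phantom_spec()`/`generate_phantom()` rasterize a spectral abdomen
phantom: an elliptic water-equivalent body (300 × 200 mm), an optional
outer fat ring (350 × 250 mm) emulating a larger habitus, and 20 mm
cylindrical rods on a 60 mm ring. Ground truth is the linear spectral
model $LE = LE_{base} + a_{low} C$, $HE = HE_{base} + (a_{low}/DER)\,C$,
plus independent additive Gaussian noise per channel. Defaults, chosen
once as representative of an abdominal PCD-CT protocol:

| parameter | iodine | iron | rationale |
|---|---|---|---|
| concentrations (mg/mL) | 0.5, 1, 2, 5, 10, 15 | 2, 5, 15, 25 | standard spectral-phantom rod series |
| $a_{low}$ (HU·mL/mg) | 26.3 | 8.8 | low-energy response magnitudes of the two materials |
| true DER (140 / 120 kV) | 2.49 / 2.10 | 2.18 / 1.93 | per-kV DER magnitudes of a clinical PCD-CT |
| $LE_{base}$, $HE_{base}$ (HU) | −2, −7 | 57, 52 | few-HU channel mismatch ($\Delta_{base} = -5$) around water / liver |
| noise SD at 100% dose (HU) | 10, 10 | 10, 10 | abdominal-protocol image noise; scaled $\propto 1/\sqrt{\text{dose fraction}}$, ×1.25 with fat ring |
| image | 256 × 256 px, 1.5 mm | same | whole phantom in the field of view at CT-like resolution |

`generate_study()` replicates the full design — 2 tube voltages × 3 dose
levels (100/120/200%) × fat ring on/off — with per-kV ground-truth DER and
dose-scaled noise, under a deterministic per-configuration seed.

The default synthetic ROI is **2 cm²** (radius 7.98 mm), not the 4 cm²
of the documented protocol: a 4 cm² circle (radius 11.28 mm) cannot fit
inside a 20 mm rod (cross-section 3.14 cm²), so a literal
circular-inside-rod 4 cm² ROI is geometrically impossible and the
generator stays inside the rods instead.

The generator is deliberately minimal: it exercises the calibration fits
and the correction, not CT physics. Not simulated: beam hardening,
scatter, detector spectral response, reconstruction-kernel and iterative-
reconstruction noise texture, noise correlation between channels, and
partial-volume effects at rod edges. Passing tests therefore demonstrate
that the estimation pipeline is correct and unbiased under the stated
linear-plus-Gaussian model — not that a specific scanner meets any
accuracy figure. Headline error percentages measured on real scanner
images depend on those un-modelled effects and are intentionally not
claimed by the synthetic studies; what the synthetic studies do reproduce
is the structural behavior: corrected errors bounded by uncorrected ones
when a base-material mismatch is present, and relative error falling as
$1/C$.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use: 1000 randomized inputs for
the algebraic identities (tolerance $10^{-9}$ relative); a noiseless
12-configuration study for exact parameter recovery (tolerance $10^{-6}$
relative, observed ~$10^{-14}$); a 200-replicate Monte-Carlo with 2 HU
Gaussian noise on the rod means for recovery under noise (mean DER within
±0.05, mean $\Delta_{base}$ within ±0.5 HU); and 256 × 256-pixel images
throughout — sizes at which the full pipeline runs in seconds while the
Monte-Carlo standard errors are an order of magnitude below the asserted
bounds.

## Limitations

* The correction addresses *systematic* channel mismatch and DER drift;
  image noise passes through unchanged, so low-concentration estimates
  remain noisy even when unbiased.
* Mean-method parameters are site-, scanner- and protocol-specific;
  parameters calibrated on one configuration set do not transfer.
* Only two-material decomposition from two energy images is supported; no
  projection-domain decomposition, no third basis material.
* DICOM series input is not implemented; images are accepted as NIfTI or
  raw float arrays with a JSON sidecar (HU already applied). Vendor
  spectral private tags are out of scope.
* Automatic rod detection is out of scope: ROI centers are supplied by
  the user (or by the synthetic manifest).
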