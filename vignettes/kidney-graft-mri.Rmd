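---
title: "Non-invasive MRI assessment of cardiac-death kidney grafts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive MRI assessment of cardiac-death kidney grafts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renograft)
```

## The problem

Kidneys from donation-after-cardiac-death (DCD) donors suffer warm ischemia
between circulatory arrest and harvest. A hallmark lesion is red-cell
congestion (RCC): erythrocytes trapped in the capillary plexus of the inner
stripe of the outer medulla (IS), plugging the microcirculation. In the rat
model this package emulates, grafts harvested 0 or 1 hour post-mortem
(CD0h, CD1h) function after transplantation, while 2-hour grafts (CD2h) do
not — and the difference is visible *before* transplantation with two
non-invasive MRI contrasts:

* **BOLD (T2\*-weighted) MRI.** Deoxyhemoglobin in trapped red cells
  shortens T2\*, so congested tissue loses signal in a gradient-echo image.
* **Diffusion-weighted MRI.** The apparent diffusion coefficient (ADC)
  rises with interstitial edema and falls with cellular edema. The failing
  phenotype couples an IS ADC *increase* (interstitial edema) with an outer
  stripe (OS) ADC *decrease* (cellular edema) — a pattern thought to lock
  red cells into the IS.

No imaging data accompany the published study; what survive are the
acquisition protocol and per-compartment summary tables (mean ± SD over
n = 3 kidneys). The package therefore rebuilds the entire analysis as a
simulation study: digital phantoms carry the published values as ground
truth, the forward models generate images, and the measurement chain must
recover what was assigned. Everything downstream of the images — mapping,
ROI transfer, statistics, the viability call — is the same code a user
would point at real TIFF/NIfTI stacks.

## The phantom

`make_kidney_phantom()` draws a 2D longitudinal kidney section on a
256 × 128 grid spanning 100 × 50 mm (0.390625 mm pixels, printed as
0.39 mm). The four quantified compartments — cortex (CTX), outer stripe
(OS), inner stripe (IS), inner medulla (IM) — are concentric elliptical
bands, IM innermost. The source describes no compartment areas, so the area
shares are a design choice fixed once: CTX : OS : IS : IM = 40 : 15 : 15 : 30
percent of kidney area, which yields anatomically plausible band widths
(roughly 2–4 mm) at this resolution. One 1 mm slice is modelled; there is
no 3D volume.

Each kidney draws one T2\* and one ADC value per compartment from the
condition preset's Normal(mean, SD) — the kidney, not the pixel, is the
biological replicate, matching the tables' n = 3. `zero_sd = TRUE`
collapses the draw to the means exactly; this is the regime used for
recovery experiments. Presets default to the published tables:
T2\*/ADC for CD0h/CD1h/CD2h, unperfused and after University of Wisconsin
(UW) solution perfusion, plus the CD0h pre/post 3 h UW incubation pair.

RCC lesions are clustered blobs (top-k pixels of a Gaussian-smoothed noise
field) covering an exact per-compartment pixel fraction. Severities are
free parameters — the published area quantification exists only as figure
bars — and default to 0.35/0.40 of the IS for CD1h/CD2h with small loads
elsewhere, partially washed out of CD1h (0.10) by UW perfusion. Two
representations coexist: the boolean mask (histology truth, lesion
visualisation) and an optional multiplicative T2\* reduction inside the
mask (`rcc_t2star_factor`, 0.35 by default in the phantom constructor).
For every recovery and acceptance computation the factor is set to 1,
because the published compartment means were measured over ROIs that
*include* congestion — they are already the compartment-level truth, and
darkening lesions on top would count the effect twice. The reduction is
kept for contrast studies where one wants visible hypointense bands.

## Forward models

`simulate_gre()` implements S(TE) = S0_eff · exp(−TE/T2\*) per pixel;
`simulate_dwi()` implements S(b) = S0_eff · exp(−b · ADC). T1 and
flip-angle steady-state weighting are deliberately absorbed into S0_eff:
each sequence in the protocol uses a single TR/flip setting, so those
factors are a constant multiplier that cancels from every quantity the
analysis uses (ratios, log-slopes). Signal units are arbitrary
(S0_eff = 1000 in tissue); no scanner scaling, k-space effects,
partial-volume blurring or susceptibility artifacts are modelled.

`add_noise()` offers Gaussian and Rician (magnitude-MRI) noise; the
protocol's "two averages" is honoured by averaging independent noisy
replicates, shrinking Gaussian SD by √n. Defaults are noiseless — the
acceptance surface is exact recovery — and the Rician floor
(mean σ√(π/2) on zero signal) is verified by test against direct sampling.

## Parameter mapping

The source reports T2\* values but describes only a single-TE acquisition;
how those values were derived is not stated. Rather than guess, the
package simulates a five-echo series (TE = 5, 10, 20, 40, 80 ms) and fits
ln S = ln S0 − TE/T2\* by log-linear least squares — exact on noiseless
data and cheap at image scale. Pixels with any non-positive signal or a
non-negative fitted slope are marked invalid, never clipped; ROI statistics
exclude them and report the excluded count.

The published ADC equation is printed as ln[S₁+S_h]/(b_h−b₁), which is
dimensionally inconsistent with the stated signal model; the package
implements the standard two-point form ADC = ln(S₁/S_h)/(b_h−b₁) at
b = 0 and 134 s/mm², which reproduces the published value ranges. Negative
ADC estimates (S_h > S₁, unphysical for pure diffusion) are invalidated but
preserved in a diagnostics channel.

The SI ratio follows the published definition directly: per-compartment
single-TE signal intensity divided by the CD0h group mean for that
compartment, computed from the TE = 10 ms frame — not from fitted T2\*.

## ROI protocol and statistics

ROIs are transferred verbatim between co-registered maps ("restore
selection" semantics): `derive_rois()` takes phantom labels directly
(`from_labels`) or reconstructs the concentric bands from the kidney
silhouette alone (`band_geometry`, ≥ 95 % pixel agreement on the default
geometry — the fallback for user images); `transfer_roi()` refuses
mismatched grids rather than resample. Group summaries use the kidney as
replicate (sample SD, n − 1); a useful identity is that {m − s, m, m + s}
has mean m and sample SD exactly s, so any printed (mean, SD, 3) row can be
reconstructed as a raw triple.

`unpaired_t_from_summary()` is the pooled-variance two-sided t-test
computed from (mean, SD, n) alone — the form that recomputes the published
p-values from table cells. Three of the four recomputable cells reproduce
exactly at printed precision; the fourth (unperfused IS ADC at 2 h) lands
at 0.0211 against a printed 0.0213, consistent with the inputs being
printed to three decimals. All tests are two-sided; the printed p-values
are consistent with two-sided tests at kidney-level n = 3, which fixes two
conventions the text leaves open. Tukey comparisons use the
studentized-range distribution (`stats::ptukey`), cross-checked in the
test suite against a 10⁶-draw Monte-Carlo oracle; the paired test exists
for protocol completeness (per-pair differences were never printed, so no
paired p-value is a recovery target).

## The viability rule

`classify_graft()` encodes the predictive claim as an explicit, configurable
rule. Three evidence flags compare a kidney against the CD0h reference:

* `is_si_depressed` — IS SI ratio below the reference mean,
* `os_adc_decreased` — OS ADC below the reference mean,
* `is_adc_increased` — IS ADC above the reference mean,

each by more than `k_sd` reference SDs (default 2). The source gives a
pattern, not thresholds; 2 SD is the package's convention and separates the
published CD0h and CD2h values for all three metrics. The default rule is
the *conjunction* of all three flags: congestion alone (the CD1h phenotype,
whose edema comparisons stay non-significant) must classify as functioning.
Flags use strict inequality with a ~1e−8 relative guard, so a metric
exactly on a boundary never fires. Reference margins default to the
published CD0h summaries (`published_reference()`); the IS SI-ratio
reference SD is propagated from the IS T2\* summary by the delta method,
SD(ratio) = TE · SD(T2\*)/mean(T2\*)², since a ratio of a kidney to its own
group mean has mean 1 by construction. On the noiseless table-value cohort
the end-to-end chain classifies 9/9 kidneys correctly.

The rule encodes the *unperfused* failing phenotype. After UW perfusion the
CD2h signature inverts to an ADC elevation across CTX/OS/IS (interstitial
edema from the perfusate); the default conjunction intentionally does not
fire there, and the cohort-level check for perfused grafts is instead that
ADC exceeds the CD0h reference by > 2 SD only for CD2h. A user studying
perfused grafts should supply a different `rule`.

## Histology

`make_histology_sample()` renders an eosin-like RGB section: white
background, pink tissue, saturated erythrocyte red inside the truth mask,
per-channel Gaussian stain noise (SD 0.02). `segment_rcc()` classifies by
redness r = R − (G+B)/2 at threshold 0.4 — the synthetic stains sit at
r ≈ 0.24 (tissue) and ≈ 0.78 (lesion), so the margin is many noise SDs —
then drops connected components under 5 pixels. Raw-RGB thresholding
suffices because the synthetic stain is separable by construction; no stain
deconvolution or scanner colour normalisation is attempted, and thresholds
are calibrated to this generator only, not to real slides. Dice against
generator truth exceeds 0.95 on lesioned sections (observed ≈ 0.99; the
shortfall is sub-5-pixel blobs removed by the size filter).

## Numerical choices

* Exact lesion counts: requested RCC fractions are realised by rank
  selection, so the fraction error is below one pixel.
* Invalidity is always a mask, never a clip; summaries report exclusions.
* Stack files (TIFF multi-page or NIfTI + JSON sidecar) store data rescaled
  to [0.5, 1] and quantised to float32 before writing; in that band the
  float32 grid is uniform and coarser than TIFF's integer sampling, which
  makes a TIFF ↔ NIfTI conversion bit-exact on re-read.
* All randomness flows through explicit seeds; generators use a private
  RNG stream and restore the caller's state. Identical seeds give
  byte-identical pipeline CSVs.

## Problem sizes and what the tests show

Unit and property tests run phantoms at 64 × 32 (the per-compartment
structure is scale-free); recovery/acceptance computations use the full
256 × 128 acquisition matrix. Cohorts are 3 kidneys/condition as in the
source; the type-I-error property uses 10⁴ null simulations at n = 3, and
the Tukey oracle 10⁶ studentized-range draws.

Passing tests demonstrate that the measurement chain is faithful to its own
forward models and that the published summary statistics are internally
reproducible. They cannot show that the generator matches real DCD kidneys:
compartment geometry, lesion morphology, stain appearance and noise are all
idealised, there is no motion, B0 inhomogeneity or perfusion signal, and
the viability thresholds were set against three published kidneys per
condition. Any clinical use would require recalibration on real data.
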