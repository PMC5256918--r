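---
title: "Methods: quantifying DNA methylation change from chromatin texture, FT-IR spectra and 5mC immunofluorescence"
author: "methylscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DNA methylation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscope)
```

# The measurement problem

Histone-deacetylase inhibitors such as valproic acid (VPA) can trigger DNA
demethylation in tumour cell lines. Because no single assay is conclusive,
demethylation is typically demonstrated by triangulating three independent
read-outs:

1. **Chromatin texture** of Feulgen-stained nuclei. Demethylated chromatin
   decondenses, which shows up in absorbance-calibrated nuclear images as a
   smaller condensed-chromatin area combined with a higher optical contrast
   of the condensed regions that remain.
2. **FT-IR spectroscopy of extracted DNA**. The methyl group of
   5-methylcytosine (5mC) absorbs in the C–H stretching window
   (2992–2850 cm⁻¹); the integrated area of that band tracks methyl-group
   abundance.
3. **5mC immunofluorescence**. Direct antibody staining whose per-nucleus
   mean intensity falls as methylation is lost.

methylscope implements all three quantification chains plus a seeded
synthetic-data layer, so every stage can be validated by parameter recovery
rather than by eye.

# Chromatin texture statistics

A digitized nucleus is a per-pixel absorbance map with square pixels
(default 0.5 µm side, i.e. 0.25 µm² per pixel, the scanning-spot geometry of
scanning microspectrophotometers). Two absorbance thresholds define the
statistics:

* the **removal floor** (default 0.020): pixels at or below it are treated
  as background and removed. The comparison is strict (`> 0.020`), so a
  pixel exactly at the floor is discarded.
* the **condensation cutoff** (default 0.100): nuclear pixels at or above
  it count as condensed chromatin. The comparison is inclusive (`>= 0.100`)
  so that the cutoff value itself is attainable.

From the masks, with pixel area $a$:

$$S_T = a\,|\text{nuclear}|,\quad S_C = a\,|\text{condensed}|,\quad
A_T = \sum_{\text{nuclear}} A_i,\quad A_C = \sum_{\text{condensed}} A_i$$

$$S_C\% = 100\,\frac{S_C}{S_T}, \qquad
\mathrm{AAR} = \frac{A_C/S_C}{A_T/S_T}.$$

The AAR is the mean absorbance of condensed chromatin relative to the mean
absorbance of the whole nucleus. Because the condensed subset is selected
by an absorbance threshold, its mean cannot fall below the overall mean, so
$\mathrm{AAR} \ge 1$ always; this is asserted property-style in the test
suite. Chromatin decondensation moves nuclei towards lower $S_C\%$ and
higher AAR in the scatter plane.

Design choices worth noting:

* The nuclear mask is defined purely by the removal floor. No connectivity
  analysis or hole filling is applied: interior pixels below the floor
  (vacuole-like holes) are excluded from $S_T$. This is the minimal rule
  consistent with automatic point removal; callers who need hole-filling
  can supply their own mask upstream.
* When no pixel reaches the cutoff, $S_C\% = 0$ and the AAR is reported as
  `NA` — the ratio is undefined, not zero or infinite. Downstream
  statistics drop undefined AARs explicitly, with logged counts.

# FT-IR processing chain

The chain mirrors standard spectrometer software practice and is enforced
in this order by state flags on the spectrum object (calling a stage out of
order is an error): per-replicate **baseline correction**, replicate
**averaging**, **normalization**, **windowing**, **deconvolution**.

## Baseline and level-plus-zero correction

Spectra are corrected with a four-point piecewise-linear baseline: the
spectrum's values at four anchor wavenumbers (defaults 3600, 2700, 1800,
800 cm⁻¹ — edges of regions that are flat in DNA spectra) are connected
linearly, extended flat beyond the outer anchors, and subtracted. The
result is then shifted so its global minimum is zero ("level plus zero").
This is the minimal reading of a four-fitting-point baseline-plus-offset
correction; proprietary implementations differ in unknowable details, but
this form is offset-invariant (adding a constant to a spectrum does not
change its corrected output), which the test suite asserts across 200
random spectra.

One consequence matters later: after a *global* minimum shift, any
sub-window of the spectrum retains a small positive pedestal (the window's
floor does not generally touch zero). See the deconvolution section.

## Averaging and normalization

Averaging is the pointwise arithmetic mean of baseline-corrected replicates
on an identical grid; grid mismatches are errors, not silent
interpolations. Normalization divides by the global maximum so the highest
absorption peak equals 1 exactly; it is idempotent and refuses degenerate
(non-positive) spectra. For DNA-like spectra the global maximum falls in
the NH/NH₂ stretching region (3425–3395 cm⁻¹).

## Peak detection

Initial band candidates are negative local minima of the second derivative
of a Savitzky–Golay-smoothed copy of the window (cubic filter, 9 points by
default, shortened automatically for narrow windows). Second-derivative
minima resolve shoulders that never form their own maxima, which is why
this is the standard initialization for band deconvolution.

Candidates must pass two gates, both expressed as a fraction of the
window's absorbance range — the *sensitivity*:

* height above the window floor ≥ fraction × range;
* apex curvature $|y''|$ ≥ fraction × the strongest candidate's curvature.

The second gate rejects noise wiggles riding on the flanks of genuine
bands, which otherwise seed spurious fit components. Sensitivity levels
map to fractions 0.05 (`low`), 0.02 (`medium`) and 0.005 (`high`); these
are implementation constants, chosen so that `low` reproduces the few-peak
regime of conservative commercial peak pickers. Finally, candidates closer
together than half a FWHM are merged (keeping the taller), because two
bands at that separation are not resolvable from the second derivative and
twin guesses make the least-squares problem degenerate.

Initial FWHMs come from the apex curvature of a Gaussian,
$y'' = -8\ln 2\, h / \mathrm{FWHM}^2$.

## Gaussian deconvolution

Bands are Gaussians parameterized by FWHM:

$$G(x) = h \exp\!\left(-4\ln 2\,\frac{(x-c)^2}{\mathrm{FWHM}^2}\right),
\qquad \text{area} = h\,\mathrm{FWHM}\sqrt{\frac{\pi}{4\ln 2}}.$$

The closed-form area is used throughout instead of numeric integration —
it is exact and makes recovery testable to machine precision.

The window model fitted by bounded Levenberg–Marquardt least squares is a
**constant window offset plus the sum of Gaussians**. The offset (bounded
to $[0, \max y]$) absorbs the pedestal left in the window by the global
level-plus-zero shift; this is the role the local-baseline term plays in
commercial peak-fitting software. Without it, the optimizer represents the
pedestal with a spurious window-wide Gaussian whose area contaminates the
band total severely at low signal. Bounds: heights non-negative, centers
inside the window extended by one initial FWHM, FWHM between twice the
grid step and the window width. Convergence tolerances are 1e-10
(relative) with 300 iterations; non-convergence is an error carrying the
residual RMS.

Three kinds of fitted component are pruned before areas are summed (and
`n_peaks` reflects the pruning):

* collapsed peaks, height < 1e-6 × window maximum;
* components stuck at the window-width FWHM bound — these model residual
  background, not a band;
* components with more than half their mass outside the window — edge
  artifacts.

On windows that are exact sums of up to three well-separated Gaussians
(centers ≥ 35 cm⁻¹ apart, FWHM 12–25 cm⁻¹ — configurations identifiable
from second-derivative initialization), the test suite requires recovery
of every parameter and the total area to 1e-4 relative; observed errors
are at machine precision.

## Point-absorbance ratio and quality report

The CH₃-bending / cytosine in-plane ratio divides the absorbances *read at
the nearest grid samples* of 1375 and 1492 cm⁻¹ (ties resolve to the
higher wavenumber) — point absorbances, not fitted heights, because that
is how such ratios are defined operationally. Both ratio directions appear
in the literature; the numerator and denominator are therefore parameters,
with 1375/1492 the default.

The DNA quality report checks three spectral marks of intact, pure, B-form
DNA: a band peak within 1232–1225 cm⁻¹ (the B-form marker, ν_as PO₂⁻), an
absorption shoulder near 1707 cm⁻¹ (base pairing intact, detected as a
negative local minimum of the smoothed second derivative in
1715–1700 cm⁻¹), and the symmetric phosphate peak (1100–1070 cm⁻¹ search
window) sitting below the antisymmetric one (1240–1220 cm⁻¹). Search
windows are padded by half a grid step on each side: on a 4 cm⁻¹ grid
anchored at 3600, a band centered at 1225 cm⁻¹ samples at 1224, which a
literal closed-interval search would miss. Because the two published
formulations of the phosphate-ratio criterion disagree in direction, the
report exposes both raw peak absorbances plus the boolean comparison and
leaves any ratio threshold to the user.

# Immunofluorescence quantification

Images are 8-bit (0–255). Segmentation is Otsu thresholding (or a fixed
threshold) followed by connected components with a minimum-size filter
(default 50 px); touching nuclei merge into one component, a documented
limitation of threshold segmentation. Per-nucleus intensity is the
arithmetic mean of mask pixels, minus the median intensity of all
non-mask pixels by default (a robust background estimate; switch it off
for parity with plain region means). Group comparisons require identical
exposure tags on all images — intensities acquired under different
exposure conditions are not comparable, and mixing them is an error rather
than a warning.

# Group statistics

$S_C\%$, AAR and fluorescence intensities are bounded, often skewed
quantities, so groups are compared with the two-sided Mann-Whitney
(Wilcoxon rank-sum) test. The exact null distribution of U is used when
the combined sample size is ≤ 20 and there are no ties; otherwise the
mid-rank normal approximation with tie and continuity correction is used,
and the result records which path was taken. The exact path is verified in
the tests against an independent exhaustive-permutation oracle for all
group sizes up to 6+6, and the approximate path is calibrated by Monte
Carlo (null rejection rate close to the nominal 0.05 at n = 50 per group).
No multiple-testing correction is applied by default, matching
per-comparison reporting conventions; a Bonferroni flag is available.
Undefined AARs are excluded pairwise with logged counts, never imputed.

# The synthetic-data layer

The generators emulate the *statistical structure* the analysis assumes,
with exported ground truth:

* **Nuclei**: a circular nucleus (default radius 8 µm, pixel 0.5 µm) with
  condensed blobs at one absorbance level over a diffuse background level.
  Blobs are rejection-sampled non-overlapping disks; the last blob is
  trimmed pixel-by-pixel (farthest first) so the realized condensed pixel
  count matches the requested fraction exactly, with a single-pixel fill
  fallback once dense packings stop accepting disks. Tests compare against
  the *realized* fraction in the emitted mask, eliminating discretization
  flakiness. Defaults (diffuse 0.06, condensed 0.25) straddle the
  standard cutoff so the simulation is recoverable; a `recoverable` flag
  enforces this. Noise is additive Gaussian truncated at zero, since
  absorbance is non-negative.
* **Spectra**: sums of Gaussian bands from a shipped DNA-like band library
  (NH/NH₂ 3410, CH₃ stretch 2935, carbonyl shoulder 1707, thymine/adenine
  1661, cytosine 1492, CH₃ bend 1375, ν_as PO₂⁻ 1225, ν_s PO₂⁻ 1080 cm⁻¹)
  plus a polynomial baseline and additive Gaussian noise, on the
  3600–800 cm⁻¹ grid at 4 cm⁻¹. Band heights and widths are generator
  defaults chosen to give a plausible DNA-like profile (tallest band in
  the NH region, ν_s phosphate below ν_as); they are not instrument
  calibrations, since no public reference spectra exist for this system.
  The heights of the two CH₃ bands scale with a methylation-level
  parameter in [0, 1], so the integrated CH₃-window absorbance is strictly
  increasing in methylation.
* **IF images**: non-overlapping disk nuclei whose interior level is
  affine in the methylation level (40 + 180·m intensity units over a
  background of 10), with Gaussian noise, rounded and clipped to 0–255.

The three-group demo labels methylation levels 1.0 / 0.6 / 0.3 as
control / 1 mM / 20 mM. These levels are illustrative dose-series values,
not measured calibrations. The demo's replicate structure uses 50 nuclei
per group for cytometry, 6 / 13 / 9 replicate spectra, and 3 fields of 8
nuclei per group for immunofluorescence.

What the generators deliberately do **not** model: optics (point-spread
function, photobleaching, uneven illumination), Feulgen stain
stoichiometry chemistry, and instrument noise beyond additive Gaussian.
Passing recovery tests therefore demonstrates correctness of the
*computational* chain under the stated statistical assumptions, not
robustness to every artifact of real micrographs and interferograms.

# Test problem sizes and numerical choices

The suite sizes its simulations for thorough yet quick runs: 100 synthetic
nuclei for exact cytometry recovery; 50 random 1–3-Gaussian windows for
the deconvolution oracle; 100 seeded repeats of the three-group FT-IR
chain (6 replicates per group, 1% noise) and of the IF dose series
(noise SD 10), each required to rank the groups correctly in ≥ 95% of
repeats; 200 random spectra for the algebraic invariants; 1000 null
repeats at n = 50 per group for Mann-Whitney calibration. Tolerances are
stated per test: machine-precision equality where the computation is
exact (closed-form areas, mask recovery), 1e-4 relative for nonlinear fit
recovery, and interval checks for Monte-Carlo rates.

# Known limitations

* One nucleus per absorbance map; multi-nucleus Feulgen fields need
  upstream segmentation.
* Gaussian band shapes only — no Voigt/Lorentzian profiles, no
  scattering or water-vapour compensation.
* Threshold segmentation merges touching IF nuclei.
* Peak *counts* from deconvolution depend strongly on the sensitivity
  constants of the detector; they are reported but should not be compared
  across software.
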