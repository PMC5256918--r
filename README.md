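# methylscope

Quantifies DNA demethylation in cultured cells from the three assay
read-outs commonly combined for that purpose:

* **Feulgen image cytometry** — per-nucleus chromatin-texture statistics
  from absorbance-calibrated nuclear images: the condensed-chromatin area
  fraction *S<sub>C</sub>%* and the average absorption ratio
  *AAR = (A<sub>C</sub>/S<sub>C</sub>)/(A<sub>T</sub>/S<sub>T</sub>)*,
  where *A* and *S* are integrated absorbance and area of the condensed
  (C) and total (T) nuclear compartments. Background pixels at or below
  an absorbance floor of 0.020 are removed; pixels at or above the 0.100
  cutoff count as condensed chromatin. Decondensation (a hallmark of DNA
  demethylation) shows as lower *S<sub>C</sub>%* with higher AAR.
* **FT-IR spectroscopy of extracted DNA** — four-point baseline and
  level-plus-zero correction, replicate averaging, normalization to the
  highest absorption peak, and Gaussian deconvolution of the –CH₃
  stretching window (2992–2850 cm⁻¹), whose band area tracks
  5-methylcytosine abundance. Includes the 1375/1492 cm⁻¹
  bending/cytosine absorbance ratio and a DNA quality report (B-form
  marker at 1232–1225 cm⁻¹, 1707 cm⁻¹ shoulder, phosphate band ordering).
* **5mC immunofluorescence** — per-nucleus mean intensity on the 8-bit
  scale from segmented micrographs, with background correction and an
  exposure-comparability contract.

Group differences are tested with the two-sided Mann-Whitney test (exact
enumeration for small tie-free samples, mid-rank normal approximation
otherwise). A seeded synthetic-data layer generates nuclei, spectra and
micrographs with exported ground truth, so the entire chain is verified by
parameter recovery; `run_pipeline()` executes all arms from one config
into a reproducible report bundle.

## Worked example

The cytometry statistics on a hand-checkable 4-pixel nucleus (pixel side
0.5 µm, so 0.25 µm² per pixel):

```r
library(methylscope)

img <- absorbance_image(matrix(c(0.05, 0.08, 0.15, 0.25), 2), pixel_um = 0.5)
measure_nucleus(img)
#> <nucleus_measurement> S_T 1.00 um^2, S_C 0.50 um^2, S_C% 50.0, AAR 1.5094
```

All four pixels clear the 0.020 floor (S_T = 4 × 0.25 = 1 µm², A_T =
0.53); two reach the 0.100 cutoff (S_C = 0.5 µm², A_C = 0.40), giving
S_C% = 50 and AAR = (0.40/0.5)/(0.53/1.0) = 1.5094 — condensed chromatin
is 1.5× as absorbing as the nuclear average.

A synthetic FT-IR group at full methylation, processed through the whole
chain (6 replicates, 1% noise, linear baseline drift):

```r
reps <- lapply(1:6, function(i) {
  baseline_correct(generate_ftir_spectrum(
    methylation_level = 1.0, baseline_coeffs = c(0.05, 5e-6),
    noise_sd = 0.01, seed = 100 + i))
})
norm <- normalize_max(average_spectra(reps))
fit_ch3_window(norm)
#> <band_fit> 1 peak(s) in 2992-2852 cm^-1; main 2934.6 cm^-1 (area 16.5579); total area 16.5579; RMS 4.86e-03
qc_report(norm)
#> <qc_report> B-form marker: TRUE; 1707 shoulder: TRUE; nu_as PO2- 0.5465, nu_s PO2- 0.4571 (nu_s below nu_as: TRUE)
bend_cytosine_ratio(norm)
#> [1] 1.0811
```

The deconvolution finds the CH₃ stretching band at ~2935 cm⁻¹; its total
area falls roughly in proportion to the methylation level (rerun with
`methylation_level = 0.3` to see the drop). The QC report confirms the
B-form and phosphate criteria the synthetic DNA library is built to
satisfy.

Small-sample group comparison with the exact Mann-Whitney path:

```r
mann_whitney(c(1, 2), c(3, 4))
#> <group_comparison> a (n=2) vs b (n=2): U = 0, p = 0.3333 (exact)
```

The full three-group demo (cytometry + FT-IR + IF, with comparison
tables, a Table-style FT-IR band summary and an S_C%/AAR scatter plot):

```r
res <- run_pipeline(demo_config("demo_out", seed = 1))
read.delim("demo_out/ftir_summary.tsv")
```

A command-line wrapper over the same functions is installed at
`inst/cli/methylscope` (subcommands `run`, `simulate`, `cytometry`,
`ftir`, `ifquant`).

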