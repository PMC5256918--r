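Package: methylscope
Title: Image Cytometry, FT-IR Band Deconvolution and Immunofluorescence
    Quantification of DNA Methylation Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA demethylation from three complementary assays:
    Feulgen image-cytometry chromatin texture statistics (condensed chromatin
    area fraction S_C% and the average absorption ratio AAR), Fourier
    transform-infrared (FT-IR) spectral processing with Gaussian deconvolution
    of the CH3 stretching window (2992-2850 cm^-1), and per-nucleus
    5-methylcytosine immunofluorescence intensity. Includes seeded synthetic
    generators for nuclei, spectra and micrographs with ground-truth masks,
    nonparametric (Mann-Whitney) group comparison, and a reproducible
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    withr,
    tiff,
    png,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
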