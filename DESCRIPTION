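Package: anthoNIR
Title: FT-NIR Chemometrics for Anthocyanins and Phenolic Acids in Purple Carrot
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and validation workflow for quantifying cyanidin-based
    anthocyanins and phenolic acids in purple carrot root powder from
    Fourier-transform near-infrared (FT-NIR) spectra. Provides spectral
    preprocessing (standard normal variate, multiplicative scatter correction,
    Savitzky-Golay derivatives, wavenumber window selection), a NIPALS partial
    least squares (PLS1) regression core with grouped k-fold cross-validation
    and rank selection, model evaluation by R2, RMSECV/RMSEP, bias and residual
    prediction deviation (RPD), and downstream statistics on anthocyanin
    composition (degree of acylation, pigment percentages), binary root-color
    phenotype diversity, and pigment-extract color density and hue. A seeded
    synthetic-data module emulates the metabolite tables, Beer-Lambert mixture
    spectra and extract absorbances of a diverse purple carrot cohort so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    vegan
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
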