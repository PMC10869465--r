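Package: specphen
Title: Hyperspectral and Chlorophyll Fluorescence Phenotyping of Cultivar Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Early-phenotyping analysis toolkit for cultivar panels screened by
    hyperspectral imaging and pulse-amplitude-modulated (PAM) chlorophyll
    fluorescence. Computes white-referenced reflectance spectra, exhaustive
    normalized difference index (NDI) wavelength-pair scans, induction-curve
    feature extraction (quantum yield of photosystem II, non-photochemical
    quenching), drought and heat tolerance indices from stepped heat-ramp
    assays, trait-spectrum Pearson correlation maps with significant-region
    extraction, and cultivar comparison statistics (ANOVA, Tukey HSD, compact
    letter display). Includes a synthetic cultivar-panel generator with
    configurable latent vigor and tolerance factors for validation, and
    packaged trait-table fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
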