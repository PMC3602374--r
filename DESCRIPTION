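Package: cyanophys
Title: Photophysiology Pipelines for Cyanobacterial Iron-Limitation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for single-turnover fast repetition
    rate (FRR) chlorophyll fluorescence and quantitative immunoblotting in
    cyanobacteria. Fits flashlet-train fluorescence induction curves to
    extract the functional absorption cross-section of photosystem II
    (sigma_PSII), Fv/Fm, qP and Phi_PSII; derives electron transport rates
    per PSII and per microgram total protein and fits
    photosynthesis-irradiance curves (Pmax, Ek); calibrates immunoblot band
    volumes against protein standards to express subunit abundances in fmol
    per microgram total protein; computes photosystem stoichiometries and a
    chlorophyll-allocation budget; estimates exponential growth rates and
    pigment indices from absorbance data; and aggregates replicate time
    courses with one-way ANOVA plus Dunnett comparisons against the
    pre-treatment control. A synthetic-data module generates every input the
    pipeline consumes so all stages are testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    mvtnorm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    multcomp
Config/testthat/edition: 3
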