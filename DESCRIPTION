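Package: lignantools
Title: Diagnostic-Fragment Annotation and HPLC-UV Quantification of
    Dibenzylbutyrolactone Lignans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based annotation of high-resolution MS/MS spectra of
    dibenzylbutyrolactone lignans and their glycosides, as found in Caulis
    Trachelospermi (Trachelospermum jasminoides). Provides elemental-formula
    arithmetic and exact-mass/ppm utilities, bounded enumeration of candidate
    molecular formulas from accurate precursor masses, a curated 25-compound
    library with diagnostic benzyl-cation fragment rules ([A]+, [A']+, [B]+,
    [C+H]+, [M+H-A]+, [A-H+Na]+) and glycoside neutral-loss ladders, subclass
    classification and compound identification from centroided peak lists,
    plus the companion HPLC-UV external-standard workflow: calibration,
    LOD/LOQ, precision, recovery, and batch content summaries. A seeded
    synthetic-data generator emulates both the spectra and the peak-area
    tables so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
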