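Package: agHC
Title: Silver-Ion HPLC/APCI-MS Profiling of Cuticular Hydrocarbons
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating long-chain aliphatic hydrocarbons separated
    by silver-ion liquid chromatography and detected by atmospheric pressure
    chemical ionization mass spectrometry (Ag-HPLC/APCI-MS). Provides
    hydrocarbon formula and adduct mass arithmetic, isotope patterns, and
    reverse m/z lookup; a seeded simulator of centroided LC-MS runs with a
    gradient retention model, mobile-phase-dependent adduct spectra,
    unsaturation-dependent response factors and noise; an annotation engine
    that reconstructs summed-ion chromatograms, integrates peaks, assigns
    carbon number, double-bond count and cis/trans geometry, and reports
    within-class relative abundances; packaged reference tables of insect
    cuticular hydrocarbon profiles; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    mzR,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
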