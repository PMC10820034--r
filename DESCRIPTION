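Package: ionlink
Title: Link Fragment-Rich and Soft-Ionization GC-HRMS Datasets to
    Identify Molecular Ions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns molecular-ion candidates from a soft-ionization
    (CI/APCI) high-resolution GC-MS run to fragment-rich (EI)
    pseudospectra from a parallel run. Pseudospectra are paired by
    retention time (optionally corrected through retention-time
    standards), molecular-ion candidates are detected through
    user-defined adduct/neutral-loss m/z-difference patterns (with an
    optional raw-data search), elemental formulas are enumerated under
    ppm tolerance and element constraints, filtered by element-ratio
    heuristics and diagnostic-isotope checks, and candidates are ranked
    by an intensity- and m/z-weighted subformula support score computed
    through a bottom-up chained assignment of fragment formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    mzR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
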