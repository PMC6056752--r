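Package: mrmsig
Title: Signature-Peptide Selection, MRM Transition Design and Bioanalytical
    Validation for Therapeutic Protein LC-MS Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for developing and validating multiple reaction monitoring
    (MRM) LC-MS assays that quantify therapeutic proteins, in particular
    Fc-fusion biopharmaceuticals, through tryptic signature peptides.
    Provides in-silico tryptic digestion with missed-cleavage and terminus
    annotation, rule-based signature-peptide candidate screening against a
    background peptide set, exact monoisotopic mass and b/y fragment m/z
    computation for transition-table construction (including disulfide-linked
    peptide dimers), internal-standard normalized calibration and
    back-calculation, N-terminal heterogeneity and oxidation-ratio analyses,
    and precision/accuracy validation statistics with guideline-style
    acceptance verdicts. A synthetic peak-area generator emulates instrument
    output so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
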