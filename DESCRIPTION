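Package: sarcosig
Title: Mutation Burden, Spectrum, Hydrophobicity-Shift and Signature
    Analysis for Somatic Variant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-exome somatic variant cohorts of
    the kind collected for angiosarcoma: per-sample mutation counts and
    tumor mutation burden per megabase with subgroup comparisons,
    12-class substitution and consequence-class spectra, 96-channel
    trinucleotide spectra, Kyte-Doolittle hydrophobicity-shift statistics
    over missense changes (paired t test with confidence interval), and
    nonnegative least-squares refitting of per-sample exposures against a
    30-signature reference with etiology-level probability summaries.
    Includes a synthetic cohort generator with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    seqinr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
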