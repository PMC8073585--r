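Package: prmassay
Title: Targeted Proteomics Assay Design and Stable-Isotope-Dilution
    Quantification for Parallel Reaction Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for parallel reaction monitoring (PRM) workflows on
    tryptic peptides: in-silico trypsin digestion with per-site cleavage
    probability scoring, proteotypic (unique) peptide screening against a
    background proteome, monoisotopic precursor and b/y fragment m/z
    computation with fixed carbamidomethyl-cysteine and stable-isotope
    labels (Lys +8.014199 Da, Arg +10.008269 Da), assembly and export of
    light/heavy transition panels, extracted-ion-chromatogram peak
    detection with a coelution detection criterion and light-to-heavy
    ratio quantification, and nonparametric multi-group comparison
    (Kruskal-Wallis with Dunn post hoc tests). Includes a synthetic-data
    generator producing proteomes and chromatographic traces with known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
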