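Package: helixscan
Title: Quantitative Analysis of Stapled-Peptide Binding, Potency, Helicity
    and Library Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for stapled alpha-helical peptide libraries
    targeting the p53-Mdm2 interaction. Implements the exact 1:1 and
    competitive fluorescence-anisotropy binding models (closed-form cubic
    solution of the two-ligand, one-site equilibrium) with least-squares
    fitting of direct and apparent dissociation constants, four-parameter
    logistic dose-response analysis with censored potencies, conversion of
    circular-dichroism spectra to mean residue ellipticity with two
    transparent helicity estimators, peptide-notation parsing for sequences
    containing non-natural residues (hydrocarbon-staple anchors, Aib,
    cyclobutylalanine, D- and N-methylated amino acids), and library-level
    analytics: alanine/D-scan fold changes, cell/target potency ratios,
    stability normalization and lipophilicity correlations. A synthetic-data
    generator with known ground truth makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
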