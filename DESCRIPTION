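Package: acidladder
Title: Acidity Ladders and pKa Scales in Nonaqueous Solvents
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds self-consistent acidity scales for weak acids in
    nonaqueous solvents from relative acidity measurements.  Provides
    spectral unmixing of UV-vis spectrophotometric titrations into
    dissociation degrees and pairwise delta-pKa values, anchored and
    tiered least-squares assignment of absolute pKa values from a
    measurement network with consistency diagnostics, cross-solvent pKa
    correlation and conversion between acetonitrile and dimethyl
    sulfoxide, and gas-phase acidity assembly from complete-basis-set
    extrapolated electronic energies.  Includes a synthetic-data
    generator for titration spectra and measurement networks with known
    ground truth, and packaged compound acidity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
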