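Package: cenh3scan
Title: Inferring Presence or Loss of Centromeric Histone CenH3 from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decide, per species, whether the centromere-specific
    histone H3 variant CenH3 (CENP-A) and the inner-kinetochore protein
    CenpC are present in, absent from, or undeterminable from a de novo
    transcriptome assembly.  Implements a translated (six-frame) homology
    search with empirically calibrated E-values, diagnostic-feature
    classification of H3-family variants (extended loop1, substitutions at
    diagnostic fold residues, divergent N-terminal tail), a
    benchmark-proteome completeness control, length-normalised abundance
    rank percentiles, phylogenetic attribution of candidates to host or
    contaminant lineages via bootstrapped neighbor-joining clade tests,
    position-specific score matrix scanning for the CenpC motif and cupin
    domain, and a synthetic assembly generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
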