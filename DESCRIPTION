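Package: ccsconv
Title: Convergence at Conservative Sites in Phylogenomic Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects parallel identical amino-acid substitutions between two
    phylogenetically distant foreground clades (a "placental" group) against
    matched aplacental control clades and an outgroup, using the
    convergence-at-conservative-sites (CCS) criterion under a symmetric
    experimental design. Includes a JTT+Gamma substitution model with
    transition-probability computation, a Felsenstein-pruning likelihood with
    coordinate-ascent estimation of branch lengths and the gamma shape
    parameter, an evolver-style sequence simulator that records internal-node
    states (for calibrating ancestral-inference accuracy and the null
    distribution of convergent calls), a synthetic 17-taxon study generator
    with planted convergent sites, and molecular-rate utilities (Tajima's
    relative rate test, fourfold-degenerate-site extraction, Kimura
    two-parameter distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
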