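Package: apoevol
Title: Gain and Loss Evolution of the Vertebrate Apolipoprotein Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of the
    exchangeable apolipoprotein (ApoA/ApoC/ApoE) gene family across
    vertebrates. Implements homology-based family-member identification by
    local protein alignment against a human query panel, presence/absence
    (phyletic) matrix construction, single-gain/multiple-loss (Dollo) event
    reconstruction on a rooted species tree with emergence ordering,
    distance-based per-family phylogenies with bootstrap support, and an
    event calculus for the 33/22/11-codon amphipathic repeat-block
    architecture of apolipoprotein genes. Ships a curated 30-species by
    10-member presence/absence fixture with its ladder species tree, and
    simulators for character evolution, sequence evolution and decoy-laden
    proteomes so the whole pipeline can be exercised without external
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
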