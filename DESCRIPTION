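Package: acylTE
Title: Subfamily Delineation and Substrate-Specificity Classification of
    Acyl-ACP Thioesterases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organising acyl-ACP thioesterase (TE) sequence
    diversity and enzyme function. Implements phylogeny-guided delineation
    of protein subfamilies from an amino-acid multiple sequence alignment:
    pairwise maximum-likelihood distances under the Jones-Taylor-Thornton
    (JTT) substitution model with pairwise gap deletion, neighbor-joining
    and minimum-evolution tree construction with bootstrap supports, and a
    z-statistic acceptance test (all pairwise z > 3.3) with iterative
    partition refinement. Also implements classification of enzymes into
    substrate-specificity classes from in vivo fatty-acid profiles:
    internal-standard quantitation, control-strain background subtraction,
    mol% composition, and Ward hierarchical clustering with multiscale
    bootstrap approximately-unbiased (AU) p-values. Seeded simulators for
    subfamily-structured alignments and class-structured fatty-acid peak
    tables make every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
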