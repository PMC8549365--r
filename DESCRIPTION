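Package: crisprtype
Title: Strain-Level Typing of Bacterial Populations from CRISPR Spacer Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for using the CRISPR array as a hypervariable marker for
    strain-level population genetics of uncultured bacteria. Calls CRISPR
    spacer-array haplotypes from long-read (CCS-like) amplicon reads by
    repeat-anchored spacer discovery and approximate string matching,
    estimates pairwise divergence between haplotypes by maximum likelihood
    under an ordered independent spacer-loss model, reconstructs a rooted
    neighbour-joining phylogeny with non-negative branch clamping, and
    quantifies hierarchical population structure via distance-based AMOVA
    with permutation tests, pairwise F(ST)/Phi(ST), Mantel tests and minimum
    spanning networks. Includes a synthetic-data generator that simulates
    spacer-array evolution, hierarchically structured sampling designs and
    error-prone amplicon reads, so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
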