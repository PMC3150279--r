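Package: skyrefugia
Title: Coalescent Tests of Multi-Refugium Diversification and Montane
    Landscape Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing Pleistocene refugium hypotheses in montane
    ("sky island") species from mitochondrial sequences and microsatellite
    genotypes. Implements structured coalescent simulation of gene trees
    within Ne-scaled population trees, the Slatkin-Maddison sorting
    statistic (Fitch parsimony of the deme character) with simulation-based
    model rejection, sequence polymorphism and neutrality statistics
    (haplotype and nucleotide diversity, Fu's Fs, Fu and Li's D,
    McDonald-Kreitman), microsatellite summaries with rarefied allelic
    richness, Nei's standard distance and F_ST, frequency-based assignment
    and exclusion tests, distance-based redundancy analysis with marginal
    and forward-selection permutation tests, classic and generalized
    skyline plots, maximum-likelihood exponential growth estimation on
    fixed genealogies, and a seeded synthetic-data generator emulating a
    ten-population, three-subregion sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
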