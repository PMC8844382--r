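Package: cocktailnet
Title: Design of Minimum-Sized Phage Cocktails from Phage-Bacteria
    Infection Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing phage cocktails from binary host-range
    matrices. Host-range data are represented as directed bipartite
    phage-bacteria infection networks (PBINs) in which node importance is
    scored by degree-based Expected Importance. Minimum-sized cocktails are
    selected either heuristically (unique-lyser seeding followed by a greedy
    pass over phages in decreasing importance) or by exhaustive combinatorial
    search with exact admissible pruning, yielding the Minimum Cocktail Size
    (MCS). Phage Cocktail Networks (PCNs) are extracted for a chosen
    cocktail and characterised by expected efficacy, coinfection
    distributions and redundancy variation, the log10 change in the fraction
    of phages lysing each bacterium between the full network and the
    cocktail. A synthetic generator produces random, nested and
    noisy-nested host-range matrices for end-to-end testing, and batch and
    correlation reporting summarise matrix collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
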