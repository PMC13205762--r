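Package: starscale
Title: Spatiotemporal Scaling of Microbial Biodiversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying how microbial taxonomic and phylogenetic
    diversity accumulate jointly over space and time. Builds nested
    accumulation surfaces of richness and Faith's phylogenetic diversity
    from community count tables and a rooted tree, fits species-area,
    species-time and interaction species-time-area (STAR) and
    phylogenetic-time-area (PTAR) power-law models, derives time-space
    equivalence ratios with exact unit-conversion algebra, assesses
    significance by restricted block permutation, contrasts treatments
    with moving-window linear mixed models, ln-response ratios and
    Cohen's d, estimates community-weighted rrn copy-number traits and
    environmental heterogeneity, and fits the Sloan neutral community
    model. A synthetic spatiotemporal community generator with
    controllable distance decay, temporal turnover and treatment
    homogenization makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    nlme,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
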