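Package: mucinforage
Title: Mucin Glycan Foraging Potential of Gut Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the mucin glycan foraging capabilities of human gut
    microbes from binary genome annotations. Given per-genome presence of
    glycoside hydrolase (GH) classes, catabolic-pathway genes and
    transporters, the package calls monosaccharide catabolic pathways with a
    gap-tolerant completeness rule, predicts which O-glycan structures each
    genome can cleave, enumerates presence-pattern statistics over the five
    mucin monosaccharides with chi-squared uniformity tests, assigns
    donor/acceptor cross-feeding roles, and detects mutualistic genome pairs
    whose combined enzyme repertoires unlock glycans neither member can
    degrade alone. A synthetic-cohort generator with taxon-structured
    Bernoulli presence and plantable mutualistic pairs makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
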