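Package: capsidarch
Title: Predicting Tailed-Phage Capsid Architecture from Genome Length and
    Major Capsid Protein Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to predict the icosahedral triangulation number (T-number)
    of tailed bacteriophage capsids. Implements the generalized icosahedral
    lattice mathematics (hexagonal and trihexagonal lattices), an allometric
    genome-length-to-T-number model with a resampling-based error model, a
    multiregion cross-validated kernel density estimator for genome-length
    distributions, construction of a major-capsid-protein/T-number library
    from annotated genomes, a nearest-neighbour similarity classifier, a
    random-forest classifier over 22 sequence-derived features, and a
    metagenome survey front end. Ships the 37-structure high-resolution
    capsid table as a fixture and seeded synthetic-data generators so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    ranger
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
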