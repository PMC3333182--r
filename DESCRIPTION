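Package: manbatools
Title: Genotype-Phenotype Analysis of MANBA Mutations in Beta-Mannosidosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural genotype-phenotype analysis of inherited
    mutations in lysosomal beta-D-mannosidase (the MANBA gene product), the
    enzyme deficient in beta-mannosidosis. Provides a curated mutation
    catalogue model with parsing and summary statistics, mutant-transcript
    editing and translation with truncation scoring and active-site retention
    flags, profile-alignment position mapping and cross-species mutation
    extrapolation with ClustalX-style conservation classes, residue-level
    distance and contact analysis on protein 3-D coordinates, a rule-based
    mild/moderate/severe phenotype classifier, gap-threshold mutational
    hot-spot detection along the gene, and seeded synthetic-data generators
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
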