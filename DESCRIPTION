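Package: aquavar
Title: Structural Annotation of Missense Variants in Human Aquaporins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a structurally annotated database of missense
    single-nucleotide polymorphisms (SNPs) in the 13 human aquaporin (AQP)
    homologs. Ingests dbSNP-style variant dumps and validates codon changes
    against the standard genetic code; classifies amino-acid substitutions
    into six physicochemical groups and aggregates them into a 6x6
    substitution-pattern matrix; maps residues to the structure-based generic
    numbering scheme of the aquaporin hour-glass fold (anchor position 50 per
    transmembrane segment and half-helix) and flags the NPA motifs and the
    aromatic/arginine selectivity filter; classifies structurally resolved
    residues of tetrameric channel structures into six structural regions
    (channel-facing, helix-helix interface, monomer-monomer interface,
    lipid-facing, cytoplasmic, extracellular) using 4 Angstrom distance
    criteria and a membrane slab; and joins everything into annotated
    database entries that can be written to CSV, aggregated into summary
    statistics and queried with conjunctive filters. A synthetic-data module
    generates ideal-helix bundle tetramers and variant tables with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
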