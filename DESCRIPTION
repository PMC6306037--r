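Package: openpan
Title: Pan-Genome Openness, Genomospecies Delimitation and Tree Congruence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bacterial pan-genome analysis from gene
    presence/absence matrices: core/accessory tier partitioning
    (hard core, soft core, shell, cloud), rarefaction over genome
    orderings with Heaps'-law power-law fitting and extrapolation of
    pan-genome growth, reciprocal-genome-count extrapolation of the core,
    tiered genomospecies delimitation from average nucleotide identity
    (ANI) and digital DNA-DNA hybridisation (dDDH) matrices, COG
    functional-category enrichment of core versus accessory gene sets,
    assembly statistics (N50/L50, GC content, coverage filtering), and
    congruence analysis between taxonomy, gene-content and phenotype
    trees via neighbor-joining, tanglegrams and Robinson-Foulds
    distances. A synthetic-data generator with planted ground truth
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    minpack.lm,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
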