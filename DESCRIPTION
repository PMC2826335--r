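Package: SSRwild
Title: Cross-Species SSR Transferability, Private Alleles, and Genome-Donor
    Inference in Wild Arachis Germplasm
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of dominant (presence/absence) SSR genotyping data
    across wild relatives of cultivated groundnut. Provides a
    SummarizedExperiment-based container for band-scoring matrices with
    accession taxonomy and marker-panel metadata; cross-species and
    cross-section marker transferability statistics with source-species
    exclusion rules; detection of species-, section-, and tetraploid-specific
    alleles and duplicated-locus signatures; Nei-Li (Dice-complement) genetic
    distances, from-scratch neighbor-joining tree construction with bootstrap
    bipartition support; genetic-distance ranking of candidate diploid genome
    donors of an allotetraploid; and a synthetic genotype simulator with a
    ground-truth ledger for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, PopulationGenetics, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'donors.R'
    'io.R'
    'phylogeny.R'
    'pipeline.R'
    'simulate.R'
    'specificity.R'
    'survey-tables.R'
    'transferability.R'
    'utils.R'
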