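Package: plastomeR
Title: Comparative Analysis of Quadripartite Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast (plastid) genomes with
    the canonical quadripartite architecture (LSC/IRb/SSC/IRa). Reads annotated
    GenBank flat files, computes genome summary statistics, detects the inverted
    repeat and reports junction-gene geometry, scans for dispersed, tandem and
    palindromic repeats and builds repeat presence/absence character matrices,
    scores and searches trees under Fitch parsimony with consistency and
    retention indices and nonparametric bootstrap, computes p-distances,
    sliding-window identity profiles and per-region variability statistics for
    rapidly evolving marker ranking, extracts and polarizes exon indels, detects
    small inversions flanked by palindromic repeats, and simulates quadripartite
    genomes evolving on a known tree so that every stage can be exercised
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'divergence.R'
    'genbank-io.R'
    'genome-stats.R'
    'parsimony.R'
    'indel-inversion.R'
    'repeatscan.R'
    'repeat-classify.R'
    'simulate.R'
    'simulate-engine.R'
    'pipeline.R'
    'plastomeR-package.R'
    'quadripartite.R'
    'utils.R'
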