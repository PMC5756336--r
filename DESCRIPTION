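Package: auxoactivity
Title: Activity, Auxotrophy and Bioenergetics of Genome-Resolved Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling genome-resolved microbial communities from
    paired metagenome/metatranscriptome experiments, motivated by microbial
    ecology of hydrocarbon-degrading consortia in oil reservoirs undergoing
    water injection. Computes genome-size-normalized relative abundance and
    per-bin cDNA/DNA mapping-rate ratios to separate active community members
    from inactive ones, FPKM expression values with a top-quantile
    highly-transcribed classification, and amino-acid/vitamin auxotrophy calls
    for genome bins from biosynthetic pathway completeness with an
    expression-based rescue rule for single-gene gaps. A Gibbs free energy
    module evaluates whether fermentation of n-alkanes to acetate coupled to
    acetoclastic methanogenesis is thermodynamically feasible across a
    pH-by-acetate grid. A synthetic-data generator plants known auxotrophy,
    abundance and activity ground truth so every stage can be validated
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
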