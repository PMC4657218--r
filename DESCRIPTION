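Package: phylosieve
Title: Locus Scoring, Bias Diagnostics and Supermatrix Assembly for
    Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating phylogenomic data sets of many
    amino-acid loci before tree inference. Scores every locus for taxon
    occupancy, missing data, rate of molecular evolution (mean branch
    length of its gene tree), substitution saturation (regression of
    uncorrected p-distances on patristic distances), average nodal
    bootstrap support, and taxon-specific long-branch (LB) scores;
    flags spurious sequences on over-long terminal branches; ranks and
    filters loci, assembles concatenated supermatrices with partition
    tables, builds progressive and rate-binned concatenation series and
    locus-jackknife replicates; recodes amino acids into reduced
    alphabets (Dayhoff-6, Dayhoff-4, hydrophobic/polar); maps
    bipartition support for topological hypotheses across tree sets and
    compares marginal likelihoods of competing hypotheses on the Bayes
    factor scale. Includes a seed-reproducible simulator of locus
    collections with heterogeneous rates, planted long branches and
    controlled missing data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
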