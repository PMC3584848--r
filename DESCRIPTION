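Package: protofam
Title: Hierarchical Protein Family Trees for Proteome Annotation and
    Paralog Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds E-value-based agglomerative protein family trees with
    stability (LifeTime) pruning, maps query proteomes onto their best
    stable clusters and lifts them to ProtoLevel-bounded family roots,
    transfers functional annotations by cluster purity (Correspondence
    Score under size and specificity filters), and computes paralog
    expansion statistics: Tree Score on UPGMA guide trees, Taxonomy
    Balance between proteomes, amplification ratios and three-way
    taxonomic Venn partitions. Ships a planted-family synthetic data
    generator with ground truth and a staged, reproducible pipeline with
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
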