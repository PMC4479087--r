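Package: nmdscope
Title: NMD-Susceptibility Classification and Downstream RNA-Seq Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-driven interpretation of two-condition bulk RNA-seq
    results. Classifies transcripts as prone to nonsense-mediated mRNA decay
    (NMD) from GTF transcript models using the 50-nt exon-junction rule, a
    long-3'UTR rule (>= 1250 bp) and a 3'UTR-intron rule; filters gene-level
    differential-expression tables by fold change and q-value; partitions
    differentially expressed genes by RNA biotype; tests disease gene-set
    over-representation with the hypergeometric tail; filters and summarizes
    alternative-splicing event tables by Bayes factor and delta-psi; and
    generates seeded synthetic annotations, expression tables, gene sets and
    event tables with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    fgsea,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
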