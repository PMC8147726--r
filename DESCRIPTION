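Package: phenolink
Title: Functionally Coherent Phenotype Clusters from Disease Annotation
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phenotype co-occurrence networks from disease-phenotype
    and disease-gene annotation corpora (OMIM/Orphanet-style records annotated
    with Human Phenotype Ontology terms), scores phenotype-phenotype and
    phenotype-gene associations with the hypergeometric index, extracts
    phenotypes typical of a disease class by one-tailed Fisher tests, maps
    phenotypes to cell functions by over-representation analysis, detects
    link communities of co-occurring phenotypes at the partition-density
    maximum, and retains clusters in which a threshold fraction of member
    phenotypes share an enriched function. Includes randomised null models
    (prevalence-matched phenotype sets, degree-preserving pair shuffles),
    literature co-mention tests over term-to-document indices, a tissue
    expression contrast, and a synthetic corpus generator so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
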