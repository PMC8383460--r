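Package: phenomine
Title: Ontology-Aware Mining and Harvesting of Disease-Phenotype Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links hierarchical disease codes (ICD-10-style) to phenotype
    ontology classes (HPO/MP-style) by two complementary routes: (1) a
    text-mining pipeline that detects class mentions in an abstract corpus
    through a label/synonym lexicon, propagates mentions over the subclass
    hierarchy, and scores disease-phenotype pairs by normalized pointwise
    mutual information (NPMI); and (2) a semi-automatic harvesting pipeline
    that merges curated association tables through cross-terminology mapping
    bridges, filters generic phenotypes, and propagates annotations over the
    disease hierarchy and via lexical superclass matches.  Also provides
    random-walk skip-gram embeddings of phenotype annotation graphs with
    cosine-similarity ranking, strict and soft evaluation against gold
    standards, and seeded synthetic fixture generators so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
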