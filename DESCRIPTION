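Package: vertlink
Title: Multi-Layer Biomarker-Phenotype Network Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Induces and integrates three orthogonal network layers for
    biomarker-phenotype discovery: a gene co-expression layer built from
    anchor-gene correlation lists and multi-dataset coherent dense
    subgraph mining, a clinical feature correlation layer built from
    binned encounter data with pairwise-complete Spearman correlation,
    and a knowledge layer of ontology-anchored concept chains derived by
    constructive induction. The three layers are cross-linked through
    identical, parent-child and sibling concept relations, and "vertical"
    complexes spanning all layers are extracted by path search. Includes
    seeded synthetic generators for expression panels, clinical encounter
    tables and toy ontologies, plus readers and writers for the plain-text
    interchange formats involved (expression TSV, encounter CSV, ontology
    TSV/OBO, Pajek NET, Graphviz DOT).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
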