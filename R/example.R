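# Worked CLL example: a hand-built three-layer fixture linking a ZAP70
# gene co-expression path to refractory-CLL clinical features through an
# ontology-anchored concept chain. Used in the documentation and as a small
# end-to-end test bed for cross-linking and complex extraction.

#' Worked CLL multi-network example
#'
#' Builds a small three-layer multi-network by hand: a gene layer with the
#' co-expression path CD8A - IL2RB - ZAP70; a conceptual layer carrying one
#' five-concept chain from "ZAP70 gene" through ligand binding, the LTB4R
#' gene product and lymphoid tissue to refractory chronic lymphocytic
#' leukaemia; and a clinical layer with a four-attribute correlation path
#' from the refractory-CLL treatment response through del(17p13) and
#' unmutated-IgVH status to raised lactate dehydrogenase. The gene node
#' ZAP70 and the clinical refractory-CLL attribute share concept ids with
#' the chain endpoints, so cross-linking joins all three layers and a
#' vertical complex from CD8A to the raised-LDH attribute exists.
#'
#' @return list with `layers` (named list of [layer_network()]s), `ontology`
#'   (an [ontology()] carrying the concepts involved) and `multinet`
#'   (the [cross_link()] result).
#' @export
cll_example_multinet <- function() {
  concepts <- data.frame(
    id = c("ZAP70_GENE", "LIGAND_BINDING", "LTB4R_PROTEIN",
           "LYMPHOID_TISSUE", "CLL_REFRACTORY", "CD8A_GENE",
           "DEL17P13", "CLL_UNMUTATED", "LDH_RAISED"),
    name = c("ZAP70 gene", "Ligand Binding", "LTB4R protein, human",
             "Lymphoid Tissue", "Chronic lymphocytic leukaemia refractory",
             "CD8A gene", "del(17p13)",
             "CLL with unmutated IgVH gene",
             "Lactic acid dehydrogenase raised"),
    synonyms = "", semantic_type = "", stringsAsFactors = FALSE)
  # associative chain relations only: no shared is-a parent, so the only
  # cross-layer links are the two identical-concept anchors
  relations <- data.frame(
    source = c("ZAP70_GENE", "LIGAND_BINDING", "LTB4R_PROTEIN",
               "LYMPHOID_TISSUE"),
    label = c("gene_plays_role_in_process",
              "biological_process_involves_gene_product",
              "gene_product_expressed_in_tissue",
              "is_normal_tissue_origin_of_disease"),
    target = c("LIGAND_BINDING", "LTB4R_PROTEIN", "LYMPHOID_TISSUE",
               "CLL_REFRACTORY"),
    stringsAsFactors = FALSE)
  onto <- ontology(concepts, relations, isa_labels = "is_a")

  gene <- layer_network(
    "gene",
    nodes = data.frame(label = c("CD8A", "IL2RB", "ZAP70"),
                       concept_id = c("CD8A_GENE", NA, "ZAP70_GENE"),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = c("CD8A", "IL2RB"),
                       to = c("IL2RB", "ZAP70"),
                       label = "coexpression", weight = 1,
                       stringsAsFactors = FALSE))
  chain <- c("ZAP70 gene", "Ligand Binding", "LTB4R protein, human",
             "Lymphoid Tissue", "Chronic lymphocytic leukaemia refractory")
  chain_ids <- c("ZAP70_GENE", "LIGAND_BINDING", "LTB4R_PROTEIN",
                 "LYMPHOID_TISSUE", "CLL_REFRACTORY")
  conceptual <- layer_network(
    "conceptual",
    nodes = data.frame(label = chain, concept_id = chain_ids,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = chain[-5], to = chain[-1],
                       label = c("gene_plays_role_in_process",
                                 "biological_process_involves_gene_product",
                                 "gene_product_expressed_in_tissue",
                                 "is_normal_tissue_origin_of_disease"),
                       weight = 1, stringsAsFactors = FALSE))
  clin_attrs <- c("CLL refractory (treatment response)", "del(17p13)",
                  "CLL unmutated IgVH", "LDH raised")
  clinical <- layer_network(
    "clinical",
    nodes = data.frame(label = clin_attrs,
                       concept_id = c("CLL_REFRACTORY", "DEL17P13",
                                      "CLL_UNMUTATED", "LDH_RAISED"),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = clin_attrs[-4], to = clin_attrs[-1],
                       label = "correlation", weight = 0.97,
                       stringsAsFactors = FALSE))
  layers <- list(conceptual = conceptual, gene = gene, clinical = clinical)
  list(layers = layers, ontology = onto,
       multinet = cross_link(layers, onto))
}
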