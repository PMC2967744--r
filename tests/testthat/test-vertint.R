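family_ontology <- function() {
  make_ontology(list(c("KID1", "is_a", "PARENT"),
                     c("KID2", "is_a", "PARENT"),
                     c("PARENT", "is_a", "GRAND")))
}

test_that("semantic links follow identity, direct is-a, and shared parents", {
  onto <- family_ontology()
  expect_equal(semantic_link("KID1", "KID1", onto), "identical")
  expect_equal(semantic_link("KID1", "PARENT", onto), "parent_child")
  expect_equal(semantic_link("PARENT", "KID1", onto), "parent_child")
  expect_equal(semantic_link("KID1", "KID2", onto), "sibling")
  expect_equal(semantic_link("KID2", "KID1", onto), "sibling")
  # grandparent-grandchild needs one direct is-a edge: no link
  expect_true(is.na(semantic_link("KID1", "GRAND", onto)))
  expect_message(bad <- semantic_link("KID1", "NOPE", onto), "not in ontology")
  expect_true(is.na(bad))
})

test_that("cross-linking equals exhaustive all-pairs evaluation", {
  onto <- family_ontology()
  layers <- list(
    conceptual = layer_network("conceptual",
      nodes = data.frame(label = c("PARENT", "KID1"),
                         concept_id = c("PARENT", "KID1"),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = "PARENT", to = "KID1", label = "is_a",
                         weight = 1, stringsAsFactors = FALSE)),
    gene = layer_network("gene",
      nodes = data.frame(label = c("GENE_A", "GENE_B"),
                         concept_id = c("KID1", "KID2"),
                         stringsAsFactors = FALSE)),
    clinical = layer_network("clinical",
      nodes = data.frame(label = c("attr1", "attr2"),
                         concept_id = c("GRAND", NA),
                         stringsAsFactors = FALSE)))
  mn <- cross_link(layers, onto)
  # brute force over every cross-layer pair with concept ids
  brute <- list()
  for (p in list(c("conceptual", "gene"), c("conceptual", "clinical"))) {
    n1 <- layers[[p[1]]]$nodes; n2 <- layers[[p[2]]]$nodes
    for (i in seq_len(nrow(n1))) for (j in seq_len(nrow(n2))) {
      if (is.na(n1$concept_id[i]) || is.na(n2$concept_id[j])) next
      tp <- suppressMessages(
        semantic_link(n1$concept_id[i], n2$concept_id[j], onto))
      if (!is.na(tp))
        brute[[length(brute) + 1]] <-
          paste(p[1], n1$label[i], p[2], n2$label[j], tp)
    }
  }
  have <- paste(mn$cross_links$from_layer, mn$cross_links$from,
                mn$cross_links$to_layer, mn$cross_links$to,
                mn$cross_links$type)
  expect_setequal(have, unlist(brute))
  # all links bridge different layers
  expect_true(all(mn$cross_links$from_layer != mn$cross_links$to_layer))
  # unmapped nodes never link
  expect_false("attr2" %in% mn$cross_links$to)
})

test_that("cross-link output is invariant under node enumeration order", {
  onto <- family_ontology()
  base <- list(
    conceptual = layer_network("conceptual",
      nodes = data.frame(label = c("KID1", "KID2", "PARENT"),
                         concept_id = c("KID1", "KID2", "PARENT"),
                         stringsAsFactors = FALSE)),
    gene = layer_network("gene",
      nodes = data.frame(label = c("g1", "g2"),
                         concept_id = c("KID2", "PARENT"),
                         stringsAsFactors = FALSE)),
    clinical = layer_network("clinical",
      nodes = data.frame(label = "a1", concept_id = "KID1",
                         stringsAsFactors = FALSE)))
  shuffled <- base
  shuffled$conceptual <- layer_network("conceptual",
    nodes = base$conceptual$nodes[c(3, 1, 2), ])
  shuffled$gene <- layer_network("gene", nodes = base$gene$nodes[2:1, ])
  mn1 <- cross_link(base, onto)
  mn2 <- cross_link(shuffled, onto)
  expect_identical(mn1$cross_links, mn2$cross_links)
})

test_that("the CLL example yields the full three-layer vertical complex", {
  ex <- cll_example_multinet()
  expect_equal(nrow(ex$multinet$cross_links), 2)
  expect_true(all(ex$multinet$cross_links$type == "identical"))
  cx <- extract_complexes(ex$multinet, "gene", "clinical", max_len = 12)
  spans3 <- Filter(function(k) k$n_layers == 3, cx)
  expect_gt(length(spans3), 0)
  full <- Filter(function(k)
    k$initial_concept == "CD8A" && k$terminal_concept == "LDH raised",
    spans3)
  expect_length(full, 1)
  expect_equal(full[[1]]$path$label,
               c("CD8A", "IL2RB", "ZAP70", "ZAP70 gene", "Ligand Binding",
                 "LTB4R protein, human", "Lymphoid Tissue",
                 "Chronic lymphocytic leukaemia refractory",
                 "CLL refractory (treatment response)", "del(17p13)",
                 "CLL unmutated IgVH", "LDH raised"))
  expect_equal(full[[1]]$path$layer,
               c(rep("gene", 3), rep("conceptual", 5), rep("clinical", 4)))
  # the first complex in sort order spans the most layers
  expect_equal(cx[[1]]$n_layers, max(vapply(cx, `[[`, 0L, "n_layers")))
})

test_that("removing the gene-to-concept anchor cuts all three-layer paths", {
  ex <- cll_example_multinet()
  mn <- ex$multinet
  keep <- !(mn$cross_links$from == "ZAP70 gene" |
              mn$cross_links$to == "ZAP70")
  mn$cross_links <- mn$cross_links[keep, , drop = FALSE]
  cx <- extract_complexes(mn, "gene", "clinical", max_len = 12)
  expect_length(Filter(function(k) k$n_layers == 3, cx), 0)
})

test_that("complex extraction equals exhaustive simple-path search", {
  onto <- family_ontology()
  layers <- list(
    conceptual = layer_network("conceptual",
      nodes = data.frame(label = c("KID1", "PARENT", "KID2"),
                         concept_id = c("KID1", "PARENT", "KID2"),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = c("KID1", "PARENT"),
                         to = c("PARENT", "KID2"),
                         label = "is_a", weight = 1,
                         stringsAsFactors = FALSE)),
    gene = layer_network("gene",
      nodes = data.frame(label = c("g1", "g2", "g3"),
                         concept_id = c("KID1", NA, "KID2"),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = c("g1", "g2"), to = c("g2", "g3"),
                         label = "coexpression", weight = 1,
                         stringsAsFactors = FALSE)),
    clinical = layer_network("clinical",
      nodes = data.frame(label = c("a1", "a2"),
                         concept_id = c("KID2", "GRAND"),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = "a1", to = "a2", label = "correlation",
                         weight = 1, stringsAsFactors = FALSE)))
  mn <- cross_link(layers, onto)
  for (len in c(3, 5, 8)) {
    cx <- extract_complexes(mn, "gene", "clinical", max_len = len)
    got <- sort(vapply(cx, function(k)
      paste(paste(k$path$layer, k$path$label, sep = "::"), collapse = "->"),
      ""))
    expect_equal(got, oracle_complexes(mn, "gene", "clinical", len),
                 info = sprintf("max_len=%d", len))
  }
  # every hop of every complex exists in the multinet
  cx <- extract_complexes(mn, "gene", "clinical", max_len = 8)
  edge_keys <- c(
    unlist(lapply(mn$layers, function(l)
      paste(pmin(l$edges$from, l$edges$to), pmax(l$edges$from, l$edges$to)))),
    paste(pmin(mn$cross_links$from, mn$cross_links$to),
          pmax(mn$cross_links$from, mn$cross_links$to)))
  for (k in cx)
    expect_true(all(paste(pmin(k$hops$from, k$hops$to),
                          pmax(k$hops$from, k$hops$to)) %in% edge_keys))
})

test_that("extraction requires a cross-link and tolerates no-path cases", {
  onto <- family_ontology()
  layers <- list(
    conceptual = layer_network("conceptual",
      nodes = data.frame(label = "KID1", concept_id = "KID1",
                         stringsAsFactors = FALSE)),
    gene = layer_network("gene",
      nodes = data.frame(label = "g1", concept_id = NA_character_,
                         stringsAsFactors = FALSE)),
    clinical = layer_network("clinical",
      nodes = data.frame(label = "a1", concept_id = "KID1",
                         stringsAsFactors = FALSE)))
  mn <- cross_link(layers, onto)  # only conceptual-clinical identical link
  expect_equal(nrow(mn$cross_links), 1)
  # no path from the unlinked gene node: empty result, not an error
  expect_length(extract_complexes(mn, "gene", "clinical"), 0)
  mn$cross_links <- mn$cross_links[0, , drop = FALSE]
  expect_error(extract_complexes(mn, "gene", "clinical"), "no cross-links")
})

test_that("DOT export writes layer clusters and round-trips", {
  ex <- cll_example_multinet()
  path <- tempfile(fileext = ".dot")
  on.exit(unlink(path), add = TRUE)
  export_multinet(ex$multinet, path, format = "dot")
  txt <- readLines(path)
  expect_length(grep("subgraph cluster_", txt), 3)
  expect_gte(length(grep("linktype=", txt)), 2)

  back <- read_multinet_dot(path)
  want_nodes <- do.call(rbind, lapply(ex$multinet$layers, function(l)
    data.frame(layer = l$layer, label = l$nodes$label,
               stringsAsFactors = FALSE)))
  expect_setequal(paste(back$nodes$layer, back$nodes$label),
                  paste(want_nodes$layer, want_nodes$label))
  n_within <- sum(vapply(ex$multinet$layers,
                         function(l) nrow(l$edges), 0L))
  expect_equal(nrow(back$edges),
               n_within + nrow(ex$multinet$cross_links))
  expect_equal(sum(!is.na(back$edges$linktype)),
               nrow(ex$multinet$cross_links))

  # empty multinetwork still writes syntactically balanced DOT
  empty <- ex$multinet
  empty$layers <- lapply(empty$layers, function(l) {
    layer_network(l$layer,
                  nodes = data.frame(label = character(),
                                     concept_id = character(),
                                     stringsAsFactors = FALSE))
  })
  empty$cross_links <- empty$cross_links[0, , drop = FALSE]
  export_multinet(empty, path, format = "dot")
  txt <- readLines(path)
  expect_equal(sum(grepl("\\{", txt)), sum(grepl("\\}", txt)))
})

test_that("Pajek export round-trips with a layer partition", {
  ex <- cll_example_multinet()
  path <- tempfile(fileext = ".net")
  on.exit(unlink(c(path, sub("\\.net$", ".clu", path))), add = TRUE)
  export_multinet(ex$multinet, path, format = "pajek")
  back <- read_pajek(path)
  n_nodes <- sum(vapply(ex$multinet$layers, function(l) nrow(l$nodes), 0L))
  expect_length(back$nodes, n_nodes)
  n_edges <- sum(vapply(ex$multinet$layers, function(l) nrow(l$edges), 0L)) +
    nrow(ex$multinet$cross_links)
  expect_equal(nrow(back$edges), n_edges)
  clu <- readLines(sub("\\.net$", ".clu", path))
  expect_equal(length(clu) - 1, n_nodes)
  expect_error(export_multinet(ex$multinet, path, format = "gexf"))
})
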