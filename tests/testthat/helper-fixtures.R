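# Fixture builders shared across test files.

# coexpr_graph from a plain edge list (pairs of node names)
make_graph <- function(nodes, pairs, rho = 0.9, support = 4L,
                       datasets = list(c("d1", "d2", "d3", "d4"))) {
  if (length(pairs)) {
    a <- vapply(pairs, `[[`, "", 1)
    b <- vapply(pairs, `[[`, "", 2)
    lo <- pmin(a, b); hi <- pmax(a, b)
    edges <- data.frame(a = lo, b = hi, rho = rho,
                        support = support, stringsAsFactors = FALSE)
    edges$datasets <- I(rep(datasets, length.out = nrow(edges)))
    edges <- edges[order(edges$a, edges$b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(), rho = numeric(),
                        support = integer(), stringsAsFactors = FALSE)
    edges$datasets <- I(list())
  }
  coexpr_graph(nodes, edges)
}

clique_pairs <- function(nodes) {
  cmb <- utils::combn(nodes, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

path_pairs <- function(nodes) {
  lapply(seq_len(length(nodes) - 1), function(i) nodes[i + 0:1])
}

# G(n, p) random pair list under a fixed seed
random_pairs <- function(nodes, p, seed) {
  set.seed(seed)
  cmb <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(cmb)) < p
  lapply(which(keep), function(i) cmb[, i])
}

# small ontology from a relation triple list
make_ontology <- function(triples, extra_concepts = character(),
                          names = NULL) {
  ids <- sort(unique(c(unlist(lapply(triples, function(t) t[c(1, 3)])),
                       extra_concepts)))
  concepts <- data.frame(
    id = ids,
    name = if (is.null(names)) ids else names[ids],
    synonyms = "", semantic_type = "", stringsAsFactors = FALSE)
  relations <- data.frame(
    source = vapply(triples, `[[`, "", 1),
    label = vapply(triples, `[[`, "", 2),
    target = vapply(triples, `[[`, "", 3), stringsAsFactors = FALSE)
  ontology(concepts, relations)
}

# element mappings pinned directly to concept ids (bypasses lexical search)
pin_mappings <- function(...) {
  pins <- list(...)
  lapply(names(pins), function(el)
    structure(list(element = el, kind = "phenotypic",
                   concepts = data.frame(concept_id = pins[[el]], score = 1,
                                         stringsAsFactors = FALSE)),
              class = "element_mapping"))
}

serialize_modules <- function(mods) {
  sort(vapply(mods, function(m) paste(m$genes, collapse = ","), ""))
}
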