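# Multi-network integration: the three layer networks (conceptual, gene,
# clinical) are cross-linked through ontology relations (identical /
# parent-child / sibling) and "vertical" biomarker-phenotype complexes are
# extracted as simple paths spanning several layers.

empty_layer_edges <- function() {
  data.frame(from = character(), to = character(), label = character(),
             weight = numeric(), stringsAsFactors = FALSE)
}

#' Layer network container
#'
#' One of the three layers of the multi-network: `conceptual` (CKC-derived
#' concept graph), `gene` (co-expression graph) or `clinical` (attribute
#' correlation graph). Node labels are unique within a layer; nodes carry an
#' optional ontology concept id used for cross-linking.
#'
#' @param layer "conceptual", "gene" or "clinical".
#' @param nodes data.frame with columns `label` and `concept_id`
#'   (NA where unmapped).
#' @param edges data.frame with columns `from`, `to`, `label` (relation or
#'   edge type) and `weight`.
#' @return An object of class `layer_network`.
#' @export
layer_network <- function(layer = c("conceptual", "gene", "clinical"),
                          nodes, edges = empty_layer_edges()) {
  layer <- match.arg(layer)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "concept_id") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$label))
    stop("node labels must be unique within a layer")
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% nodes$label))
    stop("edge endpoints missing from layer nodes")
  if (is.null(edges$label)) edges$label <- rep("", nrow(edges))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  structure(list(layer = layer, nodes = nodes, edges = edges),
            class = "layer_network")
}

#' @export
print.layer_network <- function(x, ...) {
  cat(sprintf("<layer_network '%s': %d nodes, %d edges>\n",
              x$layer, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Lift a co-expression graph into the gene layer
#'
#' @param graph a [coexpr_graph()].
#' @param concept_map optional data.frame (`label`, `concept_id`) resolving
#'   gene symbols to ontology concepts.
#' @return a [layer_network()] with `layer = "gene"`.
#' @export
gene_layer <- function(graph, concept_map = NULL) {
  stopifnot(inherits(graph, "coexpr_graph"))
  nodes <- data.frame(label = graph$nodes,
                      concept_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(concept_map))
    nodes$concept_id <- concept_map$concept_id[
      match(nodes$label, concept_map$label)]
  edges <- if (nrow(graph$edges))
    data.frame(from = graph$edges$a, to = graph$edges$b,
               label = "coexpression", weight = graph$edges$rho,
               stringsAsFactors = FALSE)
  else empty_layer_edges()
  layer_network("gene", nodes, edges)
}

#' Lift a clinical correlation network into the clinical layer
#'
#' @param net a [build_clinical_network()] result.
#' @param concept_map optional data.frame (`label`, `concept_id`) resolving
#'   attribute names to ontology concepts.
#' @return a [layer_network()] with `layer = "clinical"`.
#' @export
clinical_layer <- function(net, concept_map = NULL) {
  stopifnot(inherits(net, "clinical_network"))
  nodes <- data.frame(label = net$nodes, concept_id = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(concept_map))
    nodes$concept_id <- concept_map$concept_id[
      match(nodes$label, concept_map$label)]
  edges <- if (nrow(net$edges))
    data.frame(from = net$edges$a, to = net$edges$b,
               label = "correlation", weight = net$edges$rho,
               stringsAsFactors = FALSE)
  else empty_layer_edges()
  layer_network("clinical", nodes, edges)
}

#' Semantic relation between two concepts
#'
#' `identical` when the ids coincide; `parent_child` when a direct is-a edge
#' joins them in either direction; `sibling` when they share at least one
#' is-a parent. Precedence: identical > parent_child > sibling. Anything
#' else (including a grandparent-grandchild pair) is no link.
#'
#' @param a,b concept ids.
#' @param onto an [ontology()].
#' @return "identical", "parent_child", "sibling", or `NA_character_`.
#' @export
semantic_link <- function(a, b, onto) {
  stopifnot(inherits(onto, "ontology"))
  if (is.na(a) || is.na(b)) return(NA_character_)
  known <- c(a, b) %in% onto$concepts$id
  if (!all(known)) {
    message("concept id(s) not in ontology: ",
            paste(c(a, b)[!known], collapse = ", "))
    return(NA_character_)
  }
  if (a == b) return("identical")
  isa <- onto$relations[onto$relations$label %in% onto$isa_labels, ,
                        drop = FALSE]
  direct <- any((isa$source == a & isa$target == b) |
                  (isa$source == b & isa$target == a))
  if (direct) return("parent_child")
  pa <- isa$target[isa$source == a]
  pb <- isa$target[isa$source == b]
  if (length(intersect(pa, pb))) return("sibling")
  NA_character_
}

#' Cross-link the three layers into a multi-network
#'
#' Enumerates candidate node pairs between the conceptual (hub) layer and
#' each of the gene and clinical layers breadth-first, evaluates
#' [semantic_link()] on their concept ids, and records every non-none link.
#' Direct gene-clinical links are off by default.
#'
#' @param layers named list with elements `conceptual`, `gene`, `clinical`
#'   ([layer_network()] objects).
#' @param onto an [ontology()].
#' @param link_gene_clinical also evaluate gene-clinical pairs directly.
#' @return An object of class `multinet`: `layers` plus `cross_links`
#'   (data.frame `from_layer`, `from`, `to_layer`, `to`, `type`).
#' @export
cross_link <- function(layers, onto, link_gene_clinical = FALSE) {
  stopifnot(all(c("conceptual", "gene", "clinical") %in% names(layers)))
  for (l in c("conceptual", "gene", "clinical"))
    stopifnot(inherits(layers[[l]], "layer_network"))
  pairs <- list(c("conceptual", "gene"), c("conceptual", "clinical"))
  if (link_gene_clinical) pairs <- c(pairs, list(c("gene", "clinical")))
  links <- list()
  for (p in pairs) {
    n1 <- layers[[p[1]]]$nodes; n2 <- layers[[p[2]]]$nodes
    n1 <- n1[!is.na(n1$concept_id), , drop = FALSE]
    n2 <- n2[!is.na(n2$concept_id), , drop = FALSE]
    for (i in seq_len(nrow(n1))) for (j in seq_len(nrow(n2))) {
      type <- suppressMessages(
        semantic_link(n1$concept_id[i], n2$concept_id[j], onto))
      if (!is.na(type))
        links[[length(links) + 1]] <- data.frame(
          from_layer = p[1], from = n1$label[i],
          to_layer = p[2], to = n2$label[j], type = type,
          stringsAsFactors = FALSE)
    }
  }
  cross <- if (length(links)) do.call(rbind, links) else
    data.frame(from_layer = character(), from = character(),
               to_layer = character(), to = character(),
               type = character(), stringsAsFactors = FALSE)
  cross <- cross[order(cross$from_layer, cross$from, cross$to_layer,
                       cross$to), , drop = FALSE]
  rownames(cross) <- NULL
  structure(list(layers = layers, cross_links = cross),
            class = "multinet")
}

#' @export
print.multinet <- function(x, ...) {
  cat(sprintf("<multinet: %s; %d cross-links>\n",
              paste(vapply(x$layers, function(l)
                sprintf("%s(%d)", l$layer, nrow(l$nodes)), ""),
                collapse = ", "),
              nrow(x$cross_links)))
  invisible(x)
}

# union igraph over all layers and cross-links; vertex names "layer::label"
multinet_union <- function(mn) {
  vkey <- function(layer, label) paste(layer, label, sep = "::")
  verts <- do.call(rbind, lapply(mn$layers, function(l)
    data.frame(name = vkey(l$layer, l$nodes$label), layer = l$layer,
               label = l$nodes$label, stringsAsFactors = FALSE)))
  edges <- do.call(rbind, c(
    lapply(mn$layers, function(l) {
      if (!nrow(l$edges)) return(NULL)
      data.frame(from = vkey(l$layer, l$edges$from),
                 to = vkey(l$layer, l$edges$to),
                 provenance = paste0("within:", l$layer),
                 label = l$edges$label, stringsAsFactors = FALSE)
    }),
    list(if (nrow(mn$cross_links))
      data.frame(from = vkey(mn$cross_links$from_layer, mn$cross_links$from),
                 to = vkey(mn$cross_links$to_layer, mn$cross_links$to),
                 provenance = paste0("cross:", mn$cross_links$type),
                 label = mn$cross_links$type, stringsAsFactors = FALSE)
      else NULL)))
  igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else edges,
    directed = FALSE, vertices = verts)
}

#' Extract vertical biomarker-phenotype complexes
#'
#' Searches simple paths from nodes of `start_layer` to nodes of
#' `end_layer` over the union of within-layer edges and cross-links
#' (breadth-first, at most `max_len` hops), keeping paths that touch at
#' least two distinct layers. Each hop records its provenance (the owning
#' layer or the cross-link type). Results are sorted by number of layers
#' spanned (descending), then path length (ascending), then
#' lexicographically.
#'
#' @param mn a [cross_link()] result with at least one cross-link.
#' @param start_layer,end_layer layer names.
#' @param max_len maximum number of hops; default 12.
#' @return list of `vertical_complex` objects: `path` (data.frame `label`,
#'   `layer`), `hops` (data.frame `from`, `to`, `provenance`),
#'   `initial_concept`, `terminal_concept`, `n_layers`.
#' @export
extract_complexes <- function(mn, start_layer = "gene",
                              end_layer = "clinical", max_len = 12) {
  stopifnot(inherits(mn, "multinet"))
  if (!nrow(mn$cross_links)) stop("multi-network has no cross-links")
  ig <- multinet_union(mn)
  vlayer <- stats::setNames(igraph::V(ig)$layer, igraph::V(ig)$name)
  vlabel <- stats::setNames(igraph::V(ig)$label, igraph::V(ig)$name)
  starts <- igraph::V(ig)$name[vlayer == start_layer]
  ends <- igraph::V(ig)$name[vlayer == end_layer]
  out <- list()
  for (s in sort(starts)) {
    paths <- igraph::all_simple_paths(ig, from = s,
                                      to = ends[ends != s],
                                      cutoff = max_len)
    for (p in paths) {
      names_p <- igraph::V(ig)$name[p]
      layers_p <- unname(vlayer[names_p])
      if (length(unique(layers_p)) < 2) next
      eids <- igraph::get_edge_ids(
        ig, as.vector(rbind(names_p[-length(names_p)], names_p[-1])))
      hops <- data.frame(from = unname(vlabel[names_p[-length(names_p)]]),
                         to = unname(vlabel[names_p[-1]]),
                         provenance = igraph::E(ig)$provenance[eids],
                         stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- structure(
        list(path = data.frame(label = unname(vlabel[names_p]),
                               layer = layers_p, stringsAsFactors = FALSE),
             hops = hops,
             initial_concept = unname(vlabel[names_p[1]]),
             terminal_concept = unname(vlabel[names_p[length(names_p)]]),
             n_layers = length(unique(layers_p))),
        class = "vertical_complex")
    }
  }
  ord <- order(-vapply(out, `[[`, 0L, "n_layers"),
               vapply(out, function(x) nrow(x$hops), 0L),
               vapply(out, function(x) paste(x$path$label, collapse = "|"),
                      ""))
  out[ord]
}

#' @export
print.vertical_complex <- function(x, ...) {
  cat(sprintf("<vertical_complex: %s -> %s, %d hops, %d layers>\n",
              x$initial_concept, x$terminal_concept, nrow(x$hops),
              x$n_layers))
  invisible(x)
}

#' Export a multi-network to DOT or Pajek
#'
#' DOT output places each layer in its own `subgraph cluster` and writes the
#' cross-link type as the `linktype` edge attribute. Pajek output writes a
#' `.net` file plus a `.clu` partition file (one layer index per vertex).
#' Both formats round-trip through the package's own readers
#' ([read_multinet_dot()], [read_pajek()]).
#'
#' @param mn a `multinet`.
#' @param path output file path (for Pajek, the `.clu` file is written next
#'   to the `.net` file).
#' @param format "dot" or "pajek".
#' @return the main output path, invisibly.
#' @export
export_multinet <- function(mn, path, format = c("dot", "pajek")) {
  format <- match.arg(format)
  stopifnot(inherits(mn, "multinet"))
  if (format == "dot") {
    lines <- c("graph multinet {")
    for (l in mn$layers) {
      lines <- c(lines, sprintf("  subgraph cluster_%s {", l$layer),
                 sprintf("    label=\"%s\";", l$layer))
      for (lab in l$nodes$label)
        lines <- c(lines, sprintf("    \"%s::%s\" [label=\"%s\"];",
                                  l$layer, lab, lab))
      if (nrow(l$edges))
        lines <- c(lines, sprintf("    \"%s::%s\" -- \"%s::%s\";",
                                  l$layer, l$edges$from, l$layer, l$edges$to))
      lines <- c(lines, "  }")
    }
    if (nrow(mn$cross_links))
      lines <- c(lines, sprintf(
        "  \"%s::%s\" -- \"%s::%s\" [linktype=\"%s\"];",
        mn$cross_links$from_layer, mn$cross_links$from,
        mn$cross_links$to_layer, mn$cross_links$to, mn$cross_links$type))
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    verts <- do.call(rbind, lapply(mn$layers, function(l)
      data.frame(name = paste(l$layer, l$nodes$label, sep = "::"),
                 layer = l$layer, stringsAsFactors = FALSE)))
    idx <- stats::setNames(seq_len(nrow(verts)), verts$name)
    lines <- c(sprintf("*Vertices %d", nrow(verts)),
               sprintf("%d \"%s\"", seq_len(nrow(verts)), verts$name),
               "*Edges")
    add_edge <- function(from, to)
      sprintf("%d %d", idx[from], idx[to])
    for (l in mn$layers)
      if (nrow(l$edges))
        lines <- c(lines, add_edge(paste(l$layer, l$edges$from, sep = "::"),
                                   paste(l$layer, l$edges$to, sep = "::")))
    if (nrow(mn$cross_links))
      lines <- c(lines, add_edge(
        paste(mn$cross_links$from_layer, mn$cross_links$from, sep = "::"),
        paste(mn$cross_links$to_layer, mn$cross_links$to, sep = "::")))
    writeLines(lines, path)
    layer_idx <- match(verts$layer, c("conceptual", "gene", "clinical"))
    clu <- sub("\\.net$", ".clu", path)
    if (clu == path) clu <- paste0(path, ".clu")
    writeLines(c(sprintf("*Vertices %d", nrow(verts)),
                 as.character(layer_idx)), clu)
  }
  invisible(path)
}

#' Read a multi-network DOT file written by [export_multinet()]
#'
#' Parses the package's own DOT dialect (layer clusters, `linktype` edge
#' attributes) back into node and edge tables.
#'
#' @param path DOT file path.
#' @return list with `nodes` (data.frame `layer`, `label`) and `edges`
#'   (data.frame `from`, `to`, `linktype`; within-layer edges have
#'   `linktype = NA`).
#' @export
read_multinet_dot <- function(path) {
  lines <- readLines(path)
  node_re <- "^\\s*\"([a-z]+)::(.+)\" \\[label="
  edge_re <- "^\\s*\"([a-z]+)::(.+?)\" -- \"([a-z]+)::(.+?)\"\\s*(\\[linktype=\"([^\"]*)\"\\])?;"
  nodes <- list(); edges <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(node_re, ln))[[1]]
    if (length(m)) {
      nodes[[length(nodes) + 1]] <- data.frame(
        layer = m[2], label = m[3], stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(ln, regexec(edge_re, ln))[[1]]
    if (length(m)) {
      edges[[length(edges) + 1]] <- data.frame(
        from = paste(m[2], m[3], sep = "::"),
        to = paste(m[4], m[5], sep = "::"),
        linktype = if (nzchar(m[7])) m[7] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(nodes = if (length(nodes)) do.call(rbind, nodes) else
    data.frame(layer = character(), label = character(),
               stringsAsFactors = FALSE),
    edges = if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(), to = character(),
                 linktype = character(), stringsAsFactors = FALSE))
}
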