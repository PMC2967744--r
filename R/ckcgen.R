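# Knowledge layer: lexical mapping of data-dictionary elements to ontology
# concepts, is-a depth computation, constructive induction of concept chains
# (CKCs) through unmapped intermediate concepts under a granularity filter,
# and aggregation of kept chains into a concept network layer.

tokenize <- function(s) {
  s <- tolower(gsub("[^[:alnum:]]+", " ", s))
  unique(Filter(nzchar, strsplit(trimws(s), "\\s+")[[1]]))
}

token_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Map data-dictionary elements to ontology concepts by lexical match
#'
#' Element names and concept names/synonyms are case-folded, stripped of
#' punctuation and tokenized; the match score between an element and a
#' concept is the token-set Jaccard similarity, taking the best over the
#' concept's name and synonyms. Matches with score >= `min_score` are kept,
#' best first. Elements with no match are retained with an empty concept
#' set and logged.
#'
#' @param dictionary data.frame with columns `element` and `kind`
#'   ("phenotypic" or "bio-molecular").
#' @param onto an [ontology()].
#' @param min_score minimum token Jaccard score in (0, 1]; default 1/3.
#' @return list of `element_mapping` objects (`element`, `kind`,
#'   `concepts` data.frame with `concept_id`, `score`).
#' @export
map_elements <- function(dictionary, onto, min_score = 1/3) {
  stopifnot(is.data.frame(dictionary), nrow(dictionary) >= 1,
            all(c("element", "kind") %in% names(dictionary)),
            inherits(onto, "ontology"))
  concept_tokens <- lapply(seq_len(nrow(onto$concepts)), function(i) {
    syns <- strsplit(onto$concepts$synonyms[i], "|", fixed = TRUE)[[1]]
    lapply(c(onto$concepts$name[i], Filter(nzchar, syns)), tokenize)
  })
  lapply(seq_len(nrow(dictionary)), function(e) {
    et <- tokenize(dictionary$element[e])
    scores <- vapply(concept_tokens, function(variants)
      max(vapply(variants, function(v) token_jaccard(et, v), 0)), 0)
    keep <- which(scores >= min_score)
    keep <- keep[order(-scores[keep], onto$concepts$id[keep])]
    if (!length(keep))
      message("element '", dictionary$element[e], "' mapped to no concept")
    structure(list(element = dictionary$element[e],
                   kind = dictionary$kind[e],
                   concepts = data.frame(
                     concept_id = onto$concepts$id[keep],
                     score = scores[keep], stringsAsFactors = FALSE)),
              class = "element_mapping")
  })
}

#' Shortest is-a depth of every concept
#'
#' Depth is the shortest hierarchical path length from any root (a concept
#' with no is-a parent) down to the concept; roots have depth 0. Concepts
#' outside the hierarchy are their own roots. Used as the semantic
#' granularity measure for CKC filtering.
#'
#' @param onto an [ontology()] (the is-a subgraph must be acyclic, which
#'   the constructor enforces).
#' @return named integer vector, concept id -> depth.
#' @export
concept_depths <- function(onto) {
  stopifnot(inherits(onto, "ontology"))
  ids <- onto$concepts$id
  isa <- onto$relations[onto$relations$label %in% onto$isa_labels, ,
                        drop = FALSE]
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  parents <- split(isa$target, isa$source)   # child -> parents
  children <- split(isa$source, isa$target)  # parent -> children
  roots <- ids[!(ids %in% isa$source)]       # no outgoing is-a (no parent)
  depth[roots] <- 0L
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(depth[nxt])]  # shortest path: first assignment wins
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

# undirected adjacency over all relations; between a pair, the
# lexicographically smallest relation label is used
relation_adjacency <- function(onto) {
  rel <- onto$relations
  if (!nrow(rel)) return(list(adj = list(), label = character()))
  u <- c(rel$source, rel$target)
  v <- c(rel$target, rel$source)
  lab <- c(rel$label, rel$label)
  key <- paste(u, v, sep = "\r")
  lab_of <- tapply(lab, key, function(l) sort(l)[1])
  adj <- lapply(split(v, u), unique)
  adj <- lapply(adj, sort)
  list(adj = adj, label = lab_of)
}

#' Generate conceptual knowledge constructs (CKCs)
#'
#' For every pair of mapped concepts belonging to different data-dictionary
#' elements, enumerates simple relation paths through 1 to
#' `max_intermediates` interior concepts. Interior concepts must be
#' unmapped (constructive induction routes through concepts absent from the
#' schema) and must satisfy the granularity filter: the is-a depth of every
#' interior concept may differ from the depth of each endpoint by at most
#' `granularity_delta`. Relations are traversed direction-agnostically.
#' Reversed duplicates are removed by keeping the orientation whose first
#' concept id is lexicographically smaller.
#'
#' @param mappings list of `element_mapping` objects from [map_elements()]
#'   (at least 2 mapped elements).
#' @param onto an [ontology()].
#' @param max_intermediates maximum number of interior concepts; default 1
#'   (triplets).
#' @param granularity_delta maximum is-a depth difference between an
#'   interior concept and each endpoint.
#' @return list of `ckc` objects: `concepts` (chain), `relations` (labels
#'   between consecutive concepts), `endpoints`, `intermediates`,
#'   `annotation` (NULL until [annotate_ckcs()]).
#' @export
generate_ckcs <- function(mappings, onto, max_intermediates = 1,
                          granularity_delta = 1) {
  stopifnot(max_intermediates >= 1, granularity_delta >= 0)
  mapped_of <- lapply(mappings, function(m) m$concepts$concept_id)
  names(mapped_of) <- vapply(mappings, `[[`, "", "element")
  mapped_of <- mapped_of[vapply(mapped_of, length, 0L) > 0]
  if (length(mapped_of) < 2) stop("need at least 2 mapped elements")
  mapped <- unique(unlist(mapped_of))
  # elements each mapped concept belongs to
  elems_of <- lapply(stats::setNames(mapped, mapped), function(cid)
    names(mapped_of)[vapply(mapped_of, function(cs) cid %in% cs, TRUE)])
  depth <- concept_depths(onto)
  net <- relation_adjacency(onto)

  ok_interior <- function(c_int, e1, e2) {
    abs(depth[[c_int]] - depth[[e1]]) <= granularity_delta &&
      abs(depth[[c_int]] - depth[[e2]]) <= granularity_delta
  }
  chains <- list()
  # DFS from each mapped start over unmapped interiors to a mapped end;
  # orientation with the smaller first id is kept, so only emit start < end
  extend <- function(path, start) {
    tip <- path[length(path)]
    for (nb in net$adj[[tip]] %||% character()) {
      if (nb %in% path) next
      if (nb %in% mapped) {
        if (length(path) >= 2 && nb > start &&
            length(union(elems_of[[nb]], elems_of[[start]])) > 1) {
          interior <- path[-1]
          if (all(vapply(interior, ok_interior, TRUE, e1 = start, e2 = nb)))
            chains[[length(chains) + 1]] <<- c(path, nb)
        }
      } else if (length(path) - 1 < max_intermediates) {
        extend(c(path, nb), start)
      }
    }
  }
  for (start in sort(mapped)) extend(start, start)

  lapply(chains, function(ch) {
    labs <- vapply(seq_len(length(ch) - 1), function(i)
      unname(net$label[paste(ch[i], ch[i + 1], sep = "\r")]), "")
    structure(list(concepts = ch, relations = labs,
                   endpoints = c(ch[1], ch[length(ch)]),
                   intermediates = ch[-c(1, length(ch))],
                   annotation = NULL),
              class = "ckc")
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ckc <- function(x, ...) {
  cat("<ckc: ", paste(x$concepts, collapse = " - "), ">\n", sep = "")
  invisible(x)
}

#' Serialize CKC chains
#'
#' @param ckcs list of `ckc` objects.
#' @return character vector, one `C1|rel|C2|rel|C3` string per chain.
#' @export
format_ckc <- function(ckcs) {
  vapply(ckcs, function(k) {
    n <- length(k$concepts)
    parts <- character(2 * n - 1)
    parts[seq(1, 2 * n - 1, by = 2)] <- k$concepts
    parts[seq(2, 2 * n - 2, by = 2)] <- k$relations
    paste(parts, collapse = "|")
  }, "")
}

#' Attach subject-matter-expert annotations to CKCs
#'
#' Validity and meaningfulness are human judgments supplied as data, never
#' computed.
#'
#' @param ckcs list of `ckc` objects.
#' @param annotations data.frame with columns `ckc` (serialized chain as in
#'   [format_ckc()]), `validity` ("valid", "partially_valid" or "invalid")
#'   and `meaningfulness` ("meaningful" or "not").
#' @return the CKC list with `annotation` fields filled where matched.
#' @export
annotate_ckcs <- function(ckcs, annotations) {
  stopifnot(all(c("ckc", "validity", "meaningfulness") %in%
                  names(annotations)))
  keys <- format_ckc(ckcs)
  idx <- match(keys, annotations$ckc)
  Map(function(k, i) {
    if (!is.na(i))
      k$annotation <- list(validity = annotations$validity[i],
                           meaningfulness = annotations$meaningfulness[i])
    k
  }, ckcs, idx)
}

#' Aggregate CKCs into the conceptual network layer
#'
#' Kept chains are unioned: nodes are all concepts on the chains, edges the
#' consecutive chain links labelled by relation, with multiplicity collapsed
#' into an integer weight.
#'
#' @param ckcs list of `ckc` objects.
#' @param keep optional filter: a predicate over a `ckc`, or a character
#'   vector of admissible validity values applied to the annotations
#'   (unannotated chains are dropped when a character filter is given).
#' @return a [layer_network()] with `layer = "conceptual"`.
#' @export
ckc_network <- function(ckcs, keep = NULL) {
  if (is.function(keep)) {
    ckcs <- Filter(keep, ckcs)
  } else if (is.character(keep)) {
    ckcs <- Filter(function(k) !is.null(k$annotation) &&
                     k$annotation$validity %in% keep, ckcs)
  }
  if (!length(ckcs))
    return(layer_network("conceptual",
                         nodes = data.frame(label = character(),
                                            concept_id = character(),
                                            stringsAsFactors = FALSE),
                         edges = empty_layer_edges()))
  from <- unlist(lapply(ckcs, function(k) utils::head(k$concepts, -1)))
  to <- unlist(lapply(ckcs, function(k) k$concepts[-1]))
  lab <- unlist(lapply(ckcs, `[[`, "relations"))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, lab, sep = "\r")
  first <- !duplicated(key)
  w <- as.integer(table(key)[key[first]])
  edges <- data.frame(from = from[first], to = to[first],
                      label = lab[first], weight = w,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$label), , drop = FALSE]
  rownames(edges) <- NULL
  concepts <- sort(unique(unlist(lapply(ckcs, `[[`, "concepts"))))
  layer_network("conceptual",
                nodes = data.frame(label = concepts, concept_id = concepts,
                                   stringsAsFactors = FALSE),
                edges = edges)
}
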