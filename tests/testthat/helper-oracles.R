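# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own graph code: adjacency matrices, exhaustive enumeration and
# hand-rolled recursion only.

# ---- gene lists / overlap ----------------------------------------------

# exact upper-tail overlap probability by enumerating every possible draw
# of size_b elements from the universe (universe <= 12 or so)
oracle_overlap_p <- function(size_a, size_b, overlap, universe) {
  draws <- utils::combn(universe, size_b)
  hits <- apply(draws, 2, function(d) sum(d <= size_a) >= overlap)
  mean(hits)
}

# ---- dense-module mining ------------------------------------------------

# adjacency matrix from a canonical edge data.frame
adj_matrix <- function(nodes, edges) {
  m <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      m[edges$a[i], edges$b[i]] <- m[edges$b[i], edges$a[i]] <- TRUE
  m
}

oracle_components <- function(adj) {
  nodes <- rownames(adj)
  unseen <- nodes
  comps <- list()
  while (length(unseen)) {
    frontier <- unseen[1]; comp <- character()
    while (length(frontier)) {
      comp <- union(comp, frontier)
      nxt <- unique(unlist(lapply(frontier, function(v)
        nodes[adj[v, ]])))
      frontier <- setdiff(nxt, comp)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  comps
}

oracle_r <- function(adj, vs) {
  n <- length(vs)
  L <- sum(adj[vs, vs]) / 2
  2 * L / (n * (n - 1))
}

# mirrors the mining semantics with exhaustive primitives: min-degree
# peeling below the density bound, bridge splitting (bridge = edge whose
# removal disconnects, found by exhaustive re-traversal, tried in canonical
# order) when both sides are strictly denser
oracle_dense <- function(nodes, edges, min_r, min_size) {
  adj <- adj_matrix(nodes, edges)
  process <- function(vs) {
    out <- list()
    for (comp in oracle_components(adj[vs, vs, drop = FALSE])) {
      n <- length(comp)
      if (n < min_size) next
      r <- oracle_r(adj, comp)
      if (r > min_r) {
        split <- oracle_bridge_split(adj, comp, r)
        if (is.null(split)) {
          out <- c(out, list(sort(comp)))
        } else {
          out <- c(out, process(split[[1]]), process(split[[2]]))
        }
      } else {
        deg <- rowSums(adj[comp, comp, drop = FALSE])
        victim <- sort(comp[deg == min(deg)])[1]
        out <- c(out, process(setdiff(comp, victim)))
      }
    }
    out
  }
  res <- process(rownames(adj))
  res[order(vapply(res, `[[`, "", 1))]
}

oracle_bridge_split <- function(adj, comp, r_whole) {
  if (length(comp) < 4) return(NULL)
  sub <- adj[comp, comp, drop = FALSE]
  prs <- which(sub & upper.tri(sub), arr.ind = TRUE)
  if (!nrow(prs)) return(NULL)
  a <- comp[prs[, 1]]; b <- comp[prs[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  for (k in order(lo, hi)) {
    cut <- sub
    cut[lo[k], hi[k]] <- cut[hi[k], lo[k]] <- FALSE
    comps <- oracle_components(cut)
    if (length(comps) != 2) next
    dens <- vapply(comps, function(side)
      if (length(side) < 2) 1 else oracle_r(adj, side), 0)
    if (all(dens > r_whole)) return(comps)
  }
  NULL
}

# all connected vertex subsets of size >= min_size with r > min_r
# (used to verify density and maximality claims exhaustively)
oracle_qualifying_subsets <- function(nodes, edges, min_r, min_size) {
  adj <- adj_matrix(nodes, edges)
  n <- length(nodes)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    vs <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(vs) < min_size) next
    if (length(oracle_components(adj[vs, vs, drop = FALSE])) != 1) next
    if (oracle_r(adj, vs) > min_r) out <- c(out, list(sort(vs)))
  }
  out
}

# ---- Spearman -----------------------------------------------------------

# average ranks computed by hand, then the Pearson definition applied
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  avrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avrank(x); ry <- avrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ---- CKC path enumeration ----------------------------------------------

# exhaustive simple-path enumeration over the relation set of an ontology,
# with the same filters as generate_ckcs, serialized "C1|rel|C2|..." form
oracle_ckcs <- function(mappings, onto, max_intermediates, delta) {
  rel <- onto$relations
  mapped_of <- lapply(mappings, function(m) m$concepts$concept_id)
  names(mapped_of) <- vapply(mappings, function(m) m$element, "")
  mapped_of <- mapped_of[vapply(mapped_of, length, 0L) > 0]
  mapped <- unique(unlist(mapped_of))
  elems_of <- function(cid)
    names(mapped_of)[vapply(mapped_of, function(cs) cid %in% cs, TRUE)]
  depth <- oracle_depths(onto)
  neighbours <- function(v) {
    sort(unique(c(rel$target[rel$source == v], rel$source[rel$target == v])))
  }
  lab <- function(u, v) {
    ls <- c(rel$label[rel$source == u & rel$target == v],
            rel$label[rel$source == v & rel$target == u])
    sort(ls)[1]
  }
  chains <- character()
  walk <- function(path, start) {
    for (nb in neighbours(path[length(path)])) {
      if (nb %in% path) next
      if (nb %in% mapped) {
        if (length(path) >= 2 && nb > start &&
            length(union(elems_of(nb), elems_of(start))) > 1) {
          interior <- path[-1]
          ok <- all(vapply(interior, function(c_)
            abs(depth[[c_]] - depth[[start]]) <= delta &&
              abs(depth[[c_]] - depth[[nb]]) <= delta, TRUE))
          if (ok) {
            full <- c(path, nb)
            parts <- character(2 * length(full) - 1)
            parts[seq(1, by = 2, length.out = length(full))] <- full
            parts[seq(2, by = 2, length.out = length(full) - 1)] <-
              vapply(seq_len(length(full) - 1), function(i)
                lab(full[i], full[i + 1]), "")
            chains <<- c(chains, paste(parts, collapse = "|"))
          }
        }
      } else if (length(path) - 1 < max_intermediates) {
        walk(c(path, nb), start)
      }
    }
  }
  for (s in sort(mapped)) walk(s, s)
  sort(chains)
}

oracle_depths <- function(onto) {
  isa <- onto$relations[onto$relations$label %in% onto$isa_labels, ,
                        drop = FALSE]
  ids <- onto$concepts$id
  depth <- stats::setNames(rep(Inf, length(ids)), ids)
  depth[!(ids %in% isa$source)] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(isa))) {
      cand <- depth[[isa$target[i]]] + 1
      if (cand < depth[[isa$source[i]]]) {
        depth[[isa$source[i]]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  depth
}

# ---- vertical complexes -------------------------------------------------

# exhaustive simple-path search over the union of within-layer edges and
# cross-links, built straight from the multinet data frames
oracle_complexes <- function(mn, start_layer, end_layer, max_len) {
  vkey <- function(l, lab) paste(l, lab, sep = "::")
  edges <- list()
  for (l in mn$layers)
    if (nrow(l$edges))
      edges[[length(edges) + 1]] <-
        cbind(vkey(l$layer, l$edges$from), vkey(l$layer, l$edges$to))
  if (nrow(mn$cross_links))
    edges[[length(edges) + 1]] <-
      cbind(vkey(mn$cross_links$from_layer, mn$cross_links$from),
            vkey(mn$cross_links$to_layer, mn$cross_links$to))
  em <- do.call(rbind, edges)
  nbrs <- function(v) sort(unique(c(em[em[, 1] == v, 2],
                                    em[em[, 2] == v, 1])))
  layer_of <- function(v) sub("::.*$", "", v)
  starts <- unlist(lapply(mn$layers[[start_layer]]$nodes$label,
                          function(x) vkey(start_layer, x)))
  found <- character()
  walk <- function(path) {
    tip <- path[length(path)]
    if (length(path) > 1 && layer_of(tip) == end_layer &&
        length(unique(layer_of(path))) >= 2)
      found <<- c(found, paste(path, collapse = "->"))
    if (length(path) - 1 >= max_len) return()
    for (nb in nbrs(tip)) if (!(nb %in% path)) walk(c(path, nb))
  }
  for (s in sort(starts)) walk(s)
  sort(found)
}
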