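# Gene co-expression layer: anchor correlation lists, hypergeometric
# gene-list overlap tests, per-dataset co-expression graphs, the
# multi-dataset summary graph, dense-module mining with a coherence filter,
# differential expression and holdout classification.

#' Pearson product-moment correlation with domain checks
#'
#' Thin validated wrapper around [stats::cor()]: vectors must have equal
#' length of at least 3 and neither may be constant (the coefficient is
#' undefined for a zero-variance vector).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

# drop zero-variance genes, warning with the count (they carry no
# correlation information and would produce NaN columns)
drop_constant_genes <- function(values) {
  keep <- apply(values, 1, stats::sd) > 0
  if (!all(keep))
    warning(sum(!keep), " constant gene(s) dropped before correlation")
  values[keep, , drop = FALSE]
}

#' Anchor-gene correlation list
#'
#' Correlates every gene against a fixed anchor (e.g. ZAP70 or CD38) and
#' keeps the genes passing the threshold with the requested sign. The anchor
#' itself is excluded.
#'
#' @param ds an [expr_dataset()].
#' @param anchor gene symbol present in `ds`.
#' @param threshold correlation magnitude cutoff in (0, 1); genes with
#'   `rho >= threshold` (positive) or `rho <= -threshold` (negative) are kept.
#' @param sign "positive" or "negative".
#' @return An object of class `gene_corr_list` with a `members` data.frame
#'   (`gene`, `rho`).
#' @export
anchor_list <- function(ds, anchor, threshold = 0.4,
                        sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(ds, "expr_dataset"))
  if (!anchor %in% rownames(ds$values))
    stop("anchor gene '", anchor, "' not present in dataset '",
         ds$dataset_id, "'")
  vals <- drop_constant_genes(ds$values)
  if (!anchor %in% rownames(vals))
    stop("anchor gene '", anchor, "' has constant expression")
  rho <- drop(stats::cor(t(vals), vals[anchor, ]))
  rho <- rho[names(rho) != anchor]
  keep <- if (sign == "positive") rho >= threshold else rho <= -threshold
  members <- data.frame(gene = names(rho)[keep], rho = unname(rho[keep]),
                        stringsAsFactors = FALSE)
  members <- members[order(members$gene), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(anchor = anchor, dataset_id = ds$dataset_id,
                 threshold = threshold, sign = sign, members = members),
            class = "gene_corr_list")
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` common genes between two
#' lists of the given sizes drawn from a universe of `universe` genes
#' (the one-sided over-representation form of Fisher's exact test).
#'
#' @param size_a,size_b list sizes.
#' @param overlap observed intersection size.
#' @param universe gene universe size.
#' @return P(X >= overlap) under the hypergeometric null.
#' @export
overlap_p <- function(size_a, size_b, overlap, universe) {
  stopifnot(size_a >= 0, size_b >= 0, overlap >= 0)
  if (size_a > universe || size_b > universe)
    stop("list size exceeds universe")
  if (overlap > min(size_a, size_b))
    stop("overlap exceeds the smaller list")
  stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                lower.tail = FALSE)
}

#' Gene-list overlap test
#'
#' Intersects two gene lists and scores the overlap with the upper-tail
#' hypergeometric probability over a stated gene universe.
#'
#' @param list_a,list_b character vectors of gene symbols (or
#'   `gene_corr_list` objects, in which case their member genes are used).
#' @param universe universe size; must be at least `|list_a U list_b|`.
#' @return An object of class `intersection_result`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  if (inherits(list_a, "gene_corr_list")) list_a <- list_a$members$gene
  if (inherits(list_b, "gene_corr_list")) list_b <- list_b$members$gene
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  if (universe < length(union(list_a, list_b)))
    stop("`universe` smaller than the union of the two lists")
  ov <- sort(intersect(list_a, list_b))
  structure(list(size_a = length(list_a), size_b = length(list_b),
                 overlap = length(ov), universe = as.integer(universe),
                 p_value = overlap_p(length(list_a), length(list_b),
                                     length(ov), universe),
                 overlap_genes = ov),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("<overlap %d of (%d, %d) in universe %d: p = %.4g>\n",
              x$overlap, x$size_a, x$size_b, x$universe, x$p_value))
  invisible(x)
}

# canonical undirected edge table: lexicographically smaller node first
canonical_edges <- function(a, b, ...) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(a = a, b = b, ..., stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Co-expression graph container
#'
#' @param nodes character vector of gene symbols.
#' @param edges data.frame with columns `a`, `b` (unordered pair, smaller
#'   symbol first), `rho` (weight), `support` (number of datasets the edge
#'   occurs in) and `datasets` (list column of supporting dataset ids).
#' @param dataset_id originating dataset id (NA for a summary graph).
#' @return An object of class `coexpr_graph`.
#' @export
coexpr_graph <- function(nodes, edges, dataset_id = NA_character_) {
  nodes <- sort(unique(as.character(nodes)))
  stopifnot(all(c("a", "b", "rho", "support") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    if (!all(c(edges$a, edges$b) %in% nodes))
      stop("edge endpoints missing from nodes")
    if (anyDuplicated(paste(edges$a, edges$b))) stop("duplicate edges")
    if (any(edges$support < 1)) stop("edge support must be >= 1")
  }
  structure(list(nodes = nodes, edges = edges, dataset_id = dataset_id),
            class = "coexpr_graph")
}

#' @export
print.coexpr_graph <- function(x, ...) {
  cat(sprintf("<coexpr_graph: %d genes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build a single-dataset co-expression graph
#'
#' Links every gene pair with `|rho| >= threshold`; the edge weight is the
#' signed Pearson coefficient. Constant genes are skipped with a warning.
#'
#' @param ds an [expr_dataset()] with at least 3 samples.
#' @param threshold correlation magnitude cutoff.
#' @return A [coexpr_graph()] (support 1, tagged with the dataset id).
#' @export
build_coexpr_graph <- function(ds, threshold = 0.75) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ncol(ds$values) < 3) stop("need at least 3 samples")
  vals <- drop_constant_genes(ds$values)
  cm <- stats::cor(t(vals))
  idx <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  genes <- rownames(cm)
  edges <- canonical_edges(genes[idx[, 1]], genes[idx[, 2]],
                           rho = cm[idx], support = 1L)
  edges$datasets <- I(as.list(rep(ds$dataset_id, nrow(edges))))
  coexpr_graph(genes, edges, dataset_id = ds$dataset_id)
}

#' Multi-dataset summary graph
#'
#' Keeps every co-expression edge occurring in at least `min_support` of the
#' supplied per-dataset graphs; the kept edge records its support count, the
#' supporting dataset ids and the mean correlation over those datasets.
#'
#' @param graphs list of [coexpr_graph()] objects (one per dataset).
#' @param min_support minimum number of datasets an edge must occur in.
#' @return A [coexpr_graph()] whose nodes are the union of the input nodes.
#' @export
summary_graph <- function(graphs, min_support = 4) {
  stopifnot(length(graphs) >= 1, min_support >= 1)
  if (length(graphs) < min_support)
    stop("fewer graphs supplied than `min_support`")
  all_edges <- do.call(rbind, lapply(graphs, function(g)
    g$edges[, c("a", "b", "rho")]))
  ds_of <- unlist(lapply(graphs, function(g)
    rep(g$dataset_id, nrow(g$edges))))
  nodes <- sort(unique(unlist(lapply(graphs, `[[`, "nodes"))))
  if (is.null(all_edges) || nrow(all_edges) == 0)
    return(coexpr_graph(nodes, empty_edges()))
  key <- paste(all_edges$a, all_edges$b, sep = "\t")
  support <- table(key)
  keep_keys <- names(support)[support >= min_support]
  if (!length(keep_keys)) return(coexpr_graph(nodes, empty_edges()))
  rows <- lapply(keep_keys, function(k) {
    sel <- key == k
    ab <- strsplit(k, "\t", fixed = TRUE)[[1]]
    list(a = ab[1], b = ab[2], rho = mean(all_edges$rho[sel]),
         support = sum(sel), datasets = ds_of[sel])
  })
  edges <- data.frame(a = vapply(rows, `[[`, "", "a"),
                      b = vapply(rows, `[[`, "", "b"),
                      rho = vapply(rows, `[[`, 0, "rho"),
                      support = vapply(rows, function(r) as.integer(r$support),
                                       0L),
                      stringsAsFactors = FALSE)
  edges$datasets <- I(lapply(rows, `[[`, "datasets"))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  coexpr_graph(nodes, edges)
}

empty_edges <- function() {
  e <- data.frame(a = character(), b = character(), rho = numeric(),
                  support = integer(), stringsAsFactors = FALSE)
  e$datasets <- I(list())
  e
}

#' Connectivity ratio of a subgraph
#'
#' `r = L / (n (n - 1) / 2)`: the fraction of realizable edges present.
#'
#' @param n node count (>= 2).
#' @param L edge count, between 0 and `n (n - 1) / 2`.
#' @return connectivity ratio in `[0, 1]`.
#' @export
connectivity_ratio <- function(n, L) {
  stopifnot(n >= 2, L >= 0)
  if (L > n * (n - 1) / 2) stop("`L` exceeds the simple-graph maximum")
  2 * L / (n * (n - 1))
}

#' Mine dense modules from a co-expression graph
#'
#' Deterministic dense-subgraph extraction: each connected component is
#' processed recursively. A component below the density bound loses its
#' minimum-degree vertex (ties broken by lexicographic gene order) and the
#' remainder is reprocessed — minimum-degree peeling with density tracking.
#' A component above the bound is emitted, except that when its minimum edge
#' cut is a single bridge whose removal leaves two strictly denser sides,
#' the component is split and both sides are reprocessed (so two cliques
#' joined by one edge yield two modules, while a uniformly dense module is
#' kept whole).
#'
#' @param graph a [coexpr_graph()].
#' @param min_r minimum connectivity ratio, in (0, 1]; kept modules satisfy
#'   `r > min_r` strictly.
#' @param min_size minimum module size (>= 3).
#' @return list of `dense_module` objects (fields `genes`, `edges`, `n`,
#'   `L`, `r`, `coherence`), ordered by first gene.
#' @export
mine_dense <- function(graph, min_r = 0.4, min_size = 3) {
  stopifnot(inherits(graph, "coexpr_graph"),
            min_r > 0, min_r <= 1, min_size >= 3)
  if (nrow(graph$edges) == 0) return(list())
  ig <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                      directed = FALSE,
                                      vertices = graph$nodes)
  vertex_sets <- mine_component_sets(ig, min_r, min_size)
  mods <- lapply(vertex_sets, function(vs) {
    sel <- graph$edges$a %in% vs & graph$edges$b %in% vs
    edges <- graph$edges[sel, , drop = FALSE]
    rownames(edges) <- NULL
    n <- length(vs); L <- nrow(edges)
    structure(list(genes = sort(vs), edges = edges, n = n, L = L,
                   r = connectivity_ratio(n, L), coherence = NA_real_),
              class = "dense_module")
  })
  mods[order(vapply(mods, function(m) m$genes[1], ""))]
}

# recursive worker on an igraph; returns a list of character vertex-name sets
mine_component_sets <- function(ig, min_r, min_size) {
  out <- list()
  for (comp in igraph::decompose(ig)) {
    n <- igraph::vcount(comp)
    if (n < min_size) next
    r <- connectivity_ratio(n, igraph::ecount(comp))
    if (r > min_r) {
      split_sets <- try_bridge_split(comp, r, min_size)
      if (is.null(split_sets)) {
        out <- c(out, list(sort(igraph::V(comp)$name)))
      } else {
        for (side in split_sets)
          out <- c(out, mine_component_sets(side, min_r, min_size))
      }
    } else {
      deg <- igraph::degree(comp)
      victim <- names(sort(deg))[1]  # min degree, lexicographic tie-break
      rest <- igraph::delete_vertices(comp, victim)
      out <- c(out, mine_component_sets(rest, min_r, min_size))
    }
  }
  out
}

# if removing a bridge (cut edge) leaves two sides that are both strictly
# denser than the whole component, return the two side subgraphs, else NULL;
# bridges are tried in canonical (lexicographic endpoint) order
try_bridge_split <- function(comp, r_whole, min_size) {
  if (igraph::vcount(comp) < 4) return(NULL)
  br <- igraph::bridges(comp)
  if (!length(br)) return(NULL)
  el <- igraph::as_edgelist(comp)[as.integer(br), , drop = FALSE]
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  for (k in order(lo, hi)) {
    g2 <- igraph::delete_edges(comp, br[k])
    memb <- igraph::components(g2)$membership
    sides <- lapply(1:2, function(i)
      igraph::induced_subgraph(g2, names(memb)[memb == i]))
    dens <- vapply(sides, function(s) {
      n <- igraph::vcount(s)
      if (n < 2) return(1)  # a lone vertex never blocks the split
      connectivity_ratio(n, igraph::ecount(s))
    }, 0)
    if (all(dens > r_whole)) return(sides)
  }
  NULL
}

#' @export
print.dense_module <- function(x, ...) {
  cat(sprintf("<dense_module: n = %d, L = %d, r = %.3f%s>\n", x$n, x$L, x$r,
              if (is.na(x$coherence)) ""
              else sprintf(", coherence = %.3f", x$coherence)))
  invisible(x)
}

# mean pairwise Jaccard similarity of the edges' dataset-support sets
module_coherence <- function(edges) {
  m <- nrow(edges)
  if (m < 2) return(1)
  sets <- edges$datasets
  pairs <- utils::combn(m, 2)
  jac <- apply(pairs, 2, function(p) {
    s1 <- sets[[p[1]]]; s2 <- sets[[p[2]]]
    u <- length(union(s1, s2))
    if (u == 0) return(1)
    length(intersect(s1, s2)) / u
  })
  mean(jac)
}

#' Filter mined modules by cross-dataset coherence
#'
#' A module is coherent when its edges tend to be supported by the same
#' datasets. For every pair of module edges the Jaccard similarity of their
#' dataset-support sets is computed; the module's coherence is the mean over
#' all pairs (1 for modules with fewer than two edges). Modules below
#' `min_coherence` are discarded.
#'
#' @param modules list of `dense_module` objects from [mine_dense()] run on
#'   a [summary_graph()] (edges must carry dataset-support sets).
#' @param min_coherence minimum mean pairwise Jaccard in `[0, 1]`.
#' @return filtered list of modules with the `coherence` field set.
#' @export
coherence_filter <- function(modules, min_coherence = 0.5) {
  scored <- lapply(modules, function(m) {
    m$coherence <- module_coherence(m$edges)
    m
  })
  Filter(function(m) m$coherence >= min_coherence, scored)
}

#' Per-gene differential expression between the two phenotype groups
#'
#' Welch two-sample t-test for each gene, comparing labelled sample groups
#' (e.g. IgVH unmutated vs mutated). P-values are two-sided and by default
#' unadjusted; Benjamini-Hochberg adjustment is available.
#'
#' @param ds a labelled [expr_dataset()] with at least 2 samples per group.
#' @param genes genes to test (default: all genes in `ds`).
#' @param alpha significance level for `significant_set`.
#' @param adjust "none" (default) or "BH".
#' @return An object of class `de_result`: `table` (gene, t, p, p_adj,
#'   group means) and `significant_set`.
#' @export
differential_expression <- function(ds, genes = rownames(ds$values),
                                    alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ds, "expr_dataset"))
  if (is.null(ds$labels)) stop("dataset carries no phenotype labels")
  missing <- setdiff(genes, rownames(ds$values))
  if (length(missing))
    stop("genes not in dataset: ", paste(utils::head(missing, 5),
                                         collapse = ", "))
  g0 <- ds$labels == 0L
  if (sum(g0) < 2 || sum(!g0) < 2) stop("each group needs >= 2 samples")
  x0 <- ds$values[genes, g0, drop = FALSE]
  x1 <- ds$values[genes, !g0, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- apply(x0, 1, stats::var); v1 <- apply(x1, 1, stats::var)
  se2 <- v0 / n0 + v1 / n1
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  tab <- data.frame(gene = genes, t = unname(tstat), p = unname(p),
                    p_adj = unname(p_adj),
                    mean_group0 = unname(m0), mean_group1 = unname(m1),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, adjust = adjust,
                 significant_set = tab$gene[tab$p_adj < alpha]),
            class = "de_result")
}

#' Repeated stratified-holdout evaluation of a diagonal linear classifier
#'
#' Repeats `n_repeats` times: hold out a stratified `holdout` fraction of
#' samples, fit a diagonal linear discriminant on the rest (per-gene class
#' means with a pooled per-gene variance; a sample is assigned to the class
#' with the nearer standardized mean), and score the held-out samples.
#'
#' @param ds a labelled [expr_dataset()].
#' @param genes feature genes.
#' @param holdout held-out fraction in (0, 1); default 0.2.
#' @param n_repeats number of random splits.
#' @param seed integer seed.
#' @return An object of class `classifier_report`: mean `accuracy`,
#'   per-repeat `accuracies`, `holdout_fraction`, `n_repeats`, `seed`.
#' @export
holdout_eval <- function(ds, genes, holdout = 0.2, n_repeats = 50, seed = 1) {
  stopifnot(inherits(ds, "expr_dataset"), holdout > 0, holdout < 1)
  if (is.null(ds$labels)) stop("dataset carries no phenotype labels")
  X <- t(ds$values[genes, , drop = FALSE])  # samples x genes
  y <- ds$labels
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  if (!length(idx0) || !length(idx1)) stop("both classes must be present")
  set.seed(as.integer(seed))
  acc <- vapply(seq_len(n_repeats), function(i) {
    repeat {
      h0 <- sample(idx0, max(1, round(length(idx0) * holdout)))
      h1 <- sample(idx1, max(1, round(length(idx1) * holdout)))
      test <- c(h0, h1)
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) == 2 &&
          sum(y[train] == 0) >= 2 && sum(y[train] == 1) >= 2) break
      message("degenerate training split resampled")
    }
    mu0 <- colMeans(X[train[y[train] == 0L], , drop = FALSE])
    mu1 <- colMeans(X[train[y[train] == 1L], , drop = FALSE])
    v0 <- apply(X[train[y[train] == 0L], , drop = FALSE], 2, stats::var)
    v1 <- apply(X[train[y[train] == 1L], , drop = FALSE], 2, stats::var)
    n0 <- sum(y[train] == 0L); n1 <- sum(y[train] == 1L)
    pool <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    pool[pool == 0] <- min(pool[pool > 0], 1e-12)
    # discriminant score: positive favours class 1
    sc <- sweep(X[test, , drop = FALSE], 2, (mu0 + mu1) / 2) %*%
      ((mu1 - mu0) / pool)
    mean((sc > 0) == (y[test] == 1L))
  }, 0)
  structure(list(accuracy = mean(acc), accuracies = acc,
                 holdout_fraction = holdout, n_repeats = n_repeats,
                 seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: mean holdout accuracy %.3f over %d repeats>\n",
              x$accuracy, x$n_repeats))
  invisible(x)
}
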