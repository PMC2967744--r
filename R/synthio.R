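# Synthetic generators for the three input families the pipeline consumes:
# multi-dataset expression panels with planted co-expression modules, clinical
# encounter tables with correlated attribute blocks, and toy is-a ontologies
# with associative cross-links. All generators are pure functions of their
# arguments including `seed`.

#' Expression dataset container
#'
#' A single gene-by-sample expression matrix with an optional binary
#' phenotype label per sample (e.g. IgVH mutated vs unmutated).
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry unique rownames (gene symbols) and colnames (sample ids).
#' @param dataset_id character scalar identifying the dataset.
#' @param labels optional named integer/numeric vector of 0/1 phenotype
#'   labels; names must cover every sample.
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, dataset_id, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !setequal(names(labels), colnames(values)))
      stop("`labels` must be named and cover every sample")
    labels <- labels[colnames(values)]
    if (!all(labels %in% c(0, 1)))
      stop("`labels` must be binary (0/1)")
    labels <- as.integer(labels)
    names(labels) <- colnames(values)
  }
  structure(list(dataset_id = as.character(dataset_id),
                 values = values, labels = labels),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset '%s': %d genes x %d samples%s>\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Planted co-expression module specification
#'
#' Describes one latent-factor module: its member genes, the range their
#' factor loadings are drawn from, an optional phenotype mean shift and the
#' within-module noise standard deviation.
#'
#' @param member_genes character vector of gene symbols (disjoint across
#'   modules within one panel).
#' @param loading_range length-2 numeric interval loadings are drawn from
#'   uniformly.
#' @param effect_size mean expression shift between the two phenotype groups
#'   applied to every member gene (0 = no differential expression).
#' @param noise_sd positive gene-level noise standard deviation.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(member_genes, loading_range = c(0.9, 1.1),
                        effect_size = 0, noise_sd = 1) {
  member_genes <- as.character(member_genes)
  if (length(member_genes) < 2 || anyDuplicated(member_genes))
    stop("`member_genes` must be >= 2 unique gene symbols")
  if (length(loading_range) != 2 || loading_range[1] > loading_range[2])
    stop("`loading_range` must be an ordered interval")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be > 0")
  structure(list(member_genes = member_genes,
                 loading_range = as.numeric(loading_range),
                 effect_size = as.numeric(effect_size),
                 noise_sd = as.numeric(noise_sd)),
            class = "module_spec")
}

#' Generate a panel of expression datasets with planted modules
#'
#' Each dataset is drawn independently under a single-latent-factor model:
#' for gene g in module m, `value = loading_g * f_m(sample) + noise`, with
#' `f_m` standard normal per sample and `noise ~ N(0, noise_sd_m)`.
#' Background genes are pure `N(0, background_sd)` noise. Module genes with a
#' nonzero `effect_size` additionally have their group-1 mean shifted by
#' `effect_size`, giving planted differential expression against the balanced
#' binary phenotype labels.
#'
#' Gene ids are the module members (in order) followed by autogenerated
#' background symbols; the gene universe is shared across all datasets of
#' the panel.
#'
#' @param n_datasets,n_genes,n_samples positive counts.
#' @param modules list of [module_spec()] objects with disjoint members.
#' @param anchor_genes optional character vector; each must belong to some
#'   module (anchors are only useful if they carry signal).
#' @param background_sd standard deviation of background (non-module) genes.
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return list of [expr_dataset()] objects.
#' @export
gen_expression_panel <- function(n_datasets, n_genes, n_samples = 100,
                                 modules = list(), anchor_genes = character(),
                                 background_sd = 1, seed = 1) {
  stopifnot(n_datasets >= 1, n_genes >= 1, n_samples >= 2)
  member_all <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(member_all))
    stop("module member sets overlap: ",
         paste(unique(member_all[duplicated(member_all)]), collapse = ", "))
  if (length(member_all) > n_genes)
    stop("modules contain more genes than `n_genes`")
  if (length(anchor_genes) && !all(anchor_genes %in% member_all))
    stop("every anchor gene must be a member of some module")
  n_bg <- n_genes - length(member_all)
  gene_ids <- c(member_all,
                setdiff(sprintf("g%05d", seq_len(n_genes + length(member_all))),
                        member_all)[seq_len(n_bg)])
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  labels <- rep(c(0L, 1L), length.out = n_samples)
  names(labels) <- sample_ids

  set.seed(as.integer(seed))
  lapply(seq_len(n_datasets), function(d) {
    vals <- matrix(stats::rnorm(n_genes * n_samples, sd = background_sd),
                   nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    for (m in modules) {
      f <- stats::rnorm(n_samples)
      loadings <- stats::runif(length(m$member_genes),
                               m$loading_range[1], m$loading_range[2])
      noise <- matrix(stats::rnorm(length(m$member_genes) * n_samples,
                                   sd = m$noise_sd),
                      nrow = length(m$member_genes))
      vals[m$member_genes, ] <- outer(loadings, f) + noise
      if (m$effect_size != 0)
        vals[m$member_genes, labels == 1L] <-
          vals[m$member_genes, labels == 1L] + m$effect_size
    }
    expr_dataset(vals, dataset_id = sprintf("ds%02d", d), labels = labels)
  })
}

#' Clinical variable specification
#'
#' @param name attribute name.
#' @param kind "categorical" or "continuous".
#' @param categories ordered character vector of admissible categories
#'   (categorical only, non-empty).
#' @param reference_range optional `c(low, high)` laboratory reference range
#'   (continuous only, `low < high`).
#' @param mapped_concept optional ontology concept id this variable maps to.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("categorical", "continuous"),
                          categories = NULL, reference_range = NULL,
                          mapped_concept = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0)
      stop("categorical variable '", name, "' needs non-empty `categories`")
    categories <- as.character(categories)
  } else if (!is.null(reference_range)) {
    if (length(reference_range) != 2 || reference_range[1] >= reference_range[2])
      stop("`reference_range` must satisfy low < high for '", name, "'")
    reference_range <- as.numeric(reference_range)
  }
  structure(list(name = as.character(name), kind = kind,
                 categories = categories, reference_range = reference_range,
                 mapped_concept = mapped_concept),
            class = "variable_spec")
}

# latent Pearson correlation giving a target Spearman rho under a Gaussian
# copula (Pearson 1907 relation)
latent_from_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a clinical encounter table
#'
#' Draws one row per encounter under a latent Gaussian copula. Variables in
#' one `block_corr` entry share an exchangeable latent correlation chosen so
#' the realized Spearman correlation approximates the requested target;
#' all other variables are independent. Categorical values are produced by
#' thresholding the latent at equal-probability quantiles; continuous values
#' with a reference range are centred on the range (sd = range width / 4).
#' Null entries are placed independently at `missing_rate`
#' (missing-completely-at-random).
#'
#' @param n_encounters number of rows.
#' @param variables list of [variable_spec()] objects.
#' @param block_corr list of `list(vars = <names>, rho = <target Spearman>)`;
#'   blocks must be disjoint, `rho` strictly inside (-1, 1).
#' @param missing_rate fraction of entries set to NA, in `[0, 1)`.
#' @param seed integer seed.
#' @return An object of class `encounter_table`: `encounter_ids`,
#'   `variables`, and `data` (a data.frame with NA for null).
#' @export
gen_encounter_table <- function(n_encounters, variables, block_corr = list(),
                                missing_rate = 0, seed = 1) {
  stopifnot(n_encounters >= 1, length(variables) >= 1)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  var_names <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(var_names)) stop("duplicate variable names")
  blocked <- unlist(lapply(block_corr, `[[`, "vars"))
  if (anyDuplicated(blocked)) stop("block variable sets must be disjoint")
  if (!all(blocked %in% var_names)) stop("unknown variable in `block_corr`")
  for (b in block_corr)
    if (!is.numeric(b$rho) || abs(b$rho) >= 1)
      stop("block target rho must lie strictly inside (-1, 1)")

  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_encounters * length(variables)),
              nrow = n_encounters, dimnames = list(NULL, var_names))
  for (b in block_corr) {
    k <- length(b$vars)
    if (k < 2) next
    r <- latent_from_spearman(b$rho)
    if (r < -1 / (k - 1) + 1e-9)
      stop("block target rho too negative for a block of size ", k)
    R <- matrix(r, k, k); diag(R) <- 1
    z[, b$vars] <- matrix(stats::rnorm(n_encounters * k),
                          nrow = n_encounters) %*% chol(R)
  }

  data <- as.data.frame(matrix(NA, n_encounters, length(variables),
                               dimnames = list(NULL, var_names)))
  for (j in seq_along(variables)) {
    v <- variables[[j]]
    if (v$kind == "categorical") {
      k <- length(v$categories)
      cuts <- stats::qnorm(seq_len(k - 1) / k)
      data[[j]] <- v$categories[findInterval(z[, j], cuts) + 1L]
    } else if (!is.null(v$reference_range)) {
      mid <- mean(v$reference_range)
      sdv <- diff(v$reference_range) / 4
      data[[j]] <- mid + z[, j] * sdv
    } else {
      data[[j]] <- z[, j]
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_encounters * length(variables)) < missing_rate,
                   nrow = n_encounters)
    for (j in seq_along(variables)) data[[j]][drop[, j]] <- NA
  }
  structure(list(encounter_ids = sprintf("e%05d", seq_len(n_encounters)),
                 variables = variables, data = data),
            class = "encounter_table")
}

#' Ontology container
#'
#' Concepts plus directed typed relation triples; the sub-graph restricted to
#' `isa_labels` must be acyclic (it is the concept hierarchy).
#'
#' @param concepts data.frame with columns `id`, `name`, `synonyms`
#'   (`|`-separated, possibly empty) and `semantic_type`.
#' @param relations data.frame with columns `source`, `label`, `target`.
#' @param isa_labels relation labels treated as hierarchical (child is
#'   `source`, parent is `target`).
#' @return An object of class `ontology`.
#' @export
ontology <- function(concepts, relations, isa_labels = "is_a") {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  need <- c("id", "name", "synonyms", "semantic_type")
  if (!all(need %in% names(concepts)))
    stop("`concepts` needs columns: ", paste(need, collapse = ", "))
  if (!all(c("source", "label", "target") %in% names(relations)))
    stop("`relations` needs columns source, label, target")
  if (anyDuplicated(concepts$id)) stop("duplicate concept ids")
  dangling <- setdiff(c(relations$source, relations$target), concepts$id)
  if (length(dangling))
    stop("relation endpoints missing from concepts: ",
         paste(utils::head(dangling, 5), collapse = ", "))
  isa <- relations[relations$label %in% isa_labels, , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa[, c("source", "target")],
                                       directed = TRUE,
                                       vertices = concepts$id)
    if (!igraph::is_dag(g))
      stop("hierarchical (is-a) subgraph contains a cycle")
  }
  structure(list(concepts = concepts, relations = relations,
                 isa_labels = isa_labels),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d concepts, %d relations (%d hierarchical)>\n",
              nrow(x$concepts), nrow(x$relations),
              sum(x$relations$label %in% x$isa_labels)))
  invisible(x)
}

#' Generate a toy ontology plus a data-dictionary mapping
#'
#' Builds a rooted is-a tree of `n_concepts` with the given branching factor,
#' adds `n_crosslinks` random associative triples, generates one synonym per
#' concept by token permutation, and pairs synthetic data-dictionary element
#' names with leaf concepts (element name = concept name plus a qualifier
#' token, so lexical mapping is exercised, not trivial).
#'
#' @param n_concepts,branching positive counts.
#' @param n_crosslinks number of associative relations to add.
#' @param associative_labels labels the cross-links are drawn from.
#' @param seed integer seed.
#' @return list with elements `ontology` (an [ontology()]) and `mapping`
#'   (data.frame `element`, `concept_id`).
#' @export
gen_ontology <- function(n_concepts, branching = 2, n_crosslinks = 0,
                         associative_labels = c("associated_with",
                                                "part_of", "related_to"),
                         seed = 1) {
  stopifnot(n_concepts >= 1, branching >= 1, n_crosslinks >= 0)
  set.seed(as.integer(seed))
  ids <- sprintf("C%04d", seq_len(n_concepts))
  words <- c("marker", "assay", "finding", "cell", "protein",
             "disease", "tissue", "process")
  stems <- rep_len(words, n_concepts)
  names_ <- paste(stems, sprintf("%04d", seq_len(n_concepts)))
  syns <- paste(sprintf("%04d", seq_len(n_concepts)), stems)
  types <- rep_len(c("finding", "gene", "procedure", "disease"), n_concepts)
  concepts <- data.frame(id = ids, name = names_, synonyms = syns,
                         semantic_type = types, stringsAsFactors = FALSE)

  relations <- data.frame(source = character(), label = character(),
                          target = character(), stringsAsFactors = FALSE)
  if (n_concepts > 1) {
    child <- 2:n_concepts
    parent <- ((child - 2L) %/% branching) + 1L
    relations <- data.frame(source = ids[child], label = "is_a",
                            target = ids[parent], stringsAsFactors = FALSE)
  }
  if (n_crosslinks > 0 && n_concepts > 2) {
    seen <- character()
    added <- 0L
    while (added < n_crosslinks) {
      pair <- sort(sample.int(n_concepts, 2))
      key <- paste(pair, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      relations <- rbind(relations, data.frame(
        source = ids[pair[1]],
        label = sample(associative_labels, 1),
        target = ids[pair[2]], stringsAsFactors = FALSE))
      added <- added + 1L
    }
  }
  onto <- ontology(concepts, relations, isa_labels = "is_a")
  leaves <- setdiff(ids, relations$target[relations$label == "is_a"])
  mapping <- data.frame(element = paste(names_[match(leaves, ids)], "value"),
                        concept_id = leaves, stringsAsFactors = FALSE)
  list(ontology = onto, mapping = mapping)
}
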