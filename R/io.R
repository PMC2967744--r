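# Plain-text interchange formats: expression TSV (+ labels TSV), encounter
# CSV, ontology TSV / minimal OBO, element-concept mapping TSV, edge list
# TSV, Pajek NET. Writers produce files the readers round-trip; readers
# fail with line-numbered structural errors.

#' Write / read an expression matrix as TSV
#'
#' First column `gene_id`, header row = sample ids, tab-separated.
#'
#' @param ds an [expr_dataset()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expr_dataset"))
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param dataset_id id given to the read dataset.
#' @param labels_path optional labels TSV (columns `sample_id`, `label`)
#'   as written by [write_labels_tsv()].
#' @export
read_expression_tsv <- function(path, dataset_id = basename(path),
                                labels_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop(path, ": first column must be 'gene_id'")
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop(path, ": duplicated gene id '", df$gene_id[dup[1]],
         "' at line ", dup[1] + 1)  # +1 for the header line
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values")
  rownames(m) <- df$gene_id
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "label") %in% names(lab)))
      stop(labels_path, ": needs columns sample_id, label")
    labels <- stats::setNames(lab$label, lab$sample_id)
  }
  expr_dataset(m, dataset_id = dataset_id, labels = labels)
}

#' Write sample phenotype labels as TSV
#'
#' @param ds a labelled [expr_dataset()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_labels_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expr_dataset"), !is.null(ds$labels))
  utils::write.table(
    data.frame(sample_id = names(ds$labels), label = unname(ds$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an encounter table as CSV
#'
#' Header row of variable names; an empty field is a null (read back as NA,
#' never as an empty-string category).
#'
#' @param tbl an `encounter_table`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_encounter_csv <- function(tbl, path) {
  stopifnot(inherits(tbl, "encounter_table"))
  out <- cbind(data.frame(encounter_id = tbl$encounter_ids,
                          stringsAsFactors = FALSE), tbl$data)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_encounter_csv
#' @param variables list of [variable_spec()] objects giving each column's
#'   kind (continuous columns are parsed numerically, with the offending
#'   entry named on failure).
#' @export
read_encounter_csv <- function(path, variables) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (names(raw)[1] != "encounter_id")
    stop(path, ": first column must be 'encounter_id'")
  var_names <- vapply(variables, `[[`, "", "name")
  missing_cols <- setdiff(var_names, names(raw))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- raw[, var_names, drop = FALSE]
  for (v in variables) {
    col <- data[[v$name]]
    col[col == ""] <- NA  # empty field = null, not an empty-string category
    if (v$kind == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(path, ": non-numeric value '", col[bad[1]], "' in continuous '",
             v$name, "' at line ", bad[1] + 1)
      col <- num
    }
    data[[v$name]] <- col
  }
  structure(list(encounter_ids = raw$encounter_id, variables = variables,
                 data = data),
            class = "encounter_table")
}

#' Write / read an ontology as a TSV pair
#'
#' `<stem>_concepts.tsv` holds `id`, `name`, `synonyms` (`|`-separated) and
#' `semantic_type`; `<stem>_relations.tsv` holds `source`, `label`,
#' `target`.
#'
#' @param onto an [ontology()].
#' @param stem path stem the two files are derived from.
#' @return the concepts path, invisibly.
#' @export
write_ontology_tsv <- function(onto, stem) {
  stopifnot(inherits(onto, "ontology"))
  utils::write.table(onto$concepts, paste0(stem, "_concepts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(onto$relations, paste0(stem, "_relations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(stem, "_concepts.tsv"))
}

#' @rdname write_ontology_tsv
#' @param isa_labels relation labels treated as hierarchical.
#' @export
read_ontology_tsv <- function(stem, isa_labels = "is_a") {
  concepts <- utils::read.delim(paste0(stem, "_concepts.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  relations <- utils::read.delim(paste0(stem, "_relations.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
  if (is.null(concepts$synonyms)) concepts$synonyms <- ""
  concepts$synonyms[is.na(concepts$synonyms)] <- ""
  ontology(concepts, relations, isa_labels = isa_labels)
}

#' Read a minimal OBO ontology
#'
#' Supports `[Term]` stanzas with `id`, `name`, `synonym`, `is_a` and
#' `relationship: <label> <target>` tags; everything else is ignored.
#'
#' @param path OBO file path.
#' @return an [ontology()] with `isa_labels = "is_a"`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list(); cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(syn = character(), rel = list())
    } else if (is.null(cur) || ln == "" || startsWith(ln, "[")) {
      if (startsWith(ln, "[") && ln != "[Term]") { terms <- flush(cur, terms); cur <- NULL }
      next
    } else if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexec("synonym:\\s*\"([^\"]*)\"", ln))[[1]]
      if (length(m) < 2) stop(path, ": malformed synonym at line ", i)
      cur$syn <- c(cur$syn, m[2])
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$rel[[length(cur$rel) + 1]] <- c("is_a", tgt)
    } else if (startsWith(ln, "relationship:")) {
      parts <- strsplit(trimws(sub("!.*$", "",
                                   sub("^relationship:", "", ln))),
                        "\\s+")[[1]]
      if (length(parts) < 2)
        stop(path, ": malformed relationship at line ", i)
      cur$rel[[length(cur$rel) + 1]] <- parts[1:2]
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop(path, ": no [Term] stanzas found")
  concepts <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, function(t) t$name %||% t$id, ""),
    synonyms = vapply(terms, function(t) paste(t$syn, collapse = "|"), ""),
    semantic_type = "", stringsAsFactors = FALSE)
  rels <- do.call(rbind, unlist(lapply(terms, function(t)
    lapply(t$rel, function(r)
      data.frame(source = t$id, label = r[1], target = r[2],
                 stringsAsFactors = FALSE))), recursive = FALSE))
  if (is.null(rels))
    rels <- data.frame(source = character(), label = character(),
                       target = character(), stringsAsFactors = FALSE)
  ontology(concepts, rels, isa_labels = "is_a")
}

#' Write / read an element-to-concept mapping TSV
#'
#' @param mapping data.frame with columns `element`, `concept_id`.
#' @param path file path.
#' @return `path` / the mapping data.frame.
#' @export
write_mapping_tsv <- function(mapping, path) {
  stopifnot(all(c("element", "concept_id") %in% names(mapping)))
  utils::write.table(mapping[, c("element", "concept_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @export
read_mapping_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("element", "concept_id") %in% names(df)))
    stop(path, ": needs columns element, concept_id")
  df
}

#' Write / read a co-expression edge list TSV
#'
#' Columns `gene_a`, `gene_b`, `rho`, `support`, with the lexicographically
#' smaller gene first (canonical form for diffing).
#'
#' @param graph a [coexpr_graph()].
#' @param path file path.
#' @return `path` / a [coexpr_graph()].
#' @export
write_edgelist_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "coexpr_graph"))
  utils::write.table(
    data.frame(gene_a = graph$edges$a, gene_b = graph$edges$b,
               rho = graph$edges$rho, support = graph$edges$support),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "rho", "support")
  if (!all(need %in% names(df)))
    stop(path, ": needs columns ", paste(need, collapse = ", "))
  edges <- canonical_edges(df$gene_a, df$gene_b, rho = df$rho,
                           support = as.integer(df$support))
  edges$datasets <- I(rep(list(character()), nrow(edges)))
  coexpr_graph(unique(c(df$gene_a, df$gene_b)), edges)
}

#' Write / read a graph in Pajek NET format
#'
#' `*Vertices n` with quoted vertex names, then `*Edges` as index pairs.
#'
#' @param nodes character vector of vertex names.
#' @param edges data.frame with columns `from`, `to` (names in `nodes`).
#' @param path file path.
#' @return `path` / list(`nodes`, `edges`).
#' @export
write_pajek <- function(nodes, edges, path) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% nodes))
    stop("edge endpoints missing from nodes")
  lines <- c(sprintf("*Vertices %d", length(nodes)),
             sprintf("%d \"%s\"", seq_along(nodes), nodes),
             "*Edges")
  if (nrow(edges))
    lines <- c(lines, sprintf("%d %d", idx[edges$from], idx[edges$to]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pajek
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (!length(vhead) || !length(ehead))
    stop(path, ": not a Pajek NET file (missing *Vertices/*Edges)")
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead[1]],
                      ignore.case = TRUE))
  vlines <- lines[(vhead[1] + 1):(vhead[1] + n)]
  m <- regmatches(vlines, regexec("^(\\d+)\\s+\"(.*)\"", vlines))
  bad <- which(vapply(m, length, 0L) == 0)
  if (length(bad))
    stop(path, ": malformed vertex at line ", vhead[1] + bad[1])
  names_ <- character(n)
  names_[as.integer(vapply(m, `[[`, "", 2))] <- vapply(m, `[[`, "", 3)
  elines <- lines[seq_len(length(lines)) > ehead[1]]
  elines <- elines[nzchar(trimws(elines))]
  edges <- if (length(elines)) {
    em <- do.call(rbind, strsplit(trimws(elines), "\\s+"))
    data.frame(from = names_[as.integer(em[, 1])],
               to = names_[as.integer(em[, 2])], stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  list(nodes = names_, edges = edges)
}

#' Write a clinical correlation matrix as TSV
#'
#' Square symmetric matrix of Spearman correlations with the sentinel token
#' `NA` for pairs whose correlation is undefined (below the minimum-pair
#' rule or constant); the diagonal is 1.
#'
#' @param net a [build_clinical_network()] result. The matrix holds the
#'   correlations of thresholded edges, `NA` sentinels for undefined pairs,
#'   and blanks for defined sub-threshold pairs (which the network does not
#'   retain); undefined is never coerced to zero.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_clinical_matrix_tsv <- function(net, path) {
  stopifnot(inherits(net, "clinical_network"))
  nodes <- net$nodes
  m <- matrix("", length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(m) <- "1"
  if (nrow(net$edges)) for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]; b <- net$edges$b[i]
    m[a, b] <- m[b, a] <- format(net$edges$rho[i])
  }
  if (nrow(net$undefined_pairs)) for (i in seq_len(nrow(net$undefined_pairs))) {
    a <- net$undefined_pairs$a[i]; b <- net$undefined_pairs$b[i]
    m[a, b] <- m[b, a] <- "NA"
  }
  utils::write.table(data.frame(attribute = nodes, m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mined modules as JSON
#'
#' @param modules list of `dense_module` objects.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_modules_json <- function(modules, path) {
  payload <- lapply(modules, function(m)
    list(genes = m$genes, n = m$n, L = m$L, r = m$r,
         coherence = m$coherence))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
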