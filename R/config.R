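# Run configuration and the end-to-end pipeline. Every numeric default is
# the published operating point of the corresponding stage: anchor lists at
# |rho| >= 0.4, per-dataset graphs at |rho| >= 0.75, summary-graph support
# >= 4 datasets, module connectivity r > 0.4, clinical threshold
# rho >= 0.95 with >= 20 complete pairs, <= 8 categorical bins, 20% holdout.

#' Pipeline run configuration
#'
#' Central container for every tunable threshold and seed. Unknown keys are
#' rejected and each value is checked against its documented domain.
#'
#' @param ... overrides of the defaults: `anchor_rho` (0.4), `graph_rho`
#'   (0.75), `clinical_rho` (0.95), `min_support` (4), `min_r` (0.4),
#'   `min_size` (3), `min_pairs` (20), `max_cats` (8), `holdout` (0.2),
#'   `alpha` (0.05), `granularity_delta` (1), `max_intermediates` (1),
#'   `min_coherence` (0.5), `n_repeats` (50), `seed` (1).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    anchor_rho = 0.4, graph_rho = 0.75, clinical_rho = 0.95,
    min_support = 4L, min_r = 0.4, min_size = 3L, min_pairs = 20L,
    max_cats = 8L, holdout = 0.2, alpha = 0.05,
    granularity_delta = 1L, max_intermediates = 1L,
    min_coherence = 0.5, n_repeats = 50L, seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  in_01 <- function(key, open_low = TRUE, open_high = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1 &&
      (if (open_low) v > 0 else v >= 0) &&
      (if (open_high) v < 1 else v <= 1)
    if (!ok) stop("configuration key '", key, "' outside its domain")
  }
  in_01("anchor_rho"); in_01("graph_rho"); in_01("clinical_rho")
  in_01("min_r"); in_01("alpha"); in_01("min_coherence", open_low = FALSE)
  in_01("holdout", open_high = TRUE)
  for (key in c("min_support", "min_pairs", "max_cats", "n_repeats",
                "min_size", "seed")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("configuration key '", key, "' must be a positive integer")
    cfg[[key]] <- as.integer(v)
  }
  for (key in c("granularity_delta", "max_intermediates")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0 || v != round(v))
      stop("configuration key '", key, "' must be a non-negative integer")
    cfg[[key]] <- as.integer(v)
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Run the full discovery pipeline on synthetic data
#'
#' End-to-end demonstration and integration surface: generates a seeded
#' expression panel with one planted co-expression module, a clinical
#' encounter table with one highly correlated attribute block, and a toy
#' ontology; induces the three network layers (summary-graph dense-module
#' mining, clinical Spearman network, CKC generation), cross-links them and
#' extracts vertical complexes. When `out_dir` is given, every artifact is
#' written (expression/labels TSV, encounter CSV, ontology TSV, edge lists,
#' modules JSON, clinical matrix TSV, Pajek NET, multinet DOT, complexes
#' and summary JSON). Fully deterministic under a fixed configuration.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with the main intermediate objects and a `summary` list of
#'   headline numbers, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- gene layer ---------------------------------------------------------
  module_genes <- c("ZAP70", "CD38", sprintf("MG%02d", 1:8))
  panel <- gen_expression_panel(
    n_datasets = 6, n_genes = 100, n_samples = 100,
    modules = list(module_spec(module_genes, effect_size = 1.5,
                               noise_sd = 0.5)),
    anchor_genes = c("ZAP70", "CD38"), seed = seed)
  graphs <- lapply(panel, build_coexpr_graph, threshold = config$graph_rho)
  sg <- summary_graph(graphs, min_support = config$min_support)
  modules <- mine_dense(sg, min_r = config$min_r, min_size = config$min_size)
  modules <- coherence_filter(modules, min_coherence = config$min_coherence)
  anchors <- lapply(panel[1:2], anchor_list, anchor = "ZAP70",
                    threshold = config$anchor_rho)
  ov <- overlap_test(anchors[[1]], anchors[[2]], universe = 100)
  module_union <- sort(unique(unlist(lapply(modules, `[[`, "genes"))))
  de <- differential_expression(panel[[1]],
                                genes = if (length(module_union))
                                  module_union else module_genes,
                                alpha = config$alpha)
  clf <- holdout_eval(panel[[1]],
                      genes = if (length(de$significant_set))
                        de$significant_set else module_genes,
                      holdout = config$holdout,
                      n_repeats = config$n_repeats, seed = seed)

  # --- clinical layer -----------------------------------------------------
  # the correlated block sits on 8-level ordinal attributes: coarser
  # 3-level bins attenuate a 0.99 rank correlation below the 0.95 threshold
  grades <- sprintf("grade%d", 1:8)
  vars <- c(
    lapply(sprintf("lab_%02d", 1:4), function(n)
      variable_spec(n, "continuous", reference_range = c(4, 6))),
    lapply(sprintf("score_%02d", 1:3), function(n)
      variable_spec(n, "categorical", categories = grades)),
    lapply(sprintf("cat_%02d", 1:3), function(n)
      variable_spec(n, "categorical", categories = c("absent", "mild",
                                                     "severe"))))
  enc <- gen_encounter_table(
    1000, vars,
    block_corr = list(list(vars = c("score_01", "score_02", "score_03"),
                           rho = 0.99)),
    missing_rate = 0.1, seed = seed)
  binned <- bin_table(enc, max_cats = config$max_cats)
  clin <- build_clinical_network(binned, rho_min = config$clinical_rho,
                                 min_pairs = config$min_pairs)
  hubs <- top_hubs(clin, k = min(10, length(clin$nodes)))

  # --- knowledge layer ----------------------------------------------------
  toy <- gen_ontology(40, branching = 3, n_crosslinks = 25, seed = seed)
  dict <- data.frame(element = toy$mapping$element,
                     kind = rep(c("phenotypic", "bio-molecular"),
                                length.out = nrow(toy$mapping)),
                     stringsAsFactors = FALSE)
  mappings <- suppressMessages(map_elements(dict, toy$ontology))
  ckcs <- generate_ckcs(mappings, toy$ontology,
                        max_intermediates = config$max_intermediates,
                        granularity_delta = config$granularity_delta)
  concept_net <- ckc_network(ckcs)

  # --- integration --------------------------------------------------------
  # only the anchor markers and the planted clinical block resolve to
  # concepts; a short hop budget keeps simple-path search tractable on the
  # dense mined module
  gene_map <- data.frame(label = c("ZAP70", "CD38"),
                         concept_id = toy$mapping$concept_id[1:2],
                         stringsAsFactors = FALSE)
  clin_map <- data.frame(label = sprintf("score_%02d", 1:3),
                         concept_id = toy$mapping$concept_id[3:5],
                         stringsAsFactors = FALSE)
  layers <- list(conceptual = concept_net,
                 gene = gene_layer(sg, gene_map),
                 clinical = clinical_layer(clin, clin_map))
  mn <- cross_link(layers, toy$ontology)
  complexes <- if (nrow(mn$cross_links))
    extract_complexes(mn, "gene", "clinical", max_len = 4) else list()

  summary <- list(
    n_summary_edges = nrow(sg$edges),
    n_modules = length(modules),
    module_genes_found = module_union,
    anchor_overlap_p = ov$p_value,
    n_de_significant = length(de$significant_set),
    holdout_accuracy = clf$accuracy,
    n_clinical_edges = nrow(clin$edges),
    n_clinical_undefined = nrow(clin$undefined_pairs),
    n_ckcs = length(ckcs),
    n_cross_links = nrow(mn$cross_links),
    n_complexes = length(complexes))

  result <- list(panel = panel, summary_graph = sg, modules = modules,
                 overlap = ov, de = de, classifier = clf,
                 clinical = clin, hubs = hubs, ontology = toy$ontology,
                 ckcs = ckcs, multinet = mn, complexes = complexes,
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    for (i in seq_along(panel)) {
      write_expression_tsv(panel[[i]], p(sprintf("expression_ds%02d.tsv", i)))
      write_labels_tsv(panel[[i]], p(sprintf("labels_ds%02d.tsv", i)))
    }
    write_edgelist_tsv(sg, p("summary_edges.tsv"))
    write_modules_json(modules, p("modules.json"))
    write_encounter_csv(enc, p("encounters.csv"))
    write_clinical_matrix_tsv(clin, p("clinical_matrix.tsv"))
    write_pajek(clin$nodes,
                data.frame(from = clin$edges$a, to = clin$edges$b,
                           stringsAsFactors = FALSE),
                p("clinical_network.net"))
    write_ontology_tsv(toy$ontology, p("ontology"))
    write_mapping_tsv(toy$mapping, p("mapping.tsv"))
    utils::write.table(
      data.frame(ckc = format_ckc(ckcs)), p("ckcs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    export_multinet(mn, p("multinet.dot"), format = "dot")
    export_multinet(mn, p("multinet.net"), format = "pajek")
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}
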