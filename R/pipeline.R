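#' Default pipeline configuration
#'
#' Analysis-stage parameters for [run_pipeline()], separate from the
#' synthetic-data configuration. The `fidelity` block collects the flags
#' that toggle between this package's defaults and the stricter literal
#' readings of the source workflow: `star_only` metal networks (seed-to-
#' neighbor edges only), `significant_only` Fisher combination, and the
#' `pooled` vs `welch` per-gene t-test.
#'
#' @param min_group_size metal-group retention threshold (default 10).
#' @param cluster [cluster_params()].
#' @param min_docs,min_pmi literature-mining thresholds.
#' @param alpha meta-analysis significance level.
#' @param folds,repeats,roster cross-validation design and algorithm
#'   roster for hub classification.
#' @param top_k hubs flagged as selected by [rank_hubs()].
#' @param fidelity list of literal-reading flags (see above).
#' @export
pipeline_config <- function(min_group_size = 10,
                            cluster = cluster_params(),
                            min_docs = 3, min_pmi = 0,
                            alpha = 0.05,
                            folds = 10, repeats = 10,
                            roster = classifier_roster(),
                            top_k = 5,
                            fidelity = list(star_only = FALSE,
                                            significant_only = FALSE,
                                            ttest = "pooled")) {
  list(min_group_size = min_group_size, cluster = cluster,
       min_docs = min_docs, min_pmi = min_pmi, alpha = alpha,
       folds = folds, repeats = repeats, roster = roster, top_k = top_k,
       fidelity = fidelity)
}

#' Run the full metal-protein network workflow
#'
#' Executes the stages in order on a synthetic workspace generated from
#' `synth`: metal grouping and network construction, topology PCA against
#' Erdos-Renyi and pathway networks, cohesiveness hub extraction,
#' literature association, expression meta-analysis with batch-adjusted
#' merging, hub classification and ranking, and the cohort statistics
#' (summary-table audit, 2^-ddCt panel, correlation interdependency).
#' Outputs are written as TSV tables plus a JSON run manifest recording
#' the seed, parameters and per-file digests; a rerun with the same seed
#' reproduces the digests.
#'
#' @param synth a [synthesis_config()] (or a YAML path of its fields).
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, the manifest list; principal tables are attached as
#'   the `results` attribute.
#' @export
run_pipeline <- function(synth = synthesis_config(),
                         config = pipeline_config(),
                         out_dir = tempfile("metallonet_run_")) {
  if (is.character(synth))
    synth <- do.call(synthesis_config, yaml::read_yaml(synth))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  t0 <- Sys.time()

  # stage 1: synthesize inputs
  ws <- file.path(out_dir, "workspace")
  inputs <- synthesize_workspace(synth, ws)
  stages <- c(stages, "synthesize")

  # stage 2: metal networks (+ nulls and pathway comparators)
  ppi <- read_edge_list(inputs$ppi)
  ann <- group_by_metal(read_metal_annotations(inputs$annotations),
                        config$min_group_size)
  pns <- build_all_metal_pns(ann, ppi,
                             star_only = isTRUE(config$fidelity$star_only))
  pn_summary <- summarize_metal_pns(pns)
  write.table(pn_summary, file.path(out_dir, "metal_pns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "networks")

  # stage 3: topology PCA (metal vs ER-null vs pathway networks)
  gene_sets <- read_gene_sets(inputs$gene_sets)
  graphs <- setNames(lapply(pns, `[[`, "graph"),
                     paste0("metal_", names(pns)))
  for (i in seq_along(pns)) {
    g <- pns[[i]]$graph
    graphs[[paste0("random_", names(pns)[i])]] <-
      generate_er_null(igraph::vcount(g), igraph::ecount(g),
                       seed = synth$seed + 700L + i)
  }
  for (i in seq_along(gene_sets)) {
    nm <- names(gene_sets)[i]
    graphs[[paste0("pathway_", nm)]] <-
      build_pathway_network(gene_sets[[nm]], ppi, name = nm)
  }
  profiles <- topology_profiles(graphs)
  pca <- run_pca(profiles)
  grouping <- grouping_score(pca)
  write.table(profiles, file.path(out_dir, "topology_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(component = seq_along(pca$variance_fraction),
                         variance_fraction = pca$variance_fraction),
              file.path(out_dir, "pca_variance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "topology")

  # stage 4: hub extraction per metal network
  hubs_all <- lapply(pns, function(pn) find_hubs(pn$graph, config$cluster))
  top_hubs <- list()
  for (metal in names(hubs_all)) {
    if (length(hubs_all[[metal]]) == 0L) next
    h <- select_top_hub(hubs_all[[metal]], metal)
    h$metal <- metal
    top_hubs[[metal]] <- h
  }
  write.table(hub_table(lapply(top_hubs, list)),
              file.path(out_dir, "top_hubs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "hubs")

  # stage 5: literature mining and hub retention
  corpus <- read_corpus(inputs$corpus)
  all_symbols <- igraph::V(ppi)$name
  cooc <- count_cooccurrence(corpus, all_symbols)
  pd_proteins <- select_pd_proteins(cooc, config$min_docs, config$min_pmi)
  annotated <- annotate_hubs(top_hubs, pd_proteins)
  retained <- annotated$retained
  write.table(cooc, file.path(out_dir, "literature_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "mine")

  # stage 6: expression meta-analysis and batch-adjusted merge
  studies <- lapply(seq_len(synth$n_datasets), function(i)
    read_expression(inputs[[sprintf("expr_%02d", i)]],
                    inputs[[sprintf("expr_%02d_samples", i)]]))
  studies <- lapply(studies, normalize_dataset, force = FALSE)
  hub_genes <- sort(unique(unlist(lapply(retained, `[[`, "members"))))
  if (length(hub_genes) == 0L) hub_genes <- NULL  # fall back to all genes
  meta <- run_meta(studies, genes = hub_genes, alpha = config$alpha,
                   variant = config$fidelity$ttest,
                   significant_only = isTRUE(config$fidelity$significant_only))
  merged <- merge_with_batch_adjust(studies)
  write.table(meta, file.path(out_dir, "meta_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "meta")

  # stage 7: hub classification and ranking
  reports <- evaluate_hubs(merged, retained, roster = config$roster,
                           folds = config$folds, repeats = config$repeats,
                           seed = synth$seed + 808L)
  ranking <- rank_hubs(reports, top_k = config$top_k)
  write.table(reports, file.path(out_dir, "classification_reports.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ranking, file.path(out_dir, "hub_ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "classify")

  # stage 8: cohort statistics
  cohort <- read_cohort(inputs$cohort)
  audit <- audit_metal_table()
  ddct_rows <- do.call(rbind, lapply(synth$cohort_genes$gene, function(g) {
    r <- ddct(cohort, g)
    data.frame(gene = r$gene, ddct = r$ddct, fold = r$fold, p = r$p)
  }))
  selected <- ranking$hub[ranking$selected]
  sel_genes <- sort(unique(unlist(lapply(retained[selected], `[[`,
                                         "members"))))
  enrich <- hypergeom_enrich(sel_genes, gene_sets, all_symbols)
  corr_pairs <- t(combn(grep("^serum_", names(cohort), value = TRUE), 2))
  interdep <- interdependency_matrix(cohort, corr_pairs)
  write.table(audit, file.path(out_dir, "metal_table_audit.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ddct_rows, file.path(out_dir, "ddct.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(enrich, file.path(out_dir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(interdep, file.path(out_dir, "interdependency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "stats")

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = synth$seed,
    stages = stages,
    n_metals_retained = length(pns),
    n_hubs_retained = length(retained),
    selected_hubs = selected,
    pca_pc1 = pca$variance_fraction[1],
    grouping_silhouette = grouping$silhouette,
    parameters = list(
      min_group_size = config$min_group_size,
      cluster = config$cluster, min_docs = config$min_docs,
      alpha = config$alpha, folds = config$folds,
      repeats = config$repeats, fidelity = config$fidelity),
    input_digests = file_digests(unlist(inputs)),
    output_digests = file_digests(outputs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- list(
    pn_summary = pn_summary, profiles = profiles, pca = pca,
    grouping = grouping, top_hubs = top_hubs, retained = retained,
    pd_proteins = pd_proteins, meta = meta, merged = merged,
    reports = reports, ranking = ranking, audit = audit,
    ddct = ddct_rows, enrichment = enrich, interdependency = interdep)
  invisible(manifest)
}
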