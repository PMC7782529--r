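#' Configuration for the synthetic study workspace
#'
#' One object describing every synthetic input the pipeline can generate:
#' a planted-partition interactome (dense communities over a sparse
#' background, so hub detection has real structure to find, while the
#' Erdos-Renyi model remains the null), metal annotations keyed to the
#' planted communities, a disease-enriched abstract corpus, multi-dataset
#' case/control expression with planted differentially expressed genes
#' and additive batch effects, and a two-fluid cohort table whose analyte
#' summaries default to the published serum/CSF metal concentrations.
#'
#' @param seed master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_proteins interactome size.
#' @param community_sizes planted community sizes (sum <= `n_proteins`).
#' @param p_within,p_background within-community and background edge
#'   probabilities (`p_within > p_background`).
#' @param weight_within,weight_background uniform ranges for the
#'   interaction confidence weight of community and background edges
#'   (emulating a confidence-scored interactome).
#' @param n_metals_structured metals whose binding proteins are planted
#'   communities (one community each, in order).
#' @param n_metals_background metals drawing background proteins only.
#' @param undersized_metal_size size of one extra metal group left below
#'   the retention threshold to exercise filtering (0 disables).
#' @param n_multimetal proteins shared between consecutive structured
#'   metals (exercises multi-metal assignment).
#' @param pd_communities how many leading communities are
#'   disease-associated (their members are corpus-enriched and
#'   differentially expressed).
#' @param corpus_size number of abstracts.
#' @param p_disease_doc probability an abstract mentions the disease.
#' @param p_mention baseline per-document protein mention probability.
#' @param enrichment_odds odds multiplier for disease-protein mentions in
#'   disease abstracts (> 1 plants a positive association).
#' @param n_datasets expression datasets (batches) per tissue.
#' @param n_per_group samples per group per dataset.
#' @param effect_size case-vs-control shift of planted DE genes (log2
#'   units).
#' @param noise_sd residual log2-intensity SD.
#' @param batch_sd SD of the per-gene additive batch offset.
#' @param cohort_metals analyte summary table in the format of
#'   [pd_metal_reference()] (the default).
#' @param cohort_genes data.frame of qPCR genes: `gene`,
#'   `dct_control_mean`, `dct_pd_mean`, `dct_sd` (cycles).
#' @param cohort_correlations optional data.frame (`var1`, `var2`, `rho`)
#'   of Gaussian-copula correlations between cohort columns; `dct_<gene>`
#'   names address a gene's per-sample dCt.
#' @return List of class `synthesis_config`.
#' @export
synthesis_config <- function(seed = 1,
                             n_proteins = 250,
                             community_sizes = c(14, 14, 14, 12, 12, 12, 12, 12),
                             p_within = 0.9,
                             p_background = 0.02,
                             weight_within = c(0.7, 0.95),
                             weight_background = c(0.15, 0.45),
                             n_metals_structured = length(community_sizes),
                             n_metals_background = 3,
                             undersized_metal_size = 9,
                             n_multimetal = 2,
                             pd_communities = min(3, length(community_sizes)),
                             corpus_size = 400,
                             p_disease_doc = 0.35,
                             p_mention = 0.01,
                             enrichment_odds = 8,
                             n_datasets = 5,
                             n_per_group = 20,
                             effect_size = 2,
                             noise_sd = 1,
                             batch_sd = 2,
                             cohort_metals = pd_metal_reference(),
                             cohort_genes = default_cohort_genes(),
                             cohort_correlations = NULL) {
  stopifnot(p_within >= 0, p_within <= 1, p_background >= 0,
            p_background <= 1, p_within > p_background,
            sum(community_sizes) <= n_proteins,
            effect_size > 0, enrichment_odds > 0,
            p_disease_doc > 0, p_disease_doc < 1,
            n_metals_structured <= length(community_sizes),
            pd_communities <= length(community_sizes))
  structure(as.list(environment()), class = "synthesis_config")
}

#' Default qPCR gene panel for the synthetic cohort
#'
#' The hub-derived genes assayed in the study's PBMC validation (EFEMP2,
#' MMP9, B2M, MEAF2A, TARDBP — upregulated in PD) plus the oxidative and
#' inflammatory markers SOD1 (downregulated) and hsCRP (upregulated), with
#' beta-actin (`ACTB`) as housekeeping reference. Group dCt means encode
#' roughly 2-fold shifts.
#' @return data.frame: gene, dct_control_mean, dct_pd_mean, dct_sd.
#' @export
default_cohort_genes <- function() {
  data.frame(
    gene = c("EFEMP2", "MMP9", "B2M", "MEAF2A", "TARDBP", "SOD1", "HSCRP"),
    dct_control_mean = c(6, 7, 4, 8, 6, 5, 9),
    dct_pd_mean = c(5, 6, 3, 7, 5, 6, 8),
    dct_sd = rep(0.8, 7),
    stringsAsFactors = FALSE)
}

#' Deterministic synthetic protein symbols (`P001`, `P002`, ...)
#' @param n number of proteins.
#' @return Character vector of length `n`.
#' @export
synthetic_protein_names <- function(n)
  sprintf("P%03d", seq_len(n))

structured_metal_names <- c("CU", "FE", "CA", "MG", "AL", "ZN", "MN", "CO",
                            "NI", "MO", "CD", "SE")
background_metal_names <- c("CS", "BA", "SR", "RB", "LI", "PB")

#' Planted community membership of a synthesis configuration
#' @param config a [synthesis_config()].
#' @return Named list: community id -> member protein names (block layout
#'   over the first `sum(community_sizes)` proteins).
#' @export
planted_communities <- function(config) {
  nodes <- synthetic_protein_names(config$n_proteins)
  ends <- cumsum(config$community_sizes)
  starts <- c(1, head(ends, -1) + 1)
  setNames(lapply(seq_along(ends), function(i) nodes[starts[i]:ends[i]]),
           paste0("C", seq_along(ends)))
}

#' Generate the synthetic protein-protein interaction network
#'
#' Planted-partition graph with a degree-heterogeneous background: node
#' pairs inside the same community are connected with probability
#' `p_within`; all other pairs with probability
#' `min(0.9, p_background * a_i * a_j)` where the activities `a_i` are
#' heavy-tailed with mean 1 (a Chung-Lu-style background). The expected
#' background density is therefore `p_background`, while the degree
#' heterogeneity mimics the hub-dominated periphery of real interactomes
#' (a uniform Bernoulli background gives first-neighbor networks an
#' unrealistic fringe of degree-1 leaves). Node names are deterministic
#' (`P001..`), and the graph is a pure function of the configuration.
#'
#' @param config a [synthesis_config()].
#' @return An [interaction_graph()] with every protein as a node.
#' @export
gen_ppi <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_proteins
  nodes <- synthetic_protein_names(n)
  comm <- integer(n)                           # 0 = background
  ends <- cumsum(config$community_sizes)
  starts <- c(1, head(ends, -1) + 1)
  for (i in seq_along(ends)) comm[starts[i]:ends[i]] <- i
  activity <- rexp(n)^1.5
  activity <- activity / mean(activity)
  pairs <- combn(n, 2)
  same <- comm[pairs[1, ]] == comm[pairs[2, ]] & comm[pairs[1, ]] > 0
  p_bg <- pmin(0.9, config$p_background *
                 activity[pairs[1, ]] * activity[pairs[2, ]])
  prob <- ifelse(same, config$p_within, p_bg)
  keep <- runif(ncol(pairs)) < prob
  # STRING-style confidence weights: community (complex) edges score high,
  # background edges low -- the regime cohesiveness clustering is built for
  w <- ifelse(same[keep],
              runif(sum(keep), config$weight_within[1],
                    config$weight_within[2]),
              runif(sum(keep), config$weight_background[1],
                    config$weight_background[2]))
  interaction_graph(nodes[pairs[1, keep]], nodes[pairs[2, keep]],
                    weight = round(w, 3), nodes = nodes, label = "metal")
}

#' Generate metal-to-protein annotations over a synthetic interactome
#'
#' Each structured metal is assigned the members of one planted community
#' (plus `n_multimetal` proteins shared with the next structured metal, so
#' multi-metal proteins exist); background metals draw random background
#' proteins; one extra group is left below the size-10 retention threshold
#' to exercise filtering.
#'
#' @param config a [synthesis_config()].
#' @param graph the synthetic PPI (nodes define the protein universe).
#' @return A [metal_protein_table()].
#' @export
gen_metal_annotations <- function(config, graph) {
  stopifnot(igraph::vcount(graph) > 0)
  set.seed(config$seed + 202L)
  comms <- planted_communities(config)
  nodes <- igraph::V(graph)$name
  background <- setdiff(nodes, unlist(comms))
  entries <- list()
  k <- config$n_metals_structured
  # multi-metal proteins: background proteins shared between consecutive
  # structured metals (community members are never shared, so each metal
  # network keeps exactly one planted dense core)
  shared <- if (config$n_multimetal > 0 && k > 1)
    matrix(sample(background, config$n_multimetal * k), nrow = k)
  else NULL
  for (i in seq_len(k)) {
    members <- comms[[i]]
    if (!is.null(shared)) {
      nxt <- if (i == k) 1L else i + 1L
      members <- union(members, c(shared[i, ], shared[nxt, ]))
    }
    entries[[structured_metal_names[i]]] <- members
  }
  # noise metals must be verifiably structure-free for the planted truth
  # to be identifiable: draw them from the periphery, i.e. background
  # proteins with no interaction into a disease community (falling back to
  # the least-connected background proteins if the periphery is small)
  pd_members <- unlist(comms[seq_len(config$pd_communities)])
  n_links <- vapply(background, function(v)
    sum(igraph::V(graph)$name[igraph::neighbors(graph, v)] %in% pd_members),
    numeric(1))
  periphery <- background[order(n_links, background)]
  for (j in seq_len(config$n_metals_background)) {
    take <- periphery[seq_len(min(12L, length(periphery)))]
    periphery <- setdiff(periphery, take)
    entries[[background_metal_names[j]]] <- take
  }
  if (config$undersized_metal_size > 0)
    entries[["W"]] <- periphery[seq_len(min(config$undersized_metal_size,
                                            length(periphery)))]
  metal_protein_table(entries)
}

#' Disease-associated proteins planted by the configuration
#' @param config a [synthesis_config()].
#' @return Members of the first `pd_communities` planted communities.
#' @export
planted_pd_proteins <- function(config) {
  sort(unique(unlist(planted_communities(config)[
    seq_len(config$pd_communities)])))
}

#' Generate a synthetic abstract corpus
#'
#' Documents mention the disease phrase with probability `p_disease_doc`
#' and protein symbols as uppercase tokens. Non-disease proteins are
#' mentioned independently of the disease (PMI centred near 0); planted
#' disease proteins are mentioned in disease abstracts with their baseline
#' odds multiplied by `enrichment_odds`, and each is guaranteed at least
#' three co-occurrence documents (topped up deterministically; an error if
#' the corpus has fewer than three disease documents).
#'
#' @param config a [synthesis_config()].
#' @param pd_proteins disease-associated symbols (default: the planted
#'   set); must be a subset of `all_symbols`.
#' @param all_symbols the full symbol universe (default: all synthetic
#'   proteins).
#' @return Named character vector, doc ID -> abstract text.
#' @export
gen_corpus <- function(config,
                       pd_proteins = planted_pd_proteins(config),
                       all_symbols = synthetic_protein_names(config$n_proteins)) {
  stopifnot(all(pd_proteins %in% all_symbols))
  set.seed(config$seed + 303L)
  N <- config$corpus_size
  is_disease <- runif(N) < config$p_disease_doc
  if (sum(is_disease) < 3L)
    stop("corpus too small to guarantee 3 co-occurrence abstracts per ",
         "disease protein (", sum(is_disease), " disease documents)")
  base <- config$p_mention
  # odds-ratio enrichment of planted proteins in disease documents
  odds_base <- base / (1 - base)
  p_enriched <- min(0.95, (odds_base * config$enrichment_odds) /
                      (1 + odds_base * config$enrichment_odds))
  is_pd <- all_symbols %in% pd_proteins
  mention <- matrix(FALSE, N, length(all_symbols))
  for (j in seq_along(all_symbols)) {
    p <- if (is_pd[j]) ifelse(is_disease, p_enriched, base) else base
    mention[, j] <- runif(N) < p
  }
  # top-up guarantee: every disease protein in >= 3 disease documents
  dis_idx <- which(is_disease)
  for (j in which(is_pd)) {
    have <- sum(mention[dis_idx, j])
    if (have < 3L) {
      need <- dis_idx[!mention[dis_idx, j]][seq_len(3L - have)]
      mention[need, j] <- TRUE
    }
  }
  docs <- vapply(seq_len(N), function(i) {
    syms <- all_symbols[mention[i, ]]
    topic <- if (is_disease[i])
      "in patients with Parkinson's disease" else "in healthy tissue"
    paste0("Expression of ", paste(c(syms, "GENE"), collapse = " "),
           " was studied ", topic, ".")
  }, character(1))
  setNames(docs, sprintf("PMID%05d", seq_len(N)))
}

#' Generate synthetic case/control expression studies
#'
#' Per dataset: Gaussian log2 intensities around a fixed per-gene baseline
#' (mean 7, SD 1 across genes), an additive per-dataset-per-gene batch
#' offset (`SD = batch_sd`), residual noise `SD = noise_sd`, and a shift
#' of `+/- effect_size` in case samples for planted DE genes with a sign
#' fixed per gene and consistent across datasets.
#'
#' @param config a [synthesis_config()].
#' @param genes gene symbols (default: all synthetic proteins).
#' @param de_genes planted differentially expressed subset (default: the
#'   planted disease proteins).
#' @return List of [expression_study()] objects (`batch` = `"GSE00k"`),
#'   with attributes `de_genes` and `de_signs`.
#' @export
gen_expression <- function(config,
                           genes = synthetic_protein_names(config$n_proteins),
                           de_genes = planted_pd_proteins(config)) {
  stopifnot(all(de_genes %in% genes), config$n_per_group >= 2)
  set.seed(config$seed + 404L)
  G <- length(genes)
  baseline <- rnorm(G, 7, 1)
  de <- genes %in% de_genes
  signs <- setNames(ifelse(de, sample(c(-1, 1), G, replace = TRUE), 0),
                    genes)
  n <- config$n_per_group
  studies <- lapply(seq_len(config$n_datasets), function(d) {
    batch_offset <- rnorm(G, 0, config$batch_sd)
    mu <- baseline + batch_offset
    ctrl <- matrix(rnorm(G * n, mu, config$noise_sd), G, n)
    case <- matrix(rnorm(G * n, mu + signs * config$effect_size,
                         config$noise_sd), G, n)
    m <- cbind(ctrl, case)
    rownames(m) <- genes
    colnames(m) <- sprintf("S%d_%02d", d, seq_len(2 * n))
    expression_study(m, rep(c("control", "case"), each = n),
                     batch = sprintf("GSE%03d", d))
  })
  attr(studies, "de_genes") <- sort(genes[de])
  attr(studies, "de_signs") <- signs[de]
  studies
}

#' Generate a synthetic two-fluid cohort table
#'
#' Per-subject serum and CSF metal concentrations plus qPCR Ct values.
#' Marginals default to the published summary table (serum: 87 subjects
#' per group; CSF: the first 42 per group, remaining CSF cells `NA`) and
#' to the configured dCt panel; concentrations are truncated at 0 (the
#' configured coefficients of variation make truncation bias negligible).
#' Optional correlations between columns are imposed through a Gaussian
#' copula: the requested correlation matrix must be positive
#' semi-definite, and `dct_<gene>` names address a gene's per-sample
#' `Ct(gene) - Ct(ACTB)` so analyte-expression interdependencies can be
#' planted directly.
#'
#' @param config a [synthesis_config()].
#' @return A [as_cohort_table()] data.frame with columns `subject`,
#'   `group`, `serum_<metal>`, `csf_<metal>`, `ct_actb`, `ct_<gene>`.
#' @export
gen_cohort <- function(config) {
  set.seed(config$seed + 505L)
  metals <- config$cohort_metals
  genes <- config$cohort_genes
  n_serum <- metals$n_per_group[metals$fluid == "serum"][1]
  n_csf <- metals$n_per_group[metals$fluid == "csf"][1]
  vars <- c(paste0(metals$fluid, "_", metals$metal),
            paste0("dct_", tolower(genes$gene)))
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  if (!is.null(config$cohort_correlations)) {
    cc <- config$cohort_correlations
    for (i in seq_len(nrow(cc))) {
      if (!all(c(cc$var1[i], cc$var2[i]) %in% vars))
        stop("unknown cohort variable in correlation spec: ",
             cc$var1[i], " / ", cc$var2[i])
      R[cc$var1[i], cc$var2[i]] <- cc$rho[i]
      R[cc$var2[i], cc$var1[i]] <- cc$rho[i]
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("requested correlation matrix is not positive semi-definite")
  }
  L <- chol(R + diag(1e-10, nrow(R)))
  draw_group <- function(group, n) {
    z <- matrix(rnorm(n * length(vars)), n) %*% L
    colnames(z) <- vars
    out <- data.frame(subject = paste0(substr(group, 1, 1), seq_len(n)),
                      group = group, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(metals))) {
      v <- paste0(metals$fluid[i], "_", metals$metal[i])
      m <- if (group == "control") metals$control_mean[i] else metals$pd_mean[i]
      s <- if (group == "control") metals$control_sd[i] else metals$pd_sd[i]
      vals <- pmax(0, z[, v] * s + m)
      if (metals$fluid[i] == "csf" && n > n_csf)
        vals[(n_csf + 1):n] <- NA_real_
      out[[v]] <- vals
    }
    out$ct_actb <- rnorm(n, 18, 0.3)
    for (i in seq_len(nrow(genes))) {
      mdct <- if (group == "control") genes$dct_control_mean[i]
      else genes$dct_pd_mean[i]
      dct <- z[, paste0("dct_", tolower(genes$gene[i]))] * genes$dct_sd[i] + mdct
      out[[paste0("ct_", tolower(genes$gene[i]))]] <- out$ct_actb + dct
    }
    out
  }
  tab <- rbind(draw_group("control", n_serum), draw_group("PD", n_serum))
  as_cohort_table(tab)
}

#' Materialize a full synthetic workspace on disk
#'
#' Writes every pipeline input in the exchange formats the readers accept:
#' PPI edge list, metal annotation TSV, pathway GMT (planted communities
#' plus random background sets, usable for enrichment and prioritization),
#' corpus TSV, expression matrix + sample-sheet TSV pairs, and the cohort
#' TSV, plus a ground-truth JSON (planted communities, disease proteins,
#' DE genes).
#'
#' @param config a [synthesis_config()].
#' @param dir output directory (created).
#' @return Invisibly, the list of written paths.
#' @export
synthesize_workspace <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ppi <- gen_ppi(config)
  ann <- gen_metal_annotations(config, ppi)
  comms <- planted_communities(config)
  pdp <- planted_pd_proteins(config)
  corpus <- gen_corpus(config)
  studies <- gen_expression(config)
  cohort <- gen_cohort(config)
  set.seed(config$seed + 606L)
  nodes <- igraph::V(ppi)$name
  gmt <- c(setNames(comms, paste0("PATH_", names(comms))),
           setNames(lapply(1:8, function(i) sample(nodes, 15)),
                    paste0("PATH_RND", 1:8)))
  paths <- list(
    ppi = file.path(dir, "ppi.tsv"),
    annotations = file.path(dir, "metal_annotations.tsv"),
    gene_sets = file.path(dir, "pathways.gmt"),
    corpus = file.path(dir, "corpus.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    truth = file.path(dir, "truth.json"))
  write_edge_list(ppi, paths$ppi)
  write_metal_annotations(ann, paths$annotations)
  write_gene_sets(gmt, paths$gene_sets)
  write_corpus(corpus, paths$corpus)
  write.table(cohort, paths$cohort, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (i in seq_along(studies)) {
    mp <- file.path(dir, sprintf("expr_%02d.tsv", i))
    sp <- file.path(dir, sprintf("expr_%02d_samples.tsv", i))
    write_expression(studies[[i]], mp, sp)
    paths[[sprintf("expr_%02d", i)]] <- mp
    paths[[sprintf("expr_%02d_samples", i)]] <- sp
  }
  jsonlite::write_json(
    list(seed = config$seed, communities = comms, pd_proteins = pdp,
         de_genes = attr(studies, "de_genes")),
    paths$truth, auto_unbox = TRUE)
  invisible(paths)
}
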