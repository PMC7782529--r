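#' Filter metal groups by minimum size
#'
#' Metal-binding proteins are grouped by their bound metal; a protein with
#' several metal cofactors is assigned to every group. Only metals binding
#' at least `min_size` proteins are retained (the study keeps 24 groups at a
#' minimum of ten proteins each).
#'
#' @param annotations a [metal_protein_table()].
#' @param min_size minimum proteins per retained metal (default 10).
#' @return A filtered [metal_protein_table()]; empty result allowed with a
#'   warning.
#' @export
group_by_metal <- function(annotations, min_size = 10) {
  stopifnot(inherits(annotations, "metal_protein_table"))
  keep <- lengths(annotations$entries) >= min_size
  if (!any(keep)) {
    warning("no metal group reaches min_size = ", min_size)
    return(structure(list(entries = list()), class = "metal_protein_table"))
  }
  metal_protein_table(annotations$entries[keep])
}

#' Build a metal protein network by first-neighbor expansion
#'
#' The metal protein network (metal-PN) contains every metal-binding seed
#' protein present in the reference interactome plus each seed's immediate
#' interaction partners; edges are the reference edges induced on that node
#' set (see `star_only` for the stricter seed-to-neighbor reading).
#'
#' @param metal metal symbol (used for labelling and error messages).
#' @param seeds character vector of metal-binding protein symbols.
#' @param ppi reference interactome ([interaction_graph()]).
#' @param star_only if `TRUE`, keep only edges with at least one seed
#'   endpoint instead of the full induced subgraph.
#' @return A list of class `metal_pn` with elements `metal`, `seeds`
#'   (seeds found in the PPI), `missing` (seeds absent from the PPI,
#'   reported rather than silently dropped) and `graph`.
#' @export
build_metal_pn <- function(metal, seeds, ppi, star_only = FALSE) {
  seeds <- sort(unique(clean_symbols(seeds)))
  stopifnot(igraph::vcount(ppi) > 0)
  present <- intersect(seeds, igraph::V(ppi)$name)
  if (length(present) == 0L)
    stop("no seed protein of metal '", metal, "' is present in the PPI")
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(ppi, present),
                               function(v) igraph::V(ppi)$name[v])))
  nodes <- sort(unique(c(present, nbrs)))
  g <- igraph::induced_subgraph(ppi, nodes)
  if (star_only) {
    el <- igraph::as_data_frame(g, what = "edges")
    drop <- !(el$from %in% present) & !(el$to %in% present)
    g <- igraph::delete_edges(g, which(drop))
  }
  g$label <- "metal"
  structure(list(metal = metal, seeds = present,
                 missing = setdiff(seeds, present), graph = g),
            class = "metal_pn")
}

#' @export
print.metal_pn <- function(x, ...) {
  cat("metal_pn [", x$metal, "]: ", length(x$seeds), " seeds -> ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges", if (length(x$missing))
        paste0(" (", length(x$missing), " seeds not in PPI)"), "\n", sep = "")
  invisible(x)
}

#' Build all metal protein networks
#'
#' @param annotations filtered [metal_protein_table()].
#' @param ppi reference interactome.
#' @param star_only see [build_metal_pn()].
#' @return Named list of `metal_pn`, one per metal; metals with no seed in
#'   the PPI are skipped with a warning.
#' @export
build_all_metal_pns <- function(annotations, ppi, star_only = FALSE) {
  out <- list()
  for (metal in names(annotations$entries)) {
    pn <- tryCatch(
      build_metal_pn(metal, annotations$entries[[metal]], ppi, star_only),
      error = function(e) {
        warning(conditionMessage(e)); NULL
      })
    if (!is.null(pn)) out[[metal]] <- pn
  }
  out
}

#' Generate an Erdos-Renyi null network
#'
#' G(n, M) draw: a uniformly random simple graph with exactly
#' `target_edges` edges, node-matched (and, by default, edge-matched) to a
#' metal-PN for the topology comparison.
#'
#' @param n_nodes number of nodes.
#' @param target_edges exact number of edges, in `[0, n(n-1)/2]`.
#' @param seed RNG seed for this draw.
#' @return An [interaction_graph()] with label `"random"` and nodes
#'   `R1..Rn`.
#' @export
generate_er_null <- function(n_nodes, target_edges, seed) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (target_edges < 0 || target_edges > max_edges)
    stop("infeasible edge count ", target_edges, " for ", n_nodes, " nodes")
  set.seed(as.integer(seed))
  g <- igraph::sample_gnm(n_nodes, target_edges)
  igraph::V(g)$name <- paste0("R", seq_len(n_nodes))
  igraph::E(g)$weight <- 1
  g$label <- "random"
  g
}

#' Build a pathway comparison network
#'
#' Applies the same first-neighbor expansion rule as [build_metal_pn()] to
#' the member genes of a molecular pathway, yielding the pathway networks
#' used alongside the Erdos-Renyi nulls in the topology PCA.
#'
#' @param pathway_genes character vector of pathway member symbols.
#' @param ppi reference interactome.
#' @param name pathway name (for error messages).
#' @return An [interaction_graph()] with label `"pathway"`.
#' @export
build_pathway_network <- function(pathway_genes, ppi, name = "pathway") {
  pn <- build_metal_pn(name, pathway_genes, ppi)
  g <- pn$graph
  g$label <- "pathway"
  g
}

#' Summarize a set of metal protein networks
#' @param pns list of `metal_pn` from [build_all_metal_pns()].
#' @return data.frame with one row per metal: seed, node and edge counts.
#' @export
summarize_metal_pns <- function(pns) {
  data.frame(metal = vapply(pns, `[[`, character(1), "metal"),
             n_seeds = vapply(pns, function(p) length(p$seeds), integer(1)),
             n_missing = vapply(pns, function(p) length(p$missing), integer(1)),
             n_nodes = vapply(pns, function(p) igraph::vcount(p$graph), numeric(1)),
             n_edges = vapply(pns, function(p) igraph::ecount(p$graph), numeric(1)),
             row.names = NULL)
}
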