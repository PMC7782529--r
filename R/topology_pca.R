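#' Seven topological parameters of a network
#'
#' Computes the headline simple parameters used to compare metal, random
#' and pathway networks: node count, edge count, average degree, density,
#' average (local) clustering coefficient, characteristic path length and
#' diameter. Path-based metrics are computed on the largest connected
#' component, since metal-PNs can be disconnected; a singleton graph gets
#' path length and diameter 0. Local clustering of degree<2 nodes counts
#' as 0 in the average.
#'
#' @param graph an [interaction_graph()].
#' @param id network identifier.
#' @param class_label network class (`metal`/`random`/`pathway`); defaults
#'   to the graph's own label.
#' @return One-row data.frame: `id`, `class`, then the seven parameters.
#' @export
topology_profile <- function(graph, id = "net",
                             class_label = NULL) {
  stopifnot(igraph::vcount(graph) >= 1)
  if (is.null(class_label))
    class_label <- if (!is.null(graph$label)) graph$label else "metal"
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  avg_deg <- if (n > 0) 2 * m / n else 0
  dens <- if (n > 1) igraph::edge_density(graph) else 0
  cc <- igraph::transitivity(graph, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  comp <- igraph::components(graph)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(graph, which(comp$membership == big))
  if (igraph::vcount(sub) > 1) {
    cpl <- igraph::mean_distance(sub, directed = FALSE)
    diam <- igraph::diameter(sub, directed = FALSE, weights = NA)
  } else {
    cpl <- 0; diam <- 0
  }
  data.frame(id = id, class = class_label, n_nodes = n, n_edges = m,
             avg_degree = avg_deg, density = dens, clustering = cc,
             path_length = cpl, diameter = diam,
             stringsAsFactors = FALSE)
}

#' Topology profiles for a named list of networks
#' @param graphs named list of [interaction_graph()]s.
#' @return data.frame, one row per network.
#' @export
topology_profiles <- function(graphs) {
  do.call(rbind, lapply(names(graphs), function(nm)
    topology_profile(graphs[[nm]], id = nm)))
}

#' PCA over network topology profiles
#'
#' Column-standardized (correlation) PCA of the topological parameters of a
#' collection of networks, used to ask whether metal protein networks group
#' with curated pathway networks and apart from Erdos-Renyi nulls. Constant
#' columns are dropped with a warning before standardization. The sign of
#' each component is fixed by making its largest-magnitude loading positive,
#' so results are bit-stable across runs and input orders.
#'
#' @param profiles data.frame from [topology_profiles()] (columns `id`,
#'   `class`, then numeric parameters), or a plain numeric matrix.
#' @param standardize scale columns to unit variance (default `TRUE`;
#'   covariance PCA when `FALSE`).
#' @return List of class `topology_pca`: `scores` (networks x components),
#'   `loadings`, `variance_fraction` (sums to 1 over all components),
#'   `class` labels, `dropped` constant columns.
#' @export
run_pca <- function(profiles, standardize = TRUE) {
  if (is.data.frame(profiles)) {
    num <- vapply(profiles, is.numeric, logical(1))
    x <- as.matrix(profiles[, num, drop = FALSE])
    rownames(x) <- if ("id" %in% names(profiles)) profiles$id
    cls <- if ("class" %in% names(profiles)) profiles$class
  } else {
    x <- as.matrix(profiles)
    cls <- NULL
  }
  if (nrow(x) < 3L) stop("need >= 3 profiles for PCA")
  if (is.null(rownames(x))) rownames(x) <- paste0("net", seq_len(nrow(x)))
  cn <- colnames(x)
  const <- apply(x, 2, function(v) var(v) < .Machine$double.eps)
  if (any(const)) {
    warning("constant column(s) dropped: ", paste(cn[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  # deterministic column order so scores are input-order invariant
  ord <- order(rownames(x))
  p <- prcomp(x[ord, , drop = FALSE], center = TRUE, scale. = standardize)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  scores <- p$x[match(rownames(x), rownames(x)[ord]), , drop = FALSE]
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, loadings = p$rotation,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 class = cls, dropped = cn[const]),
            class = "topology_pca")
}

#' @export
print.topology_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$variance_fraction))], 1)
  cat("topology_pca: ", nrow(x$scores), " networks; variance explained ",
      paste0("PC", seq_along(vf), "=", vf, "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Class separation of networks in PC space
#'
#' Quantifies the qualitative grouping claim — metal and pathway networks
#' together, random networks apart — as the mean silhouette width of the
#' two-group partition \{metal + pathway\} vs \{random\} on the first two
#' components, plus pairwise class-centroid distances.
#'
#' @param result a [run_pca()] result.
#' @param labels class labels per network; defaults to those stored in the
#'   result.
#' @return List: `silhouette` (mean width of the 2-group partition),
#'   `centroid_distances` (named pairwise distances between class centroids).
#' @export
grouping_score <- function(result, labels = result$class) {
  stopifnot(!is.null(labels), length(labels) == nrow(result$scores))
  if (any(table(labels) < 1L) || length(unique(labels)) < 2L)
    stop("need >= 2 nonempty classes")
  xy <- result$scores[, 1:min(2, ncol(result$scores)), drop = FALSE]
  part <- ifelse(labels == "random", 1L, 2L)
  sil <- if (length(unique(part)) == 2L)
    mean(cluster::silhouette(part, stats::dist(xy))[, "sil_width"])
  else NA_real_
  cents <- do.call(rbind, lapply(split(as.data.frame(xy), labels), colMeans))
  cd <- as.matrix(stats::dist(cents))
  pairs <- combn(rownames(cents), 2)
  dists <- setNames(cd[t(pairs)], apply(pairs, 2, paste, collapse = "-"))
  list(silhouette = sil, centroid_distances = dists)
}
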