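# Independent oracles and small graph fixtures, built in code.

# cohesiveness from the adjacency matrix directly (independent of the
# package's edge-list implementation)
oracle_cohesiveness <- function(graph, members, penalty) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  inn <- rownames(A) %in% members
  w_in <- sum(A[inn, inn, drop = FALSE]) / 2
  w_bound <- sum(A[inn, !inn, drop = FALSE])
  d <- w_in + w_bound + penalty * sum(inn)
  if (d == 0) 0 else w_in / d
}

# TRUE iff no single boundary addition or member removal strictly
# increases cohesiveness (exhaustive single-move enumeration)
oracle_is_local_optimum <- function(graph, members, penalty) {
  cur <- oracle_cohesiveness(graph, members, penalty)
  vn <- igraph::V(graph)$name
  outside <- setdiff(vn, members)
  for (v in outside)
    if (oracle_cohesiveness(graph, c(members, v), penalty) > cur + 1e-9)
      return(FALSE)
  if (length(members) > 1L)
    for (m in members)
      if (oracle_cohesiveness(graph, setdiff(members, m), penalty) >
            cur + 1e-9)
        return(FALSE)
  TRUE
}

# two 5-cliques joined by a single bridge edge A1-B1
two_clique_bridge <- function() {
  a <- paste0("A", 1:5); b <- paste0("B", 1:5)
  ea <- t(combn(a, 2)); eb <- t(combn(b, 2))
  interaction_graph(c(ea[, 1], eb[, 1], "A1"), c(ea[, 2], eb[, 2], "B1"))
}

# small connected random graph (G(n, p) conditioned on connectivity)
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    pairs <- combn(n, 2)
    keep <- runif(ncol(pairs)) < p
    if (!any(keep)) next
    g <- interaction_graph(paste0("N", pairs[1, keep]),
                           paste0("N", pairs[2, keep]),
                           nodes = paste0("N", seq_len(n)))
    if (igraph::is_connected(g)) return(g)
  }
}

# best-Jaccard recovery of planted communities by a hub list
recovery_fraction <- function(hubs, communities, threshold = 0.75) {
  if (length(hubs) == 0L) return(0)
  jac <- vapply(communities, function(cm)
    max(vapply(hubs, function(h) {
      length(intersect(cm, h$members)) / length(union(cm, h$members))
    }, numeric(1))), numeric(1))
  mean(jac >= threshold)
}
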