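#' Clustering parameters for hub detection
#'
#' Defaults follow the published ClusterONE settings: size penalty `p = 2`
#' (models unobserved interactions of each member), overlap threshold
#' `omega = 0.8` for merging, minimum hub size 3 and minimum hub density
#' 0.3.
#'
#' @param penalty size penalty p >= 0 in the cohesiveness denominator.
#' @param overlap merge threshold on the match coefficient
#'   `|A∩B|^2 / (|A||B|)`, in (0, 1].
#' @param min_size minimum members per reported hub.
#' @param min_density minimum internal edge density per reported hub.
#' @export
cluster_params <- function(penalty = 2, overlap = 0.8, min_size = 3,
                           min_density = 0.3) {
  stopifnot(penalty >= 0, overlap > 0, overlap <= 1, min_size >= 1,
            min_density >= 0, min_density <= 1)
  list(penalty = penalty, overlap = overlap, min_size = min_size,
       min_density = min_density)
}

# named adjacency weight lists: adj[[v]] = c(u1 = w1, u2 = w2, ...)
adjacency_weights <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  vn <- igraph::V(graph)$name
  adj <- setNames(vector("list", length(vn)), vn)
  for (v in vn) adj[[v]] <- numeric(0)
  if (nrow(el)) {
    for (i in seq_len(nrow(el))) {
      a <- el$from[i]; b <- el$to[i]; w <- el$weight[i]
      adj[[a]][b] <- w
      adj[[b]][a] <- w
    }
  }
  adj
}

#' Cohesiveness of a vertex set
#'
#' The quality function driving hub extraction:
#' `w_in / (w_in + w_bound + p * |V'|)`, where `w_in` is the total weight
#' of edges with both endpoints in the set, `w_bound` the total weight of
#' edges with exactly one endpoint in the set, and `p` a per-member penalty
#' modelling unobserved interactions.
#'
#' @param graph an [interaction_graph()].
#' @param members nonempty character vector of member node names.
#' @param penalty size penalty p (default 2).
#' @return Cohesiveness in `[0, 1]`; 1 exactly when `w_bound = 0` and
#'   `p = 0`.
#' @export
cohesiveness <- function(graph, members, penalty = 2) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty member set")
  vn <- igraph::V(graph)$name
  if (!all(members %in% vn))
    stop("members not in graph: ",
         paste(setdiff(members, vn), collapse = ", "))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  a_in <- el$from %in% members
  b_in <- el$to %in% members
  w_in <- sum(el$weight[a_in & b_in])
  w_bound <- sum(el$weight[xor(a_in, b_in)])
  denom <- w_in + w_bound + penalty * length(members)
  if (denom == 0) 0 else w_in / denom
}

# incremental greedy engine shared by grow_cluster/find_hubs
grow_engine <- function(adj, strength, seed, penalty) {
  members <- seed
  in_set <- setNames(logical(length(adj)), names(adj))
  in_set[seed] <- TRUE
  # w2m[v]: total edge weight from v into the current member set
  w2m <- setNames(numeric(length(adj)), names(adj))
  for (u in names(adj[[seed]])) w2m[u] <- adj[[seed]][u]
  w_in <- 0
  w_bound <- strength[seed]
  coh <- function(wi, wb, k) {
    d <- wi + wb + penalty * k
    if (d == 0) 0 else wi / d
  }
  cur <- coh(w_in, w_bound, 1)
  repeat {
    k <- length(members)
    boundary <- names(which(w2m > 0 & !in_set))
    best <- cur; best_node <- NA_character_; best_type <- ""
    for (v in sort(boundary)) {
      val <- coh(w_in + w2m[v], w_bound - w2m[v] + (strength[v] - w2m[v]),
                 k + 1)
      if (val > best + 1e-12) {
        best <- val; best_node <- v; best_type <- "add"
      }
    }
    if (k > 1L) for (m in sort(members)) {
      val <- coh(w_in - w2m[m], w_bound + w2m[m] - (strength[m] - w2m[m]),
                 k - 1)
      if (val > best + 1e-12) {
        best <- val; best_node <- m; best_type <- "remove"
      }
    }
    if (is.na(best_node)) break
    if (best_type == "add") {
      members <- c(members, best_node)
      in_set[best_node] <- TRUE
      w_in <- w_in + w2m[best_node]
      w_bound <- w_bound - w2m[best_node] + (strength[best_node] - w2m[best_node])
      for (u in names(adj[[best_node]])) w2m[u] <- w2m[u] + adj[[best_node]][u]
    } else {
      members <- setdiff(members, best_node)
      in_set[best_node] <- FALSE
      w_in <- w_in - w2m[best_node]
      w_bound <- w_bound + w2m[best_node] - (strength[best_node] - w2m[best_node])
      for (u in names(adj[[best_node]])) w2m[u] <- w2m[u] - adj[[best_node]][u]
    }
    cur <- best
  }
  list(members = sort(members), w_in = w_in, w_bound = w_bound,
       cohesiveness = cur)
}

#' Construct a hub from an explicit member set
#'
#' @param graph the network the hub lives in.
#' @param members member protein symbols.
#' @param penalty size penalty used for the cohesiveness score.
#' @param metal metal symbol tag.
#' @param rank rank within its network (1 = top).
#' @return Object of class `hub`: members, w_in, w_bound, cohesiveness,
#'   density, size, metal, rank, `pd_proteins` annotation slot.
#' @export
new_hub <- function(graph = NULL, members, penalty = 2, metal = NA_character_,
                    rank = NA_integer_) {
  members <- sort(unique(as.character(members)))
  w_in <- w_bound <- dens <- NA_real_
  coh <- NA_real_
  if (!is.null(graph)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    if (is.null(el$weight)) el$weight <- 1
    a_in <- el$from %in% members; b_in <- el$to %in% members
    w_in <- sum(el$weight[a_in & b_in])
    w_bound <- sum(el$weight[xor(a_in, b_in)])
    coh <- cohesiveness(graph, members, penalty)
    k <- length(members)
    n_int <- sum(a_in & b_in)
    dens <- if (k > 1) n_int / (k * (k - 1) / 2) else 0
  }
  structure(list(members = members, size = length(members), w_in = w_in,
                 w_bound = w_bound, cohesiveness = coh, density = dens,
                 penalty = penalty, metal = metal, rank = rank,
                 pd_proteins = character()),
            class = "hub")
}

#' @export
print.hub <- function(x, ...) {
  cat("hub", if (!is.na(x$metal)) paste0(" [", x$metal, "]"),
      if (!is.na(x$rank)) paste0(" rank ", x$rank),
      ": ", x$size, " proteins, cohesiveness ",
      signif(x$cohesiveness, 3), "\n  ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Grow a cohesive cluster from a seed protein
#'
#' Greedy local search: starting from the seed alone, repeatedly apply the
#' single boundary-node addition or member removal that most increases
#' cohesiveness, until no single move improves it (a local optimum). Ties
#' are broken deterministically: additions before removals, then
#' lexicographically smallest node name (the candidate scan is in sorted
#' order and only strict improvements replace the incumbent).
#'
#' @param graph an [interaction_graph()].
#' @param seed seed node name.
#' @param params [cluster_params()].
#' @return A [new_hub()] at a cohesiveness local optimum.
#' @export
grow_cluster <- function(graph, seed, params = cluster_params()) {
  stopifnot(seed %in% igraph::V(graph)$name)
  adj <- adjacency_weights(graph)
  strength <- vapply(adj, sum, numeric(1))
  res <- grow_engine(adj, strength, seed, params$penalty)
  new_hub(graph, res$members, params$penalty)
}

#' Decompose a network into ranked cohesive hubs
#'
#' Seed nodes are processed in decreasing degree order (ties broken
#' lexicographically), skipping nodes already covered by a grown cluster.
#' Clusters whose pairwise match coefficient `|A∩B|^2/(|A||B|)` exceeds the
#' overlap threshold are merged (transitive-closure union, so the result is
#' order independent); merged hubs below the minimum size or internal
#' density are discarded; survivors are ranked by cohesiveness, ties by
#' size, then by lexicographically smallest member.
#'
#' @param graph an [interaction_graph()].
#' @param params [cluster_params()].
#' @return List of `hub` objects in rank order (possibly empty).
#' @export
find_hubs <- function(graph, params = cluster_params()) {
  stopifnot(igraph::vcount(graph) > 0)
  adj <- adjacency_weights(graph)
  strength <- vapply(adj, sum, numeric(1))
  deg <- lengths(adj)
  seeds <- names(deg)[order(-deg, names(deg))]
  covered <- character()
  clusters <- list()
  for (s in seeds) {
    if (s %in% covered) next
    res <- grow_engine(adj, strength, s, params$penalty)
    clusters[[length(clusters) + 1L]] <- res$members
    covered <- union(covered, res$members)
  }
  clusters <- unique(clusters)
  # transitive-closure merge over the overlap graph
  if (length(clusters) > 1L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(clusters)) {
        for (j in seq_along(clusters)) {
          if (j <= i) next
          a <- clusters[[i]]; b <- clusters[[j]]
          ov <- length(intersect(a, b))^2 / (length(a) * length(b))
          if (ov > params$overlap) {
            clusters[[i]] <- sort(union(a, b))
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  hubs <- lapply(clusters, function(m) new_hub(graph, m, params$penalty))
  keep <- vapply(hubs, function(h)
    h$size >= params$min_size && h$density >= params$min_density, logical(1))
  hubs <- hubs[keep]
  if (length(hubs) == 0L) return(list())
  key_member <- vapply(hubs, function(h) h$members[1], character(1))
  ord <- order(-vapply(hubs, `[[`, numeric(1), "cohesiveness"),
               -vapply(hubs, `[[`, numeric(1), "size"),
               key_member)
  hubs <- hubs[ord]
  for (i in seq_along(hubs)) hubs[[i]]$rank <- i
  hubs
}

#' Select the top-ranked hub of a network
#' @param hubs ranked hub list from [find_hubs()].
#' @param metal metal symbol for the error message.
#' @return The rank-1 [new_hub()].
#' @export
select_top_hub <- function(hubs, metal = "?") {
  if (length(hubs) == 0L)
    stop("no hub passed the size/density filters for metal '", metal, "'")
  hubs[[1]]
}

#' Hub table for a set of networks
#' @param hub_lists named list (metal -> list of hubs).
#' @return data.frame: metal, rank, size, cohesiveness, density, members
#'   (comma-joined).
#' @export
hub_table <- function(hub_lists) {
  rows <- list()
  for (metal in names(hub_lists)) {
    for (h in hub_lists[[metal]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        metal = metal, rank = h$rank, size = h$size,
        cohesiveness = h$cohesiveness, density = h$density,
        members = paste(h$members, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(metal = character(), rank = integer(),
                      size = integer(), cohesiveness = numeric(),
                      density = numeric(), members = character()))
  do.call(rbind, rows)
}
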