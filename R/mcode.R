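#' MCODE-style parameter set
#'
#' @param node_score_cutoff Fraction in `[0, 1)`; a node joins a cluster
#'   when its weight is at least `(1 - node_score_cutoff)` times the seed
#'   weight (default 0.2, the conventional default).
#' @param k_core Minimum core a retained cluster must contain (default 2).
#' @param haircut Remove singly-connected nodes from each cluster
#'   (default `TRUE`).
#' @param fluff Optional post-expansion step of the original algorithm;
#'   accepted for interface completeness but not implemented (a request
#'   is ignored with a warning). Default `FALSE`.
#' @return An object of class `mcode_params`.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, k_core = 2,
                         haircut = TRUE, fluff = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stopf("node_score_cutoff must be in [0, 1)")
  if (!is_count(k_core) || k_core < 2) stopf("k_core must be an integer >= 2")
  structure(list(node_score_cutoff = node_score_cutoff, k_core = as.integer(k_core),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff)),
            class = "mcode_params")
}

#' MCODE vertex weights
#'
#' Each node is weighted by the local density of its neighbourhood: the
#' core number of the highest k-core of the subgraph induced by the node's
#' open neighbourhood, multiplied by the density of that k-core subgraph.
#' Isolated nodes and leaves (whose neighbourhood has no edges) get
#' weight 0.
#'
#' @param graph Undirected simple [igraph::igraph] graph with node names.
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph) {
  vn <- igraph::V(graph)$name
  if (is.null(vn)) stopf("graph nodes must be named")
  w <- setNames(numeric(length(vn)), vn)
  adj <- igraph::as_adj_list(graph)
  for (i in seq_along(vn)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(graph, nb)
    if (igraph::ecount(sub) == 0) next
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores == kmax))
    nv <- igraph::vcount(core_sub)
    dens <- igraph::ecount(core_sub) / (nv * (nv - 1) / 2)
    w[i] <- kmax * dens
  }
  w
}

graph_density_score <- function(graph) {
  nv <- igraph::vcount(graph)
  if (nv < 2) return(0)
  dens <- igraph::ecount(graph) / (nv * (nv - 1) / 2)
  dens * nv
}

#' MCODE-style graph clustering
#'
#' Repeatedly seeds at the highest-weight unassigned node and grows a
#' cluster outwards, including reachable unassigned neighbours whose
#' weight is at least `(1 - node_score_cutoff)` times the seed weight.
#' After optional haircut (removal of nodes with fewer than two links
#' inside the cluster), clusters that do not contain a `k_core` are
#' discarded. Every visited node is assigned to at most one cluster.
#' Clusters are scored by `density * size` and ranked by score
#' (ties broken by the lexicographically smaller member list).
#'
#' @param graph Undirected simple [igraph::igraph] graph with node names.
#' @param params An `mcode_params` object.
#' @return List of clusters, each a list with `pathway_ids` (members),
#'   `mcode_score`, `rank` and `seed`.
#' @export
mcode_clusters <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  if (params$fluff) warning("fluff post-processing is not implemented; ignored")
  vn <- igraph::V(graph)$name
  if (is.null(vn)) stopf("graph nodes must be named")
  if (length(vn) == 0) return(list())
  ord <- order(vn)
  ids <- vn[ord]
  g <- igraph::permute(graph, match(igraph::V(graph)$name, ids))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  w <- mcode_vertex_weights(g)
  n <- length(ids)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  repeat {
    avail <- which(unassigned)
    if (length(avail) == 0) break
    seed <- avail[which.max(w[avail])]      # ties -> smallest index (lexicographic)
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    # BFS over unassigned nodes meeting the weight threshold
    members <- seed
    frontier <- seed
    in_cluster <- rep(FALSE, n); in_cluster[seed] <- TRUE
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        ok <- nb[unassigned[nb] & !in_cluster[nb] & w[nb] >= threshold]
        in_cluster[ok] <- TRUE
        nxt <- c(nxt, ok)
      }
      frontier <- nxt
    }
    members <- which(in_cluster)
    unassigned[members] <- FALSE
    sub <- igraph::induced_subgraph(g, members)
    if (params$haircut && igraph::vcount(sub) > 1) {
      keep <- igraph::degree(sub) >= 2
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    if (igraph::vcount(sub) == 0) next
    if (max(igraph::coreness(sub)) < params$k_core) next
    clusters[[length(clusters) + 1L]] <- list(
      pathway_ids = sort(igraph::V(sub)$name),
      mcode_score = graph_density_score(sub),
      seed = ids[seed])
  }
  rank_clusters(clusters)
}

rank_clusters <- function(clusters) {
  if (length(clusters) == 0) return(clusters)
  scores <- vapply(clusters, `[[`, numeric(1), "mcode_score")
  keys <- vapply(clusters, function(cl) paste(cl$pathway_ids, collapse = ","),
                 character(1))
  ord <- order(-scores, keys)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  clusters
}

#' Subdivide a large pathway subnetwork into dense clusters
#'
#' A subnetwork of at most `size_threshold` pathways is returned
#' unchanged as a single cluster; a larger one is re-clustered with
#' [mcode_clusters()] on its induced subgraph of the pathway network.
#'
#' @param subnet_nodes Character vector: the subnetwork's pathway ids.
#' @param pnet A `pathway_network` containing those pathways.
#' @param params An `mcode_params` object.
#' @param size_threshold Subdivision is triggered strictly above this
#'   size (default 50).
#' @return List of clusters as in [mcode_clusters()].
#' @export
subdivide_large <- function(subnet_nodes, pnet, params = mcode_params(),
                            size_threshold = 50) {
  stopifnot(inherits(pnet, "pathway_network"))
  if (!all(subnet_nodes %in% igraph::V(pnet$graph)$name))
    stopf("subnetwork node(s) missing from the pathway network")
  sub <- igraph::induced_subgraph(pnet$graph, subnet_nodes)
  if (length(subnet_nodes) <= size_threshold) {
    cl <- list(list(pathway_ids = sort(subnet_nodes),
                    mcode_score = graph_density_score(sub),
                    seed = NA_character_))
    return(rank_clusters(cl))
  }
  mcode_clusters(sub, params)
}
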