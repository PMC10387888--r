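#' Hypergeometric connectivity point mass
#'
#' Probability that a node of degree `k`, wired at random in a network of
#' `N` nodes, has exactly `ks` of its links into a module of size `s0`:
#' `choose(s0, ks) * choose(N - s0, k - ks) / choose(N, k)`. Evaluated in
#' log space (via [stats::dhyper()]) so large arguments stay accurate.
#'
#' @param N Total node count.
#' @param s0 Current module size.
#' @param k Candidate's degree.
#' @param ks Candidate's links into the module.
#' @return The point probability. Arguments are recycled.
#' @export
connectivity_pmf <- function(N, s0, k, ks) {
  check_diamond_query(N, s0, k, ks)
  dhyper(ks, m = s0, n = N - s0, k = k)
}

#' Hypergeometric connectivity p-value
#'
#' Upper-tail probability that a randomly wired node of degree `k` has at
#' least `ks` links into the module: the sum of [connectivity_pmf()] from
#' `ks` to `k`. `ks = 0` gives exactly 1.
#'
#' @inheritParams connectivity_pmf
#' @return The tail probability in `[0, 1]`.
#' @export
connectivity_pvalue <- function(N, s0, k, ks) {
  check_diamond_query(N, s0, k, ks)
  phyper(ks - 1, m = s0, n = N - s0, k = k, lower.tail = FALSE)
}

check_diamond_query <- function(N, s0, k, ks) {
  if (any(ks < 0) || any(ks > pmin(k, s0)))
    stopf("invalid query: need 0 <= ks <= min(k, s0)")
  if (any(s0 > N)) stopf("invalid query: s0 exceeds N")
  if (any(k > N - 1)) stopf("invalid query: degree k exceeds N - 1")
  invisible(TRUE)
}

#' DIAMOnD-style iterative module expansion
#'
#' Starting from a seed set, repeatedly adds the non-member node whose
#' links into the current module are most hypergeometrically surprising
#' (smallest [connectivity_pvalue()], recomputed against the grown module
#' at every iteration). Only nodes with at least one link into the module
#' are candidates. Ties are broken by higher `ks`, then lexicographic
#' node id, making the expansion deterministic.
#'
#' @param network Undirected simple [igraph::igraph] graph with node names.
#' @param seeds Character vector of seed node ids (must be in the network).
#' @param n_add Number of nodes to add. Expansion stops early (with a
#'   warning) if no candidate remains.
#' @return A `diamond_result`: data frame with columns `rank`, `node_id`,
#'   `p_value`, `ks`, `k`; attribute `seed_ids` holds the seeds.
#' @export
diamond_expand <- function(network, seeds, n_add) {
  if (!is_count(n_add)) stopf("n_add must be a positive integer")
  vn <- igraph::V(network)$name
  if (is.null(vn)) stopf("network nodes must be named")
  if (!all(seeds %in% vn)) stopf("seed(s) not present in the network")
  ord <- order(vn)
  ids <- vn[ord]
  n <- length(ids)
  g <- igraph::permute(network, match(igraph::V(network)$name, ids))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- lengths(adj)
  member <- rep(FALSE, n)
  member[match(seeds, ids)] <- TRUE
  ks <- integer(n)
  for (s in which(member)) ks[adj[[s]]] <- ks[adj[[s]]] + 1L

  ranks <- integer(n_add); nodes <- character(n_add)
  pvals <- numeric(n_add); ks_rec <- integer(n_add); k_rec <- integer(n_add)
  added <- 0L
  for (step in seq_len(n_add)) {
    cand <- which(!member & ks >= 1L)
    if (length(cand) == 0) {
      warning("no candidate left after ", added, " addition(s); stopping early")
      break
    }
    s0 <- sum(member)
    p <- phyper(ks[cand] - 1L, m = s0, n = n - s0, k = deg[cand],
                lower.tail = FALSE)
    best <- cand[order(p, -ks[cand], cand)][1]
    added <- added + 1L
    ranks[added] <- added
    nodes[added] <- ids[best]
    pvals[added] <- p[match(best, cand)]
    ks_rec[added] <- ks[best]
    k_rec[added] <- deg[best]
    member[best] <- TRUE
    nb <- adj[[best]]
    ks[nb] <- ks[nb] + 1L
  }
  idx <- seq_len(added)
  structure(data.frame(rank = ranks[idx], node_id = nodes[idx],
                       p_value = pvals[idx], ks = ks_rec[idx], k = k_rec[idx],
                       stringsAsFactors = FALSE),
            seed_ids = sort(unique(seeds)),
            class = c("diamond_result", "data.frame"))
}

#' @export
print.diamond_result <- function(x, ...) {
  cat("diamond_result:", nrow(x), "additions from",
      length(attr(x, "seed_ids")), "seeds\n")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Final module of a DIAMOnD expansion
#'
#' @param result A `diamond_result`.
#' @return Character vector: seeds plus added nodes.
#' @export
diamond_module <- function(result) {
  c(attr(result, "seed_ids"), result$node_id)
}
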