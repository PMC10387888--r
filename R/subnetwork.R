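#' Convert a p-value to a z-score
#'
#' `z = qnorm(1 - p)`: small p-values map to large positive z. Input is
#' clamped to `[1e-300, 1 - 1e-16]` so the result is always finite.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of z-scores, strictly decreasing in `p`.
#' @export
p_to_z <- function(p) {
  p <- pmin(pmax(p, P_CLAMP_LO), 1 - 1e-16)
  qnorm(p, lower.tail = FALSE)
}

#' Aggregate node z-scores into a subnetwork score
#'
#' The aggregate score of a subnetwork of `k` nodes is
#' `z_A = sum(z_i) / sqrt(k)`. Under independent standard-normal node
#' scores, `z_A` is standard normal for every `k`.
#'
#' @param z_values Non-empty numeric vector of node z-scores.
#' @return The aggregate score `z_A`.
#' @export
aggregate_z <- function(z_values) {
  if (length(z_values) == 0) stopf("cannot aggregate an empty set of z-scores")
  sum(z_values) / sqrt(length(z_values))
}

#' Monte-Carlo calibration of subnetwork scores
#'
#' Estimates, for each subnetwork size `k`, the null mean and standard
#' deviation of `z_A` over random node sets drawn (without replacement
#' within a draw) from the supplied score pool. Each Monte-Carlo draw is a
#' random permutation of the pool, whose running prefixes provide one
#' random set of every size simultaneously; each size therefore sees
#' `n_samples` uniformly drawn node sets.
#'
#' @param z_pool Named numeric vector of node z-scores (the calibration
#'   pool; topology is deliberately ignored, which keeps the null cheap
#'   and is conservative for dense subnetworks).
#' @param sizes Subnetwork sizes to calibrate. Entries are produced for
#'   every `k` from 1 up to `max(sizes)` (at most the pool size).
#' @param n_samples Monte-Carlo samples per size (minimum 100; default
#'   10000).
#' @param seed Optional integer seed for reproducibility.
#' @param sigma_floor Lower bound applied to the estimated standard
#'   deviations, guarding degenerate (near-constant) pools.
#' @return A `subnet_calibration`: list with `mu` and `sigma` (numeric
#'   vectors indexed by size `k`), `sizes`, `n_samples` and `seed`.
#' @export
calibrate_subnetwork_scores <- function(z_pool, sizes, n_samples = 10000,
                                        seed = NULL, sigma_floor = 1e-8) {
  if (n_samples < 100) stopf("n_samples must be >= 100")
  kmax <- max(sizes)
  if (any(sizes < 1)) stopf("sizes must be >= 1")
  if (kmax > length(z_pool))
    stopf("requested size %d exceeds pool size %d", kmax, length(z_pool))
  if (!is.null(seed)) set.seed(seed)
  z <- as.numeric(z_pool)
  sqrt_k <- sqrt(seq_len(kmax))
  # columns: one permutation prefix-sum per Monte-Carlo draw
  cs <- vapply(seq_len(n_samples),
               function(i) cumsum(sample(z, kmax)),
               numeric(kmax))
  cs <- matrix(cs, nrow = kmax)
  za <- cs / sqrt_k
  mu <- rowMeans(za)
  sigma <- sqrt(rowSums((za - mu)^2) / (n_samples - 1))
  sigma <- pmax(sigma, sigma_floor)
  structure(list(mu = mu, sigma = sigma, sizes = seq_len(kmax),
                 n_samples = n_samples, seed = seed),
            class = "subnet_calibration")
}

#' @export
print.subnet_calibration <- function(x, ...) {
  cat("subnet_calibration: sizes 1-", max(x$sizes), ", ",
      x$n_samples, " samples per size\n", sep = "")
  invisible(x)
}

#' Score one subnetwork against the calibrated null
#'
#' The calibrated score is `s_A = (z_A - mu_k) / sigma_k`, so a random
#' node set of size `k` scores approximately standard normal.
#'
#' @param nodes Character vector of member node ids.
#' @param z Named numeric vector of node z-scores covering all members.
#' @param calib A `subnet_calibration` with an entry for `k = length(nodes)`.
#' @param seed_node Optional id of the seed the subnetwork grew from.
#' @return A `subnetwork`: list with `node_ids`, `k`, `z_A`, `s_A`,
#'   `seed_node`.
#' @export
score_subnetwork <- function(nodes, z, calib, seed_node = NULL) {
  k <- length(nodes)
  if (!all(nodes %in% names(z))) stopf("unscored node in subnetwork")
  if (k > length(calib$mu)) stopf("no calibration entry for size %d", k)
  z_a <- aggregate_z(z[nodes])
  structure(list(node_ids = nodes, k = k, z_A = z_a,
                 s_A = (z_a - calib$mu[k]) / calib$sigma[k],
                 seed_node = seed_node),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork: k =", x$k, " z_A =", signif(x$z_A, 4),
      " s_A =", signif(x$s_A, 4), "\n")
  invisible(x)
}

#' Greedy active-subnetwork search
#'
#' Runs one greedy expansion per seed node: starting from the seed, the
#' neighbouring node whose inclusion maximises the calibrated score `s_A`
#' is added at each step (at fixed target size this is the neighbour with
#' the largest z; ties are broken by lexicographic node id). Expansion
#' stops when no addition increases `s_A` or `max_size` is reached.
#' Subnetworks with identical node sets found from different seeds are
#' collapsed; overlapping but distinct subnetworks are all reported.
#'
#' @param network Undirected simple [igraph::igraph] graph with node names.
#' @param z Named numeric vector of node z-scores. Nodes of the network
#'   without a score are excluded from seeds and candidates (reported via
#'   [message()]).
#' @param calib A `subnet_calibration` covering sizes up to `max_size`
#'   (expansion is capped at the largest calibrated size).
#' @param score_cutoff Minimum calibrated score for a subnetwork to be
#'   reported (default 3, the conventional significance cutoff for active
#'   modules).
#' @param max_size Maximum subnetwork size (default 300).
#' @param seeds Optional character vector of seed nodes; defaults to every
#'   scored node.
#' @return A `subnetwork_set`: data frame with columns `id`, `seed`, `k`,
#'   `z_A`, `s_A` and a list column `members`, sorted by `s_A` decreasing.
#' @export
active_subnetworks <- function(network, z, calib, score_cutoff = 3,
                               max_size = 300, seeds = NULL) {
  if (any(igraph::which_loop(network)) || any(igraph::which_multiple(network)))
    stopf("network must be simple (no self-loops or multi-edges)")
  vn <- igraph::V(network)$name
  if (is.null(vn)) stopf("network nodes must be named")
  scored <- vn[vn %in% names(z)]
  n_unscored <- length(vn) - length(scored)
  if (n_unscored > 0)
    message(n_unscored, " network node(s) without a score excluded from search")
  if (length(scored) == 0) return(empty_subnetwork_set())
  if (is.null(seeds)) seeds <- scored
  seeds <- seeds[seeds %in% scored]
  kcap <- min(max_size, length(calib$mu), length(scored))

  # integer-index machinery over the scored nodes, ordered by name so that
  # "lexicographically smallest id" == smallest index
  ord <- order(scored)
  ids <- scored[ord]
  n <- length(ids)
  zv <- as.numeric(z[ids])
  sub <- igraph::induced_subgraph(network, ids)
  # map back: induced_subgraph preserves names
  adj <- lapply(igraph::as_adj_list(sub), function(vs) {
    match(igraph::V(sub)$name[as.integer(vs)], ids)
  })
  names(adj) <- igraph::V(sub)$name
  adj <- adj[ids]

  results <- list()
  seen <- character()
  for (seed in sort(seeds)) {
    si <- match(seed, ids)
    in_mem <- rep(FALSE, n); in_mem[si] <- TRUE
    in_cand <- rep(FALSE, n)
    nb <- adj[[si]]
    in_cand[nb] <- TRUE
    k <- 1L
    sum_z <- zv[si]
    s_a <- (sum_z - calib$mu[1]) / calib$sigma[1]
    repeat {
      if (k >= kcap) break
      cand <- which(in_cand)
      if (length(cand) == 0) break
      # argmax s_A at size k+1 == argmax z; ties -> smallest index (lexicographic id)
      best <- cand[which.max(zv[cand])]
      z_a_new <- (sum_z + zv[best]) / sqrt(k + 1)
      s_a_new <- (z_a_new - calib$mu[k + 1]) / calib$sigma[k + 1]
      if (s_a_new <= s_a) break
      in_mem[best] <- TRUE
      in_cand[best] <- FALSE
      new_nb <- adj[[best]]
      add <- new_nb[!in_mem[new_nb] & !in_cand[new_nb]]
      in_cand[add] <- TRUE
      sum_z <- sum_z + zv[best]
      k <- k + 1L
      s_a <- s_a_new
    }
    members <- ids[in_mem]
    key <- node_set_key(members)
    if (key %in% seen) next
    seen <- c(seen, key)
    results[[length(results) + 1L]] <- list(
      seed = seed, k = k, z_A = sum_z / sqrt(k), s_A = s_a, members = members)
  }
  if (length(results) == 0) return(empty_subnetwork_set())
  tab <- data.frame(
    seed = vapply(results, `[[`, character(1), "seed"),
    k = vapply(results, `[[`, integer(1), "k"),
    z_A = vapply(results, `[[`, numeric(1), "z_A"),
    s_A = vapply(results, `[[`, numeric(1), "s_A"),
    stringsAsFactors = FALSE
  )
  tab$members <- lapply(results, `[[`, "members")
  tab <- tab[tab$s_A >= score_cutoff, , drop = FALSE]
  if (nrow(tab) == 0) return(empty_subnetwork_set())
  tab <- tab[order(-tab$s_A, tab$seed), , drop = FALSE]
  tab$id <- sprintf("subnet_%03d", seq_len(nrow(tab)))
  rownames(tab) <- NULL
  structure(tab[, c("id", "seed", "k", "z_A", "s_A", "members")],
            class = c("subnetwork_set", "data.frame"))
}

empty_subnetwork_set <- function() {
  tab <- data.frame(id = character(), seed = character(), k = integer(),
                    z_A = numeric(), s_A = numeric(), stringsAsFactors = FALSE)
  tab$members <- list()
  structure(tab, class = c("subnetwork_set", "data.frame"))
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat("subnetwork_set:", nrow(x), "subnetworks\n")
  if (nrow(x) > 0) {
    show <- as.data.frame(x)[seq_len(min(6, nrow(x))), c("id", "seed", "k", "z_A", "s_A")]
    print.data.frame(show)
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Write a subnetwork set to TSV
#'
#' Members are written comma-joined in a single column.
#'
#' @param subnets A `subnetwork_set`.
#' @param path Output path.
#' @export
write_subnetworks <- function(subnets, path) {
  tab <- as.data.frame(subnets)
  tab$members <- vapply(tab$members, paste, character(1), collapse = ",")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
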