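#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least `k` query genes inside a pathway of
#' size `g`, for a query of `d` genes drawn from a universe of `f` genes:
#' the upper tail `sum_{i = k..min(g, d)} choose(g, i) choose(f - g, d - i)
#' / choose(f, d)`.
#'
#' @param f Universe size.
#' @param g Pathway size (`g <= f`).
#' @param d Query-set size (`d <= f`).
#' @param k Overlap count (`k <= min(g, d)`).
#' @return The tail probability in `(0, 1]`. Arguments are recycled.
#' @export
enrich_p <- function(f, g, d, k) {
  if (any(g > f) || any(d > f)) stopf("pathway/query size exceeds universe")
  if (any(k > pmin(g, d)) || any(k < 0)) stopf("overlap k must satisfy 0 <= k <= min(g, d)")
  phyper(k - 1, m = g, n = f - g, k = d, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper around [stats::p.adjust()] using the two corrections in
#' routine use for pathway enrichment. Order is preserved relative to the
#' input.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param method `"benjamini_hochberg"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_values, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  p.adjust(p_values, method = switch(method,
                                     benjamini_hochberg = "BH",
                                     bonferroni = "bonferroni"))
}

#' Over-representation analysis of a gene set
#'
#' Tests a query gene set against every pathway of a collection. The query
#' is first intersected with the collection universe (out-of-universe
#' genes are dropped and reported); a pathway is called significant when
#' its adjusted p-value is strictly below `alpha`.
#'
#' @param genes Character vector of query gene ids (e.g. one subnetwork's
#'   members).
#' @param collection A `gene_set_collection`.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param method Correction method, see [adjust_pvalues()].
#' @param universe Optional universe override; defaults to the
#'   collection's universe.
#' @return An `enrichment_result`: data frame with columns `pathway_id`,
#'   `name`, `f`, `g`, `d`, `k_overlap`, `p_raw`, `p_adj`, `significant`,
#'   `rank`, ordered by (`p_adj`, `p_raw`, `pathway_id`).
#' @export
enrich_module <- function(genes, collection, alpha = 0.05,
                          method = c("benjamini_hochberg", "bonferroni"),
                          universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  method <- match.arg(method)
  universe <- universe %||% collection$universe
  query <- unique(as.character(genes))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0)
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0)
    warning("query set is disjoint from the universe; all p-values are 1")
  f <- length(universe)
  ids <- names(collection$sets)
  g <- vapply(collection$sets, function(s) length(intersect(s, universe)), integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1))
  d <- length(query)
  p_raw <- enrich_p(f, g, d, k)
  p_adj <- adjust_pvalues(p_raw, method)
  out <- data.frame(pathway_id = ids,
                    name = unname(collection$descriptions[ids]),
                    f = f, g = g, d = d, k_overlap = k,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$pathway_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, alpha = alpha, method = method,
            class = c("enrichment_result", "data.frame"))
}

#' Aggregate module-level enrichment to a dataset-level pathway list
#'
#' A dataset produces many modules, each with its own enrichment table.
#' The dataset-level evidence for a pathway is summarised as the minimum
#' adjusted p-value over the dataset's modules (the pathway's best
#' showing), together with the number of modules in which it was
#' significant.
#'
#' @param module_results List of `enrichment_result`s, one per module.
#' @param alpha Significance level applied to the aggregated p (default
#'   0.05).
#' @return Data frame with columns `pathway_id`, `name`, `p_adj` (minimum
#'   over modules), `n_modules_significant`, `significant`, `rank`.
#' @export
aggregate_enrichment <- function(module_results, alpha = 0.05) {
  if (length(module_results) == 0)
    return(data.frame(pathway_id = character(), name = character(),
                      p_adj = numeric(), n_modules_significant = integer(),
                      significant = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  ids <- sort(unique(unlist(lapply(module_results, `[[`, "pathway_id"))))
  pmin_adj <- setNames(rep(1, length(ids)), ids)
  nsig <- setNames(rep(0L, length(ids)), ids)
  nm <- setNames(rep(NA_character_, length(ids)), ids)
  for (res in module_results) {
    pmin_adj[res$pathway_id] <- pmin(pmin_adj[res$pathway_id], res$p_adj)
    nsig[res$pathway_id] <- nsig[res$pathway_id] + res$significant
    nm[res$pathway_id] <- res$name
  }
  out <- data.frame(pathway_id = ids, name = unname(nm),
                    p_adj = unname(pmin_adj),
                    n_modules_significant = unname(nsig),
                    significant = unname(pmin_adj) < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$pathway_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cross-dataset consensus of significant pathways
#'
#' Reports pathways that are significant in at least `min_datasets`
#' datasets (default: all of them, the strict consensus), with each
#' pathway's best rank and best adjusted p over the datasets in which it
#' is significant.
#'
#' @param per_dataset Named list of dataset-level pathway tables as
#'   produced by [aggregate_enrichment()] (needs columns `pathway_id`,
#'   `p_adj`, `significant`, `rank`).
#' @param min_datasets Minimum number of datasets a pathway must be
#'   significant in (default: `length(per_dataset)`).
#' @return Data frame with columns `pathway_id`, `n_datasets`,
#'   `best_rank`, `best_p_adj`, ordered by (`n_datasets` decreasing,
#'   `best_p_adj`).
#' @export
consensus_pathways <- function(per_dataset, min_datasets = NULL) {
  if (length(per_dataset) < 2) stopf("need at least 2 datasets for a consensus")
  min_datasets <- min_datasets %||% length(per_dataset)
  sig_sets <- lapply(per_dataset, function(t) t$pathway_id[t$significant])
  ids <- sort(unique(unlist(sig_sets)))
  if (length(ids) == 0)
    return(data.frame(pathway_id = character(), n_datasets = integer(),
                      best_rank = integer(), best_p_adj = numeric(),
                      stringsAsFactors = FALSE))
  n_datasets <- vapply(ids, function(id)
    sum(vapply(sig_sets, function(s) id %in% s, logical(1))), integer(1))
  best_rank <- vapply(ids, function(id) {
    r <- vapply(per_dataset, function(t) {
      i <- match(id, t$pathway_id)
      if (is.na(i) || !t$significant[i]) NA_integer_ else t$rank[i]
    }, integer(1))
    as.integer(min(r, na.rm = TRUE))
  }, integer(1))
  best_p <- vapply(ids, function(id) {
    p <- vapply(per_dataset, function(t) {
      i <- match(id, t$pathway_id)
      if (is.na(i)) NA_real_ else t$p_adj[i]
    }, numeric(1))
    min(p, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(pathway_id = ids, n_datasets = n_datasets,
                    best_rank = best_rank, best_p_adj = best_p,
                    stringsAsFactors = FALSE)
  out <- out[out$n_datasets >= min_datasets, , drop = FALSE]
  out <- out[order(-out$n_datasets, out$best_p_adj, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
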