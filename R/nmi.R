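#' Shared-gene contingency table between two module sets
#'
#' Entry `n[i, j]` is the number of genes shared by module `U_i` of the
#' first set and module `V_j` of the second. Modules may overlap (the
#' counts are per pair), so the margins are sums over the matrix, not
#' necessarily module sizes.
#'
#' @param modules_u,modules_v Non-empty lists of character vectors (gene
#'   sets).
#' @return A `module_contingency`: list with matrix `n`, margins `a`
#'   (rows) and `b` (columns), and grand total `N`.
#' @export
module_contingency <- function(modules_u, modules_v) {
  if (length(modules_u) == 0 || length(modules_v) == 0)
    stopf("both module lists must be non-empty")
  genes <- sort(unique(c(unlist(modules_u), unlist(modules_v))))
  mu <- vapply(modules_u, function(s) genes %in% s, logical(length(genes)))
  mv <- vapply(modules_v, function(s) genes %in% s, logical(length(genes)))
  mu <- matrix(mu, nrow = length(genes)); mv <- matrix(mv, nrow = length(genes))
  n <- crossprod(mu, mv)      # |U| x |V| shared-gene counts
  storage.mode(n) <- "integer"
  structure(list(n = n, a = rowSums(n), b = colSums(n), N = sum(n)),
            class = "module_contingency")
}

#' Normalized mutual information of two module sets
#'
#' From a shared-gene contingency table computes the community entropies
#' `H(U) = -sum (a_i/N) log(a_i/N)`, `H(V)` analogously, the mutual
#' information `I(U, V) = sum (n_ij/N) log((n_ij/N) / (a_i b_j / N^2))`
#' (terms with `n_ij = 0` contribute 0; natural log), and
#' `NMI_SUM = 2 I / (H(U) + H(V))`, clamped into `[0, 1]` against
#' floating-point error. The degenerate single-block case
#' `H(U) + H(V) = 0` is defined as `NMI_SUM = 1` (reported via
#' [message()]).
#'
#' @param table A `module_contingency` with `N > 0`.
#' @return An `nmi_result`: list with `h_u`, `h_v`, `i_uv`, `nmi_sum`.
#' @export
nmi <- function(table) {
  stopifnot(inherits(table, "module_contingency"))
  if (table$N == 0)
    stopf("contingency table has no shared genes (N = 0); report 'no overlap' instead")
  N <- table$N
  entropy <- function(m) {
    p <- m[m > 0] / N
    -sum(p * log(p))
  }
  h_u <- entropy(table$a)
  h_v <- entropy(table$b)
  pij <- table$n / N
  expected <- outer(table$a, table$b) / N^2
  pos <- pij > 0
  i_uv <- sum(pij[pos] * log(pij[pos] / expected[pos]))
  if (h_u + h_v == 0) {
    message("both module sets are single blocks; NMI defined as 1 by convention")
    nmi_sum <- 1
  } else {
    nmi_sum <- 2 * i_uv / (h_u + h_v)
    nmi_sum <- min(max(nmi_sum, 0), 1)
  }
  structure(list(h_u = h_u, h_v = h_v, i_uv = i_uv, nmi_sum = nmi_sum),
            class = "nmi_result")
}

#' @export
print.nmi_result <- function(x, ...) {
  cat("NMI_SUM =", signif(x$nmi_sum, 4),
      " (H(U) =", signif(x$h_u, 4),
      ", H(V) =", signif(x$h_v, 4),
      ", I =", signif(x$i_uv, 4), ")\n")
  invisible(x)
}

#' Pairwise NMI matrix across datasets
#'
#' @param sets_by_dataset Named list (dataset label -> list of gene
#'   sets). At least two datasets are required.
#' @return Symmetric numeric matrix of `NMI_SUM` values with dataset
#'   labels; the diagonal is reported as 1.
#' @export
pairwise_nmi <- function(sets_by_dataset) {
  if (length(sets_by_dataset) < 2) stopf("need at least 2 datasets")
  labels <- names(sets_by_dataset)
  m <- matrix(1, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(labels)) {
    for (j in seq_len(i - 1L)) {
      val <- nmi(module_contingency(sets_by_dataset[[i]], sets_by_dataset[[j]]))$nmi_sum
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

#' Rank of target pathways in an enrichment result
#'
#' Restricts an enrichment table to a set of target pathways (for example
#' the canonical disease pathways used to benchmark a method), preserving
#' their ranks. Targets absent from the table are reported with rank
#' `Inf` and `p_adj = 1`.
#'
#' @param enrichment An `enrichment_result` or any data frame with
#'   columns `pathway_id`, `rank`, `p_adj`.
#' @param targets Character vector of target pathway ids.
#' @return Data frame with columns `pathway_id`, `rank`, `p_adj`, in
#'   rank order.
#' @export
target_pathway_ranks <- function(enrichment, targets) {
  idx <- match(targets, enrichment$pathway_id)
  out <- data.frame(
    pathway_id = targets,
    rank = ifelse(is.na(idx), Inf, enrichment$rank[idx]),
    p_adj = ifelse(is.na(idx), 1, enrichment$p_adj[idx]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
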