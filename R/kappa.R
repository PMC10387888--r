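#' Binary gene-pathway membership matrix
#'
#' Rows are the union of all pathway genes (the collection universe),
#' columns are pathways; a cell is 1 iff the gene belongs to the pathway.
#'
#' @param collection A `gene_set_collection`.
#' @return Integer matrix with gene row names and pathway column names.
#' @export
build_membership <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- collection$universe
  m <- vapply(collection$sets,
              function(s) as.integer(genes %in% s),
              integer(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(collection$sets)))
  m
}

#' Cohen's kappa between two membership vectors
#'
#' Agreement between two pathways over a common gene universe,
#' chance-corrected via the product-of-margins expectation. With the 2x2
#' co-membership counters `cn11` (gene in both), `cn10`, `cn01`, `cn00`:
#' observed agreement `G = (cn11 + cn00) / total`, chance agreement
#' `C = ((cn11 + cn01)(cn11 + cn10) + (cn00 + cn10)(cn00 + cn01)) / total^2`,
#' and `kappa = (G - C) / (1 - C)`. The degenerate case `C = 1` (both
#' margins concentrated) is defined as `kappa = 1`.
#'
#' @param membership_a,membership_b Equal-length binary (0/1) vectors over
#'   the same gene universe.
#' @return List with `counters` (named vector `cn11`, `cn10`, `cn01`,
#'   `cn00`, `total`) and `kappa`.
#' @export
kappa_pair <- function(membership_a, membership_b) {
  if (length(membership_a) != length(membership_b))
    stopf("membership vectors differ in length")
  a <- as.logical(membership_a)
  b <- as.logical(membership_b)
  cn11 <- sum(a & b); cn10 <- sum(a & !b)
  cn01 <- sum(!a & b); cn00 <- sum(!a & !b)
  total <- length(a)
  g <- (cn11 + cn00) / total
  cc <- ((cn11 + cn01) * (cn11 + cn10) + (cn00 + cn10) * (cn00 + cn01)) / total^2
  kap <- if (cc == 1) 1 else (g - cc) / (1 - cc)
  list(counters = c(cn11 = cn11, cn10 = cn10, cn01 = cn01, cn00 = cn00,
                    total = total),
       kappa = kap)
}

#' Pairwise kappa matrix for a collection
#'
#' Vectorised computation of [kappa_pair()] kappas for every pathway pair
#' of a membership matrix.
#'
#' @param membership Binary matrix from [build_membership()].
#' @return Symmetric numeric matrix of kappa scores (diagonal 1).
#' @export
kappa_matrix <- function(membership) {
  m <- membership
  ntot <- nrow(m)
  cn11 <- crossprod(m)                       # pathways x pathways
  sz <- colSums(m)
  cn10 <- outer(sz, rep(1, length(sz))) - cn11   # in A only
  cn01 <- t(cn10)
  cn00 <- ntot - cn11 - cn10 - cn01
  g <- (cn11 + cn00) / ntot
  cc <- ((cn11 + cn01) * (cn11 + cn10) + (cn00 + cn10) * (cn00 + cn01)) / ntot^2
  kap <- (g - cc) / (1 - cc)
  kap[cc == 1] <- 1
  dimnames(kap) <- list(colnames(m), colnames(m))
  kap
}

#' Build a kappa-thresholded pathway network
#'
#' Pathways become nodes; two pathways are linked when their kappa score
#' is at or above the threshold (inclusive). Pathways without any edge
#' are kept as isolated nodes; self-pairs are excluded.
#'
#' @param collection A `gene_set_collection`.
#' @param threshold Kappa cutoff (default 0.15).
#' @return A `pathway_network`: list with `graph` (an [igraph::igraph]
#'   with edge attribute `kappa`), `threshold` and the full `kappa`
#'   matrix.
#' @export
build_pathway_network <- function(collection, threshold = 0.15) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2) stopf("need at least 2 pathways")
  kap <- kappa_matrix(build_membership(collection))
  ids <- colnames(kap)
  keep <- which(upper.tri(kap) & kap >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(keep) > 0) {
    edges <- rbind(ids[keep[, 1]], ids[keep[, 2]])
    g <- igraph::add_edges(g, as.vector(edges))
    igraph::E(g)$kappa <- kap[keep]
  }
  structure(list(graph = g, threshold = threshold, kappa = kap),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network:", igraph::vcount(x$graph), "pathways,",
      igraph::ecount(x$graph), "edges (kappa >=", x$threshold, ")\n")
  invisible(x)
}

#' Write the pathway network edge list to TSV
#'
#' @param pnet A `pathway_network`.
#' @param path Output path.
#' @export
write_pathway_network <- function(pnet, path) {
  el <- igraph::as_edgelist(pnet$graph)
  tab <- data.frame(pathway_a = el[, 1], pathway_b = el[, 2],
                    kappa = if (igraph::ecount(pnet$graph) > 0)
                      igraph::E(pnet$graph)$kappa else numeric(0),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
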