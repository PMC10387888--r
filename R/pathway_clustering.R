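#' Active-subnetwork search on the pathway network
#'
#' Runs the calibrated greedy search of [active_subnetworks()] with
#' pathways as nodes: node significance comes from dataset-level
#' enrichment p-values, converted to z-scores, and the Monte-Carlo null
#' is recomputed on the pathway significance pool (never reused from a
#' gene-level pool). Pathways present in the network but missing from
#' `sig` are assigned p = 1 (no evidence), reported via [message()].
#'
#' @param pnet A `pathway_network`.
#' @param sig Named numeric vector mapping pathway id to its (corrected)
#'   enrichment p-value in `(0, 1]`.
#' @param calib Optional `subnet_calibration`; computed from the pathway
#'   pool when `NULL`.
#' @param cutoff Subnetwork score cutoff (default 3).
#' @param max_size Maximum subnetwork size (default 300).
#' @param mc_samples Monte-Carlo samples per size when calibrating
#'   (default 10000).
#' @param seed Optional RNG seed for the calibration.
#' @return A `subnetwork_set` over pathway ids.
#' @export
pathway_subnetworks <- function(pnet, sig, calib = NULL, cutoff = 3,
                                max_size = 300, mc_samples = 10000,
                                seed = NULL) {
  stopifnot(inherits(pnet, "pathway_network"))
  ids <- igraph::V(pnet$graph)$name
  missing <- setdiff(ids, names(sig))
  if (length(missing) > 0) {
    message(length(missing), " pathway(s) without a significance value set to p = 1")
    sig <- c(sig, setNames(rep(1, length(missing)), missing))
  }
  sig <- sig[ids]
  z <- p_to_z(clamp_pvalues(sig, what = "pathway p-value"))
  names(z) <- ids
  if (is.null(calib)) {
    kmax <- min(max_size, length(z))
    calib <- calibrate_subnetwork_scores(z, sizes = seq_len(kmax),
                                         n_samples = mc_samples, seed = seed)
  }
  active_subnetworks(pnet$graph, z, calib, score_cutoff = cutoff,
                     max_size = max_size)
}

#' Cluster every pathway subnetwork
#'
#' Applies [subdivide_large()] to each subnetwork of a set and returns
#' all resulting clusters, re-ranked globally by MCODE score.
#'
#' @param subnets A `subnetwork_set` over pathway ids.
#' @param pnet The `pathway_network` the subnetworks were found in.
#' @param params An `mcode_params` object.
#' @param size_threshold Subdivision threshold (default 50).
#' @return List of clusters (see [mcode_clusters()]), globally ranked.
#' @export
cluster_pathway_subnetworks <- function(subnets, pnet,
                                        params = mcode_params(),
                                        size_threshold = 50) {
  clusters <- list()
  for (i in seq_len(nrow(subnets))) {
    cl <- subdivide_large(subnets$members[[i]], pnet, params, size_threshold)
    clusters <- c(clusters, cl)
  }
  # identical clusters can arise from overlapping subnetworks; keep one copy
  keys <- vapply(clusters, function(cl) node_set_key(cl$pathway_ids), character(1))
  clusters <- clusters[!duplicated(keys)]
  rank_clusters(clusters)
}

#' Write pathway clusters to TSV
#'
#' @param clusters List of clusters from [cluster_pathway_subnetworks()]
#'   or [mcode_clusters()].
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = sprintf("cluster_%03d", seq_along(clusters)),
    rank = vapply(clusters, `[[`, integer(1), "rank"),
    score = vapply(clusters, `[[`, numeric(1), "mcode_score"),
    n_pathways = vapply(clusters, function(cl) length(cl$pathway_ids), integer(1)),
    members = vapply(clusters, function(cl) paste(cl$pathway_ids, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
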