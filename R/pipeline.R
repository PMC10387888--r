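#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults
#' used throughout: SNP p-value filter 0.05 (strict), subnetwork score
#' cutoff 3, kappa threshold 0.15, pathway-subnetwork subdivision
#' threshold 50, significance level 0.05 with Benjamini-Hochberg
#' correction.
#'
#' @param datasets Named character vector of summary-statistics TSV
#'   paths (names are dataset labels).
#' @param ppi Path to the interaction-network edge list.
#' @param gmt Path to the pathway GMT file.
#' @param bed Path to the gene models (BED4).
#' @param out_dir Output directory for artifacts.
#' @param column_spec Column mapping for [read_summary_stats()].
#' @param p_cutoff SNP filter cutoff (default 0.05).
#' @param gene_window SNP-to-gene window in bases (default 50 kb).
#' @param statistic Gene statistic: `"max_chi2"` (default) or
#'   `"sum_chi2"`.
#' @param include_combined Also analyse the Fisher-combined dataset
#'   (default `TRUE`).
#' @param mc_samples Monte-Carlo samples per subnetwork size (default
#'   10000).
#' @param subnet_cutoff Active-subnetwork score cutoff (default 3).
#' @param max_size Maximum subnetwork size (default 300).
#' @param kappa_threshold Pathway-network kappa cutoff (default 0.15).
#' @param size_threshold Pathway-subnetwork subdivision threshold
#'   (default 50).
#' @param alpha Enrichment significance level (default 0.05).
#' @param method Correction method (default `"benjamini_hochberg"`).
#' @param rng_seed Master seed; each stochastic stage derives its own
#'   seed from it (default 1).
#' @return An object of class `pathnet_config`.
#' @export
pathnet_config <- function(datasets, ppi, gmt, bed, out_dir = "pathnet_run",
                           column_spec = list(chrom = "chrom", pos = "pos",
                                              effect_allele = "effect_allele",
                                              other_allele = "other_allele",
                                              p = "p", rsid = "rsid", fs = "fs"),
                           p_cutoff = 0.05, gene_window = 50000,
                           statistic = c("max_chi2", "sum_chi2"),
                           include_combined = TRUE,
                           mc_samples = 10000, subnet_cutoff = 3,
                           max_size = 300, kappa_threshold = 0.15,
                           size_threshold = 50, alpha = 0.05,
                           method = c("benjamini_hochberg", "bonferroni"),
                           rng_seed = 1L) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stopf("datasets must be a named vector of paths")
  structure(list(datasets = datasets, ppi = ppi, gmt = gmt, bed = bed,
                 out_dir = out_dir, column_spec = column_spec,
                 p_cutoff = p_cutoff, gene_window = gene_window,
                 statistic = statistic, include_combined = include_combined,
                 mc_samples = mc_samples, subnet_cutoff = subnet_cutoff,
                 max_size = max_size, kappa_threshold = kappa_threshold,
                 size_threshold = size_threshold, alpha = alpha,
                 method = method, rng_seed = as.integer(rng_seed)),
            class = "pathnet_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pathnet_config()];
#' `datasets` is a mapping of label to path.
#'
#' @param path Path to a YAML file.
#' @return A `pathnet_config`.
#' @export
read_pathnet_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$datasets <- unlist(y$datasets)
  do.call(pathnet_config, y)
}

stage_seed <- function(config, stage_index) {
  (config$rng_seed * 101L + stage_index * 7919L) %% 2147483647L
}

#' Run the full pathway-network analysis
#'
#' Executes, per dataset: SNP filtering, functional weighting, SNP-to-gene
#' mapping, gene scoring, Monte-Carlo-calibrated active-subnetwork search,
#' and per-module pathway enrichment. Across datasets it adds the
#' Fisher-combined gene table, the strict enrichment consensus, the kappa
#' pathway network with pathway subnetworks and MCODE clusters (computed
#' on the cross-dataset consensus significance, the per-pathway worst
#' dataset-level p), and pairwise NMI between dataset module sets. All
#' artifacts are written under `config$out_dir` together with a
#' `manifest.json` recording parameters, seeds and versions; a rerun with
#' the same config and seed reproduces every artifact byte for byte.
#'
#' @param config A `pathnet_config`.
#' @return An object of class `pathnet_run` (a list of all stage
#'   results; see the vignette for a tour).
#' @export
run_pathnet <- function(config) {
  stopifnot(inherits(config, "pathnet_config"))
  for (f in c(config$ppi, config$gmt, config$bed, config$datasets)) {
    if (!file.exists(f)) stopf("input file not found: %s", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (partial artifacts kept in %s)",
            stage, conditionMessage(e), config$out_dir))
  }

  network <- run_stage("read_ppi", read_ppi(config$ppi))
  genes <- run_stage("read_gene_models",
                     read_gene_models(config$bed, window = config$gene_window))
  collection <- run_stage("read_gmt", read_gmt(config$gmt))

  # per-dataset gene scores
  tables <- list()
  for (label in names(config$datasets)) {
    tables[[label]] <- run_stage(paste0("gene_scores:", label), {
      rec <- read_summary_stats(config$datasets[[label]], config$column_spec)
      rec <- filter_by_pvalue(rec, config$p_cutoff)
      rec <- apply_functional_weighting(rec)
      snp_map <- map_snps_to_genes(rec, genes)
      tab <- gene_score_table(snp_map, kind = config$statistic,
                              dataset_label = label)
      write_gene_scores(tab, out(paste0("gene_scores_", label, ".tsv")))
      tab
    })
  }
  if (config$include_combined && length(tables) >= 2) {
    tables$combined <- run_stage("combine", {
      tab <- combine_gene_scores(tables)
      write_gene_scores(tab, out("gene_scores_combined.tsv"))
      tab
    })
  }

  # active subnetworks + per-module enrichment, per dataset
  subnets <- list(); enrich <- list(); aggregated <- list()
  for (i in seq_along(tables)) {
    label <- names(tables)[i]
    subnets[[label]] <- run_stage(paste0("subnetworks:", label), {
      tab <- tables[[label]]
      z <- p_to_z(setNames(tab$p_gene, tab$gene_id))
      kmax <- min(config$max_size, length(z))
      calib <- calibrate_subnetwork_scores(z, sizes = seq_len(kmax),
                                           n_samples = config$mc_samples,
                                           seed = stage_seed(config, i))
      sn <- active_subnetworks(network, z, calib,
                               score_cutoff = config$subnet_cutoff,
                               max_size = config$max_size)
      write_subnetworks(sn, out(paste0("subnetworks_", label, ".tsv")))
      sn
    })
    enrich[[label]] <- run_stage(paste0("enrichment:", label), {
      lapply(subnets[[label]]$members, enrich_module,
             collection = collection, alpha = config$alpha,
             method = config$method)
    })
    aggregated[[label]] <- run_stage(paste0("aggregate:", label), {
      agg <- aggregate_enrichment(enrich[[label]], alpha = config$alpha)
      write.table(agg, out(paste0("pathways_", label, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      agg
    })
  }

  base_labels <- names(config$datasets)
  consensus <- run_stage("consensus", {
    cons <- consensus_pathways(aggregated[base_labels])
    write.table(cons, out("consensus_pathways.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cons
  })

  pnet <- run_stage("pathway_network", {
    pn <- build_pathway_network(collection, threshold = config$kappa_threshold)
    write_pathway_network(pn, out("pathway_network.tsv"))
    pn
  })

  # cross-dataset consensus significance: a pathway is only as significant
  # as its worst dataset-level showing
  consensus_sig <- run_stage("consensus_significance", {
    ids <- names(collection$sets)
    sig <- rep(0, length(ids)); names(sig) <- ids
    for (label in base_labels) {
      agg <- aggregated[[label]]
      p <- setNames(agg$p_adj, agg$pathway_id)[ids]
      p[is.na(p)] <- 1
      sig <- pmax(sig, p)
    }
    sig
  })

  pw_subnets <- run_stage("pathway_subnetworks", {
    sn <- pathway_subnetworks(pnet, consensus_sig,
                              cutoff = config$subnet_cutoff,
                              max_size = config$max_size,
                              mc_samples = config$mc_samples,
                              seed = stage_seed(config, 97L))
    write_subnetworks(sn, out("pathway_subnetworks.tsv"))
    sn
  })

  clusters <- run_stage("pathway_clusters", {
    cl <- cluster_pathway_subnetworks(pw_subnets, pnet,
                                      size_threshold = config$size_threshold)
    write_clusters(cl, out("pathway_clusters.tsv"))
    cl
  })

  nmi_subnetworks <- run_stage("nmi", {
    module_sets <- lapply(subnets[base_labels], function(sn) sn$members)
    usable <- vapply(module_sets, length, integer(1)) > 0
    if (sum(usable) >= 2) {
      m <- pairwise_nmi(module_sets[usable])
      write.table(data.frame(dataset = rownames(m), m, check.names = FALSE),
                  out("nmi_subnetworks.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      m
    } else NULL
  })

  nmi_pathways <- run_stage("nmi_pathways", {
    pw_sets <- lapply(base_labels, function(label) {
      agg <- aggregated[[label]]
      ids <- agg$pathway_id[agg$significant]
      collection$sets[ids]
    })
    names(pw_sets) <- base_labels
    usable <- vapply(pw_sets, length, integer(1)) > 0
    if (sum(usable) >= 2) {
      m <- pairwise_nmi(pw_sets[usable])
      write.table(data.frame(dataset = rownames(m), m, check.names = FALSE),
                  out("nmi_pathways.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      m
    } else NULL
  })

  manifest <- list(
    package = "pathnetgwas",
    version = as.character(utils::packageVersion("pathnetgwas")),
    parameters = list(
      p_cutoff = config$p_cutoff, p_filter_strict = TRUE,
      gene_window = config$gene_window, statistic = config$statistic,
      mc_samples = config$mc_samples, subnet_cutoff = config$subnet_cutoff,
      max_size = config$max_size, kappa_threshold = config$kappa_threshold,
      size_threshold = config$size_threshold, alpha = config$alpha,
      method = config$method),
    rng_seed = config$rng_seed,
    datasets = as.list(config$datasets),
    inputs = list(ppi = config$ppi, gmt = config$gmt, bed = config$bed)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(config = config, manifest = manifest,
                 gene_scores = tables, subnetworks = subnets,
                 enrichment = enrich, pathways = aggregated,
                 consensus = consensus, pathway_network = pnet,
                 consensus_significance = consensus_sig,
                 pathway_subnetworks = pw_subnets,
                 pathway_clusters = clusters,
                 nmi_subnetworks = nmi_subnetworks,
                 nmi_pathways = nmi_pathways),
            class = "pathnet_run")
}

#' @export
print.pathnet_run <- function(x, ...) {
  cat("pathnet_run over", length(x$gene_scores), "dataset(s)\n")
  for (label in names(x$gene_scores)) {
    cat("  ", label, ": ", nrow(x$gene_scores[[label]]), " genes, ",
        nrow(x$subnetworks[[label]]), " subnetworks, ",
        sum(x$pathways[[label]]$significant), " significant pathways\n",
        sep = "")
  }
  cat("consensus pathways:", nrow(x$consensus), "\n")
  cat("pathway network:", igraph::vcount(x$pathway_network$graph), "nodes,",
      igraph::ecount(x$pathway_network$graph), "edges\n")
  cat("pathway clusters:", length(x$pathway_clusters), "\n")
  invisible(x)
}

#' Summarise a pathway-network run
#'
#' Prints per-dataset counts, the NMI matrix and the top pathway cluster.
#'
#' @param object A `pathnet_run`.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method summary pathnet_run
#' @export
summary.pathnet_run <- function(object, ...) {
  cat("== pathnet_run summary ==\n")
  print(object)
  if (!is.null(object$nmi_subnetworks)) {
    cat("\nNMI between dataset subnetwork sets:\n")
    print(round(object$nmi_subnetworks, 3))
  }
  if (length(object$pathway_clusters) > 0) {
    top <- object$pathway_clusters[[1]]
    cat("\ntop pathway cluster (score ", signif(top$mcode_score, 4), "): ",
        paste(top$pathway_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}
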