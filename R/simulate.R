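#' Specification for a synthetic fixture
#'
#' Defines the study conditions the generator emulates: a scale-free
#' protein-interaction graph, a planted disease module of low-p genes
#' that is also more densely wired internally than chance (the premise
#' topological module detection relies on), a pathway collection with one
#' designated disease pathway plus partner pathways sharing its genes,
#' and a trio of GWAS-style summary-statistic datasets carrying the same
#' planted truth with independent noise.
#'
#' @param rng_seed Integer seed; every derived artifact is reproducible
#'   from it.
#' @param n_genes Number of genes / network nodes (default 500).
#' @param ppi_mean_degree Target mean degree of the interaction graph
#'   (default 10; preferential attachment with `m = mean degree / 2`).
#' @param n_pathways Number of pathways in the collection (default 60).
#' @param pathway_size_range Min/max pathway size (default 10-40).
#' @param overlap_rate Fraction of a background pathway's genes copied
#'   from a previously drawn pathway, controlling kappa-network density
#'   among background pathways (default 0.05).
#' @param planted_module_size Size of the planted module (default 25).
#' @param planted_p_max Upper bound of planted genes' p-values
#'   (default 1e-6).
#' @param planted_density Target edge density inside the planted module
#'   (default 0.4); extra in-module edges are added to reach it.
#' @param snps_per_gene_range Min/max SNPs simulated per gene
#'   (default 3-8).
#' @param n_datasets Number of summary-statistic datasets (default 3).
#' @param n_partner_pathways Pathways sharing a sizeable fraction of the
#'   planted genes (default 6); together with the disease pathway they
#'   form the planted pathway cluster.
#' @param fs_rate Fraction of SNPs given a functional score (default
#'   0.05).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L, n_genes = 500, ppi_mean_degree = 10,
                         n_pathways = 60, pathway_size_range = c(10, 40),
                         overlap_rate = 0.05, planted_module_size = 25,
                         planted_p_max = 1e-6, planted_density = 0.4,
                         snps_per_gene_range = c(3, 8), n_datasets = 3,
                         n_partner_pathways = 6, fs_rate = 0.05) {
  if (n_genes < 10) stopf("n_genes must be >= 10")
  if (planted_module_size > n_genes) stopf("planted module larger than gene set")
  if (overlap_rate < 0 || overlap_rate >= 1) stopf("overlap_rate must be in [0, 1)")
  structure(list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
                 ppi_mean_degree = ppi_mean_degree,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 overlap_rate = overlap_rate,
                 planted_module_size = as.integer(planted_module_size),
                 planted_p_max = planted_p_max,
                 planted_density = planted_density,
                 snps_per_gene_range = as.integer(snps_per_gene_range),
                 n_datasets = as.integer(n_datasets),
                 n_partner_pathways = as.integer(n_partner_pathways),
                 fs_rate = fs_rate),
            class = "fixture_spec")
}

fixture_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a scale-free interaction network
#'
#' Preferential attachment (Barabasi-Albert) with `m` edges per arriving
#' node, giving the heavy-tailed degree distribution characteristic of
#' protein-interaction networks; the graph is connected by construction.
#'
#' @param spec A `fixture_spec`. The RNG seed is taken from the spec.
#' @return An undirected simple [igraph::igraph] graph with gene-id node
#'   names.
#' @export
simulate_ppi <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  m <- max(1L, round(spec$ppi_mean_degree / 2))
  g <- igraph::sample_pa(spec$n_genes, m = m, directed = FALSE)
  igraph::V(g)$name <- fixture_gene_ids(spec$n_genes)
  igraph::simplify(g)
}

#' Plant a disease module in the network
#'
#' Selects a connected subgraph of the requested size by breadth-first
#' search from a random root, densifies it with random in-module edges up
#' to the spec's `planted_density`, and assigns gene p-values: planted
#' genes uniform on `(0, planted_p_max)`, background genes uniform on
#' `(0, 1)`.
#'
#' @param graph Network from [simulate_ppi()].
#' @param spec A `fixture_spec` (seeding: `rng_seed + 1`).
#' @return List with `graph` (the densified network), `pvalues` (named
#'   per-gene p-values) and `truth` (list with `planted_gene_ids` and
#'   `seed_subset`, a random third of the planted genes for propagation
#'   experiments).
#' @export
plant_module <- function(graph, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed + 1L)
  vn <- igraph::V(graph)$name
  n <- length(vn)
  size <- spec$planted_module_size
  root <- sample(n, 1)
  ord <- as.integer(igraph::bfs(graph, root, order = TRUE)$order)
  ord <- ord[!is.na(ord)]
  if (length(ord) < size)
    stopf("connected component (%d) smaller than requested module (%d)",
          length(ord), size)
  mod <- sort(ord[seq_len(size)])
  target_edges <- ceiling(spec$planted_density * choose(size, 2))
  current <- igraph::ecount(igraph::induced_subgraph(graph, mod))
  guard <- 0L
  while (current < target_edges && guard < 100000L) {
    pair <- sample(mod, 2)
    if (!igraph::are_adjacent(graph, pair[1], pair[2])) {
      graph <- igraph::add_edges(graph, pair)
      current <- current + 1L
    }
    guard <- guard + 1L
  }
  p <- runif(n)
  p[mod] <- runif(size, 0, spec$planted_p_max)
  names(p) <- vn
  planted <- vn[mod]
  truth <- list(planted_gene_ids = planted,
                seed_subset = sort(sample(planted, max(1L, round(size / 3)))))
  list(graph = graph, pvalues = p, truth = truth)
}

#' Simulate a pathway collection with a planted disease pathway
#'
#' One designated disease pathway holds 90% of the planted genes (plus a
#' little background padding); partner pathways each carry 40% of the
#' planted genes, so they both enrich for the planted signal and link to
#' the disease pathway in the kappa network. Remaining background
#' pathways draw genes uniformly, sharing an `overlap_rate` fraction with
#' a previously drawn background pathway.
#'
#' @param spec A `fixture_spec` (seeding: `rng_seed + 2`).
#' @param truth Truth list from [plant_module()]; gains
#'   `planted_pathway_ids` and `disease_pathway` on return (via
#'   attribute, see Value).
#' @return A list with `collection` (a `gene_set_collection`) and
#'   `truth` (the input truth extended with `disease_pathway` and
#'   `planted_pathway_ids`).
#' @export
simulate_pathways <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed + 2L)
  genes <- fixture_gene_ids(spec$n_genes)
  planted <- truth$planted_gene_ids
  background <- setdiff(genes, planted)
  rng_size <- function() sample_from(seq(spec$pathway_size_range[1],
                                         spec$pathway_size_range[2]))
  sets <- list()
  ids <- sprintf("pw%03d", seq_len(spec$n_pathways))
  disease_id <- ids[1]
  core <- sample(planted, ceiling(0.9 * length(planted)))
  sets[[disease_id]] <- sort(c(core, sample(background, max(2, round(0.1 * length(core))))))
  n_partner <- min(spec$n_partner_pathways, spec$n_pathways - 1L)
  partner_ids <- ids[seq_len(n_partner) + 1L]
  for (id in partner_ids) {
    share <- sample(planted, max(1L, round(0.4 * length(planted))))
    size <- max(rng_size(), length(share) + 2L)
    sets[[id]] <- sort(c(share, sample(background, size - length(share))))
  }
  bg_ids <- setdiff(ids, c(disease_id, partner_ids))
  for (i in seq_along(bg_ids)) {
    size <- rng_size()
    n_shared <- if (i > 1) round(spec$overlap_rate * size) else 0L
    shared <- if (n_shared > 0) {
      donor <- sets[[bg_ids[sample(i - 1L, 1)]]]
      sample(donor, min(n_shared, length(donor)))
    } else character(0)
    fresh <- sample(setdiff(genes, shared), size - length(shared))
    sets[[bg_ids[i]]] <- sort(unique(c(shared, fresh)))
  }
  truth$disease_pathway <- disease_id
  truth$planted_pathway_ids <- c(disease_id, partner_ids)
  list(collection = gene_set_collection(sets), truth = truth)
}

#' Gene models laid out for the fixture
#'
#' Genes are spaced 200 kb apart (20 kb bodies) across 22 chromosome
#' labels so that the default 50 kb mapping windows of neighbouring genes
#' never overlap and the planted truth stays crisp at the SNP level.
#'
#' @param spec A `fixture_spec`.
#' @param window Mapping window recorded in the models (default 50 kb).
#' @return Gene model data frame as from [read_gene_models()].
#' @export
fixture_gene_models <- function(spec, window = 50000) {
  genes <- fixture_gene_ids(spec$n_genes)
  idx <- seq_along(genes) - 1L
  chrom <- as.character(idx %% 22L + 1L)
  slot <- idx %/% 22L
  start <- slot * 200000L + 100000L
  data.frame(gene_id = genes, chrom = chrom, start = start,
             end = start + 20000L, window = as.integer(window),
             stringsAsFactors = FALSE)
}

#' Simulate GWAS summary-statistic datasets
#'
#' Each dataset draws, per gene, a target gene-level p-value (planted
#' genes uniform on `(0, planted_p_max)`, background uniform on
#' `(0, 1)`), places one best SNP at exactly that p-value and the
#' remaining SNPs uniformly above it, so the gene-level minimum-p equals
#' the target. A random `fs_rate` fraction of SNPs receives a functional
#' score uniform on `[0, 1]`.
#'
#' @param spec A `fixture_spec` (seeding: `rng_seed + 3 + dataset index`).
#' @param truth Truth list from [plant_module()].
#' @param gene_models Gene models from [fixture_gene_models()].
#' @return Named list of SNP record data frames (labels `sim1`,
#'   `sim2`, ...), each in the layout of [read_summary_stats()].
#' @export
simulate_summary_stats <- function(spec, truth, gene_models) {
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- truth$planted_gene_ids
  out <- list()
  for (d in seq_len(spec$n_datasets)) {
    set.seed(spec$rng_seed + 3L + d)
    rows <- vector("list", nrow(gene_models))
    rs_counter <- 0L
    for (i in seq_len(nrow(gene_models))) {
      gm <- gene_models[i, ]
      n_snps <- sample_from(seq(spec$snps_per_gene_range[1],
                                spec$snps_per_gene_range[2]))
      target <- if (gm$gene_id %in% planted)
        runif(1, 0, spec$planted_p_max) else runif(1)
      p <- c(target, if (n_snps > 1) runif(n_snps - 1, target, 1))
      pos <- sort(sample(seq(gm$start + 1L, gm$end), n_snps))
      alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * n_snps, replace = TRUE),
                        ncol = 2)
      same <- alleles[, 1] == alleles[, 2]
      alleles[same, 2] <- vapply(alleles[same, 1], function(a)
        sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
      fs <- rep(NA_real_, n_snps)
      scored <- runif(n_snps) < spec$fs_rate
      fs[scored] <- runif(sum(scored))
      rows[[i]] <- data.frame(
        chrom = gm$chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        p_gwas = p,
        rsid = sprintf("rs%d_%d", d, rs_counter + seq_len(n_snps)),
        fs = fs, p_w = p,
        stringsAsFactors = FALSE)
      rs_counter <- rs_counter + n_snps
    }
    out[[sprintf("sim%d", d)]] <- do.call(rbind, rows)
  }
  out
}

#' Generate a complete synthetic fixture
#'
#' Orchestrates [simulate_ppi()], [plant_module()],
#' [simulate_pathways()], [fixture_gene_models()] and
#' [simulate_summary_stats()] into one reproducible bundle.
#'
#' @param spec A `fixture_spec`.
#' @return List with `spec`, `graph`, `pvalues`, `truth`, `collection`,
#'   `gene_models` and `datasets`.
#' @export
simulate_fixture <- function(spec = fixture_spec()) {
  g <- simulate_ppi(spec)
  pm <- plant_module(g, spec)
  pw <- simulate_pathways(spec, pm$truth)
  gm <- fixture_gene_models(spec)
  ds <- simulate_summary_stats(spec, pw$truth, gm)
  list(spec = spec, graph = pm$graph, pvalues = pm$pvalues,
       truth = pw$truth, collection = pw$collection,
       gene_models = gm, datasets = ds)
}

#' Write a fixture to disk
#'
#' Emits `ppi.tsv` (edge list), `genes.bed` (BED4), one
#' `dataset<i>.tsv` per summary-statistic dataset, `pathways.gmt` and
#' `truth.json`. All files are plain text and byte-reproducible from the
#' spec's seed.
#'
#' @param fixture Fixture bundle from [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  el <- igraph::as_edgelist(fixture$graph)
  p <- file.path(dir, "ppi.tsv")
  write.table(data.frame(a = el[, 1], b = el[, 2]), p, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths["ppi"] <- p
  p <- file.path(dir, "genes.bed")
  gm <- fixture$gene_models
  write.table(gm[, c("chrom", "start", "end", "gene_id")], p, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths["bed"] <- p
  for (label in names(fixture$datasets)) {
    p <- file.path(dir, paste0("dataset_", label, ".tsv"))
    tab <- fixture$datasets[[label]]
    tab <- tab[, c("chrom", "pos", "effect_allele", "other_allele",
                   "p_gwas", "rsid", "fs")]
    names(tab)[5] <- "p"
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[label] <- p
  }
  p <- file.path(dir, "pathways.gmt")
  write_gmt(fixture$collection, p)
  paths["gmt"] <- p
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(fixture$truth, p, auto_unbox = FALSE, pretty = TRUE)
  paths["truth"] <- p
  invisible(paths)
}
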