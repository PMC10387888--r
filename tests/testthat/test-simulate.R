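test_that("fixture generation is bit-reproducible from its seed", {
  spec <- small_fixture_spec(71)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  write_fixture(simulate_fixture(spec), d1)
  write_fixture(simulate_fixture(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "fixC")
  write_fixture(simulate_fixture(small_fixture_spec(72)), d3)
  expect_false(identical(readLines(file.path(d1, "ppi.tsv")),
                         readLines(file.path(d3, "ppi.tsv"))))
})

test_that("simulated interactome is connected with the requested edge budget", {
  spec <- fixture_spec(rng_seed = 3, n_genes = 100, ppi_mean_degree = 10)
  g <- simulate_ppi(spec)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::components(g)$no, 1)
  # m = 5 edges per arriving node: ~500 minus the warm-up deficit
  expect_gt(igraph::ecount(g), 440)
  expect_lt(igraph::ecount(g), 510)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
})

test_that("planted module is connected, dense and carries the p-value signal", {
  spec <- small_fixture_spec(73)
  pm <- plant_module(simulate_ppi(spec), spec)
  truth <- pm$truth$planted_gene_ids
  expect_length(truth, spec$planted_module_size)
  sub <- igraph::induced_subgraph(pm$graph, truth)
  expect_equal(igraph::components(sub)$no, 1)
  dens <- igraph::ecount(sub) / choose(spec$planted_module_size, 2)
  expect_gte(dens, spec$planted_density - 0.01)
  expect_true(all(pm$pvalues[truth] <= spec$planted_p_max))
  z <- p_to_z(pm$pvalues)
  expect_true(all(z[truth] >= p_to_z(spec$planted_p_max)))
  expect_true(all(pm$truth$seed_subset %in% truth))
  # the module is too large for a tiny component
  tiny <- igraph::make_ring(5)
  igraph::V(tiny)$name <- letters[1:5]
  expect_error(plant_module(tiny, spec), "smaller than")
})

test_that("disease pathway enriches at rank 1 for the planted genes", {
  spec <- small_fixture_spec(74)
  pm <- plant_module(simulate_ppi(spec), spec)
  sim <- simulate_pathways(spec, pm$truth)
  expect_s3_class(sim$collection, "gene_set_collection")
  disease <- sim$truth$disease_pathway
  core <- intersect(sim$collection$sets[[disease]], pm$truth$planted_gene_ids)
  expect_gte(length(core) / length(pm$truth$planted_gene_ids), 0.8)
  res <- enrich_module(pm$truth$planted_gene_ids, sim$collection)
  expect_equal(res$pathway_id[1], disease)
})

test_that("summary statistics carry the planted gene-level signal", {
  spec <- small_fixture_spec(75)
  pm <- plant_module(simulate_ppi(spec), spec)
  sim <- simulate_pathways(spec, pm$truth)
  gm <- fixture_gene_models(spec)
  ds <- simulate_summary_stats(spec, sim$truth, gm)
  expect_length(ds, spec$n_datasets)

  planted <- sim$truth$planted_gene_ids
  tables <- lapply(names(ds), function(label) {
    snp_map <- map_snps_to_genes(ds[[label]], gm)
    gene_score_table(snp_map, kind = "max_chi2", dataset_label = label)
  })
  for (tab in tables) {
    p <- setNames(tab$p_gene, tab$gene_id)
    expect_true(all(p[planted] <= spec$planted_p_max))
    expect_true(all(tab$n_snps >= spec$snps_per_gene_range[1]))
    expect_true(all(tab$n_snps <= spec$snps_per_gene_range[2]))
  }

  # Fisher combination sharpens the planted signal relative to any single dataset
  comb <- combine_gene_scores(tables)
  pc <- setNames(comb$p_gene, comb$gene_id)[planted]
  single_best <- do.call(pmin, lapply(tables, function(tab)
    setNames(tab$p_gene, tab$gene_id)[planted]))
  expect_lt(median(pc / single_best), 1)
})

test_that("fixture files round-trip through the package readers", {
  spec <- small_fixture_spec(76)
  fix <- simulate_fixture(spec)
  dir <- file.path(tempdir(), "fix_rt")
  paths <- write_fixture(fix, dir)

  g <- read_ppi(paths[["ppi"]])
  expect_equal(igraph::vcount(g), igraph::vcount(fix$graph))
  expect_equal(igraph::ecount(g), igraph::ecount(fix$graph))

  gm <- read_gene_models(paths[["bed"]], window = 50000)
  expect_equal(gm$gene_id, fix$gene_models$gene_id)
  expect_equal(gm$start, fix$gene_models$start)

  coll <- read_gmt(paths[["gmt"]])
  expect_equal(names(coll$sets), names(fix$collection$sets))
  expect_identical(coll$sets, fix$collection$sets)

  rec <- read_summary_stats(paths[["sim1"]],
                            column_spec = list(chrom = "chrom", pos = "pos",
                                               effect_allele = "effect_allele",
                                               other_allele = "other_allele",
                                               p = "p", rsid = "rsid", fs = "fs"))
  expect_equal(nrow(rec), nrow(fix$datasets$sim1))
  expect_equal(rec$p_gwas, fix$datasets$sim1$p_gwas)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$planted_gene_ids, fix$truth$planted_gene_ids)
})

test_that("GMT writer agrees with an independent GMT reader", {
  spec <- small_fixture_spec(77)
  fix <- simulate_fixture(spec)
  path <- file.path(tempdir(), "xcheck.gmt")
  write_gmt(fix$collection, path)
  ref <- fgsea::gmtPathways(path)
  expect_identical(ref[names(fix$collection$sets)], fix$collection$sets)
})
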