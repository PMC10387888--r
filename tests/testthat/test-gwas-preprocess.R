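test_that("summary statistics parse, drop bad rows and honour column maps", {
  df <- toy_snp_frame(c(0.01, 0.2, 0.9))
  rec <- read_summary_stats(write_snp_tsv(df),
                            column_spec = list(chrom = "chrom", pos = "pos",
                                               effect_allele = "effect_allele",
                                               other_allele = "other_allele",
                                               p = "p", rsid = "rsid", fs = "fs"))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$p_gwas, c(0.01, 0.2, 0.9))
  expect_equal(rec$p_w, rec$p_gwas)

  # renamed columns resolved through the spec
  df2 <- df
  names(df2)[names(df2) == "p"] <- "PVAL"
  names(df2)[names(df2) == "chrom"] <- "CHR"
  rec2 <- read_summary_stats(write_snp_tsv(df2),
                             column_spec = list(chrom = "CHR", pos = "pos",
                                                effect_allele = "effect_allele",
                                                other_allele = "other_allele",
                                                p = "PVAL"))
  expect_equal(rec2$p_gwas, rec$p_gwas)

  # unparsable p dropped and counted
  df$p <- as.character(df$p)
  df$p[2] <- "NA"
  expect_message(
    rec3 <- read_summary_stats(write_snp_tsv(df),
                               column_spec = list(chrom = "chrom", pos = "pos",
                                                  effect_allele = "effect_allele",
                                                  other_allele = "other_allele",
                                                  p = "p")),
    "1 row")
  expect_equal(nrow(rec3), 2)

  # header-only file -> empty with warning; missing column -> error
  hdr <- write_snp_tsv(toy_snp_frame(numeric(0)))
  expect_warning(empty <- read_summary_stats(hdr,
    column_spec = list(chrom = "chrom", pos = "pos",
                       effect_allele = "effect_allele",
                       other_allele = "other_allele", p = "p")), "no data rows")
  expect_equal(nrow(empty), 0)
  expect_error(read_summary_stats(write_snp_tsv(toy_snp_frame(0.5)),
    column_spec = list(chrom = "chrom", pos = "pos",
                       effect_allele = "effect_allele",
                       other_allele = "other_allele", p = "missing_col")),
    "missing_col")
})

test_that("p-value filter is strict and monotone in the cutoff", {
  rec <- toy_records(c(0.01, 0.05, 0.9))
  kept <- filter_by_pvalue(rec, 0.05)
  expect_equal(kept$p_gwas, 0.01)          # 0.05 itself is excluded
  expect_equal(nrow(filter_by_pvalue(rec, 1)), 3)
  expect_equal(nrow(filter_by_pvalue(rec[0, ], 0.05)), 0)
  expect_error(filter_by_pvalue(rec, 0), "cutoff")

  set.seed(1)
  rec <- toy_records(runif(200))
  sizes <- vapply(c(1, 0.5, 0.2, 0.05, 0.01),
                  function(cut) nrow(filter_by_pvalue(rec, cut)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("functional weighting divides by 10^fs and validates scores", {
  rec <- toy_records(c(0.04, 0.04, 0.05), fs = c(0, 1, 0.5))
  w <- apply_functional_weighting(rec)
  expect_equal(w$p_w[1], 0.04)
  expect_equal(w$p_w[2], 0.004)
  # log-space oracle: log p_w = log p - fs * log 10
  expect_equal(w$p_w[3], exp(log(0.05) - 0.5 * log(10)), tolerance = 1e-12)
  expect_equal(w$p_w[3], 0.0158, tolerance = 1e-3)

  # missing fs means no weighting; fs out of range is rejected by name
  w2 <- apply_functional_weighting(toy_records(0.3))
  expect_equal(w2$p_w, 0.3)
  expect_error(apply_functional_weighting(toy_records(0.3, fs = 1.5)), "fs = 1.5")

  # fs can also come from an rsid-keyed source
  rec3 <- toy_records(c(0.1, 0.1))
  w3 <- apply_functional_weighting(rec3, fs_source = c(rs2 = 1))
  expect_equal(w3$p_w, c(0.1, 0.01))

  # invariant: p_w <= p_gwas, equality iff fs == 0
  set.seed(2)
  rec4 <- apply_functional_weighting(
    toy_records(runif(100), fs = ifelse(runif(100) < 0.5, NA, runif(100))))
  expect_true(all(rec4$p_w <= rec4$p_gwas))
  fs0 <- is.na(rec4$fs) | rec4$fs == 0
  expect_equal(rec4$p_w == rec4$p_gwas, fs0)
})

test_that("SNP-to-gene mapping honours half-open windows and chr prefixes", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("1", "1"),
                      start = c(100L, 150L), end = c(200L, 260L),
                      window = 0L, stringsAsFactors = FALSE)
  # BED [100, 200) with 1-based SNP positions: 101 is the first inside base
  rec <- toy_records(c(0.1, 0.2, 0.3, 0.4), pos = c(101L, 100L, 160L, 5000L),
                     chrom = "chr1")
  expect_message(m <- map_snps_to_genes(rec, genes), "2 SNP")
  expect_equal(sort(names(m)), c("gA", "gB"))
  expect_true(0.1 %in% m$gA)
  expect_false(0.2 %in% m$gA)          # pos 100 = 0-based 99, outside [100, 200)
  expect_true(0.3 %in% m$gA && 0.3 %in% m$gB)   # overlapping genes share the SNP

  # windows extend the interval
  genes$window <- 50L
  m2 <- map_snps_to_genes(toy_records(0.7, pos = 60L, chrom = "1"), genes)
  expect_equal(m2$gA, 0.7)

  # weighted p-values are what get aggregated
  rec_w <- apply_functional_weighting(toy_records(0.1, pos = 101L, fs = 1))
  m3 <- map_snps_to_genes(rec_w, genes)
  expect_equal(m3$gA, 0.01)
})

test_that("gene scores: max_chi2 is min-p, sum_chi2 matches the closed form", {
  expect_equal(gene_score(c(0.2, 0.01), "max_chi2"), 0.01)
  expect_equal(gene_score(0.37, "max_chi2"), 0.37)
  expect_equal(gene_score(0.37, "sum_chi2"), 0.37, tolerance = 1e-12)
  expect_error(gene_score(numeric(0)), "no SNP")

  # 2-df chi-squared survival has closed form exp(-x/2)
  x <- sum(qchisq(c(0.5, 0.5), df = 1, lower.tail = FALSE))
  expect_equal(gene_score(c(0.5, 0.5), "sum_chi2"), exp(-x / 2), tolerance = 1e-12)
  expect_equal(gene_score(c(0.5, 0.5), "sum_chi2"), 0.634, tolerance = 1e-3)

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_identical(gene_score(p, "max_chi2"), min(p))
  }
})

test_that("sum_chi2 gene p-values are uniform under the null", {
  set.seed(4)
  p_gene <- replicate(10000, gene_score(runif(sample(1:6, 1)), "sum_chi2"))
  ks <- suppressWarnings(stats::ks.test(p_gene, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher combination matches the chi-squared tail and is monotone", {
  expect_equal(fisher_combine(0.42)$p_combined, 0.42, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1))$p_combined, 1)

  # 4-df survival closed form: exp(-x/2) * (1 + x/2)
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$chi2_stat, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(res$df, 4L)
  x <- res$chi2_stat
  expect_equal(res$p_combined, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(res$p_combined, 0.0174, tolerance = 5e-3)

  expect_error(fisher_combine(c(0.5, 0)), "in \\(0, 1]")

  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:5, 1))
    expect_equal(fisher_combine(sample(p))$p_combined,
                 fisher_combine(p)$p_combined)
    p2 <- p
    p2[1] <- p2[1] / 2
    expect_lte(fisher_combine(p2)$p_combined, fisher_combine(p)$p_combined)
  }
})

test_that("cross-dataset combination keeps only shared genes", {
  t1 <- gene_score_table(c(gA = 0.01, gB = 0.2, gC = 0.5), dataset_label = "d1")
  t2 <- gene_score_table(c(gA = 0.02, gB = 0.3), dataset_label = "d2")
  comb <- combine_gene_scores(list(t1, t2))
  expect_equal(comb$gene_id, c("gA", "gB"))
  expect_equal(comb$p_gene[1], fisher_combine(c(0.01, 0.02))$p_combined)
  expect_true(all(comb$statistic_kind == "fisher_combined"))
  expect_warning(combine_gene_scores(list(t1, gene_score_table(c(gZ = 0.1)))),
                 "no genes shared")
})
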