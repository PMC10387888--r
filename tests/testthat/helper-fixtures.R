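# Shared builders for small in-code fixtures.

write_snp_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_snp_frame <- function(p, chrom = "1", pos = seq_along(p) * 1000L,
                          rsid = sprintf("rs%d", seq_along(p)), fs = NA_real_) {
  n <- length(p)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             effect_allele = rep_len("A", n), other_allele = rep_len("G", n),
             p = p, rsid = rsid, fs = rep_len(fs, n), stringsAsFactors = FALSE)
}

# records straight from a data frame, bypassing file IO
toy_records <- function(p, fs = NA_real_, chrom = "1",
                        pos = seq_along(p) * 1000L) {
  n <- length(p)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             effect_allele = rep_len("A", n), other_allele = rep_len("G", n),
             p_gwas = p, rsid = sprintf("rs%d", seq_len(n)), fs = rep_len(fs, n),
             p_w = p, stringsAsFactors = FALSE)
}

named_graph <- function(edges, isolates = character()) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolates) > 0) g <- igraph::add_vertices(g, length(isolates),
                                                      name = isolates)
  igraph::simplify(g)
}

clique_graph <- function(ids) {
  pairs <- t(utils::combn(ids, 2))
  named_graph(as.vector(t(pairs)))
}

# calibration object with known mu/sigma, for exact score checks
manual_calibration <- function(mu, sigma) {
  structure(list(mu = mu, sigma = sigma, sizes = seq_along(mu),
                 n_samples = NA_integer_, seed = NULL),
            class = "subnet_calibration")
}

toy_collection <- function() {
  gene_set_collection(list(
    pwA = c("g1", "g2", "g3", "g4"),
    pwB = c("g3", "g4", "g5", "g6"),
    pwC = c("g7", "g8", "g9")
  ))
}

small_fixture_spec <- function(seed = 5L) {
  fixture_spec(rng_seed = seed, n_genes = 120, ppi_mean_degree = 8,
               n_pathways = 20, pathway_size_range = c(6, 15),
               planted_module_size = 12, n_partner_pathways = 4)
}
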