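#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file into a SNP record table.
#' Column names in the file are mapped to the canonical fields via
#' `column_spec`, so files from different consortia can be ingested without
#' renaming. Rows whose p-value cannot be parsed or falls outside `(0, 1]`
#' are dropped; the number of dropped rows is reported via [message()].
#'
#' @param path Path to a TSV file with a header row.
#' @param column_spec Named list mapping canonical field names (`chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `p`, and optionally `rsid`,
#'   `fs`) to the column names used in the file.
#' @return A data frame of SNP records with columns `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `p_gwas`, `rsid`, `fs` and `p_w`.
#'   Before [apply_functional_weighting()] is called, `p_w` equals `p_gwas`.
#' @seealso [filter_by_pvalue()], [apply_functional_weighting()],
#'   [map_snps_to_genes()]
#' @export
read_summary_stats <- function(path,
                               column_spec = list(chrom = "chrom", pos = "pos",
                                                  effect_allele = "effect_allele",
                                                  other_allele = "other_allele",
                                                  p = "p")) {
  if (!file.exists(path)) stopf("summary statistics file not found: %s", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "effect_allele", "other_allele", "p")
  for (field in required) {
    col <- column_spec[[field]]
    if (is.null(col)) stopf("column_spec is missing an entry for '%s'", field)
    if (nrow(raw) > 0 || ncol(raw) > 0) {
      if (!col %in% names(raw)) {
        stopf("required column '%s' (field '%s') not present in %s",
              col, field, path)
      }
    }
  }
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(empty_snp_records())
  }
  p <- suppressWarnings(as.numeric(raw[[column_spec$p]]))
  keep <- !is.na(p) & p > 0 & p <= 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped (unparsable or out-of-range p) from ",
            basename(path))
  }
  rsid_col <- column_spec$rsid
  fs_col <- column_spec$fs
  rec <- data.frame(
    chrom = as.character(raw[[column_spec$chrom]])[keep],
    pos = as.integer(raw[[column_spec$pos]])[keep],
    effect_allele = as.character(raw[[column_spec$effect_allele]])[keep],
    other_allele = as.character(raw[[column_spec$other_allele]])[keep],
    p_gwas = p[keep],
    rsid = if (!is.null(rsid_col) && rsid_col %in% names(raw))
      as.character(raw[[rsid_col]])[keep] else NA_character_,
    fs = if (!is.null(fs_col) && fs_col %in% names(raw))
      suppressWarnings(as.numeric(raw[[fs_col]]))[keep] else NA_real_,
    stringsAsFactors = FALSE
  )
  rec$p_w <- rec$p_gwas
  rec
}

empty_snp_records <- function() {
  data.frame(chrom = character(), pos = integer(),
             effect_allele = character(), other_allele = character(),
             p_gwas = numeric(), rsid = character(), fs = numeric(),
             p_w = numeric(), stringsAsFactors = FALSE)
}

#' Read gene models from a BED4 file
#'
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' The `window` is a flanking distance (in bases) added to each side when
#' SNPs are assigned to genes.
#'
#' @param path Path to a BED4 file (chrom, start, end, gene_id), no header.
#' @param window Flanking distance in bases (default 50 kb each side).
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `window`.
#' @export
read_gene_models <- function(path, window = 50000) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  if (window < 0) stopf("window must be >= 0")
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stopf("expected BED4 (chrom, start, end, gene_id): %s", path)
  out <- data.frame(gene_id = as.character(bed[[4]]),
                    chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]),
                    window = as.integer(window),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stopf("degenerate gene interval (start >= end) in %s", path)
  out
}

#' Read a protein-protein interaction network
#'
#' Accepts a two-column TSV edge list or a SIF file (node, relation, node).
#' The result is simplified: self-loops and duplicate edges are removed.
#'
#' @param path Path to the edge list.
#' @param format `"auto"` (default), `"tsv"` or `"sif"`. With `"auto"`,
#'   three-column files are treated as SIF.
#' @return An undirected simple [igraph::igraph] graph with node names.
#' @export
read_ppi <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("network file not found: %s", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (format == "auto") format <- if (ncol(tab) >= 3) "sif" else "tsv"
  edges <- if (format == "sif") tab[, c(1, 3)] else tab[, c(1, 2)]
  g <- igraph::graph_from_edgelist(as.matrix(apply(edges, 2, as.character)),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated: set id, description, then member genes. Duplicate
#' member genes within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection` (see [gene_set_collection()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields in %s", path)
  ids <- vapply(fields, `[[`, character(1), 1)
  descriptions <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, descriptions = setNames(descriptions, ids))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (pathway id -> member genes).
#' @param descriptions Optional named character vector of display names.
#' @param universe Optional gene universe; defaults to the union of all
#'   member genes. Every set must be contained in the universe.
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `descriptions` and `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) == 0) stopf("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must have unique names")
  if (any(lengths(sets) == 0)) stopf("empty pathway in collection")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  missing <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(missing) > 0)
    stopf("%d pathway gene(s) outside the supplied universe", length(missing))
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets,",
      length(x$universe), "genes in universe\n")
  cat("set sizes:", paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write a gene score table to TSV
#'
#' @param table A `gene_score_table` (see [gene_score_table()]).
#' @param path Output path.
#' @export
write_gene_scores <- function(table, path) {
  write.table(as.data.frame(table)[, c("gene_id", "p_gene", "n_snps", "statistic_kind")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene score table written by [write_gene_scores()]
#'
#' Use this to supply precomputed per-gene p-values (for example from an
#' LD-aware scorer) to the downstream network stages.
#'
#' @param path Path to the TSV.
#' @param dataset_label Label to attach to the table.
#' @return A `gene_score_table`.
#' @export
read_gene_scores <- function(path, dataset_label = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "p_gene")
  if (!all(need %in% names(tab))) stopf("expected columns gene_id, p_gene in %s", path)
  gene_score_table(setNames(tab$p_gene, tab$gene_id),
                   n_snps = if ("n_snps" %in% names(tab)) setNames(tab$n_snps, tab$gene_id) else NULL,
                   statistic_kind = if ("statistic_kind" %in% names(tab))
                     tab$statistic_kind[1] else "provided",
                   dataset_label = dataset_label)
}
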