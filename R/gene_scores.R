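#' Filter SNP records by association p-value
#'
#' Keeps records with `p_gwas` strictly below the cutoff (a SNP at exactly
#' the cutoff is removed). Filtering on nominal significance retains the many
#' variants of mild effect whose collective behaviour the network stages
#' exploit.
#'
#' @param records SNP record data frame from [read_summary_stats()].
#' @param cutoff P-value cutoff in `(0, 1]`; default 0.05.
#' @return The filtered records, input order preserved.
#' @export
filter_by_pvalue <- function(records, cutoff = 0.05) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1)
    stopf("cutoff must be a single value in (0, 1]")
  records[records$p_gwas < cutoff, , drop = FALSE]
}

#' Apply functional weighting to SNP p-values
#'
#' Computes weighted p-values `p_w = p_gwas / 10^fs`, where `fs` is a
#' functional-impact score in `[0, 1]` (for example a VEST score). A SNP
#' with no functional score keeps its raw p-value (`fs` treated as 0), so
#' `p_w <= p_gwas` always holds.
#'
#' @param records SNP record data frame.
#' @param fs_source Optional named numeric vector mapping `rsid` to
#'   functional score. When `NULL`, the records' own `fs` column is used.
#' @return The records with `fs` resolved and `p_w` filled in.
#' @export
apply_functional_weighting <- function(records, fs_source = NULL) {
  fs <- records$fs
  if (!is.null(fs_source)) {
    hit <- !is.na(records$rsid) & records$rsid %in% names(fs_source)
    fs[hit] <- fs_source[records$rsid[hit]]
  }
  bad <- !is.na(fs) & (fs < 0 | fs > 1)
  if (any(bad)) {
    i <- which(bad)[1]
    stopf("functional score outside [0, 1] for record %d (%s:%d, fs = %g)",
          i, records$chrom[i], records$pos[i], fs[i])
  }
  records$fs <- fs
  fs0 <- ifelse(is.na(fs), 0, fs)
  records$p_w <- records$p_gwas / 10^fs0
  records
}

#' Assign SNPs to genes by physical distance
#'
#' A SNP is assigned to every gene whose window-extended interval contains
#' it; a SNP inside two overlapping gene windows contributes to both genes.
#' Gene intervals are 0-based half-open (BED); SNP positions are 1-based.
#' Chromosome labels are compared after stripping any `chr` prefix.
#'
#' @param records SNP record data frame (weighted p-values `p_w` are used
#'   when present, otherwise `p_gwas`).
#' @param genes Gene model data frame from [read_gene_models()].
#' @return Named list mapping `gene_id` to the numeric vector of assigned
#'   SNP p-values. Genes with no assigned SNP are omitted. The number of
#'   SNPs matching no gene is reported via [message()].
#' @export
map_snps_to_genes <- function(records, genes) {
  if (any(genes$start >= genes$end)) stopf("degenerate gene interval (start >= end)")
  if (nrow(records) == 0L) return(setNames(list(), character()))
  p <- if ("p_w" %in% names(records)) records$p_w else records$p_gwas
  snp_chr <- normalize_chrom(records$chrom)
  gene_chr <- normalize_chrom(genes$chrom)
  assigned <- rep(FALSE, nrow(records))
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (chr in unique(gene_chr)) {
    gi <- which(gene_chr == chr)
    si <- which(snp_chr == chr)
    if (length(si) == 0) next
    # BED [start, end) 0-based, +/- window -> 1-based closed [start-w+1, end+w]
    gr <- IRanges::IRanges(start = genes$start[gi] - genes$window[gi] + 1L,
                           end = genes$end[gi] + genes$window[gi])
    sr <- IRanges::IRanges(start = records$pos[si], width = 1L)
    hits <- IRanges::findOverlaps(sr, gr)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    assigned[si[q]] <- TRUE
    for (j in unique(s)) {
      gid <- gi[j]
      out[[gid]] <- c(out[[gid]], p[si[q[s == j]]])
    }
  }
  n_unassigned <- sum(!assigned)
  if (n_unassigned > 0) message(n_unassigned, " SNP(s) matched no gene window")
  out[!vapply(out, is.null, logical(1))]
}

#' Aggregate SNP p-values into a single gene-level p-value
#'
#' SNP p-values are transformed to 1-df chi-squared statistics via the
#' inverse chi-squared quantile. `max_chi2` takes the maximum statistic
#' (equivalently, the minimum SNP p-value) as the gene score; `sum_chi2`
#' sums the statistics and refers the sum to a chi-squared distribution
#' with one degree of freedom per SNP. Neither statistic corrects for LD
#' or gene size, which is recorded in the `statistic_kind` of the tables
#' built by [gene_score_table()].
#'
#' @param snp_pvalues Non-empty numeric vector of p-values in `(0, 1]`.
#' @param kind `"max_chi2"` or `"sum_chi2"`.
#' @return A single gene-level p-value.
#' @export
gene_score <- function(snp_pvalues, kind = c("max_chi2", "sum_chi2")) {
  kind <- match.arg(kind)
  if (length(snp_pvalues) == 0) stopf("no SNP p-values for gene")
  p <- clamp_pvalues(snp_pvalues)
  if (kind == "max_chi2") {
    # max of chi-squared transforms == min p (1-df quantile is decreasing in p)
    min(p)
  } else {
    stat <- sum(qchisq(p, df = 1, lower.tail = FALSE))
    pchisq(stat, df = length(p), lower.tail = FALSE)
  }
}

#' Build a per-gene score table for one dataset
#'
#' @param x Either a named list of SNP p-value vectors (as produced by
#'   [map_snps_to_genes()]) or a named numeric vector of precomputed gene
#'   p-values.
#' @param kind Gene statistic, `"max_chi2"` (default) or `"sum_chi2"`;
#'   ignored when `x` is already per-gene.
#' @param dataset_label Label identifying the dataset.
#' @param n_snps Optional named SNP counts when `x` is per-gene.
#' @param statistic_kind Statistic label when `x` is per-gene
#'   (default `"provided"`).
#' @return A `gene_score_table`: data frame with columns `gene_id`,
#'   `p_gene`, `n_snps`, `statistic_kind` and attribute `dataset_label`.
#' @export
gene_score_table <- function(x, kind = c("max_chi2", "sum_chi2"),
                             dataset_label = "dataset",
                             n_snps = NULL, statistic_kind = "provided") {
  kind <- match.arg(kind)
  if (is.list(x)) {
    if (length(x) == 0) {
      tab <- data.frame(gene_id = character(), p_gene = numeric(),
                        n_snps = integer(), statistic_kind = character(),
                        stringsAsFactors = FALSE)
    } else {
      tab <- data.frame(
        gene_id = names(x),
        p_gene = vapply(x, gene_score, numeric(1), kind = kind),
        n_snps = lengths(x),
        statistic_kind = kind,
        stringsAsFactors = FALSE
      )
    }
  } else {
    p <- clamp_pvalues(as.numeric(x), what = "gene p-value")
    tab <- data.frame(
      gene_id = names(x) %||% character(0),
      p_gene = p,
      n_snps = if (is.null(n_snps)) rep(NA_integer_, length(p))
               else as.integer(n_snps[names(x)]),
      statistic_kind = rep_len(statistic_kind, length(p)),
      stringsAsFactors = FALSE
    )
  }
  rownames(tab) <- NULL
  structure(tab, dataset_label = dataset_label,
            class = c("gene_score_table", "data.frame"))
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat("gene_score_table [", attr(x, "dataset_label"), "]: ",
      nrow(x), " genes\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values for one gene across datasets:
#' `chi2 = -2 * sum(log(p_i))` referred to a chi-squared distribution with
#' `2m` degrees of freedom.
#'
#' @param p_by_dataset Numeric vector of p-values in `(0, 1]`, one per
#'   dataset.
#' @return List with `chi2_stat`, `df` and `p_combined`.
#' @export
fisher_combine <- function(p_by_dataset) {
  if (length(p_by_dataset) == 0) stopf("no p-values to combine")
  if (any(is.na(p_by_dataset)) || any(p_by_dataset <= 0) || any(p_by_dataset > 1))
    stopf("fisher_combine requires p-values in (0, 1]; clamp before calling")
  stat <- -2 * sum(log(p_by_dataset))
  df <- 2L * length(p_by_dataset)
  list(chi2_stat = stat, df = df,
       p_combined = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Combine gene score tables across datasets
#'
#' Applies [fisher_combine()] gene by gene, restricted to genes present in
#' every dataset.
#'
#' @param tables List of `gene_score_table`s.
#' @param dataset_label Label for the combined table (default "combined").
#' @return A `gene_score_table` over the common genes, with the Fisher
#'   p-value as `p_gene` and `statistic_kind = "fisher_combined"`.
#' @export
combine_gene_scores <- function(tables, dataset_label = "combined") {
  if (length(tables) < 1) stopf("need at least one gene score table")
  common <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  common <- sort(common)
  if (length(common) == 0) {
    warning("no genes shared by all datasets")
    return(gene_score_table(setNames(numeric(0), character(0)),
                            dataset_label = dataset_label,
                            statistic_kind = "fisher_combined"))
  }
  pmat <- vapply(tables, function(t) {
    setNames(t$p_gene, t$gene_id)[common]
  }, numeric(length(common)))
  pmat <- matrix(pmat, nrow = length(common))
  p_comb <- apply(pmat, 1, function(p) fisher_combine(p)$p_combined)
  gene_score_table(setNames(p_comb, common), dataset_label = dataset_label,
                   statistic_kind = "fisher_combined")
}
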