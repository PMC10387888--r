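# Internal helpers shared across stages.

# p-values are clamped on ingest so that downstream log/quantile transforms
# (qnorm, qchisq, log) stay finite.
P_CLAMP_LO <- 1e-300

clamp_pvalues <- function(p, lo = P_CLAMP_LO, hi = 1, what = "p-value") {
  out_of_range <- !is.na(p) & (p < lo | p > hi)
  if (any(out_of_range)) {
    message(sum(out_of_range), " ", what, "(s) clamped to [", lo, ", ", hi, "]")
  }
  pmin(pmax(p, lo), hi)
}

# Chromosome labels arrive as "chr1", "Chr1" or "1" depending on the source;
# comparisons are done on the stripped form.
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# Deterministic key for a node set, used to collapse duplicate subnetworks.
node_set_key <- function(ids) paste(sort(ids), collapse = "|")

# sample() treats a length-1 numeric as 1:n; this keeps draws from a set safe.
sample_from <- function(x, size = 1) x[sample.int(length(x), size)]
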