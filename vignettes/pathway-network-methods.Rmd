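---
title: "Pathway- and network-oriented analysis of GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway- and network-oriented analysis of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathnetgwas)
```

## The problem

Single-variant GWAS tests are underpowered for complex disease: risk is spread
over many variants of mild effect, acting through shared pathways and
physically interacting proteins. `pathnetgwas` implements a post-GWAS analysis
that aggregates nominally significant SNPs into gene scores, searches a
protein–protein interaction (PPI) network for *active subnetworks* of
associated genes, tests those modules for pathway over-representation, and
then lifts the same subnetwork machinery one level up: pathways themselves
become nodes of a network whose edges encode gene-sharing (Cohen's kappa), so
that clusters of mutually related, disease-associated pathways can be
identified. Module sets obtained from different GWAS datasets of the same
phenotype are compared with normalized mutual information (NMI).

The package is a toolkit: each stage is an exported function, and
`run_pathnet()` orchestrates them end to end from a single configuration.

## Stage by stage

### From SNPs to gene scores

SNP records are filtered at `p < 0.05` (strict inequality): the point of the
pipeline is the *collective* behaviour of mild-effect variants, so everything
nominally significant is retained and everything else discarded. Where a
functional-impact score $FS \in [0,1]$ is available for a SNP (e.g. a VEST
score for a missense variant), the association p-value is sharpened to a
weighted p-value

$$p_W = p_{GWAS} / 10^{FS},$$

so a maximally damaging variant gains one order of magnitude of evidence and
an unannotated variant (treated as $FS = 0$) is untouched; $p_W \le p_{GWAS}$
always.

SNPs are assigned to every gene whose window-extended interval contains them
(default window 50 kb per side; BED intervals are 0-based half-open, SNP
positions 1-based, and the conversion is internal and tested). Per gene, SNP
p-values are aggregated through the 1-df inverse chi-squared transform:
`max_chi2` takes the strongest signal (equivalently the minimum p), `sum_chi2`
refers $\sum_i \chi^2_1(p_i)$ to a $\chi^2_m$ distribution. Neither statistic
corrects for LD or gene size — the scores are deliberately the uncorrected
textbook statistics, and `statistic_kind` records which one produced each
gene p-value, so LD-aware scores computed elsewhere can be substituted via
`read_gene_scores()`. Across datasets, genes present in *every* dataset are
combined with Fisher's method, $-2\sum_i \ln p_i \sim \chi^2_{2m}$.

### Active subnetworks (top-down)

Gene p-values become z-scores, $z_i = \Phi^{-1}(1 - p_i)$. A subnetwork $A$
with $k$ genes scores

$$z_A = \frac{1}{\sqrt{k}} \sum_{i \in A} z_i, \qquad
  s_A = \frac{z_A - \mu_k}{\sigma_k},$$

where $(\mu_k, \sigma_k)$ are estimated by Monte Carlo from random node sets
of size $k$ drawn from the score pool (default 10,000 samples per size). The
implementation draws random *permutations* of the pool and uses their running
prefixes, so one pass yields a uniformly drawn set of every size; within a
draw, sampling is without replacement. Calibration ignores topology — random
node sets, not random connected sets — which keeps the null cheap and is
conservative for dense subnetworks.

The search is greedy, one run per seed (by default every scored node): at each
step the neighbouring node whose inclusion maximises $s_A$ is added — at a
fixed target size that is simply the neighbour with the largest $z$, which is
what makes the search fast — and the run stops when no addition improves
$s_A$ or the size cap (default 300) is reached. Ties are broken by
lexicographic node id, so the whole search is deterministic. Identical node
sets reached from different seeds are collapsed; overlapping but distinct
subnetworks are all reported. Only subnetworks with $s_A \ge 3$, the
conventional significance cutoff for active modules, are returned.

Two caveats are worth stating plainly. First, the calibration is computed for
*random* sets but the cutoff is applied to *greedily maximised* scores, so the
null is anti-conservative under optimisation; the cutoff is applied as the
method defines it, and the planted-truth tests show it behaves sensibly, but
$s_A$ should not be read as a z-score with a literal normal p-value. Second,
network nodes without a score are excluded from seeds and candidates (and
reported), rather than imputed.

### Seed expansion (bottom-up)

`diamond_expand()` implements DIAMOnD-style module growth. For a candidate
node of degree $k$ with $k_s$ links into the current module of size $s_0$ in a
network of $N$ nodes, the connectivity p-value is the hypergeometric tail

$$p(k, k_s) = \sum_{k_i = k_s}^{k}
  \frac{\binom{s_0}{k_i}\binom{N-s_0}{k-k_i}}{\binom{N}{k}},$$

computed via `phyper()` (log-space internally, exact to 1e-12 against
enumeration). At each iteration every non-member with at least one link into
the module is scored against the *current* module and the minimum-p node is
added; ties prefer higher $k_s$, then lexicographic id. Candidates with
$k_s = 0$ carry p-value 1 and are excluded — expansion is neighbourhood
growth. The original algorithm's seed-weighting parameter is not exposed;
the implementation corresponds to unweighted seeds. Typical module-size
presets are 200 and 500 additions.

### Enrichment, consensus

Over-representation uses the hypergeometric tail with universe $f$ (by default
all genes in the pathway collection), pathway size $g$, query size $d$
(counted after intersecting with the universe) and overlap $k$, corrected by
Benjamini–Hochberg (default) or Bonferroni; a pathway is significant when the
adjusted p is strictly below $\alpha = 0.05$. A dataset yields many modules;
its pathway-level evidence is summarised as the *minimum adjusted p over the
dataset's modules*. That aggregation rule is an explicit design choice (the
alternatives — significance frequency across modules, rank products — are
defensible; min-p is the most direct "best showing" summary and keeps ranks
interpretable). The strict consensus reports pathways significant in every
dataset; a relaxed `min_datasets` report is available.

### The pathway network and its clusters

From the binary gene–pathway membership matrix, each pathway pair gets a
Cohen's kappa: with co-membership counters $CN_{11}, CN_{10}, CN_{01},
CN_{00}$ over the gene universe and total $T$,

$$G = \frac{CN_{11} + CN_{00}}{T}, \qquad
  C = \frac{(CN_{11}+CN_{01})(CN_{11}+CN_{10}) +
            (CN_{00}+CN_{10})(CN_{00}+CN_{01})}{T^2}, \qquad
  \kappa = \frac{G - C}{1 - C},$$

the standard chance-corrected agreement with product-of-margins expectation
($\kappa = 1$ is defined for the degenerate $C = 1$ case). Pairs with
$\kappa \ge 0.15$ (inclusive) become edges; isolated pathways remain as
nodes; self-pairs are excluded. The 0.15 default reproduces, on real KEGG
collections, a node-to-edge ratio comparable to human PPI networks; an edge
count sweep over thresholds is monotone by construction and is part of the
test suite.

The active-subnetwork search then runs *on the pathway network*, with node
significance taken from enrichment results and the Monte-Carlo null
recomputed on the pathway significance pool (never reused from the gene
level). In the cross-dataset pipeline the driving significance is the
per-pathway *maximum* of the dataset-level aggregated p-values — a pathway is
only as significant as its worst dataset — which is the same strictness as
the consensus table; per-dataset pathway searches can be run directly via
`pathway_subnetworks()`.

Pathway subnetworks larger than 50 are subdivided with an MCODE-style
clustering (subdivision triggers strictly above 50; smaller subnetworks pass
through as single clusters). Vertex weights are local-density based: the core
number of the highest k-core of a node's open-neighbourhood subgraph times
that k-core's density. Clusters grow outward from the highest-weight
unassigned seed, including reachable unassigned nodes whose weight is at
least $(1 - \text{cutoff})$ of the seed weight (default cutoff 0.2), then a
haircut removes singly-connected members, and clusters lacking a 2-core are
discarded. Cluster score is density × size; ranking is by score. The `fluff`
flag of the original algorithm is accepted but not implemented (off in the
conventional defaults). One behavioural consequence of these rules worth
knowing: two equally dense blocks joined by a *direct* bridge edge have
uniform vertex weights and therefore merge into one cluster — separation
requires the bridge to pass through sparser, lower-weight nodes, which is the
situation that arises in practice in kappa networks.

### Comparing module sets across datasets

For module sets $U = \{U_1..U_R\}$ and $V = \{V_1..V_S\}$, the contingency
matrix $n_{ij} = |U_i \cap V_j|$ (modules may overlap; counts are per pair)
yields margins $a_i, b_j$ and total $N$, entropies
$H(U) = -\sum_i (a_i/N)\log(a_i/N)$, mutual information
$I(U,V) = \sum_{ij} (n_{ij}/N) \log\frac{n_{ij}/N}{a_i b_j / N^2}$ (natural
log; $0\log 0 = 0$), and

$$\mathrm{NMI}_{SUM} = \frac{2\, I(U,V)}{H(U) + H(V)} \in [0, 1],$$

clamped against floating-point error. When both sets are single blocks the
entropies vanish and the value is defined as 1 (continuity; reported via a
message). For overlapping module sets the partition interpretation of NMI is
heuristic — the quantity is still well defined from the table and is applied
exactly as written. One consequence: if every module within each dataset
contains the same strong core (as happens when many greedy seeds absorb one
dominant module), rows and columns of the table are nearly exchangeable and
NMI is close to zero even though the *gene-level* agreement is high — NMI
measures correspondence of the partition structure, not overlap per se.

## The synthetic-data generator

`fixture_spec()` / `simulate_fixture()` generate a complete, seeded, known
truth world:

* **Interactome**: preferential attachment with $m = $ mean degree / 2
  (default 500 genes, mean degree 10) — connected, heavy-tailed degrees, the
  regime in which the hypergeometric connectivity test is informative.
* **Planted module**: a BFS-selected connected subgraph (default 25 genes)
  whose genes receive p-values uniform on $(0, 10^{-6})$, background uniform
  on $(0,1)$. The module is additionally densified to internal edge density
  0.4. The densification is the point, not a convenience: bottom-up expansion
  uses *only* topology, and its premise is that disease modules are more
  densely interconnected than chance; a module that is merely a random
  connected subgraph carries no topological signal to recover. At this scale
  (background edge probability ≈ 0.02) density 0.4 corresponds to planted
  genes having roughly half their links inside the module.
* **Pathways** (default 60): one disease pathway holding 90% of the planted
  genes plus light padding; six partner pathways each carrying 40% of the
  planted genes (they enrich and kappa-link to the disease pathway, forming
  the planted pathway cluster); background pathways share an `overlap_rate`
  (default 0.05) fraction of genes with earlier ones, keeping the background
  kappa network sparse.
* **Summary statistics** (default a trio of datasets, mirroring multi-cohort
  designs): per gene and dataset a target p is drawn (planted genes below
  $10^{-6}$, independent across datasets), one SNP is placed at exactly the
  target and the remaining 2–7 SNPs above it, so the gene-level min-p equals
  the target; 5% of SNPs receive functional scores; genes are laid out 200 kb
  apart so 50 kb windows never overlap and the truth stays crisp.

What the generator does *not* emulate: LD structure (SNPs within a gene are
independent draws, and the no-LD gene statistics are exactly correct here,
which they are not on real data), allele-frequency structure, overlapping
gene windows, biased gene sizes, and the scale of real inputs (hundreds of
nodes versus $10^4$ proteins and $10^6$ SNPs). Passing the planted-truth
tests therefore demonstrates the machinery is implemented correctly and the
signal flow works end to end — not that the method's error rates on real
GWAS data are calibrated.

## Numerical and design choices

* P-values are clamped to $[10^{-300}, 1]$ on ingest (and to
  $1 - 10^{-16}$ from above inside the z transform) so logs and quantiles
  stay finite; clamping is reported.
* $\sigma_k$ estimates are floored at $10^{-8}$ to guard constant pools.
* All tie-breaks (greedy neighbour choice, DIAMOnD candidate choice, MCODE
  seeding, cluster ranking) are lexicographic on node id after the primary
  keys, so every stage is bit-reproducible given a seed; the pipeline derives
  one seed per stochastic stage from the master seed and the manifest records
  everything needed to re-execute the run.
* Problem sizes used by the test suite and the acceptance script (500-gene
  worlds, 10–20 replicates, 10,000 Monte-Carlo samples per size) were chosen
  so each statistical check has comfortable resolution at its stated
  tolerance while the whole suite stays quick to run.

## Known limitations

* No LD correction in gene scoring: on real data min-p and sum statistics are
  biased by gene size and LD; the interface accepts externally computed
  corrected gene scores as a drop-in.
* The $s_A \ge 3$ cutoff inherits the anti-conservativeness of scoring
  optimised sets against a random-set null, as discussed above.
* Dataset-level min-p aggregation over modules favours pathways hit by at
  least one strong module over pathways hit consistently but weakly.
* MCODE's `fluff` option is a stub; and direct bridges between equally dense
  regions are not cut (see above).
* NMI on overlapping module sets is a heuristic summary of partition
  correspondence, and is near zero when modules within a dataset are
  near-duplicates.
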