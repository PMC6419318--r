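---
title: "Integrative gene family identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative gene family identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamkit)
```

genefamkit classifies gene-family membership in plant proteomes by combining
orthogroup clustering with ranked profile-HMM searches, then layers motif
verification, duplication typing, Ka/Ks estimation and expression labeling
on top. This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic fixtures do and do
not demonstrate.

## The membership model

The decision engine treats two homology signals as complementary errors-in-
different-directions detectors. A profile HMM per subfamily gives a ranked
hit list with E-values; a graph-based orthogroup clustering (OrthoMCL
`groups` format) gives cluster context. Neither is trusted alone: the HMM
score threshold is anchored on biology rather than chosen freely, and the
cluster context rescues or vetoes marginal hits.

**Threshold rule.** Each subfamily has a set of previously validated
reference members in an anchor species. For each reference gene we take its
first-occurring hit in the ranked output (transcript variants collapse to
genes; the representative is the variant with the smallest rank). The
inclusion cutoff is the E-value of the reference gene whose representative
hit is worst — the family is assumed to extend at least as far as its
weakest validated member. The comparison is inclusive (`evalue <= cutoff`),
so the anchoring hit itself passes. Ties on E-value break toward the later
output position, then lexicographic id, reading "last in the output"
positionally.

**Decision table.** With the cutoff fixed, each cluster is assessed:
`singleton` (one member gene), `complete` (all genes above), `absent` (none
above), otherwise `partial`, with a *completion ratio* = fraction of member
genes above the cutoff. A cluster is *known* if it contains a reference
member. A candidate gene is kept iff it is above threshold and (its cluster
is known, or is a singleton, or has completion ratio at or above
`completion_threshold`), or it is on the `force_include` list (reference
genes are kept unconditionally). Everything else is rejected with a
machine-readable reason code. Two points were genuinely open and are decided
as follows:

* An above-threshold gene in an *unknown complete* cluster has no explicit
  table row; completion ratio 1 satisfies the ≥ 50% representation rule, so
  it is kept (reason `PARTIAL_GE50`). The alternative (rejecting coherent
  novel clusters) would make the method unable to discover families absent
  from the reference species.
* Below-threshold members of a cluster that meets the representation rule
  are rejected by default, keeping the engine *sound*: every kept gene
  outside the forced list is above threshold. `partial_keep_below = TRUE`
  flips this for users who prefer cluster-level rescue.

Genes absent from the clustering are treated as singleton clusters of
themselves, mirroring how OrthoMCL reports unclustered sequences. A gene
with hits in two subfamilies receives a decision in each and is flagged
`ambiguous` rather than silently resolved — resolution requires biological
judgment (or the motif evidence of the next stage).

`completion_threshold` defaults to 0.5 (dimensionless fraction of cluster
members); raising it only ever removes kept genes, and loosening the E-value
cutoff only ever adds them — both monotonicity properties are tested.

## Exact motif p-values

Subfamily-diagnostic kinase subdomain VIII motifs are written as degenerate
consensus patterns (single residue, `(A/B/C)` alternation, `x` wildcard) and
compiled to log2 log-odds PWMs: allowed residues in a column share
probability mass `1 − 20·pseudocount` uniformly (pseudocount default 0,
added to every residue when nonzero), wildcard columns equal the background
exactly (log-odds 0), and `−Inf` entries are capped at −30 bits so the
discretized dynamic program needs no sentinels. The background defaults to
uniform 1/20 and is configurable to proteome-derived frequencies.

The null distribution of window scores under i.i.d. background is computed
exactly on an integer grid: one bin width for the whole matrix, chosen so
the widest column spans `granularity` bins (default 1000), then per-column
score distributions are convolved. p-values are tail sums read at the upper
(conservative) side of the bin; the same grid scores observed windows, so a
brute-force enumeration over all $20^L$ words reproduces the distribution
identically — that equivalence is asserted in the tests exactly for motif
length ≤ 3 and to total variation < 1e-12 at length 6. Scanning slides all
`len − L + 1` windows, keeps the best window per protein ("unique hits in
individual proteins"), and reports it only below the threshold (primary
1e-4, relaxed re-scan 1e-3, both strict). Unknown residues (`X`) score the
column minimum, a conservative choice that cannot manufacture hits.

## Collinearity and duplication typing

Homolog pairs are an input (two-column TSV) rather than recomputed by
all-vs-all alignment, which keeps the module testable and decouples it from
any search engine. Pairs are mapped to gene-rank coordinates (the order
index of each gene along its chromosome — proximity rules operate on gene
ranks, not base pairs) and chained per chromosome pair and orientation by
dynamic programming: an anchor scores 1, consecutive anchors must advance
strictly monotonically on both chromosomes with at most `max_gap`
(default 25) intervening ranks on either side, and a chain pays
`gap_penalty` (default 0.25) per skipped rank (the larger of the two gaps).
Chains with at least `min_block_size` (default 5) anchors are extracted
greedily — best chain first, anchors removed, repeat — so blocks never share
anchors. These defaults mirror common practice for collinearity detection in
plant genomes; all are configurable. The gap and monotonicity invariants are
re-asserted on every emitted block, and the DP is tested against exhaustive
monotone-subset search for up to 12 anchors.

Duplication types follow the usual precedence — membership in any block
anchor makes a gene `wgd_segmental`; else a same-chromosome partner within
`tandem_rank` (default 1, i.e. adjacent) ranks makes it `tandem`; within
`proximal_rank` (default 10) ranks, `proximal`; any remaining partner,
`dispersed`; no partner, `singleton`. A subgenome summary partitions blocks
into within-A, within-D and A↔D counts for allopolyploid genomes.

## Ka/Ks

The estimator is Nei–Gojobori (1986) with Jukes–Cantor correction — the
standard companion to collinearity scans, chosen because it is assumption-
light and exactly testable; the estimator sits behind a single function and
could be swapped. Sites: per codon position, the fraction of the three
single-nucleotide changes that are synonymous (changes to stop codons count
as nonsynonymous), so each codon contributes exactly 3 sites; site totals
average the two sequences. Substitutions: differing codons are resolved by
averaging over all orderings of the differing positions, skipping pathways
through stop codons (if every pathway hits a stop, all are used with stop
steps counted as nonsynonymous — a rare degenerate case). Proportions are
corrected by d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4 is flagged `saturated`
rather than extrapolated, and Ka/Ks is `NA` (never 0 or ∞) when Ks = 0 or
either distance is saturated. Alignments must be in frame; gapped codon
pairs are dropped pairwise, trailing stops trimmed, internal stops are an
error.

## Expression labeling

Fold changes are computed on the shifted scale, log2FC = log2(FPKM_treat+1)
− log2(FPKM_ctrl+1), which absorbs zeros without special-casing. Labels use
strict inequalities: significant beyond 1.5/0.5, moderate beyond 1.2/0.8.
The default direction makes upregulation positive; a literal
control-minus-treatment subtraction is available as
`direction = "control_vs_treatment"` since both conventions appear in the
literature and they differ only by sign. Values are assumed
replicate-averaged upstream — no significance testing is performed, only
thresholding, so the labels are descriptive, not inferential.

## What the simulator emulates — and what it does not

`simulate_family()` plants subfamily members whose proteins embed an
instantiated copy of the diagnostic motif in a random backbone (250–350
residues), with decoy proteins lacking it. Hit tables are generated
directly: member E-values are drawn log-uniformly from a wide band
(10^−150 to 10^−60) and decoys at least `evalue_separation` (default 10)
orders of magnitude weaker, with the worst member value placed on an
anchor-species reference gene so the threshold rule can recover the planted
family exactly. This E-value model is a deliberate stand-in for running a
real profile search — it preserves the *rank structure* the classifier
consumes, not HMMER's score statistics. Orthogroups mirror the true
families (one gene per species, a configurable number reduced to
non-anchor singletons, one gene given a second transcript variant to
exercise variant collapsing); contamination adds enough decoys to a group
to push its completion ratio below 0.5. `simulate_genome()` plants
segmental blocks (8-gene runs, alternating orientation), tandem,
proximal and dispersed pairs on four chromosomes of 120 genes across two
subgenomes, each gene in at most one feature. `simulate_cds_pairs()`
evolves one copy of a random sense-codon sequence under uniform proposals
with synonymous changes always accepted and nonsynonymous accepted with
probability ω, scaled so expected synonymous substitutions per synonymous
site equal `ks_depth` (defaults ω = 0.2, depth 0.3, 300 codons — a regime
where the NG86 estimator is effectively unbiased, as the recovery test
shows). `simulate_expression()` plants fold classes {2, 1.3, 1, 0.7, 0.4}
on the shifted scale so noise-free recovery is exact.

Passing on these fixtures demonstrates internal correctness — the decision
table, p-value machinery, chaining optimality and estimators do what they
claim. It does *not* demonstrate robustness to the pathologies of real
data: HMM score heteroscedasticity across subfamilies, clustering errors
correlated with sequence divergence, fragmented assemblies, alignment error
in CDS pairs, or replicate noise in FPKM. The default problem sizes (3
species, 24 orthogroups, 30 decoys, 480 genome genes, 50 codon pairs) were
chosen as the smallest sizes at which every planted structure class appears
multiple times.

Determinism: every simulator output draws from a stream derived from the
master seed and the output's name, so outputs are byte-identical across
runs and adding a new fixture type never perturbs existing ones.

## Known limitations

* Multi-subfamily hits are flagged, not resolved.
* The completion ratio counts genes; if variants of one gene straddle the
  threshold the gene counts as above (any-variant rule).
* Collinearity chaining is within-genome and orientation-aware but does not
  subclassify transposed duplicates.
* NG86 saturates near p = 3/4; deeply diverged pairs need a
  maximum-likelihood estimator, which is out of scope.
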