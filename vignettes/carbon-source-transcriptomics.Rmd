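---
title: "Methods: carbon-source transcriptome analysis for bacterial endophytes"
author: "endolife package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-source transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endolife)
```

# Scope and model of the experiment

`endolife` analyses bulk RNA-seq of a bacterium grown on two carbon sources
(lactate and sucrose) sampled at two timepoints, in triplicate: conditions
L6, L12, S6 and S12. Sucrose is a plant-derived sugar, so for an endophytic
bacterium the contrast between the two carbon sources is a proxy for
proximity to the plant host; the quantities of interest are per-gene fold
changes between conditions, expression-pattern clusters, and regulatory
edges compatible with the observed changes.

The pipeline mirrors a deliberately simple, fully transparent analysis
stack: suffix-array read mapping with a unique-hit policy, coding-sequence
containment counting, RPKM plus quantile normalization, a conditional
negative-binomial exact test, Spearman-distance hierarchical clustering with
length-aware category enrichment, and projection of a reference regulatory
network through an ortholog map followed by sign-consistency filtering.
Every stage is exposed as a function; `runPipeline()` composes them and
writes a manifest.

# Read mapping

Reads are 71 nt and single-ended. Because base quality degrades along the
read, 4 nt are removed from the 5' end and 31 nt from the 3' end, leaving a
36 nt segment (`trimReads()`; all three numbers are parameters, constrained
to sum to the read length). Mapping a 36-mer is justified by the genome's
k-mer uniqueness: `kmerUniqueness()` reports the fraction of k-mer start
positions whose sequence occurs exactly once. For a random genome of the
default simulated size this is essentially 1 at k = 30; real bacterial
chromosomes with repeats sit slightly lower. Both strand modes are exposed
(`forward_only`, and the default `both_strands` in which a k-mer matching
its own reverse complement elsewhere is not unique), because a read matching
both strands is genuinely ambiguous for counting.

`buildIndex()` constructs a suffix array over the genome concatenated,
through a sentinel that can match no base, with its reverse complement, so
one lookup finds hits on either strand. Circular genomes are extended by
`readLength - 1` wrap-around bases and positions are reported modulo the
genome length; for that reason a circular index only accepts queries of the
length it was built for. The one-mismatch search enumerates the three
alternative bases at every read position (all four at an N, since N matches
nothing on either side) and performs exact lookups of each variant — exact
rather than heuristic, which is affordable because bacterial genomes are
small. Distinct variants cannot share a hit position, so each one-mismatch
placement is found exactly once.

The acceptance policy never chooses among multiple hits: exactly one exact
hit gives `unique_exact`; no exact hit and exactly one 1-mismatch hit gives
`unique_one_mismatch`; any other multiplicity is `ambiguous`, and no hit is
`unmapped`. Only unique placements are counted. The whole mapper is checked
against a brute-force Hamming scan (status, position and strand must agree
exactly on random genomes up to 10 kb).

# Quantification and normalization

A uniquely placed read covering positions p … p+35 increments gene g exactly
when the read is fully contained in g's coordinates. Read strand is ignored
by default (the library protocol is unstranded; `stranded = TRUE` is
available), and a read contained in several overlapping genes increments
each — no disambiguation rule is imposed. Per-sample totals count every
uniquely placed read, contained in a gene or not, since they estimate
sequencing depth.

Within-sample normalization divides by gene length and between-sample
normalization by total mapped reads: `RPKM = counts * 1e9 / (length *
total)`. Because residual distributional differences between libraries
remain (e.g. global shifts from cDNA amounts), quantile normalization is
then applied to the pooled RPKM table of all 12 samples: each sample's
values are replaced by the mean of the rank-matched order statistics, ties
receiving the mean of the reference values they span (delegated to
`limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
rule). Finally values are rounded half-away-from-zero to integers, the form
the exact test consumes. The order — RPKM, then joint quantile
normalization, then rounding — is fixed.

# Differential expression

The test is a conditional exact test under a negative-binomial model with a
single common dispersion φ, closely paralleling Fisher's exact test.
Quantile normalization has equalized the samples' distributions, so equal
effective library sizes are assumed and no offsets are used. For one gene,
conditioning on the total S of both groups, the probability of every split
(s, S−s) follows from the fact that a sum of n iid NB(μ, φ) variables is
NB(nμ, φ/n); the two-sided p-value sums the probabilities of all splits at
most as probable as the observed one (with a 1e-10 relative tolerance for
ties in probability). At φ = 0 the split distribution is binomial with
proportion n_A/(n_A+n_B) — the Poisson limit — and the implementation is
verified against full enumeration to 1e-12 for all totals S ≤ 200, and
against an independent implementation (edgeR's small-p exact test) at
φ > 0.

φ is estimated by conditional maximum likelihood on the within-condition
replicates (all conditions jointly), maximizing on log(φ) to tolerance 1e-6.
Identical replicates drive the estimate to the boundary and 0 is returned;
with no replication the dispersion is not identifiable and 0 is used with a
warning. Genes with zero counts in every sample of a contrast are dropped
(their p-value is undefined). Four pairwise contrasts are tested (S6 vs L6,
S12 vs L12, S12 vs S6, L12 vs L6) and Benjamini–Hochberg FDR is applied per
contrast, not pooled. Fold changes are ratios of replicate means; a
pseudocount (0.5) is only introduced when one group mean is zero, and such
genes form the "smear" class at the left edge of the MA plot, whose
coordinates (`maValues()`) are log2 mean read proportion against log2 fold
change. Significance defaults to FDR < 0.05 with no fold cutoff; the
`ma_highlight` preset (FDR < 0.1, |log2 FC| > 1) reproduces the usual MA
plot highlighting rule.

Under the study conditions (2000 genes, 100 true 8-fold effects, φ = 0.2,
3 + 3 replicates, 20 seeds) the realized false-discovery proportion at
nominal FDR 0.05 and the power at an 8-fold effect are recomputed by
`scripts/acceptance.R`; the test suite asserts FDP ≤ 0.10 and power ≥ 0.8.

# Clustering and category enrichment

Each gene's profile is the per-condition mean of log2(normalized value + 1)
— four numbers. The distance between genes is `(1 − ρ)/2` with ρ the
Spearman rank correlation, so monotone-identical patterns are at distance 0
and reversed patterns at 1. Rank correlation is undefined for constant
profiles; such genes are excluded with a warning rather than silently
placed. Agglomerative clustering uses average linkage (UPGMA) — the
conventional default for correlation distances; nothing in the design
depended on the linkage — and the tree is cut into K = 5 groups by cluster
count. With only 4 conditions the set of possible rank patterns is small,
which is precisely why a handful of clusters suffices.

Enrichment of functional categories within a cluster is one-sided
over-representation. Two modes exist: exact hypergeometric, and the default
length-aware mode that corrects the length bias inherent to RNA-seq (longer
genes collect more reads, hence more power, hence spurious enrichment of
categories of long genes). A monotone probability-weighting function of
cluster membership against gene length is fitted by weighted isotonic
regression — as a function of length, so tied lengths share one fitted
value, and in whichever orientation (increasing or decreasing) fits better —
floored at 1e-4; null clusters of the same size are drawn by weighted
sampling without replacement and the p-value is the add-one-smoothed
fraction of ≥ 10,000 resamples reaching the observed overlap. With equal
lengths the weights are constant and the mode converges to the
hypergeometric answer, which the tests assert.

# Regulatory-network projection and filtering

A signed regulatory network of a well-annotated reference organism
(RegulonDB-style edges: activation, repression or dual) is projected onto
the study organism through an ortholog map: an edge survives exactly when
both endpoints have orthologs, and is renamed; duplicate pairs with
conflicting signs collapse to dual. Many-to-many ortholog assignments are
dropped by default so the map is a bijection on its domain.

Expression differences for the S12 − L12 contrast are superimposed on the
projected network. A gene is "changed" when |Δ| ≥ τ on the rounded
normalized scale; τ defaults to 1 (the smallest nonzero difference that
scale can express) and is reported in output headers. An edge is kept when
both endpoints changed and the sign is compatible: activation requires equal
signs, repression opposite signs, and dual is compatible with any
combination of changes — the most permissive reading of a dual annotation.
Genes with no called change make incident edges ineligible rather than
neutral; the alternative reading (only the target must change) is available
behind `requireBothEndpoints = FALSE`. Filtering is idempotent, and on a
synthetic regulon built fully sign-consistent it retains exactly the
constructed edge set.

Hub regulators are ranked by out-degree (targets regulated), with
lexicographic tie-breaks; total degree is an option. For a regulator absent
from the study genome, `sharedTargetRegulators()` ranks candidate
substitutes by Jaccard overlap between target sets — the operation that
identifies two-component systems taking over the role of a missing
regulator.

# The synthetic study and what it does (not) show

`simConfig()` fixes the simulated study: a 150 kb circular genome with 80
non-overlapping genes of 300–1500 bp (a scaled-down bacterial chromosome
with realistic gene density), four conditions in triplicate, 50,000 reads
per library of 71 nt, NB dispersion 0.1 (typical for technical plus mild
biological replication), 15% of genes with condition effects whose fold
changes are log-uniform between 2 and 1500 — the upper end mirroring the
>1000-fold inductions that carbon-source shifts can produce — including
condition-specific shutoffs, and a per-base substitution error rate of
0.005. The library is unstranded (each read from either strand with
probability 1/2) because the protocol does not preserve strand. Qualities
are a constant placeholder; they are never used. Gene packing is greedy
left-to-right with multinomial gaps — the simplest scheme satisfying
non-overlap. Counts are per-gene read counts directly: a single-end 71 nt
protocol has no insert-size model to emulate. Reads per library is a free
choice (no canonical depth exists for this design); 50,000 keeps a
laptop-scale runtime while giving every moderately expressed gene tens of
reads.

The generator intentionally omits rRNA contamination, adapter read-through
and quality-dependent error profiles. Consequently, passing tests show that
the pipeline's inference is correct under its own model — NB counts, uniform
read starts within gene bodies, uniform substitution errors — not that it is
robust to artefacts of real libraries (rRNA carry-over inflating totals,
coverage bias along transcripts). The `syntheticBenchmarkTable()` fixture is
likewise a labelled stand-in: it encodes literature-scale fold inductions
with replicate scatter so that fold-change recovery can be benchmarked; it
contains no measured data.

# Numerical choices and degenerate inputs

* Exact test: probabilities are computed in log space and normalized;
  `S = 0` returns p = 1; the "as probable" comparison uses a 1e-10 relative
  tolerance so exact ties in split probability are included.
* Dispersion: optimization bounds are φ ∈ [1e-6, 20] on the log scale;
  estimates at the lower boundary are reported as 0.
* Rounding is half-away-from-zero (base `round()` is half-to-even, which
  would bias toward even integers).
* Mapper: any multiplicity discards the read; ties never choose arbitrarily.
  N in either read or genome matches nothing; a hit overlapping the
  strand-concatenation boundary is impossible by the sentinel construction.
* Clustering ties are resolved deterministically by `hclust` in input
  order; cluster labels are stable to gene order up to relabeling.
* Enrichment resampling uses add-one smoothing, so the minimum attainable
  p is 1/(R+1).
* Problem sizes in the shipped tests and acceptance script (genomes of
  20–150 kb, 15–80 genes, hundreds to tens of thousands of reads, 2000-gene
  DE simulations over 20 seeds) were chosen so the whole validation runs on
  a single CPU in minutes while keeping every statistical check
  well-powered.

# Known limitations

* Only substitutions are modelled in mapping: no indels, no quality-aware
  scoring, no paired ends, no spliced alignment.
* The common-dispersion NB model has no tagwise shrinkage or covariates;
  strongly gene-specific overdispersion will inflate the error rates of the
  exact test.
* The exact-test definition is this package's own (documented above); it is
  verified against enumeration and an independent implementation, but no
  attempt is made to chase version-specific behaviour of other tools.
* Quantile normalization assumes most of the transcriptome is unchanged;
  with very widespread regulation it compresses true global shifts.
* The category vocabulary is a flat user-supplied table, not an ontology
  DAG; no term propagation is performed.
* Reproducing a specific organism's published network (hundreds of genes
  and edges) requires that era's ortholog and regulon snapshots and is out
  of scope; the network stage is validated on synthetic regulons with known
  consistent subsets.
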