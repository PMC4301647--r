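# endolife

Transcriptome analysis of a bacterium grown on two carbon sources — for
microbiologists studying how a plant-derived sugar (sucrose) versus a
non-plant carbon source (lactate) reprograms gene expression in endophytic
bacteria, and for anyone who wants a fully transparent, testable bacterial
RNA-seq stack whose every stage is a plain R function.

The experimental design is four conditions in triplicate — lactate and
sucrose at 6 h and 12 h (`L6`, `L12`, `S6`, `S12`) — with 71 nt single-end
reads. The pipeline:

1. **Mapping** — reads trimmed to 36 nt (4 nt off the 5' end, 31 nt off the
   3' end) are placed by suffix-array lookup, exact first and then allowing
   one mismatch, keeping only *unique* hits: one exact hit, or one
   1-mismatch hit with no exact hit; any multiplicity discards the read.
   Genome mappability is profiled as k-mer uniqueness (fraction of k-mers
   occurring exactly once).
2. **Quantification** — a read counts for a gene iff it is fully contained
   in the coding sequence; RPKM = counts x 10^9 / (length x total mapped
   reads); quantile normalization across all 12 libraries; rounding to
   integers.
3. **Differential expression** — conditional negative-binomial exact test
   with common dispersion phi estimated by conditional maximum likelihood:
   given the two groups' total S, the p-value sums the probabilities of all
   splits of S no more probable than the observed one (binomial in the
   Poisson limit phi = 0). Benjamini–Hochberg FDR per contrast, four
   contrasts: S6 vs L6, S12 vs L12, S12 vs S6, L12 vs L6.
4. **Clustering & enrichment** — hierarchical clustering (average linkage,
   K = 5) of per-condition log2 profiles under the distance
   d = (1 − Spearman rho)/2; functional-category over-representation per
   cluster, either exact hypergeometric or length-aware (weighted null
   resampling under a monotone length-bias fit).
5. **Regulatory network** — a signed reference network (activation /
   repression / dual) is projected through an ortholog map (edge survives
   iff both endpoints map), filtered to edges whose sign agrees with the
   observed S12 − L12 changes (both endpoints changed; activation = same
   direction, repression = opposite, dual = either), then hub regulators are
   ranked by out-degree and substitutes for missing regulators found by
   Jaccard target-set overlap.

A synthetic-data generator (genome, annotation, FASTQ reads, design table,
signed regulon, ortholog map) with known ground truth makes the whole
pipeline testable offline.

## Worked example

```r
library(endolife)

cfg <- pipelineConfig(
  outdir = "run1",
  sim = simConfig(genomeLength = 40000, geneCount = 25,
                  geneLengthRange = c(300, 1200),
                  readsPerSample = 5000, seed = 42),
  seed = 42)
res <- runPipeline(cfg)

table(res$mappings$status)
#>        unique_exact unique_one_mismatch            unmapped
#>               47210                8510                 765

head(res$de$S12_vs_L12[order(res$de$S12_vs_L12$FDR), ], 4)
#>   gene_id logFC   PValue      FDR significant
#>  SYN_0004  5.64 1.10e-10 2.74e-09        TRUE
#>  SYN_0002 -5.07 2.50e-09 3.12e-08        TRUE
#>  SYN_0011 -3.60 5.69e-06 4.75e-05        TRUE
#>  SYN_0007  2.75 3.34e-04 2.09e-03        TRUE

summarizeGene("SYN_0004", res)$expression
#>       L6      L12       S6      S12
#>  15068.3  11934.3 594068.0 594068.0
```

Reading the output: of the 60,000 simulated reads, 47,210 mapped with a
unique exact hit and 8,510 with a unique single mismatch (the simulated
sequencer error rate is 0.5%/base); none were ambiguous on this small
genome. `SYN_0004` is a sucrose-induced gene: its normalized expression
rises from ~12–15k on lactate to ~594k on sucrose, a log2 fold change of
5.6 at FDR 2.7e-9 in the S12 vs L12 contrast, and it is flagged significant.
The full run also writes per-stage TSVs (mappings, counts, normalized
expression, per-contrast DE tables, clusters, enrichment, the filtered
regulon and its hubs) plus a JSON manifest with parameters, input checksums
and per-stage record counts; a rerun with the same config is bit-identical.

Individual stages are ordinary functions — `kmerUniqueness()`,
`buildIndex()` / `mapReads()`, `countReads()`, `rpkm()` /
`quantileNormalize()` / `roundExpression()`, `exactTestContrast()`,
`clusterProfiles()` / `categoryEnrichment()`, `projectNetwork()` /
`signConsistencyFilter()` / `hubRegulators()` — and can be used on your own
FASTA/FASTQ/TSV inputs; `inst/scripts/endolife.R` is a thin command-line
wrapper.

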