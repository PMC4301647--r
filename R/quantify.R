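#' Count uniquely mapped reads fully contained in coding sequences
#'
#' A read placed at position p (covering p .. p + mappedLength - 1) increments
#' a gene exactly when the whole read lies inside the gene's coordinates,
#' irrespective of the read strand (unstranded library; set `stranded = TRUE`
#' to require the read strand to match the gene strand). A read contained in
#' several overlapping genes increments each of them. Per-sample totals count
#' every uniquely placed read (contained in a gene or not), the denominator
#' of "per million mapped reads".
#'
#' @param mappings data.frame from [mapReads()] with an additional `sample`
#'   column
#' @param annotation `GRanges` gene annotation with `gene_id`
#' @param design data.frame with columns `sample`, `condition` (and optionally
#'   `replicate`) listing every library
#' @param mappedLength read footprint in bases (36 after default trimming)
#' @param genomeLength genome length; placements extending beyond it are an
#'   error unless `circular`
#' @param circular circular-genome flag; origin-wrapping placements are kept
#'   in the totals but can be contained in no (non-wrapping) gene
#' @param stranded require read strand to equal gene strand
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowRanges` = annotation, and per-sample `total_mapped` in
#'   `colData`
#' @export
countReads <- function(mappings, annotation, design, mappedLength = 36L,
                       genomeLength = NULL, circular = FALSE,
                       stranded = FALSE) {
  stopifnot(all(c("status", "position", "sample") %in% names(mappings)))
  placed <- mappings[mappings$status %in%
                       c("unique_exact", "unique_one_mismatch"), , drop = FALSE]
  totals <- table(factor(placed$sample, levels = design$sample))
  if (!is.null(genomeLength) && nrow(placed)) {
    over <- placed$position + mappedLength - 1L > genomeLength
    if (any(over)) {
      if (!circular)
        stop("placement beyond the end of a non-circular genome")
      placed <- placed[!over, , drop = FALSE]  # wrapping reads: in totals only
    }
  }
  counts <- matrix(0L, length(annotation), nrow(design),
                   dimnames = list(annotation$gene_id, design$sample))
  if (nrow(placed)) {
    reads <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(annotation))[1],
      ranges = IRanges::IRanges(start = placed$position, width = mappedLength),
      strand = if (stranded) placed$strand else "*")
    hits <- GenomicRanges::findOverlaps(reads, annotation, type = "within",
                                        ignore.strand = !stranded)
    if (length(hits)) {
      tb <- table(factor(S4Vectors::subjectHits(hits),
                         levels = seq_along(annotation)),
                  factor(placed$sample[S4Vectors::queryHits(hits)],
                         levels = design$sample))
      counts <- counts + matrix(as.integer(tb), nrow = nrow(counts))
    }
  }
  cd <- S4Vectors::DataFrame(design, total_mapped = as.integer(totals[design$sample]))
  rownames(cd) <- design$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = annotation, colData = cd)
  S4Vectors::metadata(se)$stage <- "counts"
  se
}

#' Reads per kilobase of gene per million mapped reads
#'
#' `RPKM = counts * 1e9 / (gene length * total mapped reads)`: a
#' within-library (gene length) and between-library (sequencing depth)
#' normalization making expression comparable across genes and samples.
#'
#' @param x counts: an integer matrix or a `SummarizedExperiment` from
#'   [countReads()]
#' @param lengths gene lengths in bases (matrix method)
#' @param totals per-sample total mapped reads (matrix method)
#' @param ... unused
#' @return same shape as the input; for a `SummarizedExperiment`, an added
#'   assay `rpkm` and stage tag `raw_rpkm`
#' @examples
#' rpkm(matrix(100), lengths = 500, totals = 2e6)  # 100
#' @export
setGeneric("rpkm", function(x, ...) standardGeneric("rpkm"))

#' @rdname rpkm
#' @export
setMethod("rpkm", "matrix", function(x, lengths, totals, ...) {
  if (any(totals <= 0)) stop("total mapped reads must be positive")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  sweep(x / lengths, 2, totals, "/") * 1e9
})

#' @rdname rpkm
#' @export
setMethod("rpkm", "SummarizedExperiment", function(x, ...) {
  lens <- GenomicRanges::width(SummarizedExperiment::rowRanges(x))
  tot <- x$total_mapped
  SummarizedExperiment::assay(x, "rpkm") <-
    rpkm(SummarizedExperiment::assay(x, "counts"), lens, tot)
  S4Vectors::metadata(x)$stage <- "raw_rpkm"
  x
})

#' Quantile normalization across samples
#'
#' Replaces each sample's values by the mean of the rank-matched order
#' statistics across all samples, so that every sample shares one empirical
#' distribution; ties within a sample receive the mean of the reference
#' values they span. Applied to the pooled RPKM table of all libraries.
#'
#' @param x numeric matrix (genes x samples, >= 2 columns) or a
#'   `SummarizedExperiment` carrying an `rpkm` assay
#' @param ... unused
#' @return normalized matrix, or the experiment with an added assay
#'   `normalized` and stage tag `quantile_normalized`
#' @export
setGeneric("quantileNormalize", function(x, ...) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "SummarizedExperiment", function(x, ...) {
  SummarizedExperiment::assay(x, "normalized") <-
    quantileNormalize(SummarizedExperiment::assay(x, "rpkm"))
  S4Vectors::metadata(x)$stage <- "quantile_normalized"
  x
})

#' Round normalized expression to integers
#'
#' Rounds half away from zero, producing the integer gene expression values
#' used by the exact test.
#'
#' @param x numeric matrix or a `SummarizedExperiment` carrying a
#'   `normalized` assay
#' @param ... unused
#' @return integer-valued matrix, or the experiment with an added assay
#'   `expression` and stage tag `rounded`
#' @examples
#' roundExpression(matrix(c(2.5, 0.49)))  # 3 and 0
#' @export
setGeneric("roundExpression", function(x, ...) standardGeneric("roundExpression"))

#' @rdname roundExpression
#' @export
setMethod("roundExpression", "matrix", function(x, ...) .roundHalfAway(x))

#' @rdname roundExpression
#' @export
setMethod("roundExpression", "SummarizedExperiment", function(x, ...) {
  if (!identical(S4Vectors::metadata(x)$stage, "quantile_normalized"))
    stop("roundExpression expects quantile-normalized input")
  SummarizedExperiment::assay(x, "expression") <-
    .roundHalfAway(SummarizedExperiment::assay(x, "normalized"))
  S4Vectors::metadata(x)$stage <- "rounded"
  x
})
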