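# Readers and writers for the pipeline's plain-text interchange formats:
# FASTA/FASTQ via Biostrings, GFF3 via rtracklayer when requested, and flat
# TSVs for annotation, design, mappings, expression, edge lists and ortholog
# maps.

#' Read a genome FASTA
#' @param path FASTA file
#' @param circular circular-genome flag to record on the object
#' @return `DNAStringSet` with `metadata(x)$circular` set
#' @export
readGenomeFasta <- function(path, circular = FALSE) {
  g <- Biostrings::readDNAStringSet(path)
  S4Vectors::metadata(g)$circular <- isTRUE(circular)
  g
}

#' Write a genome FASTA
#' @param genome `DNAStringSet`
#' @param path output file
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a gene annotation (flat TSV or GFF3)
#'
#' TSV files need columns `gene_id`, `start`, `end`, `strand` and optionally
#' `category`; GFF3 files (`.gff`/`.gff3`, read with rtracklayer) use records
#' of type `gene` with an `ID` attribute.
#'
#' @param path annotation file
#' @return `GRanges` with `gene_id` (and `category` when present)
#' @export
readGeneAnnotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ann <- GenomicRanges::granges(gr)
    ann$gene_id <- gr$ID
    if (!is.null(gr$category)) ann$category <- gr$category
    return(ann)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (any(tab$start > tab$end)) stop("annotation has start > end")
  ann <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand, gene_id = tab$gene_id)
  if ("category" %in% names(tab)) ann$category <- tab$category
  ann
}

#' Write a gene annotation as flat TSV
#' @param annotation `GRanges` with `gene_id`
#' @param path output file
#' @export
writeAnnotationTsv <- function(annotation, path) {
  df <- data.frame(gene_id = annotation$gene_id,
                   start = GenomicRanges::start(annotation),
                   end = GenomicRanges::end(annotation),
                   strand = as.character(GenomicRanges::strand(annotation)),
                   length = GenomicRanges::width(annotation))
  if (!is.null(annotation$category)) df$category <- annotation$category
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene annotation as GFF3
#' @param annotation `GRanges` with `gene_id`
#' @param path output file
#' @export
writeAnnotationGff3 <- function(annotation, path) {
  attrs <- paste0("ID=", annotation$gene_id,
                  if (!is.null(annotation$category))
                    paste0(";category=", gsub("[;=\t]", "_", annotation$category))
                  else "")
  lines <- paste(as.character(GenomicRanges::seqnames(annotation)), "endolife",
                 "gene", GenomicRanges::start(annotation),
                 GenomicRanges::end(annotation), ".",
                 as.character(GenomicRanges::strand(annotation)), ".",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file
#' @return `DNAStringSet` named by read id (qualities are discarded: they are
#'   a constant placeholder in this protocol and never used)
#' @export
readFastq <- function(path) {
  if (file.size(path) == 0L) return(Biostrings::DNAStringSet())
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Read a sample design table
#' @param path TSV with columns `sample`, `condition` (optional `replicate`)
#' @return data.frame
#' @export
readDesign <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(d)))
    stop("design TSV must have columns sample, condition")
  d
}

#' Write the per-read mapping table
#' @param mappings data.frame from [mapReads()]
#' @param path output TSV
#' @export
writeMappingTsv <- function(mappings, path) {
  utils::write.table(mappings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix with its processing stage
#' @param x matrix
#' @param path output TSV
#' @param stage stage tag written as a column
#' @export
writeExpressionTsv <- function(x, path, stage) {
  df <- data.frame(gene_id = rownames(x), stage = stage, x,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed regulatory edge list
#'
#' Expects a RegulonDB-like TSV with columns `regulator`, `target`, `sign`
#' (tokens `+`, `-`, `+-` or the spelled-out forms); a malformed sign token
#' raises an error naming the offending line.
#'
#' @param path edge-list TSV
#' @return a [RegulatoryNetwork-class]
#' @export
readEdgeList <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "sign") %in% names(e)))
    stop("edge list must have columns regulator, target, sign")
  regulatoryNetwork(e)
}

#' Write a regulatory network as edge-list TSV (RegulonDB-style signs)
#' @param net a [RegulatoryNetwork-class]
#' @param path output TSV
#' @export
writeEdgeList <- function(net, path) {
  e <- networkEdges(net)
  e$sign <- c(activation = "+", repression = "-", dual = "+-")[e$sign]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulatory network in SIF format for network viewers
#' @param net a [RegulatoryNetwork-class]
#' @param path output `.sif` file
#' @export
exportSif <- function(net, path) {
  e <- networkEdges(net)
  writeLines(paste(e$regulator, e$sign, e$target, sep = "\t"), path)
  invisible(path)
}

#' Read an ortholog map
#' @param path TSV with columns `reference`, `study`
#' @return data.frame
#' @export
readOrthologMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reference", "study") %in% names(d)))
    stop("ortholog map must have columns reference, study")
  d
}

#' Read a functional-category table
#' @param path TSV with columns `gene_id`, `category`
#' @return data.frame
#' @export
readCategories <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(d)))
    stop("category table must have columns gene_id, category")
  d
}
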