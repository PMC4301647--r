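#' Pipeline configuration
#'
#' One declarative object driving [runPipeline()]. Either a [simConfig()] is
#' supplied (the synthetic study is generated and analysed end to end) or
#' paths to existing inputs are given. Stage parameters mirror the individual
#' module defaults.
#'
#' @param outdir output directory (created if needed)
#' @param sim a [simConfig()] for a fully synthetic run, or NULL
#' @param genome,annotation,reads,design,network,orthologs,categories input
#'   paths for a file-driven run (`reads` a directory of `<sample>.fastq`);
#'   ignored when `sim` is given, except `network`/`orthologs` which override
#'   the synthetic regulon
#' @param trim5,trim3,mappedLength read trimming scheme (defaults 4/31/36)
#' @param strandMode index strand mode (default `both_strands`)
#' @param k k-mer length for the uniqueness profile (default 30)
#' @param K number of expression clusters (default 5)
#' @param tau change-call threshold for the network contrast (default 1)
#' @param fdrThreshold,logfcThreshold significance calling (defaults 0.05, 0)
#' @param nResamples resamples of the length-aware enrichment null
#' @param nRegulators,targetsPerRegulator,consistentFraction synthetic regulon
#'   shape (see [simulateRegulon()])
#' @param seed integer seed for every stochastic step
#' @return a validated config (list of class `endolifeConfig`)
#' @export
pipelineConfig <- function(outdir, sim = simConfig(), genome = NULL,
                           annotation = NULL, reads = NULL, design = NULL,
                           network = NULL, orthologs = NULL,
                           categories = NULL, trim5 = 4L, trim3 = 31L,
                           mappedLength = 36L,
                           strandMode = c("both_strands", "forward_only"),
                           k = 30L, K = 5L, tau = 1, fdrThreshold = 0.05,
                           logfcThreshold = 0, nResamples = 10000L,
                           nRegulators = 8L, targetsPerRegulator = 6L,
                           consistentFraction = 0.8, seed = 1L) {
  strandMode <- match.arg(strandMode)
  cfg <- list(outdir = outdir, sim = sim, genome = genome,
              annotation = annotation, reads = reads, design = design,
              network = network, orthologs = orthologs,
              categories = categories, trim5 = as.integer(trim5),
              trim3 = as.integer(trim3),
              mappedLength = as.integer(mappedLength),
              strandMode = strandMode, k = as.integer(k), K = as.integer(K),
              tau = tau, fdrThreshold = fdrThreshold,
              logfcThreshold = logfcThreshold,
              nResamples = as.integer(nResamples),
              nRegulators = as.integer(nRegulators),
              targetsPerRegulator = as.integer(targetsPerRegulator),
              consistentFraction = consistentFraction,
              seed = as.integer(seed))
  class(cfg) <- "endolifeConfig"
  if (is.null(cfg$sim)) {
    for (f in c("genome", "annotation", "design")) {
      if (is.null(cfg[[f]])) stop("config field missing: ", f)
      if (!file.exists(cfg[[f]])) stop("config field ", f,
                                       ": file not found: ", cfg[[f]])
    }
    if (is.null(cfg$reads) || !dir.exists(cfg$reads))
      stop("config field reads: directory not found")
  } else {
    validObject(cfg$sim)
    if (cfg$trim5 + cfg$trim3 + cfg$mappedLength != cfg$sim@readLength)
      stop("trim5 + trim3 + mappedLength must equal the simulated read length")
  }
  for (f in c("network", "orthologs", "categories")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field ", f, ": file not found: ", cfg[[f]])
  }
  if (cfg$tau < 0 || cfg$fdrThreshold < 0 || cfg$fdrThreshold > 1)
    stop("parameters out of range")
  cfg
}

#' Run the pipeline end to end
#'
#' Executes (optionally) simulate, then index, map, count, normalize,
#' differential expression for the four contrasts, clustering, category
#' enrichment, and regulatory-network projection and filtering. All outputs
#' are written under `config$outdir` together with a JSON manifest recording
#' parameters, input checksums and per-stage record counts. A rerun with the
#' same config reproduces identical outputs.
#'
#' @param config a [pipelineConfig()]
#' @param quiet suppress stage messages
#' @return (invisibly) a list with the main objects of every stage and the
#'   `manifest`
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "endolifeConfig"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  manifest <- list(package = "endolife",
                   version = as.character(utils::packageVersion("endolife")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   parameters = config[!(names(config) %in% "sim")],
                   stages = list())
  stage <- function(name, records) {
    manifest$stages[[name]] <<- list(records = records)
    say("stage ", name, ": ", records, " records")
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulateGenome(config$sim)
    genome <- sim$genome
    annotation <- sim$annotation
    cc <- simulateCounts(annotation, config$sim)
    design <- cc$design
    truth <- cc$truth
    readDir <- file.path(out, "reads")
    fq <- simulateReads(genome, annotation, cc$counts, config$sim, readDir)
    writeGenomeFasta(genome, file.path(out, "genome.fasta"))
    writeAnnotationTsv(annotation, file.path(out, "annotation.tsv"))
    writeAnnotationGff3(annotation, file.path(out, "annotation.gff3"))
    utils::write.table(design, file.path(out, "design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage("simulate", sum(cc$counts))
    circular <- config$sim@circular
  } else {
    genome <- readGenomeFasta(config$genome, circular = TRUE)
    annotation <- readGeneAnnotation(config$annotation)
    design <- readDesign(config$design)
    fq <- stats::setNames(file.path(config$reads,
                                    paste0(design$sample, ".fastq")),
                          design$sample)
    missing <- !file.exists(fq)
    if (any(missing)) stop("FASTQ missing for sample(s): ",
                           paste(design$sample[missing], collapse = ", "))
    circular <- TRUE
    stage("simulate", 0L)
  }
  manifest$inputs <- as.list(tools::md5sum(
    c(Filter(file.exists, unlist(config[c("genome", "annotation", "design",
                                          "network", "orthologs",
                                          "categories")])), unname(fq))))

  uniq <- kmerUniqueness(genome, k = config$k, strandMode = config$strandMode)
  manifest$kmer_uniqueness <- list(k = config$k, fraction = uniq)
  index <- buildIndex(genome, strandMode = config$strandMode,
                      readLength = config$mappedLength)
  stage("index", length(index@sa))

  mapList <- list()
  skipped <- 0L
  for (s in design$sample) {
    rd <- readFastq(fq[[s]])
    if (length(rd) == 0L) {
      mapList[[s]] <- data.frame(read_id = character(), status = character(),
                                 position = integer(), strand = character(),
                                 mismatches = integer(), sample = character())
      next
    }
    tr <- suppressWarnings(trimReads(as.character(rd), config$trim5,
                                     config$trim3, config$mappedLength))
    skipped <- skipped + tr$skipped
    m <- mapReads(index, tr$reads, readIds = names(rd)[tr$kept])
    m$sample <- s
    mapList[[s]] <- m
  }
  mappings <- do.call(rbind, mapList)
  rownames(mappings) <- NULL
  writeMappingTsv(mappings, file.path(out, "mappings.tsv"))
  tab <- table(mappings$status)
  say("mapping summary: ", paste(names(tab), as.integer(tab),
                                 collapse = ", ", sep = "="),
      "; skipped=", skipped)
  stage("map", nrow(mappings))

  se <- countReads(mappings, annotation, design,
                   mappedLength = config$mappedLength,
                   genomeLength = nchar(.genomeString(genome)),
                   circular = circular)
  utils::write.table(
    data.frame(gene_id = rownames(se), SummarizedExperiment::assay(se, "counts"),
               check.names = FALSE),
    file.path(out, "counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  stage("count", sum(SummarizedExperiment::assay(se, "counts")))

  se <- roundExpression(quantileNormalize(rpkm(se)))
  expr <- SummarizedExperiment::assay(se, "expression")
  writeExpressionTsv(SummarizedExperiment::assay(se, "rpkm"),
                     file.path(out, "expression_rpkm.tsv"), "raw_rpkm")
  writeExpressionTsv(expr, file.path(out, "expression_normalized.tsv"),
                     "rounded")
  stage("normalize", length(expr))

  conds <- design$condition
  phi <- estimateCommonDispersion(expr, conds)$phi
  de <- lapply(designContrasts(), function(ab)
    callDE(exactTestContrast(expr, conds, ab, phi = phi),
           fdrThreshold = config$fdrThreshold,
           logfcThreshold = config$logfcThreshold))
  for (nm in names(de))
    utils::write.table(de[[nm]], file.path(out, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  stage("de", sum(vapply(de, nrow, 1L)))

  profiles <- conditionProfiles(expr, conds)
  clust <- suppressWarnings(clusterProfiles(profiles, k = config$K))
  utils::write.table(
    data.frame(gene_id = names(clust$assignment), cluster = clust$assignment),
    file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage("cluster", length(clust$assignment))

  cats <- if (!is.null(config$categories)) readCategories(config$categories)
          else data.frame(gene_id = annotation$gene_id,
                          category = annotation$category)
  lens <- stats::setNames(GenomicRanges::width(annotation),
                          annotation$gene_id)
  universe <- names(clust$assignment)
  set.seed(config$seed + 10L)
  enrich <- do.call(rbind, lapply(sort(unique(clust$assignment)), function(kk) {
    res <- categoryEnrichment(universe[clust$assignment == kk], universe,
                              cats, lengths = lens,
                              nResamples = config$nResamples)
    cbind(cluster = kk, res)
  }))
  utils::write.table(enrich, file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("enrich", nrow(enrich))

  delta <- deltaExpression(expr, conds, tau = config$tau)
  regulonTruth <- NULL
  if (!is.null(config$network)) {
    reference <- readEdgeList(config$network)
    orthologs <- readOrthologMap(config$orthologs)
  } else {
    regulonTruth <- simulateRegulon(
      annotation, delta, nRegulators = config$nRegulators,
      targetsPerRegulator = config$targetsPerRegulator,
      consistentFraction = config$consistentFraction,
      seed = config$seed + 20L)
    reference <- regulonTruth$reference
    orthologs <- regulonTruth$orthologs
    writeEdgeList(reference, file.path(out, "regulon_reference.tsv"))
    utils::write.table(orthologs, file.path(out, "orthologs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  projected <- projectNetwork(reference, orthologs)
  filtered <- signConsistencyFilter(projected, delta)
  writeEdgeList(filtered, file.path(out, "regulon_filtered.tsv"))
  hubs <- hubRegulators(filtered, topN = 5)
  utils::write.table(hubs, file.path(out, "hub_regulators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodeAttr <- data.frame(gene = delta$gene, delta = delta$delta,
                         sign = delta$sign)
  nodeAttr <- cbind(nodeAttr, vapply(unique(conds), function(cc)
    rowMeans(expr[, conds == cc, drop = FALSE]), numeric(nrow(expr))))
  utils::write.table(nodeAttr, file.path(out, "network_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  exportSif(filtered, file.path(out, "regulon_filtered.sif"))
  stage("regnet", length(filtered))

  manifest$mapping_summary <- c(as.list(tab), skipped = skipped)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, annotation = annotation, design = design,
                 truth = truth, mappings = mappings, experiment = se,
                 dispersion = phi, de = de, clusters = clust,
                 enrichment = enrich, delta = delta, projected = projected,
                 network = filtered, hubs = hubs,
                 regulonTruth = regulonTruth, manifest = manifest))
}

#' Consolidated per-gene report
#'
#' Collects, for one gene, the mean normalized expression per condition, the
#' per-contrast log fold change, p-value, FDR and significance call (NA when
#' the gene was dropped from a contrast), its cluster, and the regulatory
#' edges it participates in. Values are taken verbatim from the stage outputs.
#'
#' @param geneId gene identifier
#' @param results the list returned by [runPipeline()]
#' @return list with components `gene`, `expression`, `contrasts`, `cluster`,
#'   `edges`
#' @export
summarizeGene <- function(geneId, results) {
  expr <- SummarizedExperiment::assay(results$experiment, "expression")
  if (!(geneId %in% rownames(expr))) {
    near <- utils::head(rownames(expr)[order(utils::adist(geneId,
                                                          rownames(expr)))], 3)
    stop("unknown gene '", geneId, "'; nearest identifiers: ",
         paste(near, collapse = ", "))
  }
  conds <- results$design$condition
  expression <- vapply(unique(conds), function(cc)
    mean(expr[geneId, conds == cc]), numeric(1))
  contrasts <- do.call(rbind, lapply(names(results$de), function(nm) {
    d <- results$de[[nm]]
    i <- match(geneId, d$gene_id)
    data.frame(contrast = nm,
               logFC = if (is.na(i)) NA_real_ else d$logFC[i],
               PValue = if (is.na(i)) NA_real_ else d$PValue[i],
               FDR = if (is.na(i)) NA_real_ else d$FDR[i],
               significant = if (is.na(i)) NA else d$significant[i])
  }))
  cl <- results$clusters$assignment[geneId]
  e <- networkEdges(results$network)
  edges <- e[e$regulator == geneId | e$target == geneId, , drop = FALSE]
  list(gene = geneId, expression = expression, contrasts = contrasts,
       cluster = if (is.na(cl)) NA_integer_ else unname(cl), edges = edges)
}
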