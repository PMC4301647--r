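#' Simulate an annotated bacterial genome
#'
#' Generates a random genome and places non-overlapping genes on both strands
#' by greedy left-to-right packing with multinomially distributed intergenic
#' gaps. Coordinates are 1-based inclusive. Each gene receives a functional
#' category label from a small two-level-style vocabulary so that enrichment
#' analyses can be exercised with known truth.
#'
#' @param config a [simConfig()] object
#' @return list with `genome` (a named [Biostrings::DNAStringSet] of length 1,
#'   circularity recorded in `metadata(genome)$circular`) and `annotation`
#'   (a [GenomicRanges::GRanges] with `gene_id`, `length` and `category`)
#' @examples
#' sim <- simulateGenome(simConfig(genomeLength = 20000, geneCount = 10, seed = 7))
#' sim$annotation
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  seq <- paste(sample(c("A", "C", "G", "T"), config@genomeLength,
                      replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chr"))
  S4Vectors::metadata(genome)$circular <- config@circular
  n <- config@geneCount
  if (n == 0L) {
    ann <- GenomicRanges::GRanges(seqnames = character(), ranges = IRanges::IRanges(),
                                  strand = character(),
                                  gene_id = character(), category = character())
    return(list(genome = genome, annotation = ann))
  }
  lens <- sample(seq(config@geneLengthRange[1], config@geneLengthRange[2]),
                 n, replace = TRUE)
  slack <- config@genomeLength - sum(lens)
  if (slack < 0L)
    stop("infeasible packing: total gene length exceeds the genome")
  gaps <- as.integer(stats::rmultinom(1, slack, rep(1, n + 1L)))
  starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n]))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  cats <- sample(.categoryVocabulary(), n, replace = TRUE,
                 prob = c(rep(1, 7), 3))  # "unknown function" most common
  ann <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = starts, width = lens),
    strand = strands,
    gene_id = sprintf("SYN_%04d", seq_len(n)),
    category = cats)
  list(genome = genome, annotation = ann)
}

.categoryVocabulary <- function() {
  c("TCA cycle", "motility and chemotaxis", "pilus biosynthesis",
    "colanic acid biosynthesis", "iron uptake", "nitrogen metabolism",
    "acid stress", "unknown function")
}

#' Simulate per-gene negative-binomial counts with known truth
#'
#' Draws a genes-by-samples count matrix under the four-condition triplicate
#' design. A `deFraction` of genes receives condition-specific effects with
#' log-uniform fold changes over `foldChangeRange`, including patterns with
#' very large inductions and condition-specific shutoffs. Counts are
#' NB(mu, phi); `dispersion = 0` degenerates to Poisson.
#'
#' @param annotation gene annotation from [simulateGenome()]
#' @param config a [simConfig()]
#' @return list with `counts` (integer matrix, genes x samples), `design`
#'   (data.frame: sample, condition, replicate) and `truth` (per-gene
#'   per-condition means `mu`, `pattern`, `foldChange`, and `deFlags`, a
#'   logical genes x contrasts matrix for the four pairwise contrasts)
#' @export
simulateCounts <- function(annotation, config) {
  stopifnot(is(config, "SimConfig"))
  if (length(annotation) == 0L) stop("annotation must be nonempty")
  if (config@dispersion < 0) stop("dispersion must be >= 0")
  set.seed(config@seed + 1L)
  n <- length(annotation)
  conds <- config@conditions
  genes <- annotation$gene_id
  base <- rlnorm(n, meanlog = log(60), sdlog = 1)
  mu <- matrix(base, n, length(conds), dimnames = list(genes, conds))
  nDE <- round(config@deFraction * n)
  pattern <- rep("flat", n)
  fc <- rep(1, n)
  if (nDE > 0L) {
    de <- sample.int(n, nDE)
    pattern[de] <- sample(c("S_up", "S_down", "late_S_up", "time_up", "S_shutoff"),
                          nDE, replace = TRUE,
                          prob = c(0.3, 0.2, 0.25, 0.15, 0.1))
    fc[de] <- exp(runif(nDE, log(config@foldChangeRange[1]),
                        log(config@foldChangeRange[2])))
    for (i in de) {
      f <- fc[i]
      mu[i, ] <- switch(pattern[i],
        S_up      = base[i] * c(1, 1, f, f)[match(conds, c("L6", "L12", "S6", "S12"))],
        S_down    = base[i] * c(f, f, 1, 1)[match(conds, c("L6", "L12", "S6", "S12"))],
        late_S_up = base[i] * c(1, 1, 1, f)[match(conds, c("L6", "L12", "S6", "S12"))],
        time_up   = base[i] * c(1, f, 1, f)[match(conds, c("L6", "L12", "S6", "S12"))],
        S_shutoff = pmax(base[i] * c(f, f, 0, 0)[match(conds, c("L6", "L12", "S6", "S12"))], 0.02))
    }
  }
  # scale so the average library has about readsPerSample reads
  mu <- mu * config@readsPerSample / mean(colSums(mu))
  design <- data.frame(
    sample = paste(rep(conds, each = config@replicates),
                   seq_len(config@replicates), sep = "_"),
    condition = rep(conds, each = config@replicates),
    replicate = rep(seq_len(config@replicates), length(conds)),
    stringsAsFactors = FALSE)
  counts <- matrix(0L, n, nrow(design), dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    m <- mu[, design$condition[j]]
    counts[, j] <- if (config@dispersion == 0) rpois(n, m)
                   else rnbinom(n, mu = m, size = 1 / config@dispersion)
  }
  cts <- designContrasts()
  deFlags <- vapply(cts, function(ab) {
    abs(log(mu[, ab[1]] / mu[, ab[2]])) > 1e-9
  }, logical(n))
  rownames(deFlags) <- genes
  list(counts = counts, design = design,
       truth = list(mu = mu, pattern = pattern, foldChange = fc,
                    deFlags = deFlags))
}

#' Simulate 71 nt single-end reads and write FASTQ files
#'
#' For every gene and sample, emits as many reads as the count matrix states,
#' with start positions uniform over placements keeping the read inside the
#' gene body. By default the library is unstranded: each read comes from
#' either strand with probability 1/2. Substitution errors are applied at the
#' configured per-base rate; qualities are a constant placeholder (`I`) since
#' they are never used downstream. Read names encode the true origin
#' (`gene|position|strand`) so mapping can be validated.
#'
#' @param genome genome `DNAStringSet` from [simulateGenome()]
#' @param annotation matching `GRanges` annotation
#' @param counts genes x samples matrix from [simulateCounts()]
#' @param config the same [simConfig()]
#' @param dir output directory for per-sample FASTQ files
#' @return named character vector of FASTQ paths (one per sample)
#' @export
simulateReads <- function(genome, annotation, counts, config, dir) {
  stopifnot(is(config, "SimConfig"))
  if (!identical(rownames(counts), annotation$gene_id))
    stop("counts rows must align with the annotation")
  if (any(GenomicRanges::width(annotation) < config@readLength))
    stop("gene shorter than readLength")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config@seed + 2L)
  fwd <- as.character(genome[[1]])
  L <- config@readLength
  starts0 <- GenomicRanges::start(annotation)
  ends0 <- GenomicRanges::end(annotation)
  gstrand <- as.character(GenomicRanges::strand(annotation))
  paths <- character(0)
  for (s in colnames(counts)) {
    cnt <- counts[, s]
    idx <- rep(seq_along(cnt), cnt)
    nr <- length(idx)
    path <- file.path(dir, paste0(s, ".fastq"))
    if (nr == 0L) {
      file.create(path)
      paths[s] <- path
      next
    }
    p <- starts0[idx] + floor(runif(nr) * (ends0[idx] - starts0[idx] - L + 2L))
    rs <- if (config@stranded) gstrand[idx] else sample(c("+", "-"), nr, TRUE)
    seqs <- substring(fwd, p, p + L - 1L)
    minus <- rs == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    if (config@errorRate > 0) {
      nerr <- rbinom(nr, L, config@errorRate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(L, nerr[i])
        ch <- strsplit(seqs[i], "")[[1]]
        for (q in pos) ch[q] <- sample(setdiff(c("A", "C", "G", "T"), ch[q]), 1)
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    ids <- sprintf("@%s:%d %s|%d|%s", s, seq_len(nr),
                   annotation$gene_id[idx], p, rs)
    qual <- strrep("I", L)
    writeLines(as.vector(rbind(ids, seqs, "+", qual)), path)
    paths[s] <- path
  }
  paths
}

#' Simulate a signed regulon with a known sign-consistent edge subset
#'
#' Builds a RegulonDB-style edge list among the simulated genes together with
#' an ortholog map to an invented reference organism. Exactly
#' `round(consistentFraction * nEdges)` edges are constructed so that their
#' sign agrees with the supplied expression differences (activation: regulator
#' and target change in the same direction; repression: opposite directions;
#' dual: any direction provided both endpoints change). The remaining edges
#' are made inconsistent either by an incompatible sign label or by touching
#' an unchanged gene. The ortholog map is a bijection on a subset of genes;
#' a few reference-only genes and edges are added to exercise projection
#' drop-out.
#'
#' @param annotation gene annotation (`>= 2` genes)
#' @param delta per-gene expression differences from [deltaExpression()]
#'   (columns `gene`, `delta`, `sign`)
#' @param nRegulators number of regulator genes
#' @param targetsPerRegulator targets per regulator
#' @param consistentFraction fraction of edges built sign-consistent
#' @param seed integer seed
#' @return list with `reference` (a [RegulatoryNetwork-class] in reference
#'   gene ids), `orthologs` (data.frame reference/study), `study` (the same
#'   network in study ids, i.e. the expected projection), and `consistent`
#'   (data.frame of the edges constructed to be sign-consistent, study ids)
#' @export
simulateRegulon <- function(annotation, delta, nRegulators = 8,
                            targetsPerRegulator = 6, consistentFraction = 0.8,
                            seed = 1) {
  if (length(annotation) < 2L) stop("need at least 2 genes")
  if (consistentFraction < 0 || consistentFraction > 1)
    stop("consistentFraction must be in [0, 1]")
  set.seed(seed)
  genes <- annotation$gene_id
  sgn <- stats::setNames(delta$sign, delta$gene)[genes]
  sgn[is.na(sgn)] <- 0L
  changed <- genes[sgn != 0L]
  unchanged <- genes[sgn == 0L]
  nEdges <- nRegulators * targetsPerRegulator
  nCons <- round(consistentFraction * nEdges)
  if (length(changed) < nRegulators + 1L && nCons > 0L)
    stop("not enough expression-responsive genes to build consistent edges")
  regulators <- sample(changed, min(nRegulators, length(changed)))
  if (length(regulators) < nRegulators)
    regulators <- c(regulators,
                    sample(unchanged, nRegulators - length(regulators)))
  # candidate (regulator, target) pairs, no self-duplicates
  pairs <- expand.grid(regulator = regulators, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  pairs$tchanged <- sgn[pairs$target] != 0L
  pairs$rchanged <- sgn[pairs$regulator] != 0L
  consPool <- which(pairs$rchanged & pairs$tchanged)
  inconPool <- setdiff(seq_len(nrow(pairs)), integer(0))
  if (length(consPool) < nCons)
    stop("not enough changed gene pairs for the requested consistent edges")
  consIdx <- sample(consPool, nCons)
  restPool <- setdiff(inconPool, consIdx)
  nIncon <- nEdges - nCons
  inconIdx <- sample(restPool, nIncon)
  mkSign <- function(i, consistent) {
    r <- sgn[pairs$regulator[i]]; t <- sgn[pairs$target[i]]
    if (consistent) {
      if (runif(1) < 0.15) "dual"
      else if (r == t) "activation" else "repression"
    } else {
      if (r != 0L && t != 0L) {
        # both changed: attach the incompatible sign
        if (r == t) "repression" else "activation"
      } else sample(c("activation", "repression"), 1)
    }
  }
  edges <- rbind(
    if (nCons) data.frame(regulator = pairs$regulator[consIdx],
                          target = pairs$target[consIdx],
                          sign = vapply(consIdx, mkSign, "", consistent = TRUE)),
    if (nIncon) data.frame(regulator = pairs$regulator[inconIdx],
                           target = pairs$target[inconIdx],
                           sign = vapply(inconIdx, mkSign, "", consistent = FALSE)))
  study <- regulatoryNetwork(edges)
  consistent <- data.frame(regulator = pairs$regulator[consIdx],
                           target = pairs$target[consIdx],
                           stringsAsFactors = FALSE)
  # ortholog map: bijection on edge genes plus ~90% of the others
  edgeGenes <- unique(c(edges$regulator, edges$target))
  others <- setdiff(genes, edgeGenes)
  mapped <- c(edgeGenes, sample(others, floor(0.9 * length(others))))
  orth <- data.frame(reference = sprintf("K12_%04d", seq_along(mapped)),
                     study = mapped, stringsAsFactors = FALSE)
  toRef <- stats::setNames(orth$reference, orth$study)
  refEdges <- data.frame(regulator = unname(toRef[edges$regulator]),
                         target = unname(toRef[edges$target]),
                         sign = edges$sign, stringsAsFactors = FALSE)
  # reference-only genes whose edges must drop out at projection
  extraRef <- sprintf("K12_X%02d", 1:2)
  refEdges <- rbind(refEdges,
                    data.frame(regulator = c(extraRef[1], unname(toRef[edgeGenes[1]])),
                               target = c(unname(toRef[edgeGenes[1]]), extraRef[2]),
                               sign = c("activation", "repression")))
  list(reference = regulatoryNetwork(refEdges), orthologs = orth,
       study = study, consistent = consistent)
}

#' Synthetic benchmark expression table for strongly responsive genes
#'
#' A small, fully synthetic stand-in for a published normalized-expression
#' summary table: for a set of benchmark genes with literature-reported fold
#' inductions between carbon sources (acetoin/2,3-butanediol synthesis
#' \emph{budABC}, indole-3-pyruvate decarboxylase \emph{ipdC}, sucrose
#' phosphorylase \emph{ycjM}, the hemin-transport \emph{hmu} operon, the
#' nitrate-assimilation \emph{nasAB-nrtCBA-nasR} cluster, and acid-shock
#' \emph{asr}), triplicate normalized values are drawn per condition with
#' log-normal replicate scatter around means whose ratios equal the target
#' fold changes. The table carries its own ground truth so that fold-change
#' recovery can be benchmarked; it contains no measured data.
#'
#' @param seed integer seed
#' @param cv multiplicative replicate coefficient of variation (default 0.05,
#'   typical technical scatter of normalized values for well-expressed genes)
#' @return list with `expr` (genes x 12 samples), `conditions` (label per
#'   column) and `truth` (data.frame: gene, contrast, fold)
#' @export
syntheticBenchmarkTable <- function(seed = 1, cv = 0.05) {
  set.seed(seed)
  conds <- c("L6", "L12", "S6", "S12")
  # per-gene condition means: baseline, then the targeted inductions
  genes <- list(
    # gene = c(L6, L12, S6, S12)
    budA = c(15, 15, 12000, 15 * 1321),
    budB = c(18, 18, 11000, 18 * 1054),
    budC = c(40, 40, 8000, 40 * 283),
    ipdC = c(120, 110, 300, 110 * 8),
    ycjM = c(25, 25, 30, 30 * 76),      # induced late on sucrose vs S6
    hmuR = c(12, 12, 400, 12 * 150),
    hmuS = c(10, 10, 350, 10 * 130),
    hmuT = c(14, 14, 380, 14 * 120),
    hmuU = c(11, 11, 300, 11 * 110),
    asr  = c(20, 18, 20 * 40, 18 * 1000)
  )
  # nitrate-assimilation cluster: six genes averaging 20-fold S12 vs L12
  nasFc <- c(12, 15, 18, 22, 26, 27)
  nasFc <- nasFc * 20 / mean(nasFc)
  for (i in seq_along(nasFc)) {
    b <- 30 + 5 * i
    genes[[paste0("nas", LETTERS[i])]] <- c(b, b, 3 * b, b * nasFc[i])
  }
  mu <- do.call(rbind, genes)
  colnames(mu) <- conds
  conditions <- rep(conds, each = 3)
  expr <- mu[, conditions] * matrix(rlnorm(length(mu[, conditions]),
                                           -cv^2 / 2, cv),
                                    nrow(mu))
  colnames(expr) <- paste(conditions, rep(1:3, 4), sep = "_")
  truth <- data.frame(
    gene = c("budA", "budB", "budC", "ipdC", "ycjM", "asr"),
    contrast = c(rep("S12_vs_L12", 4), "S12_vs_S6", "S12_vs_L12"),
    fold = c(1321, 1054, 283, 8, 76, 1000))
  list(expr = expr, conditions = conditions, truth = truth)
}
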