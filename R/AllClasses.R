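#' Simulation configuration
#'
#' Parameters of the synthetic study: a small annotated bacterial genome,
#' negative-binomial per-gene counts with condition-specific effects, and
#' 71 nt single-end reads drawn from gene bodies. Defaults mirror the study
#' design: four conditions (lactate/sucrose at 6 h and 12 h) in triplicate,
#' 71 nt reads, and fold changes reaching the >1000-fold inductions seen for
#' strongly carbon-source-responsive operons.
#'
#' @slot genomeLength genome size in bases
#' @slot geneCount number of genes to place
#' @slot geneLengthRange min/max gene length (bases)
#' @slot readLength read length in bases (71 for this protocol)
#' @slot readsPerSample expected sequenced reads per library
#' @slot replicates biological replicates per condition
#' @slot conditions ordered condition labels
#' @slot dispersion negative-binomial dispersion phi (0 = Poisson)
#' @slot deFraction fraction of genes given condition effects
#' @slot foldChangeRange range of simulated fold changes (log-uniform)
#' @slot errorRate per-base substitution probability of the sequencer
#' @slot circular whether the genome is circular
#' @slot stranded if TRUE reads come from the gene strand only; default
#'   unstranded (either strand with probability 1/2)
#' @slot seed integer seed making every simulation reproducible
#'
#' @exportClass SimConfig
setClass("SimConfig", representation(
  genomeLength = "integer", geneCount = "integer",
  geneLengthRange = "integer", readLength = "integer",
  readsPerSample = "integer", replicates = "integer",
  conditions = "character", dispersion = "numeric",
  deFraction = "numeric", foldChangeRange = "numeric",
  errorRate = "numeric", circular = "logical",
  stranded = "logical", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be positive")
  if (object@geneCount < 0L) msg <- c(msg, "geneCount must be >= 0")
  if (length(object@geneLengthRange) != 2L ||
      object@geneLengthRange[1] > object@geneLengthRange[2])
    msg <- c(msg, "geneLengthRange must be (min, max) with min <= max")
  if (object@geneCount > 0L &&
      as.numeric(object@geneCount) * object@geneLengthRange[2] > object@genomeLength)
    msg <- c(msg, "infeasible packing: geneCount * max gene length exceeds genomeLength")
  if (object@geneCount > 0L && object@readLength > object@geneLengthRange[1])
    msg <- c(msg, "readLength must not exceed the minimum gene length")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must be in [0, 1]")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must be in [0, 1]")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@foldChangeRange <= 0))
    msg <- c(msg, "foldChangeRange must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param genomeLength,geneCount,geneLengthRange,readLength,readsPerSample,
#'   replicates,conditions,dispersion,deFraction,foldChangeRange,errorRate,
#'   circular,stranded,seed see the [SimConfig-class] slots
#' @return a validated `SimConfig` object
#' @examples
#' cfg <- simConfig(genomeLength = 20000, geneCount = 15, seed = 1)
#' @export
simConfig <- function(genomeLength = 150000, geneCount = 80,
                      geneLengthRange = c(300, 1500), readLength = 71,
                      readsPerSample = 50000, replicates = 3,
                      conditions = c("L6", "L12", "S6", "S12"),
                      dispersion = 0.1, deFraction = 0.15,
                      foldChangeRange = c(2, 1500), errorRate = 0.005,
                      circular = TRUE, stranded = FALSE, seed = 1) {
  new("SimConfig",
      genomeLength = as.integer(genomeLength),
      geneCount = as.integer(geneCount),
      geneLengthRange = as.integer(geneLengthRange),
      readLength = as.integer(readLength),
      readsPerSample = as.integer(readsPerSample),
      replicates = as.integer(replicates),
      conditions = as.character(conditions),
      dispersion = as.numeric(dispersion),
      deFraction = as.numeric(deFraction),
      foldChangeRange = as.numeric(foldChangeRange),
      errorRate = as.numeric(errorRate),
      circular = isTRUE(circular),
      stranded = isTRUE(stranded),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@geneCount, "genes on a",
      object@genomeLength, "bp", if (object@circular) "circular" else "linear",
      "genome\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "),
      "x", object@replicates, "replicates;",
      object@readsPerSample, "reads/sample of", object@readLength, "nt\n")
  cat("  NB dispersion:", object@dispersion,
      "; DE fraction:", object@deFraction,
      "; error rate:", object@errorRate, "\n")
})

#' Suffix-array index of a genome
#'
#' The search text is the genome (extended by `readLength - 1` wrap-around
#' bases when circular) optionally concatenated, through a sentinel that can
#' match no base, with its reverse complement so that hits on either strand
#' are found in one lookup. Positions are reported as 1-based leftmost
#' coordinates on the forward genome with a strand flag.
#'
#' @slot text the indexed search text
#' @slot sa integer suffix array (0-based positions, lexicographic order)
#' @slot genomeLength length of the underlying genome in bases
#' @slot fwdLength length of the forward half of the text
#' @slot strandMode `"both_strands"` or `"forward_only"`
#' @slot circular whether wrap-around matches are allowed
#'
#' @exportClass SuffixIndex
setClass("SuffixIndex", representation(
  text = "character", sa = "integer", genomeLength = "integer",
  fwdLength = "integer", strandMode = "character", circular = "logical"
))

setValidity("SuffixIndex", function(object) {
  n <- nchar(object@text)
  if (length(object@sa) != n)
    return("suffix array length must equal text length")
  if (n > 1L) {
    # spot-check sortedness on a handful of adjacent pairs (byte order, not
    # locale collation, must be used: the sentinel sorts below the bases)
    idx <- unique(as.integer(seq(1L, n - 1L, length.out = min(25L, n - 1L))))
    ok <- vapply(idx, function(i) {
      a <- substr(object@text, object@sa[i] + 1L, object@sa[i] + 50L)
      b <- substr(object@text, object@sa[i + 1L] + 1L, object@sa[i + 1L] + 50L)
      .byteLE(a, b)
    }, logical(1))
    if (!all(ok)) return("suffix array is not sorted")
  }
  TRUE
})

setMethod("show", "SuffixIndex", function(object) {
  cat("SuffixIndex over a", object@genomeLength, "bp",
      if (object@circular) "circular" else "linear", "genome (",
      object@strandMode, "), text length", nchar(object@text), "\n")
})

#' Signed regulatory network
#'
#' A directed edge list (regulator, target) with sign `activation`,
#' `repression` or `dual`. Duplicate (regulator, target) pairs with
#' conflicting signs are collapsed to `dual` at construction.
#'
#' @slot edges data.frame with columns `regulator`, `target`, `sign`
#'
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork", representation(edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  if (!all(c("regulator", "target", "sign") %in% names(e)))
    return("edges must have columns regulator, target, sign")
  if (nrow(e) && !all(e$sign %in% c("activation", "repression", "dual")))
    return("sign must be activation, repression or dual")
  if (anyDuplicated(paste(e$regulator, e$target, sep = "\r")))
    return("duplicate (regulator, target) pairs are not allowed")
  TRUE
})

#' Construct a regulatory network from an edge data frame
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`; sign
#'   tokens `+`, `-` and `+-` (RegulonDB dialect) are accepted and translated
#' @return a `RegulatoryNetwork`
#' @export
regulatoryNetwork <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
  tok <- c("+" = "activation", "-" = "repression", "+-" = "dual", "-+" = "dual",
           activation = "activation", repression = "repression", dual = "dual")
  bad <- !(edges$sign %in% names(tok))
  if (any(bad))
    stop("malformed sign token at edge line(s): ",
         paste(which(bad), collapse = ", "))
  edges$sign <- unname(tok[edges$sign])
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    sgn <- tapply(edges$sign, key, function(s)
      if (length(unique(s)) > 1L) "dual" else s[1])
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$sign <- unname(sgn[paste(edges$regulator, edges$target, sep = "\r")])
  }
  rownames(edges) <- NULL
  new("RegulatoryNetwork", edges = edges[, c("regulator", "target", "sign")])
}

#' @describeIn regulatoryNetwork number of edges
#' @param x,object a `RegulatoryNetwork`
#' @export
setMethod("length", "RegulatoryNetwork", function(x) nrow(x@edges))

#' Edge table of a regulatory network
#' @param net a `RegulatoryNetwork`
#' @return data.frame with columns regulator, target, sign
#' @export
networkEdges <- function(net) net@edges

setMethod("show", "RegulatoryNetwork", function(object) {
  e <- object@edges
  cat("RegulatoryNetwork:", nrow(e), "edges,",
      length(unique(e$regulator)), "regulators,",
      length(unique(c(e$regulator, e$target))), "genes\n")
  if (nrow(e)) print(head(e, 4))
})
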