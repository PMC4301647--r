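#' Condition-mean expression profiles on the log2 scale
#'
#' Per-gene mean of `log2(value + pseudocount)` over the replicates of each
#' condition, the profile clustered across the four conditions.
#'
#' @param x normalized expression matrix (genes x samples)
#' @param conditions condition label per column
#' @param pseudocount added before the log (default 1)
#' @return matrix genes x conditions (condition order of first appearance)
#' @export
conditionProfiles <- function(x, conditions, pseudocount = 1) {
  conds <- unique(conditions)
  out <- vapply(conds, function(cc)
    rowMeans(log2(x[, conditions == cc, drop = FALSE] + pseudocount)),
    numeric(nrow(x)))
  colnames(out) <- conds
  out
}

#' Spearman correlation distance
#'
#' `d = (1 - rho) / 2` where `rho` is the Spearman rank correlation, so that
#' identical rank patterns have distance 0 and perfectly reversed patterns
#' distance 1. Undefined for constant vectors (rank correlation has no value
#' there).
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return distance in `[0, 1]`
#' @examples
#' spearmanDistance(1:4, c(1, 3, 2, 4))  # (1 - 0.8) / 2 = 0.1
#' @export
spearmanDistance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  (1 - stats::cor(x, y, method = "spearman")) / 2
}

#' Pairwise Spearman distance matrix of expression profiles
#'
#' @param profiles matrix (genes x conditions)
#' @return a `dist` object of `(1 - rho) / 2` values
#' @export
spearmanDistanceMatrix <- function(profiles) {
  as.dist((1 - stats::cor(t(profiles), method = "spearman")) / 2)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering on the Spearman correlation distance, cut into
#' `k` groups. Genes with constant profiles (undefined rank correlation) are
#' excluded with a warning. Average linkage (UPGMA) is the default, the
#' conventional choice for correlation distances; ties are resolved
#' deterministically in input order by `hclust`.
#'
#' @param profiles matrix from [conditionProfiles()] with gene rownames
#' @param k number of clusters (default 5)
#' @param linkage linkage criterion for [stats::hclust()]
#' @return list with `assignment` (named integer vector, 1..k), `tree`
#'   (the `hclust` object) and `excluded` (constant-profile gene names)
#' @export
clusterProfiles <- function(profiles, k = 5, linkage = "average") {
  const <- apply(profiles, 1, function(r) stats::sd(r) == 0)
  if (any(const))
    warning(sum(const), " constant-profile gene(s) excluded from clustering")
  prof <- profiles[!const, , drop = FALSE]
  n <- nrow(prof)
  if (k < 1 || k > n) stop("k must be between 1 and the number of genes")
  tree <- stats::hclust(spearmanDistanceMatrix(prof), method = linkage)
  assignment <- stats::cutree(tree, k = k)
  names(assignment) <- rownames(prof)
  list(assignment = assignment, tree = tree,
       excluded = rownames(profiles)[const])
}

# weighted pool-adjacent-violators: nondecreasing fit of y with weights w
.pava <- function(y, w) {
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_along(y)) {
    v <- y[i]; ww <- w[i]; sz <- 1L
    while (length(vals) && vals[length(vals)] > v) {
      k <- length(vals)
      v <- (vals[k] * wts[k] + v * ww) / (wts[k] + ww)
      ww <- wts[k] + ww
      sz <- sizes[k] + sz
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
    }
    vals <- c(vals, v); wts <- c(wts, ww); sizes <- c(sizes, sz)
  }
  rep(vals, sizes)
}

# monotone probability-weighting function of cluster membership vs gene
# length: the fit is a function of length (tied lengths share one value,
# averaged before the isotonic step), in the orientation (increasing or
# decreasing) with the smaller weighted squared error, floored away from zero
.lengthBiasWeights <- function(member, lengths) {
  ul <- sort(unique(lengths))
  grp <- match(lengths, ul)
  ybar <- as.numeric(tapply(as.numeric(member), grp, mean))
  wgrp <- as.numeric(table(grp))
  up <- .pava(ybar, wgrp)
  dn <- rev(.pava(rev(ybar), rev(wgrp)))
  sseUp <- sum(wgrp * (ybar - up)^2)
  sseDn <- sum(wgrp * (ybar - dn)^2)
  fit <- if (sseUp <= sseDn) up else dn
  pmax(fit[grp], 1e-4)
}

#' Functional-category over-representation within a gene cluster
#'
#' Tests each functional category for over-representation among the genes of
#' one cluster. `mode = "hypergeometric"` uses the one-sided exact
#' hypergeometric tail. The default `mode = "length_aware"` corrects for gene
#' length bias the way RNA-seq-specific enrichment methods do: a monotone
#' probability-weighting function of cluster membership against gene length is
#' fitted, null clusters of the same size are drawn by weighted sampling
#' without replacement, and the p-value is the (add-one smoothed) fraction of
#' resamples whose category overlap reaches the observed one.
#'
#' @param clusterGenes genes of the cluster under test
#' @param universe all analysable genes
#' @param categories data.frame with columns `gene_id`, `category` (a gene may
#'   carry several rows), or a named character vector gene -> category
#' @param lengths named gene lengths in bases (required for `length_aware`)
#' @param mode `"length_aware"` (default) or `"hypergeometric"`
#' @param nResamples null resamples for the length-aware mode (default 10000)
#' @return data.frame: `category`, `overlap` (genes of the category in the
#'   cluster), `size` (category size in the universe), `p`
#' @export
categoryEnrichment <- function(clusterGenes, universe, categories,
                               lengths = NULL,
                               mode = c("length_aware", "hypergeometric"),
                               nResamples = 10000) {
  mode <- match.arg(mode)
  if (!is.data.frame(categories))
    categories <- data.frame(gene_id = names(categories),
                             category = unname(categories),
                             stringsAsFactors = FALSE)
  allCats <- unique(categories$category)
  categories <- categories[categories$gene_id %in% universe, , drop = FALSE]
  catList <- split(categories$gene_id, factor(categories$category, levels = allCats))
  empty <- vapply(catList, length, 1L) == 0L
  if (any(empty)) {
    warning("categories absent from the universe skipped: ",
            paste(names(catList)[empty], collapse = ", "))
    catList <- catList[!empty]
  }
  if (!length(catList)) stop("no category overlaps the universe")
  clusterGenes <- intersect(clusterGenes, universe)
  N <- length(universe)
  kk <- length(clusterGenes)
  obs <- vapply(catList, function(g) length(intersect(g, clusterGenes)), 1L)
  size <- vapply(catList, length, 1L)
  if (mode == "hypergeometric") {
    p <- stats::phyper(obs - 1L, size, N - size, kk, lower.tail = FALSE)
  } else {
    if (is.null(lengths)) stop("length_aware mode needs gene lengths")
    w <- .lengthBiasWeights(universe %in% clusterGenes, lengths[universe])
    inCat <- vapply(catList, function(g) universe %in% g,
                    logical(N))  # N x nCat
    exceed <- integer(length(catList))
    for (r in seq_len(nResamples)) {
      nullIdx <- sample.int(N, kk, prob = w)
      ov <- colSums(inCat[nullIdx, , drop = FALSE])
      exceed <- exceed + (ov >= obs)
    }
    p <- (1 + exceed) / (1 + nResamples)
  }
  data.frame(category = names(catList), overlap = as.integer(obs),
             size = as.integer(size), p = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
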