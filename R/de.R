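# Negative-binomial conditional exact testing on quantile-normalized integer
# expression values. Quantile normalization equalizes effective library sizes,
# so group sums can be conditioned on directly with no offset: the sum of n
# iid NB(mu, phi) variables is NB(n*mu, phi/n), and given the grand total S
# the split between the two groups follows a (negative-) hypergeometric law
# that the test enumerates.

# probability of every split (s, S - s) of the total S between groups with
# nA and nB libraries under H0, common dispersion phi
.splitProbs <- function(S, nA, nB, phi) {
  s <- 0:S
  if (phi == 0) {
    lp <- stats::dbinom(s, S, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    lp <- lgamma(s + rA) - lgamma(s + 1) - lgamma(rA) +
      lgamma(S - s + rB) - lgamma(S - s + 1) - lgamma(rB)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Conditional exact test for one gene
#'
#' Conditions on the total `S` of both groups and computes, under the null of
#' equal means and common NB dispersion `phi`, the probability of every split
#' of `S`; the two-sided p-value is the sum of the probabilities of all splits
#' at most as probable as the observed one. `phi = 0` degenerates to a
#' binomial split with proportion `nA / (nA + nB)` (the Poisson limit, closely
#' paralleling Fisher's exact test). `S = 0` returns p = 1.
#'
#' @param countsA,countsB integer replicate values of the two groups
#' @param phi common negative-binomial dispersion (>= 0)
#' @return two-sided exact p-value
#' @examples
#' exactTestGene(0, 10, phi = 0)  # 2/1024
#' @export
exactTestGene <- function(countsA, countsB, phi = 0) {
  if (phi < 0) stop("dispersion must be >= 0")
  sA <- sum(countsA)
  S <- sA + sum(countsB)
  if (S == 0) return(1)
  p <- .splitProbs(S, length(countsA), length(countsB), phi)
  pobs <- p[sA + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]))
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the log-likelihood of the within-condition replicate counts
#' conditional on their sums, summed over genes and conditions, under a
#' negative-binomial model with one shared dispersion. Equal effective
#' library sizes are assumed (guaranteed upstream by quantile normalization).
#' The 1-D optimization runs on log(phi) to tolerance 1e-6. With no
#' replication anywhere the dispersion is not identifiable and 0 is returned
#' with a warning.
#'
#' @param x integer expression matrix (genes x samples)
#' @param conditions condition label per column of `x`
#' @return list with `phi` (the estimate) and `method` (`"qCML"`)
#' @export
estimateCommonDispersion <- function(x, conditions) {
  stopifnot(ncol(x) == length(conditions))
  groups <- split(seq_len(ncol(x)), conditions)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (!length(groups)) {
    warning("no replicated condition: dispersion not estimable, using 0")
    return(list(phi = 0, method = "qCML"))
  }
  # per-group precomputations
  parts <- lapply(groups, function(j) {
    y <- x[, j, drop = FALSE]
    keep <- rowSums(y) > 0
    list(y = y[keep, , drop = FALSE], S = rowSums(y)[keep], n = length(j))
  })
  negll <- function(logphi) {
    r <- exp(-logphi)  # per-library size parameter 1/phi
    ll <- 0
    for (p in parts) {
      if (!nrow(p$y)) next
      ll <- ll + sum(lgamma(p$y + r)) - nrow(p$y) * p$n * lgamma(r) -
        sum(lgamma(p$S + p$n * r)) + nrow(p$y) * lgamma(p$n * r)
    }
    -ll
  }
  opt <- stats::optimize(negll, interval = c(log(1e-6), log(20)), tol = 1e-6)
  phi <- exp(opt$minimum)
  if (phi <= 1.5e-6) phi <- 0  # boundary: effectively Poisson
  list(phi = phi, method = "qCML")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control with enforced monotonicity.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return adjusted values (q-values)
#' @export
fdrAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Fold change between two conditions
#'
#' Ratio of replicate means, `(meanA + c) / (meanB + c)` with pseudocount `c`.
#' With `c = 0` and a zero denominator the ratio is undefined and reported as
#' NA with a warning (set `pseudocount = 0.5` to stabilise such genes).
#'
#' @param x expression matrix (genes x samples)
#' @param conditions condition label per column
#' @param condA,condB conditions to compare (fold = A over B)
#' @param genes optional subset of rownames
#' @param pseudocount nonnegative constant added to both means (default 0)
#' @return named vector of fold changes
#' @examples
#' m <- cbind(a1 = c(g = 80), a2 = c(g = 80), b1 = c(g = 10), b2 = c(g = 10))
#' foldChange(m, c("A", "A", "B", "B"), "A", "B")  # 8
#' @export
foldChange <- function(x, conditions, condA, condB, genes = NULL,
                       pseudocount = 0) {
  stopifnot(ncol(x) == length(conditions))
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  mA <- rowMeans(x[, conditions == condA, drop = FALSE]) + pseudocount
  mB <- rowMeans(x[, conditions == condB, drop = FALSE]) + pseudocount
  fc <- mA / mB
  und <- mB == 0
  if (any(und)) {
    warning(sum(und), " gene(s) with zero denominator mean: fold change NA")
    fc[und] <- NA_real_
  }
  fc
}

#' Exact-test differential expression for one contrast
#'
#' Runs the conditional exact test gene by gene for one pairwise comparison,
#' reports log2 fold change, log2 concentration (mean read proportion), exact
#' p-values and BH-adjusted FDR. Genes with zero counts in every sample of the
#' contrast are dropped (their p-value is undefined).
#'
#' @param x integer expression matrix (genes x samples)
#' @param conditions condition label per column
#' @param contrast `c(groupA, groupB)` condition labels, or the name of one of
#'   [designContrasts()]
#' @param phi common dispersion; estimated from the contrast samples with
#'   [estimateCommonDispersion()] when NULL
#' @param pseudocount added to the group means for logFC when either is zero
#'   (default 0.5); means both positive use the raw ratio
#' @return data.frame: `gene_id`, `logConc`, `logFC`, `PValue`, `FDR`, `smear`
#'   (TRUE when one group's mean is zero)
#' @export
exactTestContrast <- function(x, conditions, contrast, phi = NULL,
                              pseudocount = 0.5) {
  if (is.character(contrast) && length(contrast) == 1L)
    contrast <- designContrasts()[[contrast]]
  jA <- which(conditions == contrast[1])
  jB <- which(conditions == contrast[2])
  if (!length(jA) || !length(jB)) stop("contrast conditions absent from data")
  sub <- x[, c(jA, jB), drop = FALSE]
  keep <- rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  if (is.null(phi))
    phi <- estimateCommonDispersion(sub, conditions[c(jA, jB)])$phi
  A <- sub[, seq_along(jA), drop = FALSE]
  B <- sub[, length(jA) + seq_along(jB), drop = FALSE]
  pv <- vapply(seq_len(nrow(sub)), function(i)
    exactTestGene(A[i, ], B[i, ], phi), numeric(1))
  mA <- rowMeans(A); mB <- rowMeans(B)
  smear <- mA == 0 | mB == 0
  c0 <- ifelse(smear, pseudocount, 0)
  logFC <- log2((mA + c0) / (mB + c0))
  props <- sweep(sub, 2, colSums(x[, c(jA, jB), drop = FALSE]), "/")
  logConc <- log2(rowMeans(props))
  data.frame(gene_id = rownames(sub), logConc = logConc, logFC = logFC,
             PValue = pv, FDR = fdrAdjust(pv), smear = smear,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' MA-plot coordinates for a contrast
#'
#' Per-gene log2 concentration (mean proportion of a sample's reads assigned
#' to the gene, across the contrast's samples) against log2 fold change.
#' Genes expressed in neither group are excluded; genes with zero counts in
#' exactly one group form the "smear" class at the left edge of the plot.
#'
#' @inheritParams exactTestContrast
#' @return data.frame: `gene_id`, `logConc`, `logFC`, `smear`
#' @export
maValues <- function(x, conditions, contrast, pseudocount = 0.5) {
  de <- exactTestContrast(x, conditions, contrast, phi = 0,
                          pseudocount = pseudocount)
  de[, c("gene_id", "logConc", "logFC", "smear")]
}

#' Call differentially expressed genes
#'
#' A gene is significant when `FDR < fdrThreshold` and
#' `|logFC| > logfcThreshold`. The methods default is FDR 0.05 with no fold
#' cutoff; `preset = "ma_highlight"` applies the MA-plot highlighting rule
#' (FDR < 0.1 and |logFC| > 1).
#'
#' @param de data.frame from [exactTestContrast()]
#' @param fdrThreshold FDR cutoff (default 0.05)
#' @param logfcThreshold absolute log2-fold-change cutoff (default 0)
#' @param preset `"ma_highlight"` overrides the thresholds to (0.1, 1)
#' @return the input with a logical `significant` column
#' @export
callDE <- function(de, fdrThreshold = 0.05, logfcThreshold = 0,
                   preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "ma_highlight")
    fdrThreshold <- 0.1
    logfcThreshold <- 1
  }
  stopifnot(fdrThreshold >= 0, fdrThreshold <= 1, logfcThreshold >= 0)
  de$significant <- de$FDR < fdrThreshold & abs(de$logFC) > logfcThreshold
  de
}
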