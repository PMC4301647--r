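# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's suffix-array / dbinom code paths.

# Hamming-scan read mapper: compares every window of the (optionally
# circularly extended) genome, on both strands, against each read. N matches
# no base on either side.
naiveMap <- function(genomeStr, reads, circular = FALSE, bothStrands = TRUE) {
  m <- nchar(reads[1])
  stopifnot(all(nchar(reads) == m))
  L <- nchar(genomeStr)
  ext <- if (circular) paste0(genomeStr, substr(genomeStr, 1, m - 1)) else genomeStr
  np <- if (circular) L else L - m + 1L
  raws <- charToRaw(ext)
  raws[raws == charToRaw("N")] <- as.raw(1L)  # genome N matches nothing
  W <- matrix(raws[outer(0:(m - 1L), seq_len(np), "+")], nrow = m)
  res <- data.frame(status = character(length(reads)),
                    position = NA_integer_, strand = NA_character_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    clean <- gsub("[^ACGT]", "N", reads[i])
    r <- charToRaw(clean)
    r[r == charToRaw("N")] <- as.raw(2L)  # read N matches nothing
    mmF <- colSums(W != r)
    hF <- which(mmF <= 1L)
    hits <- data.frame(position = hF, strand = rep("+", length(hF)),
                       mm = mmF[hF])
    if (bothStrands) {
      rc <- charToRaw(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(clean))))
      rc[rc == charToRaw("N")] <- as.raw(2L)
      mmR <- colSums(W != rc)
      hR <- which(mmR <= 1L)
      hits <- rbind(hits, data.frame(position = hR,
                                     strand = rep("-", length(hR)),
                                     mm = mmR[hR]))
    }
    if (circular) hits$position <- (hits$position - 1L) %% L + 1L
    ex <- hits[hits$mm == 0L, , drop = FALSE]
    one <- hits[hits$mm == 1L, , drop = FALSE]
    if (nrow(ex) == 1L) {
      res[i, ] <- list("unique_exact", ex$position, ex$strand, 0L)
    } else if (nrow(ex) >= 2L) {
      res$status[i] <- "ambiguous"
    } else if (nrow(one) == 1L) {
      res[i, ] <- list("unique_one_mismatch", one$position, one$strand, 1L)
    } else if (nrow(one) >= 2L) {
      res$status[i] <- "ambiguous"
    } else {
      res$status[i] <- "unmapped"
    }
  }
  res
}

# k-mer uniqueness by hash counting, independent of the vectorised code path
naiveKmerUniqueness <- function(genomeStr, k, bothStrands = TRUE,
                                circular = FALSE) {
  L <- nchar(genomeStr)
  ext <- if (circular) paste0(genomeStr, substr(genomeStr, 1, k - 1)) else genomeStr
  np <- if (circular) L else L - k + 1L
  kmers <- vapply(seq_len(np), function(i) substr(ext, i, i + k - 1L), "")
  kmers <- kmers[!grepl("N", kmers)]
  fwd <- table(kmers)
  cnt <- as.integer(fwd[kmers])
  if (bothStrands) {
    rc <- vapply(kmers, function(km) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(km))), "")
    rcCnt <- as.integer(fwd[rc])
    rcCnt[is.na(rcCnt)] <- 0L
    cnt <- cnt + rcCnt
  }
  mean(cnt == 1L)
}

# full-enumeration two-sided exact p at phi = 0 via log-binomial coefficients
enumBinomExactP <- function(sA, sB, nA = 1L, nB = 1L) {
  S <- sA + sB
  if (S == 0) return(1)
  s <- 0:S
  lp <- lchoose(S, s) + s * log(nA / (nA + nB)) + (S - s) * log(nB / (nA + nB))
  pr <- exp(lp)
  sum(pr[pr <= pr[sA + 1L] * (1 + 1e-10)]) / sum(pr)
}

randomGenome <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

mutateRead <- function(read, k) {
  ch <- strsplit(read, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# tiny simulation config shared by several files (any default overridable)
tinyConfig <- function(seed = 7, ...) {
  args <- list(genomeLength = 20000, geneCount = 15,
               geneLengthRange = c(200, 900), readsPerSample = 1200,
               errorRate = 0.005, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}
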