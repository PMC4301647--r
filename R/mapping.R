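#' Fraction of genome k-mers occurring exactly once
#'
#' Mappability proxy used to justify mapping with short (trimmed) reads: the
#' fraction of k-mer start positions whose k-mer sequence occurs exactly once
#' in the search text. With `strandMode = "both_strands"` an occurrence of the
#' reverse complement also counts (a k-mer matching both strands, e.g. a
#' palindrome, is not unique). Circular genomes wrap across the origin.
#' Positions whose k-mer contains N are excluded.
#'
#' @param genome a `DNAStringSet`/`DNAString` or a plain DNA string
#' @param k k-mer length (>= 1, <= genome length)
#' @param strandMode `"both_strands"` (default) or `"forward_only"`
#' @param circular whether the genome is circular; defaults to the flag stored
#'   by [simulateGenome()], else FALSE
#' @return fraction in `[0, 1]`
#' @examples
#' kmerUniqueness("ACGTACGTA", k = 4, strandMode = "forward_only",
#'                circular = FALSE)  # 2/6
#' @export
kmerUniqueness <- function(genome, k,
                           strandMode = c("both_strands", "forward_only"),
                           circular = NULL) {
  strandMode <- match.arg(strandMode)
  s <- .genomeString(genome)
  if (is.null(circular)) circular <- .genomeCircular(genome)
  L <- nchar(s)
  if (k > L) stop("k exceeds the genome length")
  ext <- if (circular) paste0(s, substr(s, 1L, k - 1L)) else s
  np <- if (circular) L else L - k + 1L
  kmers <- substring(ext, seq_len(np), seq_len(np) + k - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  kmers <- kmers[valid]
  if (!length(kmers)) return(NaN)
  u <- unique(kmers)
  cnt <- tabulate(match(kmers, u), nbins = length(u))
  tot <- cnt
  if (strandMode == "both_strands") {
    rcu <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
    rcCnt <- cnt[match(rcu, u)]
    rcCnt[is.na(rcCnt)] <- 0L
    tot <- cnt + rcCnt
  }
  mean(tot[match(kmers, u)] == 1L)
}

#' Trim fixed numbers of bases from both read ends
#'
#' The sequencing protocol yields 71 nt reads whose extremities have lower
#' quality; by default 4 bases are removed from the 5' end and 31 from the 3'
#' end, leaving a 36 nt mapped segment. Reads of unexpected length are skipped
#' with a warning and counted.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences
#' @param trim5 bases removed from the 5' end (default 4)
#' @param trim3 bases removed from the 3' end (default 31)
#' @param mappedLength length of the retained segment (default 36); reads must
#'   be exactly `trim5 + trim3 + mappedLength` long
#' @return list with `reads` (trimmed sequences), `kept` (logical index into
#'   the input) and `skipped` (number of wrong-length reads)
#' @export
trimReads <- function(reads, trim5 = 4L, trim3 = 31L, mappedLength = 36L) {
  reads <- as.character(reads)
  want <- trim5 + trim3 + mappedLength
  kept <- nchar(reads) == want
  if (any(!kept))
    warning(sum(!kept), " read(s) skipped: length != ", want)
  list(reads = substr(reads[kept], trim5 + 1L, trim5 + mappedLength),
       kept = kept, skipped = sum(!kept))
}

.genomeString <- function(genome) {
  if (is(genome, "DNAStringSet")) toupper(as.character(genome[[1]]))
  else if (is(genome, "DNAString")) toupper(as.character(genome))
  else toupper(as.character(genome)[1])
}

.genomeCircular <- function(genome) {
  if (is(genome, "DNAStringSet")) isTRUE(S4Vectors::metadata(genome)$circular)
  else FALSE
}

#' Build a suffix-array index of a genome
#'
#' Constructs the search text (genome, extended by `readLength - 1`
#' wrap-around bases when circular, concatenated through a `#` sentinel with
#' its reverse complement in `both_strands` mode) and its suffix array.
#'
#' @param genome genome sequence (see [kmerUniqueness()])
#' @param strandMode `"both_strands"` (default) or `"forward_only"`
#' @param circular circular genome flag; defaults to the stored flag
#' @param readLength maximum query length that may wrap the origin (36 for
#'   the default trimming scheme)
#' @return a [SuffixIndex-class]
#' @export
buildIndex <- function(genome, strandMode = c("both_strands", "forward_only"),
                       circular = NULL, readLength = 36L) {
  strandMode <- match.arg(strandMode)
  s <- .genomeString(genome)
  if (nchar(s) == 0L) stop("genome must be nonempty")
  if (is.null(circular)) circular <- .genomeCircular(genome)
  pad <- if (circular) readLength - 1L else 0L
  fwd <- paste0(s, substr(s, 1L, pad))
  text <- if (strandMode == "both_strands")
    paste0(fwd, "#", .revcomp(fwd)) else fwd
  new("SuffixIndex", text = text, sa = .sa_build(text),
      genomeLength = nchar(s), fwdLength = nchar(fwd),
      strandMode = strandMode, circular = circular)
}

#' Exact occurrences of a query in an indexed genome
#'
#' @param index a [SuffixIndex-class]
#' @param query DNA string; a query containing N matches nothing
#' @return data.frame with 1-based leftmost genome `position` and `strand`
#' @examples
#' idx <- buildIndex("ACACA", strandMode = "forward_only", circular = FALSE)
#' lookupIndex(idx, "ACA")  # positions 1 and 3
#' @export
lookupIndex <- function(index, query) {
  stopifnot(is(index, "SuffixIndex"), nchar(query) >= 1L)
  if (grepl("[^ACGT]", query))
    return(data.frame(position = integer(), strand = character()))
  p0 <- .sa_find(index@text, index@sa, query)
  if (!length(p0))
    return(data.frame(position = integer(), strand = character()))
  m <- nchar(query)
  fwd <- p0 < index@fwdLength
  pos <- integer(length(p0)); strand <- character(length(p0))
  pos[fwd] <- p0[fwd] %% index@genomeLength + 1L
  strand[fwd] <- "+"
  if (any(!fwd)) {
    q <- p0[!fwd] - index@fwdLength - 1L
    pos[!fwd] <- (index@fwdLength - q - m) %% index@genomeLength + 1L
    strand[!fwd] <- "-"
  }
  o <- order(pos, strand)
  data.frame(position = pos[o], strand = strand[o])
}

#' Map trimmed reads with the unique-hit acceptance policy
#'
#' Each read is placed by exact suffix-array lookup; reads without an exact
#' hit are retried allowing one mismatch (by exact lookups of every
#' single-base variant). Acceptance: exactly one exact hit gives
#' `unique_exact`; no exact hit and exactly one 1-mismatch hit gives
#' `unique_one_mismatch`; any multiplicity gives `ambiguous`; no hit at all
#' gives `unmapped`. Only `unique_*` reads carry a position and are used for
#' counting. N matches no base, so a read with one N can at best map with one
#' mismatch and a read with two or more Ns is unmapped.
#'
#' @param index a [SuffixIndex-class]
#' @param reads character vector (or `DNAStringSet`) of trimmed reads
#' @param readIds optional read identifiers (default `read_1`, ...)
#' @return data.frame: `read_id`, `status` (one of `unique_exact`,
#'   `unique_one_mismatch`, `ambiguous`, `unmapped`), `position` (1-based
#'   leftmost genome coordinate or NA), `strand` (`+`/`-` or NA),
#'   `mismatches` (0, 1 or NA)
#' @export
mapReads <- function(index, reads, readIds = NULL) {
  stopifnot(is(index, "SuffixIndex"))
  reads <- toupper(as.character(reads))
  if (any(nchar(reads) == 0L)) stop("empty read")
  if (index@circular) {
    m0 <- index@fwdLength - index@genomeLength + 1L
    if (any(nchar(reads) != m0))
      stop("a circular index built for ", m0, " nt queries cannot map reads ",
           "of other lengths (origin-wrapping hits would be miscounted)")
  }
  if (is.null(readIds)) readIds <- paste0("read_", seq_along(reads))
  res <- .sa_map_reads(index@text, index@sa, reads,
                       index@fwdLength, index@genomeLength)
  status <- c("unmapped", "unique_exact", "unique_one_mismatch",
              "ambiguous")[res$status + 1L]
  data.frame(read_id = readIds, status = status, position = res$position,
             strand = res$strand, mismatches = res$mismatches,
             stringsAsFactors = FALSE)
}
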