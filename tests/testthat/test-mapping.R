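test_that("k-mer uniqueness matches enumeration on hand-checked genomes", {
  # ACGTACGTA, k=4, forward: kmers ACGT,CGTA,GTAC,TACG,ACGT,CGTA -> 2/6 unique
  expect_equal(kmerUniqueness("ACGTACGTA", 4, "forward_only", circular = FALSE),
               2 / 6)
  # all k-mers distinct
  expect_equal(kmerUniqueness("ACGT", 2, "forward_only", circular = FALSE), 1)
  # homopolymer: every k-mer identical
  expect_equal(kmerUniqueness("AAAAAA", 3, "forward_only", circular = FALSE), 0)
  expect_error(kmerUniqueness("ACGT", 5, circular = FALSE), "exceeds")
})

test_that("k-mer uniqueness equals brute-force hash counting", {
  set.seed(21)
  for (i in 1:6) {
    g <- randomGenome(sample(200:800, 1))
    k <- sample(4:8, 1)
    circ <- i %% 2 == 0
    expect_equal(kmerUniqueness(g, k, "forward_only", circular = circ),
                 naiveKmerUniqueness(g, k, bothStrands = FALSE, circular = circ))
    expect_equal(kmerUniqueness(g, k, "both_strands", circular = circ),
                 naiveKmerUniqueness(g, k, bothStrands = TRUE, circular = circ))
  }
  # N-containing k-mer positions are excluded
  gN <- paste0(randomGenome(100), "N", randomGenome(100))
  expect_equal(kmerUniqueness(gN, 5, "forward_only", circular = FALSE),
               naiveKmerUniqueness(gN, 5, bothStrands = FALSE))
})

test_that("read trimming keeps the configured window and skips bad reads", {
  r71 <- paste0(strrep("N", 4), strrep("A", 36), strrep("C", 31))
  expect_equal(trimReads(r71)$reads, strrep("A", 36))
  # zero trimming is the identity
  expect_equal(trimReads("ACGTACGT", 0, 0, 8)$reads, "ACGTACGT")
  # wrong-length read: skipped with a warning, counter incremented
  expect_warning(tr <- trimReads(c(r71, strrep("A", 70))), "skipped")
  expect_equal(tr$skipped, 1L)
  expect_equal(tr$kept, c(TRUE, FALSE))
  expect_length(tr$reads, 1L)
})

test_that("suffix-array lookup returns every exact occurrence", {
  idx <- buildIndex("ACACA", strandMode = "forward_only", circular = FALSE)
  expect_equal(lookupIndex(idx, "ACA")$position, c(1, 3))
  expect_equal(nrow(lookupIndex(idx, "GGG")), 0L)
  expect_equal(lookupIndex(idx, "ACACA")$position, 1)
  # both-strand lookups report reverse-complement hits with strand "-"
  idx2 <- buildIndex("AAAACCCCGGGG", strandMode = "both_strands",
                     circular = FALSE)
  hit <- lookupIndex(idx2, "GGTT")  # revcomp AACC at position 3
  expect_equal(hit$position, 3)
  expect_equal(hit$strand, "-")
  expect_error(buildIndex(""), "nonempty")
})

test_that("the unique-hit policy resolves exact, one-mismatch and ambiguous reads", {
  idx <- buildIndex("AAAACCCCGGGG", strandMode = "forward_only",
                    circular = FALSE)
  m <- mapReads(idx, c("ACCC", "GGGT", "ATCC"))
  expect_equal(m$status,
               c("unique_exact", "unique_one_mismatch", "ambiguous"))
  expect_equal(m$position[1:2], c(4L, 9L))
  expect_equal(m$strand[1:2], c("+", "+"))
  expect_equal(m$mismatches[1:2], c(0L, 1L))
  expect_true(is.na(m$position[3]))
  expect_error(mapReads(idx, ""), "empty read")
})

test_that("mapping agrees exactly with a naive Hamming scan", {
  set.seed(31)
  m <- 12L
  for (rep in 1:8) {
    L <- sample(300:1500, 1)
    g <- randomGenome(L)
    circ <- rep %% 2 == 0
    idx <- buildIndex(g, strandMode = "both_strands", circular = circ,
                      readLength = m)
    starts <- sample(L - m + 1L, 20, replace = TRUE)
    exact <- substring(g, starts, starts + m - 1L)
    mut1 <- vapply(exact[1:8], mutateRead, "", k = 1)
    mut2 <- vapply(exact[9:12], mutateRead, "", k = 2)
    rnd <- vapply(1:6, function(i) randomGenome(m), "")
    withN <- vapply(exact[13:15], function(r) {
      substr(r, sample(m, 1), sample(m, 1)) <- "N"; r
    }, "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(exact[16:18])))
    reads <- unname(c(exact, mut1, mut2, rnd, withN, rc))
    got <- mapReads(idx, reads)
    want <- naiveMap(g, reads, circular = circ, bothStrands = TRUE)
    expect_equal(got$status, want$status)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("unique placements reproduce the read from the genome", {
  set.seed(32)
  g <- randomGenome(2000)
  idx <- buildIndex(g, strandMode = "both_strands", circular = FALSE,
                    readLength = 10L)
  reads <- c(vapply(1:30, function(i) {
    p <- sample(1991, 1); substr(g, p, p + 9)
  }, ""), vapply(1:30, function(i) randomGenome(10), ""))
  m <- mapReads(idx, reads)
  for (i in which(m$status == "unique_exact")) {
    src <- substr(g, m$position[i], m$position[i] + 9)
    if (m$strand[i] == "-")
      src <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(src)))
    expect_identical(src, reads[i])
  }
  for (i in which(m$status == "unique_one_mismatch")) {
    src <- substr(g, m$position[i], m$position[i] + 9)
    if (m$strand[i] == "-")
      src <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(src)))
    expect_equal(sum(charToRaw(src) != charToRaw(reads[i])), 1L)
  }
})

test_that("error-free simulated reads map uniquely back to their origin", {
  cfg <- tinyConfig(seed = 13, errorRate = 0, readsPerSample = 600)
  sim <- simulateGenome(cfg)
  cc <- simulateCounts(sim$annotation, cfg)
  fq <- simulateReads(sim$genome, sim$annotation, cc$counts, cfg,
                      withr::local_tempdir())
  rd <- readFastq(fq[[1]])
  origin <- do.call(rbind, strsplit(sub("^\\S+ ", "", names(rd)), "|",
                                    fixed = TRUE))
  tr <- trimReads(as.character(rd))
  idx <- buildIndex(sim$genome, readLength = 36L)
  m <- mapReads(idx, tr$reads)
  expect_true(all(m$status == "unique_exact"))
  # a trimmed read starts 4 nt into the sequenced read; on the minus strand
  # the sequenced read starts at its rightmost genome coordinate
  truePos <- ifelse(origin[, 3] == "+",
                    as.integer(origin[, 2]) + 4L,
                    as.integer(origin[, 2]) + cfg@readLength - 4L - 36L)
  expect_equal(m$position, truePos)
  expect_equal(m$strand, origin[, 3])
})

test_that("reads with Ns can only map with a mismatch, two Ns never map", {
  g <- randomGenome(1000)
  idx <- buildIndex(g, strandMode = "forward_only", circular = FALSE,
                    readLength = 12L)
  r <- substr(g, 101, 112)
  rN <- r; substr(rN, 5, 5) <- "N"
  rNN <- r; substr(rNN, 5, 5) <- "N"; substr(rNN, 9, 9) <- "N"
  m <- mapReads(idx, c(r, rN, rNN))
  expect_equal(m$status[2], "unique_one_mismatch")
  expect_equal(m$position[2], 101L)
  expect_equal(m$status[3], "unmapped")
})
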