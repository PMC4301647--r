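test_that("genome simulation is deterministic and respects the packing rules", {
  cfg <- simConfig(genomeLength = 10000, geneCount = 10,
                   geneLengthRange = c(150, 600), seed = 7)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))

  ann <- a$annotation
  expect_length(ann, 10L)
  expect_true(all(GenomicRanges::start(ann) <= GenomicRanges::end(ann)))
  expect_true(all(GenomicRanges::width(ann) >= 150 &
                    GenomicRanges::width(ann) <= 600))
  # non-overlapping, inside the genome
  expect_true(all(GenomicRanges::end(ann) <= cfg@genomeLength))
  o <- order(GenomicRanges::start(ann))
  expect_true(all(GenomicRanges::start(ann)[o][-1] >
                    GenomicRanges::end(ann)[o][-length(ann)]))
  expect_true(all(as.character(GenomicRanges::strand(ann)) %in% c("+", "-")))
})

test_that("degenerate and infeasible simulation configs are handled", {
  empty <- simulateGenome(simConfig(genomeLength = 5000, geneCount = 0, seed = 1))
  expect_length(empty$annotation, 0L)
  expect_equal(nchar(as.character(empty$genome[[1]])), 5000L)
  expect_error(simConfig(genomeLength = 1000, geneCount = 10,
                         geneLengthRange = c(150, 600)),
               "infeasible packing")
  expect_error(simConfig(genomeLength = 10000, geneCount = 5,
                         geneLengthRange = c(50, 60), readLength = 71),
               "readLength")
  expect_error(simConfig(dispersion = -0.5), "dispersion")
})

test_that("simulated counts follow the negative-binomial model", {
  # standardized residuals z = (x - mu)/sqrt(mu + phi mu^2) have mean 0 and
  # variance 1 under the NB model; phi = 0 is the Poisson limit
  zCheck <- function(dispersion, seed, tol) {
    cfg <- simConfig(genomeLength = 4e6, geneCount = 2500,
                     geneLengthRange = c(300, 1500), dispersion = dispersion,
                     deFraction = 0, replicates = 1,
                     readsPerSample = 2500 * 5, seed = seed)
    sim <- simulateGenome(cfg)
    cc <- simulateCounts(sim$annotation, cfg)
    M <- cc$truth$mu[, cc$design$condition]
    z <- (cc$counts - M) / sqrt(M + dispersion * M^2)
    n <- length(z)
    expect_lt(abs(mean(z)), 3 / sqrt(n))
    expect_lt(abs(var(as.numeric(z)) - 1), tol)
    cc
  }
  # Poisson: SE(var(z)) ~ sqrt((2 + 1/mu)/n); mu ~ 5, n = 10000 -> 3 SE ~ .045
  zCheck(0, seed = 11, tol = 0.045)
  # NB phi = 0.5: heavier tails inflate the variance of var(z); generous 0.12
  cc1 <- zCheck(0.5, seed = 12, tol = 0.12)

  # determinism: same seed, same matrices
  cfg <- simConfig(genomeLength = 4e6, geneCount = 2500,
                   geneLengthRange = c(300, 1500), dispersion = 0.5,
                   deFraction = 0, replicates = 1,
                   readsPerSample = 2500 * 5, seed = 12)
  sim <- simulateGenome(cfg)
  expect_identical(cc1$counts, simulateCounts(sim$annotation, cfg)$counts)
})

test_that("simulated reads come from gene bodies with the stated error rate", {
  cfg <- tinyConfig(seed = 5, errorRate = 0)
  sim <- simulateGenome(cfg)
  cc <- simulateCounts(sim$annotation, cfg)
  dir <- withr::local_tempdir()
  fq <- simulateReads(sim$genome, sim$annotation, cc$counts, cfg, dir)

  # emitted read count per sample equals the column sum of the count matrix
  nlines <- vapply(fq, function(p) length(readLines(p)), 1L)
  expect_equal(unname(nlines), unname(4L * colSums(cc$counts)))

  # with no errors every read is a substring of its gene (either orientation)
  rd <- readFastq(fq[[1]])
  ids <- names(rd)
  origin <- do.call(rbind, strsplit(sub("^\\S+ ", "", ids), "|", fixed = TRUE))
  fwd <- as.character(sim$genome[[1]])
  for (i in sample(length(rd), 25)) {
    g <- match(origin[i, 1], sim$annotation$gene_id)
    gseq <- substr(fwd, GenomicRanges::start(sim$annotation)[g],
                   GenomicRanges::end(sim$annotation)[g])
    s <- as.character(rd[[i]])
    hit <- grepl(s, gseq, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(rd[[i]])), gseq,
            fixed = TRUE)
    expect_true(hit)
  }

  # zero counts -> empty FASTQ
  zero <- cc$counts; zero[] <- 0L
  fq0 <- simulateReads(sim$genome, sim$annotation, zero, cfg,
                       withr::local_tempdir())
  expect_true(all(file.size(fq0) == 0))

  # substitution rate recovered within 3 binomial standard errors
  cfgE <- tinyConfig(seed = 6, errorRate = 0.01, readsPerSample = 2000)
  simE <- simulateGenome(cfgE)
  ccE <- simulateCounts(simE$annotation, cfgE)
  fqE <- simulateReads(simE$genome, simE$annotation, ccE$counts, cfgE,
                       withr::local_tempdir())
  rdE <- readFastq(fqE[[1]])
  originE <- do.call(rbind, strsplit(sub("^\\S+ ", "", names(rdE)), "|",
                                     fixed = TRUE))
  fwdE <- as.character(simE$genome[[1]])
  mism <- 0L; tot <- 0L
  for (i in seq_along(rdE)) {
    p <- as.integer(originE[i, 2])
    src <- substr(fwdE, p, p + cfgE@readLength - 1L)
    s <- if (originE[i, 3] == "-")
      as.character(Biostrings::reverseComplement(rdE[[i]]))
    else as.character(rdE[[i]])
    mism <- mism + sum(charToRaw(s) != charToRaw(src))
    tot <- tot + cfgE@readLength
  }
  se <- sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(mism / tot - 0.01), 3 * se)
})

test_that("the synthetic regulon flags exactly the constructed consistent edges", {
  cfg <- tinyConfig(seed = 9, genomeLength = 50000, geneCount = 40,
                    deFraction = 0.6)
  sim <- simulateGenome(cfg)
  cc <- simulateCounts(sim$annotation, cfg)
  # use the true means as an idealised expression matrix for the delta
  expr <- cc$truth$mu[, rep(cfg@conditions, each = 3)]
  colnames(expr) <- paste(rep(cfg@conditions, each = 3), 1:3, sep = "_")
  delta <- deltaExpression(expr, rep(cfg@conditions, each = 3), tau = 1)

  full <- simulateRegulon(sim$annotation, delta, nRegulators = 5,
                          targetsPerRegulator = 10, consistentFraction = 1,
                          seed = 2)
  expect_equal(nrow(full$consistent), 50L)
  kept <- signConsistencyFilter(full$study, delta)
  expect_setequal(paste(networkEdges(kept)$regulator, networkEdges(kept)$target),
                  paste(full$consistent$regulator, full$consistent$target))

  half <- simulateRegulon(sim$annotation, delta, nRegulators = 5,
                          targetsPerRegulator = 10, consistentFraction = 0.5,
                          seed = 3)
  expect_equal(nrow(half$consistent), 25L)

  none <- simulateRegulon(sim$annotation, delta, nRegulators = 5,
                          targetsPerRegulator = 10, consistentFraction = 0,
                          seed = 4)
  expect_equal(nrow(none$consistent), 0L)

  expect_error(simulateRegulon(sim$annotation, delta, consistentFraction = 1.2),
               "consistentFraction")
})
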