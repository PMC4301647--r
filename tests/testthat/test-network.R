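mkNet <- function(...) {
  regulatoryNetwork(data.frame(...))
}

test_that("edge lists validate signs and collapse duplicates to dual", {
  net <- mkNet(regulator = c("r1", "r1"), target = c("t1", "t1"),
               sign = c("+", "-"))
  expect_equal(length(net), 1L)
  expect_equal(networkEdges(net)$sign, "dual")
  expect_error(mkNet(regulator = "r1", target = "t1", sign = "bogus"),
               "line\\(s\\): 1")
  # RegulonDB tokens are translated
  net2 <- mkNet(regulator = c("a", "b", "c"), target = c("x", "y", "z"),
                sign = c("+", "-", "+-"))
  expect_equal(networkEdges(net2)$sign,
               c("activation", "repression", "dual"))
})

test_that("network projection renames mapped endpoints and drops the rest", {
  ref <- mkNet(regulator = c("A", "A", "B", "C"),
               target = c("B", "C", "C", "D"),
               sign = c("+", "-", "+", "+"))
  orth <- data.frame(reference = c("A", "B", "C"),
                     study = c("a1", "b1", "c1"))
  proj <- projectNetwork(ref, orth)
  e <- networkEdges(proj)
  expect_equal(length(proj), 3L)  # C -> D dropped (D unmapped)
  expect_setequal(paste(e$regulator, e$target),
                  c("a1 b1", "a1 c1", "b1 c1"))
  expect_equal(e$sign[e$regulator == "a1" & e$target == "b1"], "activation")
  expect_equal(attr(proj@edges, "projection")$edges_dropped, 1L)
  # many-to-many ortholog entries are dropped under one-to-one enforcement
  orth2 <- rbind(orth, data.frame(reference = "A", study = "a2"))
  proj2 <- projectNetwork(ref, orth2)
  expect_equal(length(proj2), 1L)  # only B -> C survives
})

test_that("sign-consistency filtering implements the agreement rule", {
  # two up-regulated targets, two down-regulated, one unchanged, so each
  # (regulator, target) pair is distinct
  delta <- data.frame(gene = c("r", "u1", "u2", "d1", "d2", "t_flat"),
                      delta = c(4, 6, 6, -6, -6, 0.2),
                      sign = c(1L, 1L, 1L, -1L, -1L, 0L))
  net <- regulatoryNetwork(data.frame(
    regulator = "r",
    target = c("u1", "d1", "u2", "d2", "t_flat", "u3"),
    sign = c("activation", "activation", "repression", "repression",
             "activation", "dual")))
  delta <- rbind(delta, data.frame(gene = "u3", delta = 5, sign = 1L))
  # r is up: activation kept iff target up; repression kept iff target down;
  # dual kept for any changed target; unchanged target always removed
  kept <- networkEdges(signConsistencyFilter(net, delta))
  expect_setequal(paste(kept$target, kept$sign),
                  c("u1 activation", "d2 repression", "u3 dual"))
  # requireBothEndpoints = FALSE keeps edges from unchanged regulators too
  delta2 <- delta; delta2$sign[1] <- 0L
  kept2 <- networkEdges(signConsistencyFilter(net, delta2,
                                              requireBothEndpoints = FALSE))
  expect_setequal(kept2$target, c("u1", "d1", "u2", "d2", "u3"))
  expect_equal(length(signConsistencyFilter(net, delta2)), 0L)
  # genes missing from delta are treated as unchanged
  net3 <- mkNet(regulator = "r", target = "unknown", sign = "activation")
  expect_equal(length(signConsistencyFilter(net3, delta)), 0L)
})

test_that("filtering is idempotent", {
  set.seed(71)
  genes <- paste0("g", 1:30)
  delta <- data.frame(gene = genes, delta = rnorm(30, sd = 3),
                      sign = sample(c(-1L, 0L, 1L), 30, TRUE))
  e <- data.frame(regulator = sample(genes, 40, TRUE),
                  target = sample(genes, 40, TRUE),
                  sign = sample(c("activation", "repression", "dual"), 40, TRUE))
  net <- regulatoryNetwork(e)
  f1 <- signConsistencyFilter(net, delta)
  f2 <- signConsistencyFilter(f1, delta)
  expect_identical(networkEdges(f1), networkEdges(f2))
})

test_that("hub ranking counts connections with deterministic tie-breaks", {
  star <- regulatoryNetwork(data.frame(
    regulator = "hub", target = paste0("t", 1:10), sign = "+"))
  h <- hubRegulators(star, topN = 3)
  expect_equal(h$regulator[1], "hub")
  expect_equal(h$connections[1], 10L)
  expect_equal(nrow(hubRegulators(mkNet(regulator = character(),
                                        target = character(),
                                        sign = character()), topN = 5)), 0L)
  # planted degrees 9 > 7 > 5 recovered in order
  e <- rbind(data.frame(regulator = "r9", target = paste0("a", 1:9), sign = "+"),
             data.frame(regulator = "r7", target = paste0("b", 1:7), sign = "-"),
             data.frame(regulator = "r5", target = paste0("c", 1:5), sign = "+"))
  h2 <- hubRegulators(regulatoryNetwork(e), topN = 3)
  expect_equal(h2$regulator, c("r9", "r7", "r5"))
  expect_equal(h2$connections, c(9L, 7L, 5L))
  # lexicographic tie-break
  e3 <- rbind(data.frame(regulator = "z", target = paste0("a", 1:3), sign = "+"),
              data.frame(regulator = "m", target = paste0("b", 1:3), sign = "+"))
  expect_equal(hubRegulators(regulatoryNetwork(e3), topN = 2)$regulator,
               c("m", "z"))
  expect_error(hubRegulators(star, topN = 0), "positive")
})

test_that("shared-target search ranks regulators by Jaccard overlap", {
  e <- rbind(
    data.frame(regulator = "X", target = c("a", "b", "d"), sign = "+"),
    data.frame(regulator = "exact", target = c("a", "b", "c"), sign = "+"),
    data.frame(regulator = "none", target = c("p", "q"), sign = "-"))
  net <- regulatoryNetwork(e)
  res <- sharedTargetRegulators(net, c("a", "b", "c"), topN = 3)
  expect_equal(res$regulator[1], "exact")
  expect_equal(res$jaccard[1], 1)
  expect_equal(res$jaccard[res$regulator == "X"], 2 / 4)
  expect_equal(res$jaccard[res$regulator == "none"], 0)
  expect_error(sharedTargetRegulators(net, character(0)), "nonempty")
})

test_that("expression deltas call changes at the threshold tau", {
  m <- cbind(L12_1 = c(g1 = 10, g2 = 10, g3 = 10),
             L12_2 = c(10, 10, 10),
             S12_1 = c(13, 7, 10.4), S12_2 = c(13, 7, 10.4))
  d <- deltaExpression(m, c("L12", "L12", "S12", "S12"), tau = 1)
  expect_equal(d$sign, c(1L, -1L, 0L))
  expect_equal(d$delta, c(3, -3, 0.4), tolerance = 1e-12)
  # wider tau suppresses the calls
  d2 <- deltaExpression(m, c("L12", "L12", "S12", "S12"), tau = 5)
  expect_equal(d2$sign, c(0L, 0L, 0L))
})

test_that("report counts equal a brute-force pass over the edge list", {
  set.seed(72)
  genes <- paste0("g", 1:25)
  e <- unique(data.frame(regulator = sample(genes, 60, TRUE),
                         target = sample(genes, 60, TRUE),
                         sign = sample(c("+", "-"), 60, TRUE)))
  e <- e[!duplicated(e[, 1:2]), ]
  net <- regulatoryNetwork(e)
  expect_equal(length(net), nrow(e))
  h <- hubRegulators(net, topN = 100)
  for (i in seq_len(nrow(h)))
    expect_equal(h$connections[i], sum(e$regulator == h$regulator[i]))
})
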