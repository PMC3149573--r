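# Gene collapse, partial-correlation ranking, enrichment score walk,
# permutation GSEA and over-representation with BH.

test_that("probeset collapse averages probesets per gene", {
  expr <- matrix(c(1, 2, 4, 6, 6, 8, 10, 20), 2, 4,
                 dimnames = list(c("s1", "s2"), c("p1", "p2", "p3", "p4")))
  map <- c(p1 = "GA", p2 = "GB", p3 = "GB", p4 = "GC")
  g <- collapseProbesets(expr, map)
  expect_equal(unname(g[, "GA"]), c(1, 2))       # single probeset: copied
  expect_equal(unname(g["s1", "GB"]), (4 + 6) / 2)
  expect_equal(unname(g["s2", "GB"]), (6 + 8) / 2)

  expect_message(collapseProbesets(expr, map[1:3]), "unmapped")
  expect_error(collapseProbesets(expr, character(0)), "empty")
})

test_that("a 24123-probeset mapping collapses to 18017 genes", {
  nP <- 24123; nG <- 18017
  probes <- sprintf("p%05d", seq_len(nP))
  map <- simulateProbesetGeneMap(probes, nG, 23)
  expr <- matrix(rnorm(2 * nP), 2, nP, dimnames = list(c("a", "b"), probes))
  g <- collapseProbesets(expr, map)
  expect_equal(ncol(g), nG)
})

test_that("ranking metric equals the QTT partial correlation, ties by id", {
  set.seed(100)
  ph <- toyPheno(16, 4); ph$met <- rnorm(16)
  expr <- toyExpr(16, 25, seed = 101, prefix = "g")
  ranked <- rankByPartialCorrelation(expr, ph, "met")
  expect_true(!is.unsorted(-ranked$metric))
  qtt <- callQtt(expr, ph, "met", tissue = "T")
  expect_lt(max(abs(ranked$metric[match(qtt@results$probeset, ranked$gene)] -
                    qtt@results$rPartial)), 1e-10)

  # a gene equal to the residualized trait ranks first with metric 1
  resT <- residualize(setNames(ph$met, ph$sample), ph)
  expr2 <- cbind(expr, gTOP = as.numeric(resT))
  r2 <- rankByPartialCorrelation(expr2, ph, "met")
  expect_equal(r2$gene[1], "gTOP")
  expect_equal(r2$metric[1], 1, tolerance = 1e-10)

  # sign antisymmetry
  expr3 <- expr; expr3[, 3] <- -expr3[, 3]
  r3 <- rankByPartialCorrelation(expr3, ph, "met")
  g3 <- colnames(expr)[3]
  expect_equal(r3$metric[r3$gene == g3], -ranked$metric[ranked$gene == g3])

  # constant gene gets metric 0
  expr4 <- cbind(expr, gFLAT = 7)
  r4 <- rankByPartialCorrelation(expr4, ph, "met")
  expect_equal(r4$metric[r4$gene == "gFLAT"], 0)
})

test_that("enrichment score matches brute force and closed forms", {
  set.seed(110)
  N <- 60
  ranked <- data.frame(gene = sprintf("g%02d", 1:N),
                       metric = sort(rnorm(N), decreasing = TRUE))

  # all members at the very top -> ES ~ 1
  top <- enrichmentScore(ranked, ranked$gene[1:5], 1)
  expect_equal(top$es, 1, tolerance = 1e-9)

  # weight 0, single member at position k: closed form
  for (k in c(1, 10, 35, 60)) {
    es <- enrichmentScore(ranked, ranked$gene[k], 0)$es
    up <- 1 - (k - 1) / (N - 1)
    down <- -(k - 1) / (N - 1)
    expect_equal(es, if (abs(up) >= abs(down)) up else down, tolerance = 1e-12)
  }

  # random sets vs the independent step-by-step walk
  for (i in 1:20) {
    set <- sample(ranked$gene, sample(3:20, 1))
    p <- sample(c(0, 1, 1.5), 1)
    mine <- enrichmentScore(ranked, set, p)$es
    oracle <- bruteEnrichmentScore(ranked$metric, ranked$gene %in% set, p)
    expect_lt(abs(mine - oracle), 1e-12)
  }

  # scale invariance at weight 0
  scaled <- ranked; scaled$metric <- ranked$metric * 13
  set <- ranked$gene[c(2, 17, 40)]
  expect_equal(enrichmentScore(ranked, set, 0)$es,
               enrichmentScore(scaled, set, 0)$es, tolerance = 1e-12)
  expect_error(enrichmentScore(ranked, "absent_gene", 1), "no member")
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(120)
  N <- 200
  stats <- sort(rnorm(N), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%03d", 1:N), metric = stats)
  for (i in 1:10) {
    pos <- sort(sample(N, 15))
    mine <- enrichmentScore(ranked, ranked$gene[pos], 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = pos, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation GSEA is deterministic and finds a planted set", {
  m <- matrix(0, 12, 1); m[3, ] <- 30
  d <- simulationDesign(nTissues = 1, nProbesets = 250, nModules = 0,
                        nTrueQtt = m, qttPartialCorrelation = 0.9)
  sim <- simulateCohort(d, 19)
  probes <- colnames(sim$expression[[1]])
  map <- simulateProbesetGeneMap(probes, 200, 20)
  sets <- simulateGeneSets(sim$truth, map, nDecoySets = 15, seed = 21, decoySize = 20)
  gexpr <- collapseProbesets(sim$expression[[1]], map)

  res <- gsea(gexpr, sim$phenotypes, "NEFA", sets, nPerm = 200, seed = 22)
  res2 <- gsea(gexpr, sim$phenotypes, "NEFA", sets, nPerm = 200, seed = 22)
  expect_identical(res, res2)

  trueRow <- res[grepl("^true_", res$set), ]
  expect_equal(res$set[which.max(abs(res$nes))], trueRow$set)  # outranks decoys
  expect_lt(trueRow$fdrQ, 0.05)
  expect_gt(trueRow$nes, 0)   # planted associations are positive
  expect_true(all(sign(res$nes) == sign(res$es), na.rm = TRUE))
  expect_true(all(res$pNominal >= 0 & res$pNominal <= 1))
  expect_error(gsea(gexpr, sim$phenotypes, "NEFA", sets, nPerm = 5), "nPerm")
})

test_that("over-representation matches enumeration and hand-computed BH", {
  universe <- sprintf("g%02d", 1:12)
  members <- universe[1:4]
  sets <- list(self = members, half = universe[3:8], none = universe[9:12])
  res <- hypergeometricEnrichment(members, universe, sets)
  self <- res[res$category == "self", ]
  expect_equal(self$fold, 12 / 4)
  expect_equal(res$category[1], "self")  # minimal p among categories

  # exhaustive oracle on the 12-gene universe
  for (nm in names(sets)) {
    K <- length(sets[[nm]])
    kObs <- length(intersect(sets[[nm]], members))
    expect_lt(abs(res$pRaw[res$category == nm] -
                  enumHyperUpper(12, K, 4, kObs)), 1e-12)
  }

  # BH of (0.01, 0.02, 0.03, 0.04) is 0.04 everywhere
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_error(hypergeometricEnrichment(character(0), universe, sets), "empty")
  expect_error(hypergeometricEnrichment("not_there", universe, sets), "subset")
})

test_that("topNes returns the strongest sets per direction", {
  g <- data.frame(set = letters[1:8], size = 5, es = 0,
                  nes = c(3, 2, 1, 0.5, -0.4, -1, -2.5, NA),
                  pNominal = 0.5, fdrQ = 0.5, leadingEdge = "")
  top <- topNes(g, k = 2)
  expect_identical(top$set[top$direction == "positive"], c("a", "b"))
  expect_identical(top$set[top$direction == "negative"], c("g", "f"))
})
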