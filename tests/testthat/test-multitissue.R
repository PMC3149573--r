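# Multi-tissue network: node pooling, inter-tissue connectivity, tissue-pair
# strength, module-tissue enrichment, hubs and significant edges.

mkQtt2 <- function(tissue, members, universeIds, trait = "NEFA") {
  p <- ifelse(universeIds %in% members, 1e-6, 0.5)
  new("QTTSet", tissue = tissue, trait = trait,
      results = data.frame(probeset = universeIds, coefficient = 0, t = 0,
                           p = p, rPartial = 0, member = p < 0.01,
                           constant = FALSE, stringsAsFactors = FALSE),
      alpha = 0.01, nPermutations = 0L, fdrEstimate = NA_real_,
      permMeanCount = NA_real_)
}

test_that("pooled node count is the sum of QTT sizes, with tissue tagging", {
  n <- 8
  ids <- sprintf("p%02d", 1:30)
  res <- lapply(c(A = 1, B = 2), function(s) {
    m <- toyExpr(n, 30, seed = 200 + s)
    colnames(m) <- ids
    m
  })
  qtt <- list(A = mkQtt2("A", ids[1:5], ids), B = mkQtt2("B", ids[3:12], ids))
  mat <- buildMultiTissueMatrix(qtt, res)
  expect_equal(ncol(mat), 15)
  # the same probeset in two tissues is two distinct nodes
  expect_true(all(c("A|p03", "B|p03") %in% colnames(mat)))
  expect_equal(as.vector(table(attr(mat, "tissues"))[c("A", "B")]), c(5L, 10L))

  one <- buildMultiTissueMatrix(qtt["A"], res["A"])
  expect_equal(ncol(one), 5)

  resBad <- res
  rownames(resBad$B) <- rev(rownames(resBad$B))
  expect_error(buildMultiTissueMatrix(qtt, resBad), "mismatch")
})

test_that("pooling the published NEFA QTT sizes yields 5148 nodes", {
  sizes <- c(FATB = 458, GONA = 1113, AHYP = 1919, THYG = 655, HYPO = 1003)
  n <- 16
  ids <- sprintf("p%05d", 1:2000)
  res <- lapply(seq_along(sizes), function(s) {
    m <- matrix(0, n, 2000, dimnames = list(sprintf("S%02d", 1:n), ids))
    m
  })
  names(res) <- names(sizes)
  qtt <- lapply(names(sizes), function(tis) mkQtt2(tis, ids[seq_len(sizes[[tis]])], ids))
  names(qtt) <- names(sizes)
  mat <- buildMultiTissueMatrix(qtt, res)
  expect_equal(ncol(mat), 5148L)
})

test_that("inter-tissue connectivity equals the brute-force external mean", {
  tags <- setNames(rep(c("A", "B"), each = 4), paste0("n", 1:8))
  set.seed(210)
  r <- matrix(runif(64), 8); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(names(tags), names(tags))
  prof <- interTissueConnectivity(r, tags)$profile
  for (i in 1:8) {
    ext <- which(tags != tags[i])
    expect_lt(abs(prof$kInterStd[i] - mean(r[i, ext])), 1e-12)
  }
  expect_true(all(prof$kInterStd >= 0 & prof$kInterStd <= 1))

  # constant adjacency c -> K_inter_std = c everywhere
  ac <- matrix(0.3, 8, 8); diag(ac) <- 1; dimnames(ac) <- dimnames(r)
  expect_true(all(abs(interTissueConnectivity(ac, tags)$profile$kInterStd - 0.3) < 1e-12))

  # node fully connected to every external node -> 1
  a1 <- matrix(0, 8, 8); diag(a1) <- 1
  a1[1, 5:8] <- 1; a1[5:8, 1] <- 1
  dimnames(a1) <- dimnames(r)
  expect_equal(interTissueConnectivity(a1, tags)$profile$kInterStd[1], 1)
  expect_error(interTissueConnectivity(r, setNames(rep("A", 8), names(tags))),
               "2 tissues")
})

test_that("tissue-pair connection is the symmetric cross-block mean", {
  tags <- setNames(rep(c("A", "B", "C"), c(3, 2, 3)), paste0("n", 1:8))
  set.seed(220)
  r <- matrix(runif(64), 8); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(names(tags), names(tags))
  tp <- tissuePairConnection(r, tags)
  expect_equal(tp$matrix["A", "B"], mean(r[1:3, 4:5]))
  expect_equal(tp$matrix, t(tp$matrix))
  expect_true(!is.unsorted(-tp$ranking$strength))

  ac <- matrix(0.3, 8, 8); diag(ac) <- 1; dimnames(ac) <- dimnames(r)
  expect_true(all(abs(tissuePairConnection(ac, tags)$ranking$strength - 0.3) < 1e-12))
})

test_that("module-tissue enrichment matches enumeration on a 12-node toy", {
  tags <- rep(c("A", "B"), c(4, 8))          # tissue A is 1/3 of nodes
  part <- rep(c(1L, 2L), each = 6)
  names(tags) <- names(part) <- paste0("n", 1:12)
  part[1:4] <- 1L                             # module 1 holds all of tissue A
  res <- moduleTissueEnrichment(part, tags)
  top <- res[1, ]
  expect_equal(top$module, 1)
  expect_equal(top$tissue, "A")
  for (i in seq_len(nrow(res))) {
    row <- res[i, ]
    expect_lt(abs(row$pRaw - enumHyperUpper(12, row$tissueSize,
                                            row$moduleSize, row$inModule)),
              1e-12)
  }
  expect_equal(res$pBH, p.adjust(res$pRaw, "BH"))
})

test_that("hub sets take the ceiling of the fraction, ties by node id", {
  prof <- data.frame(node = sprintf("n%04d", 1:1140),
                     module = 1L, k = 0, kIntra = c(1140:1))
  h <- hubNodes(prof, 0.10)
  expect_length(h[["1"]], 114)                 # ceil(0.10 * 1140)
  expect_identical(h[["1"]], prof$node[order(-prof$kIntra)][1:114])

  prof2 <- data.frame(node = letters[1:10], module = 1L, k = 0, kIntra = 1:10)
  expect_identical(hubNodes(prof2, 0.1)[["1"]], "j")     # single max-K node
  expect_length(hubNodes(prof2, 1)[["1"]], 10)           # fraction 1: all
  # deterministic tie-break by node id: ceil(1/3 * 3) = 1 hub
  prof3 <- data.frame(node = c("b", "a", "c"), module = 1L, k = 0, kIntra = c(5, 5, 1))
  expect_identical(hubNodes(prof3, 1 / 3)[["1"]], "a")
  expect_error(hubNodes(prof2, 0), "fraction")
})

test_that("significant edges: sign, null calibration, permutation oracle", {
  set.seed(230)
  n <- 16
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  x[, 2] <- x[, 1]                            # duplicated node pair
  e <- significantEdges(x, edgeAlpha = 1e-4, edgeFdr = 0.05, designRank = 0)
  expect_true(any(e$node1 == "v1" & e$node2 == "v2"))
  expect_equal(e$sign[e$node1 == "v1" & e$node2 == "v2"], "+")

  # independent nodes: essentially nothing survives alpha = 1e-4
  y <- matrix(rnorm(16 * 100), 16, 100, dimnames = list(NULL, paste0("w", 1:100)))
  e0 <- significantEdges(y, 1e-4, 0.05, designRank = 0)
  expect_lte(nrow(e0), 2)

  # two-node toy: the t-transform p matches a permutation p within MC error
  set.seed(231)
  a <- rnorm(16); b <- 0.7 * a + rnorm(16, sd = 0.8)
  robs <- cor(a, b)
  pt2 <- 2 * pt(-abs(robs * sqrt(14) / sqrt(1 - robs^2)), 14)
  nPerm <- 20000
  rperm <- replicate(nPerm, abs(cor(a, sample(b))))
  pperm <- (1 + sum(rperm >= abs(robs))) / (1 + nPerm)
  mcSd <- sqrt(pt2 * (1 - pt2) / nPerm)
  expect_lt(abs(pt2 - pperm), 4 * mcSd + 2 / nPerm)

  expect_error(significantEdges(x[1:2, ]), "3 samples")
  expect_error(significantEdges(x, designRank = 14), "df")
})

test_that("K decomposes exactly into intra- plus cross-module sums", {
  set.seed(240)
  r <- matrix(runif(15 * 15), 15); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("v", 1:15), paste0("v", 1:15))
  part <- setNames(c(rep(1L, 6), rep(2L, 5), rep(0L, 4)), rownames(r))
  prof <- intramodularConnectivity(r, part)
  a0 <- r; diag(a0) <- 0
  for (i in 1:15) {
    cross <- sum(a0[i, part != part[i]])
    same <- sum(a0[i, part == part[i]])
    expect_equal(prof$k[i], cross + same, tolerance = 1e-12)
    if (part[i] > 0) expect_equal(prof$kIntra[i], same, tolerance = 1e-12)
  }
})

test_that("a tissue loaded most on the shared factor has top inter-tissue K", {
  # larger cohort so planted QTT are recovered near-completely in every
  # tissue; otherwise weakly loaded tissues select only their luckiest
  # probesets and the inter-tissue ranking is confounded by selection
  m <- matrix(0, 12, 3); m[3, ] <- 30
  d <- simulationDesign(nTissues = 3, nProbesets = 150, nModules = 0,
                        samplesPerBreed = 12, malesPerBreed = 6,
                        nTrueQtt = m, tissueLoadings = c(0.6, 0.8, 1.0))
  sim <- simulateCohort(d, 31)
  qtt <- lapply(names(sim$expression), function(tis)
    callQtt(sim$expression[[tis]], sim$phenotypes, "NEFA", tissue = tis))
  names(qtt) <- names(sim$expression)
  expect_true(all(vapply(qtt, qttCount, integer(1)) > 3))
  resid <- lapply(sim$expression, residualize, pheno = sim$phenotypes)
  mt <- multiTissueNetwork(qtt, resid, runConfig(betaCandidates = 1:8))
  summ <- mt$interTissue$tissueSummary
  expect_equal(summ$tissue[which.max(summ$median)], names(sim$expression)[3])
  # node conservation through all stages
  expect_equal(nrow(mt$network@adjacency), sum(vapply(qtt, qttCount, integer(1))))
  expect_equal(nrow(mt$interTissue$profile), ncol(mt$nodes))
})
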