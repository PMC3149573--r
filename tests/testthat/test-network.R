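# Single-tissue weighted network: adjacency, scale-free fit, TOM, modules,
# connectivity. Oracles are naive loop implementations from the helpers.

test_that("soft adjacency is |r|^beta with flags for constant nodes", {
  x <- toyExpr(10, 4, seed = 130)
  x[, 2] <- x[, 1]                       # identical pair
  net <- softAdjacency(x, 1)
  a <- adjacency(net)
  expect_equal(unname(a[1, 2]), 1)
  expect_equal(a, t(a))
  expect_true(all(a >= 0 & a <= 1))

  expect_equal(abs(0.5)^6, 0.015625)     # the power rule at beta 6
  net6 <- softAdjacency(x, 6)
  expect_equal(adjacency(net6)[1, 3], abs(net@correlations[1, 3])^6)

  # brute-force pairwise correlations on a 5x4 toy
  y <- toyExpr(5, 4, seed = 131)
  net2 <- softAdjacency(y, 3)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_lt(abs(adjacency(net2)[i, j] - abs(cor(y[, i], y[, j]))^3), 1e-12)
  }

  y2 <- y; y2[, 2] <- 5
  netc <- softAdjacency(y2, 2)
  expect_identical(attr(adjacency(netc), "constantNodes"), colnames(y)[2])
  expect_true(all(adjacency(netc)[2, -2] == 0))
  expect_error(softAdjacency(y[1:2, ], 2), "3 samples")
})

test_that("soft-threshold choice follows the scale-free criterion", {
  x <- toyExpr(16, 150, seed = 140)
  sf1 <- pickSoftThreshold(x, candidates = 1, r2Cut = 0.8)
  expect_equal(sf1$beta, 1)

  # per-node connectivity is non-increasing in beta (|r| <= 1)
  absr <- abs(cor(x)); diag(absr) <- 0
  K4 <- colSums(absr^4); K8 <- colSums(absr^8)
  expect_true(all(K8 <= K4 + 1e-12))

  # degenerate connectivity: all-equal K gives R^2 = 0
  dup <- matrix(rep(rnorm(10), 5), 10, 5)
  sfd <- pickSoftThreshold(dup, candidates = c(2, 3), r2Cut = 0.8)
  expect_true(all(sfd$fitTable$r2 == 0))
})

test_that("modular cohorts yield beta in 4..12 with R^2 >= 0.8 (5 seeds)", {
  d <- simulationDesign(nProbesets = 600, nModules = 5, moduleSizes = 40,
                        withinModuleCorrelation = 0.7, nTissues = 1, nTraits = 2)
  for (s in 1:5) {
    sim <- simulateCohort(d, s)
    res <- residualize(sim$expression[[1]], sim$phenotypes)
    sf <- pickSoftThreshold(res, 1:20, 0.8)
    expect_true(sf$beta >= 4 && sf$beta <= 12)
    expect_gte(sf$fitTable$r2[sf$fitTable$beta == sf$beta], 0.8)
  }
})

test_that("TOM dissimilarity matches hand computation and the loop oracle", {
  # 2-node network: TOM = a / (a + 1 - a) = a, so d = 1 - a
  a2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  d2 <- tomDissimilarity(a2)
  expect_equal(unname(d2[1, 2]), 1 - 0.6 / (0.6 + 1 - 0.6), tolerance = 1e-12)
  expect_equal(diag(d2), c(0, 0))

  # zero adjacency -> maximal dissimilarity off-diagonal
  a0 <- diag(4)
  d0 <- tomDissimilarity(a0)
  expect_true(all(d0[upper.tri(d0)] == 1))

  # random 6-node adjacency vs the triple-loop oracle
  set.seed(150)
  r <- matrix(runif(36), 6); r <- (r + t(r)) / 2; diag(r) <- 1
  a <- r^2
  expect_lt(max(abs(tomDissimilarity(a) - bruteTomDissimilarity(a))), 1e-12)

  # bounds and symmetry on many random instances
  for (i in 1:200) {
    n <- sample(3:8, 1)
    r <- matrix(runif(n * n), n); r <- (r + t(r)) / 2; diag(r) <- 1
    d <- tomDissimilarity(r^3)
    expect_true(all(d >= 0 & d <= 1))
    expect_lt(max(abs(d - t(d))), 1e-12)
    expect_true(all(diag(d) == 0))
  }
})

test_that("dynamic tree cut recovers planted blocks and orders modules", {
  set.seed(160)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(
    sapply(1:60, function(i) sqrt(0.8) * f1 + sqrt(0.2) * rnorm(n)),
    sapply(1:40, function(i) sqrt(0.8) * f2 + sqrt(0.2) * rnorm(n)))
  colnames(x) <- sprintf("n%03d", 1:100)
  net <- softAdjacency(x, 6)
  part <- detectModules(tomDissimilarity(net), minModuleSize = 30)
  truth <- rep(1:2, c(60, 40))
  expect_gt(qttnet:::randIndex(part, truth), 0.95)
  # labels ordered by decreasing size
  sizes <- table(part[part > 0])
  expect_equal(as.integer(names(sizes)), seq_along(sizes))
  expect_true(!is.unsorted(rev(sizes)))
  expect_equal(unname(sizes["1"]), 60)

  # duplicated block + independent columns: the block forms one module
  set.seed(161)
  base <- rnorm(30)
  y <- cbind(matrix(rep(base, 40), 30, 40) + rnorm(30 * 40, sd = 0.01),
             matrix(rnorm(30 * 40), 30, 40))
  colnames(y) <- sprintf("m%03d", 1:80)
  party <- detectModules(tomDissimilarity(softAdjacency(y, 6)), 30)
  # the duplicated block is exactly one module; the independent columns
  # never join it
  expect_true(all(party[1:40] == party[1]) && party[1] > 0)
  expect_false(any(party[41:80] == party[1]))

  # fewer nodes than the minimum size: everything unassigned
  small <- toyExpr(10, 5, seed = 162)
  part0 <- detectModules(tomDissimilarity(softAdjacency(small, 2)), 30)
  expect_true(all(part0 == 0))
})

test_that("connectivity sums obey closed forms and conservation", {
  # uniform adjacency inside a module of size m: K_intra = a (m - 1)
  m <- 6; a <- matrix(0.4, m, m); diag(a) <- 1
  part <- setNames(rep(1L, m), paste0("n", 1:m))
  dimnames(a) <- list(names(part), names(part))
  prof <- intramodularConnectivity(a, part)
  expect_equal(prof$kIntra, rep(0.4 * (m - 1), m))
  expect_equal(prof$k, prof$kIntra)  # single module spans the network

  # singleton module
  a1 <- matrix(1, 1, 1, dimnames = list("x", "x"))
  p1 <- intramodularConnectivity(a1, setNames(1L, "x"))
  expect_equal(p1$kIntra, 0)

  # conservation: sum of K_intra over a module = 2 * upper-triangle sum
  set.seed(170)
  r <- matrix(runif(100), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("v", 1:10), paste0("v", 1:10))
  part2 <- setNames(rep(c(1L, 2L), each = 5), rownames(r))
  prof2 <- intramodularConnectivity(r, part2)
  for (mod in 1:2) {
    idx <- which(part2 == mod)
    blk <- r[idx, idx]
    expect_equal(sum(prof2$kIntra[idx]), 2 * sum(blk[upper.tri(blk)]),
                 tolerance = 1e-12)
  }
  # label-0 nodes get zero intramodular connectivity
  part3 <- part2; part3[1:3] <- 0L
  expect_true(all(intramodularConnectivity(r, part3)$kIntra[1:3] == 0))
})

test_that("buildCoexpressionNetwork assembles all network components", {
  d <- simulationDesign(nProbesets = 150, nModules = 2, moduleSizes = 40,
                        withinModuleCorrelation = 0.8, nTissues = 1, nTraits = 2)
  sim <- simulateCohort(d, 23)
  res <- residualize(sim$expression[[1]], sim$phenotypes)
  net <- buildCoexpressionNetwork(res, runConfig(betaCandidates = 1:10,
                                                 minModuleSize = 30))
  expect_s4_class(net, "CoexpressionNetwork")
  expect_length(moduleLabels(net), 150)
  expect_equal(nrow(connectivity(net)), 150)
  expect_true(all(connectivity(net)$k >= connectivity(net)$kIntra - 1e-12))
  expect_true(all(connectivity(net)$k <= 149))
})
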