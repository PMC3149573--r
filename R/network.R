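#' Soft-threshold adjacency from residual expression
#'
#' Pearson correlations over samples, raised elementwise to the power beta on
#' the absolute value: a_ij = |r_ij|^beta. The signed correlations are kept
#' alongside. Constant columns get zero correlation to every other node and
#' are flagged in `attr(x, "constantNodes")` of the adjacency.
#'
#' @param resid samples x nodes residual matrix (see [residualize()])
#' @param beta positive integer soft-threshold power
#' @return a [CoexpressionNetwork-class] (modules/connectivity empty)
#' @export
softAdjacency <- function(resid, beta) {
  if (nrow(resid) < 3) stop("need at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(resid, 2, stats::sd)
  r <- suppressWarnings(stats::cor(resid))
  if (any(sds == 0)) {
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  a <- abs(r)^beta
  diag(a) <- 1
  attr(a, "constantNodes") <- colnames(resid)[sds == 0]
  new("CoexpressionNetwork", adjacency = a, correlations = r,
      beta = as.numeric(beta), modules = integer(), tissues = character(),
      connectivity = data.frame(), fit = list())
}

# Scale-free topology fit: R^2 of log10 p(K) vs log10 K over 10 equal-width
# bins of the connectivity distribution; fits with positive slope get R^2 0.
scaleFreeFitR2 <- function(K, nBins = 10) {
  K <- K[K > 0]
  if (length(K) < nBins || max(K) - min(K) < 1e-12)
    return(c(r2 = 0, slope = NA_real_))
  breaks <- seq(min(K), max(K), length.out = nBins + 1)
  bin <- cut(K, breaks, include.lowest = TRUE)
  freq <- tapply(K, bin, length)
  meanK <- tapply(K, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(c(r2 = 0, slope = NA_real_))
  x <- log10(meanK[keep]); y <- log10(freq[keep] / length(K))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (is.na(slope) || slope > 0) r2 <- 0
  c(r2 = r2, slope = slope)
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' For each candidate beta, node connectivities K_i = sum_j |r_ij|^beta
#' (j != i) are binned and log10 p(K) is regressed on log10 K; the chosen
#' beta is the smallest candidate whose fit R^2 reaches `r2Cut`, or the
#' candidate maximizing R^2 if none does. Positive-slope fits (the opposite of
#' scale-free decay) are reported with R^2 = 0.
#'
#' @param resid samples x nodes residual matrix
#' @param candidates candidate powers (default 1:20)
#' @param r2Cut minimum acceptable R^2 (default 0.8)
#' @return list of class `ScaleFreeFit`: `fitTable` (beta, r2, slope, meanK),
#'   `beta` (chosen power)
#' @export
pickSoftThreshold <- function(resid, candidates = 1:20, r2Cut = 0.8) {
  if (length(candidates) < 1) stop("need at least one candidate beta")
  candidates <- sort(unique(as.integer(candidates)))
  absr <- abs(suppressWarnings(stats::cor(resid)))
  absr[is.na(absr)] <- 0
  diag(absr) <- 0
  rows <- lapply(candidates, function(b) {
    K <- colSums(absr^b)
    f <- scaleFreeFitR2(K)
    data.frame(beta = b, r2 = f[["r2"]], slope = f[["slope"]], meanK = mean(K))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2 >= r2Cut)
  chosen <- if (length(ok)) tab$beta[ok[1]] else tab$beta[which.max(tab$r2)]
  structure(list(fitTable = tab, beta = chosen), class = "ScaleFreeFit")
}

#' Topological overlap dissimilarity
#'
#' Unsigned TOM: TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(K_i, K_j) + 1 -
#' a_ij) with u ranging over nodes other than i and j and K the connectivity;
#' the dissimilarity is d_ij = 1 - TOM_ij with zero diagonal. Entries lie in
#' [0,1] and the matrix is symmetric.
#'
#' @param adj adjacency matrix or a [CoexpressionNetwork-class]
#' @return dissimilarity matrix d = 1 - TOM
#' @export
tomDissimilarity <- function(adj) {
  a <- if (is(adj, "CoexpressionNetwork")) adj@adjacency else adj
  a0 <- a
  diag(a0) <- 0
  K <- rowSums(a0)
  L <- a0 %*% a0
  denom <- outer(K, K, pmin) + 1 - a0
  tom <- (L + a0) / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  d <- 1 - tom
  diag(d) <- 0
  dimnames(d) <- dimnames(a)
  d
}

# Children and member sets of each merge node of an hclust tree.
hclustNodes <- function(hc) {
  nMerge <- nrow(hc$merge)
  members <- vector("list", nMerge)
  for (i in seq_len(nMerge)) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    members[[i]] <- c(if (left < 0) -left else members[[left]],
                      if (right < 0) -right else members[[right]])
  }
  members
}

#' Detect modules by dynamic cutting of the average-linkage tree
#'
#' Average-linkage hierarchical clustering of the dissimilarity, cut
#' adaptively: a static cut at `cutHeight` (default 0.99 of the maximum merge
#' height) yields initial branches, and a branch is re-cut recursively
#' wherever its internal merge heights show a pronounced break (a consecutive
#' height gap exceeding `gap` times the branch's top height) — this separates
#' tight cores from loosely chained stragglers without a fixed global
#' threshold. Branches smaller than `minModuleSize` are left unassigned
#' (label 0); modules are relabelled 1..M by decreasing size (ties broken by
#' the smallest member index).
#'
#' @param d dissimilarity matrix (see [tomDissimilarity()])
#' @param minModuleSize smallest reported module (default 30)
#' @param cutHeight static cut height; default 0.99 * max merge height
#' @param gap relative height break required to re-cut a branch (default 0.15)
#' @return named integer vector of module labels (0 = unassigned)
#' @export
detectModules <- function(d, minModuleSize = 30L, cutHeight = NULL, gap = 0.15) {
  n <- nrow(d)
  nodeNames <- rownames(d) %||% as.character(seq_len(n))
  if (n < minModuleSize)
    return(stats::setNames(integer(n), nodeNames))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  maxh <- max(hc$height)
  if (is.null(cutHeight)) cutHeight <- 0.99 * maxh
  members <- hclustNodes(hc)
  heights <- hc$height
  merge <- hc$merge

  # maximal subtrees below height h under `root` (negative entries = leaves)
  collectBelow <- function(root, h) {
    out <- integer(0); stack <- root
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd < 0 || heights[nd] <= h) out <- c(out, nd)
      else stack <- c(stack, merge[nd, 1], merge[nd, 2])
    }
    out
  }
  # all merge heights inside the subtree rooted at nd
  subHeights <- function(nd) {
    out <- numeric(0); stack <- nd
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x > 0) { out <- c(out, heights[x]); stack <- c(stack, merge[x, ]) }
    }
    out
  }
  memb <- function(nd) if (nd < 0) -nd else members[[nd]]

  clusters <- list()
  queue <- as.list(collectBelow(nrow(merge), cutHeight))
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    if (nd < 0) { clusters[[length(clusters) + 1L]] <- -nd; next }
    hs <- sort(subHeights(nd))
    split <- FALSE
    if (length(hs) >= 2) {
      gaps <- diff(hs)
      i <- which.max(gaps)
      if (gaps[i] > gap * max(hs)) {
        mid <- (hs[i] + hs[i + 1]) / 2
        queue <- c(queue, as.list(collectBelow(nd, mid)))
        split <- TRUE
      }
    }
    if (!split) clusters[[length(clusters) + 1L]] <- members[[nd]]
  }

  sizes <- lengths(clusters)
  keep <- which(sizes >= minModuleSize)
  ord <- keep[order(-sizes[keep],
                    vapply(clusters[keep], min, numeric(1)))]
  labels <- integer(n)
  for (m in seq_along(ord)) labels[clusters[[ord[m]]]] <- m
  stats::setNames(labels, nodeNames)
}

#' Whole-network and intramodular connectivity
#'
#' K_i is the sum of a node's adjacencies to every other node; K_intra is the
#' same sum restricted to nodes of its own module (0 for unassigned nodes).
#'
#' @param adj adjacency matrix or [CoexpressionNetwork-class]
#' @param part named integer module labels (see [detectModules()])
#' @return data.frame: node, module, k, kIntra
#' @export
intramodularConnectivity <- function(adj, part) {
  a <- if (is(adj, "CoexpressionNetwork")) adj@adjacency else adj
  if (length(part) != nrow(a)) stop("partition must cover all nodes")
  a0 <- a
  diag(a0) <- 0
  K <- rowSums(a0)
  Kin <- numeric(nrow(a))
  for (m in setdiff(unique(part), 0L)) {
    idx <- which(part == m)
    Kin[idx] <- if (length(idx) > 1) rowSums(a0[idx, idx, drop = FALSE]) else 0
  }
  nodes <- rownames(a) %||% as.character(seq_len(nrow(a)))
  data.frame(node = nodes, module = as.integer(part), k = K, kIntra = Kin,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a complete single-tissue co-expression network
#'
#' Convenience wrapper running the full chain: soft-threshold selection (or a
#' fixed beta), adjacency, TOM dissimilarity, module detection and
#' connectivity statistics.
#'
#' @param resid samples x probesets residual matrix
#' @param config a [RunConfig-class] supplying beta candidates, R^2 cut and
#'   minimum module size
#' @param beta optional fixed power overriding the scale-free selection
#' @return a [CoexpressionNetwork-class] with modules, connectivity and fit
#'   filled in
#' @export
buildCoexpressionNetwork <- function(resid, config = runConfig(), beta = NULL) {
  fit <- list()
  if (is.null(beta)) {
    sf <- pickSoftThreshold(resid, config@betaCandidates, config@scaleFreeR2Cut)
    beta <- sf$beta
    fit <- sf
  }
  net <- softAdjacency(resid, beta)
  d <- tomDissimilarity(net@adjacency)
  part <- detectModules(d, config@minModuleSize)
  net@modules <- part
  net@connectivity <- intramodularConnectivity(net@adjacency, part)
  net@fit <- if (length(fit)) unclass(fit) else list()
  net
}
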