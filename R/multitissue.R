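#' Pool QTT across tissues into one tissue-tagged residual matrix
#'
#' Columns are the (tissue, probeset) QTT of one trait, tagged
#' `tissue|probeset`; the same probeset selected in two tissues contributes
#' two distinct nodes. All tissues must cover the same samples in the same
#' order. The node count is the sum of the per-tissue QTT counts.
#'
#' @param qttSets named list (tissue -> [QTTSet-class]) for one trait
#' @param residuals named list (tissue -> samples x probesets residual matrix)
#' @return samples x nodes matrix with `attr(x, "tissues")` (named character,
#'   node -> tissue) and `attr(x, "designRank")` propagated from the residuals
#' @export
buildMultiTissueMatrix <- function(qttSets, residuals) {
  tissues <- names(qttSets)
  if (is.null(tissues) || !all(tissues %in% names(residuals)))
    stop("qttSets and residuals must be named by the same tissues")
  traits <- unique(vapply(qttSets, function(s) s@trait, character(1)))
  if (length(traits) > 1)
    stop("all QTT sets must concern the same trait; found: ",
         paste(traits, collapse = ", "))
  ref <- rownames(residuals[[tissues[1]]])
  blocks <- list(); tags <- character()
  for (tis in tissues) {
    res <- residuals[[tis]]
    if (!identical(rownames(res), ref))
      stop("sample mismatch across tissues (", tis, " differs from ", tissues[1], ")")
    mem <- qttMembers(qttSets[[tis]])
    miss <- setdiff(mem, colnames(res))
    if (length(miss))
      stop(length(miss), " QTT probeset(s) of ", tis, " missing from its residual matrix")
    block <- res[, mem, drop = FALSE]
    colnames(block) <- paste(tis, mem, sep = "|")
    blocks[[tis]] <- block
    tags <- c(tags, stats::setNames(rep(tis, length(mem)), colnames(block)))
  }
  out <- do.call(cbind, blocks)
  attr(out, "tissues") <- tags
  attr(out, "designRank") <- attr(residuals[[tissues[1]]], "designRank")
  out
}

#' Standardized inter-tissue connectivity
#'
#' For node i of tissue t, K_inter_std(i) is the mean adjacency from i to all
#' N_ot nodes of the other tissues — a [0,1] quantity comparable across
#' tissues of different QTT counts.
#'
#' @param adj adjacency matrix or [CoexpressionNetwork-class] over
#'   tissue-tagged nodes
#' @param tags named character vector (node -> tissue)
#' @return list: `profile` (data.frame node, tissue, kInterStd) and
#'   `tissueSummary` (per-tissue mean/median/n)
#' @export
interTissueConnectivity <- function(adj, tags) {
  a <- if (is(adj, "CoexpressionNetwork")) adj@adjacency else adj
  if (length(tags) != nrow(a)) stop("tags must label every node")
  tags <- unname(tags)
  if (length(unique(tags)) < 2) stop("need nodes from at least 2 tissues")
  a0 <- a
  diag(a0) <- 0
  N <- nrow(a0)
  total <- rowSums(a0)
  kInter <- numeric(N)
  for (tis in unique(tags)) {
    idx <- which(tags == tis)
    nOt <- N - length(idx)
    if (nOt == 0) stop("tissue ", tis, " has no external nodes")
    same <- if (length(idx) > 1) rowSums(a0[idx, idx, drop = FALSE]) else 0
    kInter[idx] <- (total[idx] - same) / nOt
  }
  nodes <- rownames(a) %||% as.character(seq_len(N))
  profile <- data.frame(node = nodes, tissue = tags, kInterStd = kInter,
                        row.names = NULL, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(profile$kInterStd, profile$tissue),
    function(v) data.frame(mean = mean(v), median = stats::median(v), n = length(v))))
  summ <- data.frame(tissue = rownames(summ), summ, row.names = NULL)
  list(profile = profile, tissueSummary = summ[order(-summ$mean), ])
}

#' Tissue-pair connection strength
#'
#' C(t1, t2) is the mean adjacency over all cross-tissue node pairs of
#' tissues t1 and t2: (1/(N1 N2)) sum_i sum_j a_ij.
#'
#' @param adj adjacency matrix or [CoexpressionNetwork-class]
#' @param tags named character vector (node -> tissue)
#' @return list: `matrix` (symmetric tissue x tissue, NA diagonal) and
#'   `ranking` (data.frame of pairs sorted by decreasing strength)
#' @export
tissuePairConnection <- function(adj, tags) {
  a <- if (is(adj, "CoexpressionNetwork")) adj@adjacency else adj
  tags <- unname(tags)
  tissues <- unique(tags)
  if (length(tissues) < 2) stop("need at least 2 tissues")
  m <- matrix(NA_real_, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  rows <- list()
  for (i in seq_along(tissues)) for (j in seq_along(tissues)) {
    if (i >= j) next
    bi <- which(tags == tissues[i]); bj <- which(tags == tissues[j])
    v <- mean(a[bi, bj, drop = FALSE])
    m[i, j] <- m[j, i] <- v
    rows[[length(rows) + 1L]] <- data.frame(
      tissue1 = tissues[i], tissue2 = tissues[j], strength = v,
      stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$strength), , drop = FALSE]
  rownames(ranking) <- NULL
  list(matrix = m, ranking = ranking)
}

#' Tissue enrichment of multi-tissue modules
#'
#' For each (module, tissue) the upper-tail hypergeometric test of the
#' tissue's node count inside the module against the tissue's overall share,
#' BH-adjusted across all (module x tissue) tests.
#'
#' @param part named integer module labels over tissue-tagged nodes
#' @param tags named character vector (node -> tissue)
#' @return data.frame: module, tissue, inModule, moduleSize, tissueSize,
#'   fold, pRaw, pBH — sorted by pRaw
#' @export
moduleTissueEnrichment <- function(part, tags) {
  if (length(part) != length(tags)) stop("partition and tags must cover the same nodes")
  tags <- unname(tags); part <- unname(part)
  N <- length(tags)
  rows <- list()
  for (m in sort(setdiff(unique(part), 0L))) {
    inMod <- part == m
    n <- sum(inMod)
    for (tis in unique(tags)) {
      K <- sum(tags == tis)
      k <- sum(inMod & tags == tis)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, tissue = tis, inModule = k, moduleSize = n, tissueSize = K,
        fold = (k / n) / (K / N),
        pRaw = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$pBH <- stats::p.adjust(out$pRaw, method = "BH")
  out <- out[order(out$pRaw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub nodes per module
#'
#' The ceiling(fraction * N_m) nodes with the highest intramodular
#' connectivity in each module (labels >= 1); ties broken by node id.
#'
#' @param profile connectivity data.frame (node, module, k, kIntra) as from
#'   [intramodularConnectivity()]
#' @param fraction top fraction in (0, 1] (default 0.10)
#' @return named list: module label -> character vector of hub node ids
#' @export
hubNodes <- function(profile, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0,1]")
  out <- list()
  for (m in sort(setdiff(unique(profile$module), 0L))) {
    sub <- profile[profile$module == m, , drop = FALSE]
    nHub <- ceiling(fraction * nrow(sub))
    ord <- order(-sub$kIntra, sub$node, method = "radix")
    out[[as.character(m)]] <- sub$node[ord][seq_len(nHub)]
  }
  out
}

#' Significant signed edges among selected nodes
#'
#' Pearson correlation per node pair of the residual values; two-sided p from
#' the t transform with df = n - q - 2, where q is the number of design
#' columns removed by residualization (residualization consumes degrees of
#' freedom, and ignoring this inflates significance in small cohorts). An
#' edge is kept when p < `edgeAlpha` and its BH q over the tested pairs is
#' below `edgeFdr`; edges carry the correlation sign.
#'
#' @param residValues samples x nodes residual matrix for the selected
#'   (typically hub) nodes; `attr(x, "designRank")` supplies q if `designRank`
#'   is missing
#' @param edgeAlpha nominal p threshold (default 1e-4)
#' @param edgeFdr BH q threshold (default 0.05)
#' @param designRank number of design columns removed by residualization
#' @return data.frame of retained edges: node1, node2, r, p, q, sign
#' @export
significantEdges <- function(residValues, edgeAlpha = 1e-4, edgeFdr = 0.05,
                             designRank = NULL) {
  n <- nrow(residValues)
  if (n < 3) stop("need at least 3 samples")
  q <- designRank %||% attr(residValues, "designRank") %||% 0
  df <- n - q - 2
  if (df < 1) stop("non-positive df (n = ", n, ", design columns = ", q, ")")
  r <- suppressWarnings(stats::cor(residValues))
  r[is.na(r)] <- 0
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  tstat <- rv * sqrt(df) / sqrt(pmax(1 - rv^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df)
  qbh <- stats::p.adjust(p, method = "BH")
  keep <- p < edgeAlpha & qbh < edgeFdr
  nodes <- colnames(residValues) %||% as.character(seq_len(ncol(residValues)))
  out <- data.frame(node1 = nodes[idx[keep, 1]], node2 = nodes[idx[keep, 2]],
                    r = rv[keep], p = p[keep], q = qbh[keep],
                    sign = ifelse(rv[keep] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Full multi-tissue co-expression network analysis for one trait
#'
#' Pools the per-tissue QTT into tissue-tagged nodes, picks the
#' soft-threshold power on the pooled matrix, builds adjacency and TOM,
#' detects modules, and computes intramodular connectivity, standardized
#' inter-tissue connectivity, tissue-pair connection strength, module-tissue
#' enrichment, hub nodes and the significant signed edges among hubs.
#'
#' @param qttSets named list (tissue -> [QTTSet-class]) for one trait
#' @param residuals named list (tissue -> residual matrix)
#' @param config a [RunConfig-class]
#' @param beta optional fixed soft-threshold power
#' @return list: `network` ([CoexpressionNetwork-class] with tissue tags),
#'   `interTissue`, `tissuePairs`, `moduleEnrichment`, `hubs`, `hubEdges`,
#'   `nodes` (the tissue-tagged matrix)
#' @export
multiTissueNetwork <- function(qttSets, residuals, config = runConfig(),
                               beta = NULL) {
  mat <- buildMultiTissueMatrix(qttSets, residuals)
  tags <- attr(mat, "tissues")
  net <- buildCoexpressionNetwork(mat, config, beta)
  net@tissues <- tags
  inter <- interTissueConnectivity(net@adjacency, tags)
  pairs <- tissuePairConnection(net@adjacency, tags)
  modEnr <- moduleTissueEnrichment(net@modules, tags)
  hubs <- hubNodes(net@connectivity, config@hubFraction)
  hubIds <- unlist(hubs, use.names = FALSE)
  hubEdges <- if (length(hubIds) >= 2)
    significantEdges(mat[, hubIds, drop = FALSE], config@edgeAlpha,
                     config@edgeFdr, designRank = attr(mat, "designRank"))
  else data.frame()
  list(network = net, interTissue = inter, tissuePairs = pairs,
       moduleEnrichment = modEnr, hubs = hubs, hubEdges = hubEdges,
       nodes = mat)
}
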