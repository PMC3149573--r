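#' Collapse probesets to gene-level expression
#'
#' When a gene is represented by more than one probeset, its expression in
#' each sample is the arithmetic mean of those probesets' values. Unmapped
#' probesets are dropped (a message reports how many).
#'
#' @param expr samples x probesets matrix
#' @param map named character vector mapping probeset -> gene
#' @return samples x genes matrix
#' @export
collapseProbesets <- function(expr, map) {
  if (length(map) == 0) stop("empty probeset-to-gene mapping")
  mapped <- intersect(colnames(expr), names(map))
  dropped <- ncol(expr) - length(mapped)
  if (length(mapped) == 0) stop("no probeset of the matrix is in the mapping")
  if (dropped > 0) message(dropped, " unmapped probeset(s) dropped in gene collapse")
  genes <- map[mapped]
  grouped <- rowsum(t(expr[, mapped, drop = FALSE]), group = genes)
  counts <- as.vector(table(genes)[rownames(grouped)])
  t(grouped / counts)
}

#' Rank genes by partial correlation with a trait
#'
#' The metric is the Pearson correlation of sex/breed-residualized gene
#' expression with the sex/breed-residualized trait — identical to the
#' `rPartial` of QTT calling. Genes are sorted by decreasing metric; ties are
#' broken by gene id (lexicographic), so the ranking is fully reproducible.
#' Constant genes get metric 0.
#'
#' @param geneExpr samples x genes matrix (see [collapseProbesets()])
#' @param pheno phenotype table
#' @param trait metabolite column name
#' @return data.frame (gene, metric) sorted by decreasing metric
#' @export
rankByPartialCorrelation <- function(geneExpr, pheno, trait) {
  st <- partialCorStats(geneExpr, pheno, trait)
  ord <- order(-st$r, st$probeset, method = "radix")
  data.frame(gene = st$probeset[ord], metric = st$r[ord],
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at a set member ("hit") the running sum increases by
#' |metric|^weightExponent normalized by the sum over hits, at a miss it
#' decreases by 1/(N - N_hits). The enrichment score is the signed maximum
#' deviation from zero. With `weightExponent = 0` the walk reduces to the
#' classic KS statistic. If all hit weights are zero, hits are weighted
#' uniformly.
#'
#' @param ranked data.frame (gene, metric) sorted by decreasing metric
#' @param set character vector of member genes
#' @param weightExponent exponent on |metric| (default 1)
#' @return list: `es`, `runningSum` (length N), `peak` (index of the
#'   extremum), `leadingEdge` (member genes up to/after the peak)
#' @export
enrichmentScore <- function(ranked, set, weightExponent = 1) {
  hit <- ranked$gene %in% set
  nHit <- sum(hit)
  if (nHit == 0) stop("no member of the set is present in the ranked list")
  N <- nrow(ranked)
  if (N == nHit) stop("the set covers the whole ranked list")
  w <- abs(ranked$metric)^weightExponent
  denom <- sum(w[hit])
  steps <- numeric(N)
  steps[hit] <- if (denom > 0) w[hit] / denom else 1 / nHit
  steps[!hit] <- -1 / (N - nHit)
  rs <- cumsum(steps)
  peak <- which.max(abs(rs))
  es <- rs[peak]
  leading <- if (es >= 0) ranked$gene[seq_len(peak)][hit[seq_len(peak)]]
             else ranked$gene[peak:N][hit[peak:N]]
  list(es = es, runningSum = rs, peak = peak, leadingEdge = leading)
}

# ES for every set against one ranking; NA for sets with no gene in the list.
esForSets <- function(ranked, sets, weightExponent) {
  vapply(sets, function(s) {
    if (!any(ranked$gene %in% s)) return(NA_real_)
    enrichmentScore(ranked, s, weightExponent)$es
  }, numeric(1))
}

#' Gene set enrichment analysis ranked by partial correlation
#'
#' Observed rankings come from [rankByPartialCorrelation()]; the null
#' distribution re-ranks the genes after permuting whole phenotype rows
#' (trait with its sex/breed covariates), consistent with the QTT permutation
#' scheme, and recomputes every set's enrichment score. NES = ES divided by
#' the mean |null ES| of the same sign; nominal p is the same-sign tail
#' fraction; FDR q follows the positive/negative NES tail procedure (pooled
#' null NES over all sets against the observed NES distribution).
#'
#' @param geneExpr samples x genes matrix
#' @param pheno phenotype table
#' @param trait metabolite column name
#' @param sets named list of gene sets (see [readGmt()])
#' @param nPerm number of phenotype permutations (>= 10)
#' @param seed integer seed (deterministic for a fixed seed)
#' @param weightExponent exponent on |metric| in the running sum
#' @return data.frame per scored set: set, size (members in the list), es,
#'   nes, pNominal, fdrQ, leadingEdge (comma-separated); sets with no member
#'   in the list are omitted with a message
#' @export
gsea <- function(geneExpr, pheno, trait, sets, nPerm = 1000L, seed = 1L,
                 weightExponent = 1) {
  if (nPerm < 10) stop("nPerm must be >= 10")
  ranked <- rankByPartialCorrelation(geneExpr, pheno, trait)
  present <- vapply(sets, function(s) any(ranked$gene %in% s), logical(1))
  if (any(!present))
    message(sum(!present), " set(s) with no gene in the ranked list omitted")
  sets <- sets[present]
  if (length(sets) == 0) stop("no scorable gene set")
  obsEs <- vapply(sets, function(s) enrichmentScore(ranked, s, weightExponent)$es,
                  numeric(1))
  leading <- vapply(sets, function(s)
    paste(enrichmentScore(ranked, s, weightExponent)$leadingEdge, collapse = ","),
    character(1))
  sizes <- vapply(sets, function(s) sum(ranked$gene %in% s), integer(1))

  nullEs <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(i) {
      rp <- rankByPartialCorrelation(geneExpr, permutePhenotypes(pheno), trait)
      esForSets(rp, sets, weightExponent)
    }, numeric(length(sets))))
  })

  nSets <- length(sets)
  nes <- numeric(nSets); pNom <- numeric(nSets)
  nullNes <- matrix(NA_real_, nPerm, nSets)
  for (j in seq_len(nSets)) {
    nullJ <- nullEs[, j]
    pos <- nullJ[!is.na(nullJ) & nullJ > 0]
    neg <- nullJ[!is.na(nullJ) & nullJ < 0]
    meanPos <- if (length(pos)) mean(pos) else NA_real_
    meanNeg <- if (length(neg)) mean(abs(neg)) else NA_real_
    es <- obsEs[j]
    if (es >= 0) {
      nes[j] <- if (is.na(meanPos)) NA_real_ else es / meanPos
      pNom[j] <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else {
      nes[j] <- if (is.na(meanNeg)) NA_real_ else -abs(es) / meanNeg
      pNom[j] <- (1 + sum(abs(neg) >= abs(es))) / (1 + length(neg))
    }
    nullNes[, j] <- ifelse(is.na(nullJ), NA,
                           ifelse(nullJ >= 0, nullJ / meanPos, -abs(nullJ) / meanNeg))
  }

  pooled <- nullNes[!is.na(nullNes)]
  fdr <- vapply(seq_len(nSets), function(j) {
    x <- nes[j]
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- sum(pooled >= x) / max(1, sum(pooled >= 0))
      den <- sum(nes >= x) / max(1, sum(nes >= 0))
    } else {
      num <- sum(pooled <= x) / max(1, sum(pooled < 0))
      den <- sum(nes <= x) / max(1, sum(nes < 0))
    }
    if (den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  data.frame(set = names(sets), size = sizes, es = obsEs, nes = nes,
             pNominal = pNom, fdrQ = fdr, leadingEdge = leading,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation with Benjamini-Hochberg correction
#'
#' Standard over-representation analysis of a member gene list against set
#' categories over a gene universe: upper-tail hypergeometric p per category,
#' fold = (k/n)/(K/N), and BH adjustment across the categories tested.
#' Categories with no gene in the universe are skipped.
#'
#' @param members character vector of interesting genes (subset of `universe`)
#' @param universe character vector of all genes considered
#' @param sets named list of gene categories
#' @return data.frame: category, overlap k, setSize K (in-universe), fold,
#'   pRaw, pBH — sorted by pRaw
#' @export
hypergeometricEnrichment <- function(members, universe, sets) {
  if (length(members) == 0) stop("empty member list")
  universe <- unique(universe)
  members <- unique(members)
  if (!all(members %in% universe)) stop("members must be a subset of the universe")
  N <- length(universe); n <- length(members)
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    if (K == 0) return(NULL)
    k <- length(intersect(sets[[nm]], members))
    data.frame(category = nm, overlap = k, setSize = K,
               fold = (k / n) / (K / N),
               pRaw = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category has genes in the universe")
  out$pBH <- stats::p.adjust(out$pRaw, method = "BH")
  out <- out[order(out$pRaw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top positive and negative NES summary
#'
#' The per-trait summary used for heat-map style reporting: the `k` sets with
#' the largest positive and the `k` with the most negative NES.
#'
#' @param gseaResult data.frame from [gsea()]
#' @param k sets per direction (default 5)
#' @return data.frame subset with a `direction` column
#' @export
topNes <- function(gseaResult, k = 5) {
  g <- gseaResult[!is.na(gseaResult$nes), , drop = FALSE]
  pos <- g[g$nes > 0, , drop = FALSE]
  neg <- g[g$nes < 0, , drop = FALSE]
  pos <- pos[order(-pos$nes), , drop = FALSE][seq_len(min(k, nrow(pos))), , drop = FALSE]
  neg <- neg[order(neg$nes), , drop = FALSE][seq_len(min(k, nrow(neg))), , drop = FALSE]
  pos$direction <- if (nrow(pos)) "positive" else character(0)
  neg$direction <- if (nrow(neg)) "negative" else character(0)
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}
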