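#' Hypergeometric enrichment test for the overlap of two QTT sets
#'
#' Tests whether two QTT sets drawn from a shared probeset universe of size
#' `universe` share more members than expected by chance: expected =
#' |A||B|/N, fold = observed/expected, and p is the hypergeometric upper tail
#' P(X >= observed), identical to a one-sided Fisher's exact test on the
#' 2x2 table. Bonferroni correction multiplies by `nTests` (capped at 1).
#'
#' @param nA,nB sizes of the two sets
#' @param observed observed overlap count
#' @param universe probeset universe size N
#' @param nTests Bonferroni family size (default 1 = no correction)
#' @param trait,tissueA,tissueB optional labels carried into the result
#' @return one-row data.frame: trait, tissueA, tissueB, nA, nB, observed,
#'   expected, fold (NA when expected = 0), pRaw, pBonferroni, universe
#' @examples
#' overlapTest(373, 547, 50, 24123)  # fold ~ 5.9
#' @export
overlapTest <- function(nA, nB, observed, universe, nTests = 1,
                        trait = NA_character_, tissueA = NA_character_,
                        tissueB = NA_character_) {
  if (nA > universe || nB > universe) stop("set sizes cannot exceed the universe")
  if (observed > min(nA, nB)) stop("observed overlap exceeds the smaller set")
  expected <- nA * nB / universe
  fold <- if (expected == 0) NA_real_ else observed / expected
  pRaw <- stats::phyper(observed - 1, nA, universe - nA, nB, lower.tail = FALSE)
  data.frame(trait = trait, tissueA = tissueA, tissueB = tissueB,
             nA = nA, nB = nB, observed = observed, expected = expected,
             fold = fold, pRaw = pRaw,
             pBonferroni = min(1, pRaw * nTests), universe = universe,
             stringsAsFactors = FALSE)
}

#' Overlap test for two QTTSet objects
#'
#' Convenience wrapper around [overlapTest()] computing the observed overlap
#' from the member probesets (stripped of any tissue tags).
#'
#' @param setA,setB [QTTSet-class] objects for the same trait in two tissues
#' @param universe probeset universe size N
#' @param nTests Bonferroni family size
#' @return one-row data.frame as from [overlapTest()]
#' @export
qttOverlap <- function(setA, setB, universe, nTests = 1) {
  a <- qttMembers(setA); b <- qttMembers(setB)
  overlapTest(length(a), length(b), length(intersect(a, b)), universe, nTests,
              trait = setA@trait, tissueA = setA@tissue, tissueB = setB@tissue)
}

#' Scan all (trait, tissue-pair) QTT overlaps
#'
#' One hypergeometric test per trait and unordered tissue pair; the Bonferroni
#' family size is the total number of tests (n_traits x C(n_tissues, 2))
#' unless overridden. Results are sorted by raw p and filtered at
#' `pBonferroni <= reportThreshold`.
#'
#' @param qttSets list of [QTTSet-class] objects covering >= 2 tissues
#' @param universe probeset universe size N
#' @param reportThreshold report rows with Bonferroni p at or below this
#'   (default 1 = report everything)
#' @param nTests override the Bonferroni family size
#' @return data.frame of overlap results sorted by `pRaw`
#' @export
overlapScan <- function(qttSets, universe, reportThreshold = 1, nTests = NULL) {
  tissues <- vapply(qttSets, function(s) s@tissue, character(1))
  traits <- vapply(qttSets, function(s) s@trait, character(1))
  uTissues <- unique(tissues)
  uTraits <- unique(traits)
  if (length(uTissues) < 2) stop("need QTT sets for at least 2 tissues")
  if (is.null(nTests)) nTests <- length(uTraits) * choose(length(uTissues), 2)
  rows <- list()
  for (tr in uTraits) {
    idx <- which(traits == tr)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i < j)
        rows[[length(rows) + 1L]] <-
          qttOverlap(qttSets[[idx[i]]], qttSets[[idx[j]]], universe, nTests)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pRaw), , drop = FALSE]
  rownames(out) <- NULL
  out[out$pBonferroni <= reportThreshold, , drop = FALSE]
}
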