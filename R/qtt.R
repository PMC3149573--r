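#' Remove sex and breed effects by least squares
#'
#' Projects expression columns (or a trait vector) onto the orthogonal
#' complement of the intercept + sex + breed design: residuals =
#' (I - H) values, where H is the hat matrix. Residualizing twice equals
#' residualizing once, residual column means are ~0, and residual columns are
#' orthogonal to the design.
#'
#' @param x samples x probesets matrix with sample rownames, or a numeric
#'   vector named by sample
#' @param pheno phenotype table covering the samples of `x`
#' @return residual matrix (or vector) of the same shape, with the number of
#'   design columns recorded in `attr(x, "designRank")`
#' @export
residualize <- function(x, pheno) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1, dimnames = list(names(x), "y")) else x
  al <- alignSamples(m, pheno)
  X <- designMatrix(al$pheno)
  if (nrow(X) <= ncol(X))
    stop("need more samples (", nrow(X), ") than design columns (", ncol(X), ")")
  qrX <- qr(X)
  res <- qr.resid(qrX, al$expr)
  attr(res, "designRank") <- ncol(X)
  if (vec) {
    out <- stats::setNames(as.vector(res), rownames(al$expr))
    attr(out, "designRank") <- ncol(X)
    out
  } else res
}

# Partial correlations of expression columns with a trait, conditional on the
# sex/breed design; shared workhorse of callQtt and the GSEA ranking.
# Returns r, df, constant flags and the expression coefficient.
partialCorStats <- function(expr, pheno, trait) {
  al <- alignSamples(expr, pheno, trait)
  X <- designMatrix(al$pheno)
  n <- nrow(X); q <- ncol(X)
  df <- n - q - 1L
  if (df < 2) stop("residual df = ", df, " < 2: too few samples for association testing")
  qrX <- qr(X)
  resY <- qr.resid(qrX, al$pheno[[trait]])
  resE <- qr.resid(qrX, al$expr)
  ssE <- colSums(resE^2)
  # residual sum of squares ~0 means the probeset is constant (or fully
  # explained by the design): not testable, flagged and excluded
  constant <- ssE < 1e-12
  ssY <- sum(resY^2)
  r <- if (ssY == 0) rep(0, ncol(resE)) else
    as.vector(crossprod(resE, resY)) / sqrt(pmax(ssE, 1e-300) * ssY)
  r[constant] <- 0
  r <- pmin(1, pmax(-1, r))
  coefficient <- as.vector(crossprod(resE, resY)) / pmax(ssE, 1e-300)
  coefficient[constant] <- 0
  list(probeset = colnames(al$expr), r = r, coefficient = coefficient,
       constant = constant, df = df, n = n, q = q)
}

#' Call quantitative trait transcripts for one tissue and metabolite
#'
#' For each probeset, the trait is modelled as intercept + sex + breed +
#' expression; the two-sided t-test on the expression coefficient defines
#' membership at `p < alpha`. Equivalently, the partial correlation r of the
#' residualized trait with the residualized expression gives
#' t = r sqrt(df) / sqrt(1 - r^2), df = n - q - 1 (q = design columns); the
#' implementation uses the partial-correlation route, which is algebraically
#' identical to the per-probeset regression. Zero-variance probesets are
#' reported with p = 1 and excluded from membership.
#'
#' @param expr samples x probesets matrix for one tissue
#' @param pheno phenotype table
#' @param trait metabolite column name
#' @param alpha nominal p threshold (default 0.01)
#' @param tissue tissue label stored in the result
#' @return a [QTTSet-class]
#' @examples
#' sim <- simulateCohort(simulationDesign(nProbesets = 50), seed = 1)
#' callQtt(sim$expression$FATB, sim$phenotypes, "NEFA", tissue = "FATB")
#' @export
callQtt <- function(expr, pheno, trait, alpha = 0.01, tissue = "tissue") {
  st <- partialCorStats(expr, pheno, trait)
  tstat <- st$r * sqrt(st$df) / sqrt(pmax(1 - st$r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), st$df)
  p[st$constant] <- 1
  tstat[st$constant] <- 0
  results <- data.frame(
    probeset = st$probeset, coefficient = st$coefficient, t = tstat, p = p,
    rPartial = st$r, member = p < alpha & !st$constant, constant = st$constant,
    stringsAsFactors = FALSE)
  if (any(st$constant))
    message(sum(st$constant), " constant probeset(s) excluded from QTT calling")
  new("QTTSet", tissue = tissue, trait = trait, results = results,
      alpha = alpha, nPermutations = 0L,
      fdrEstimate = NA_real_, permMeanCount = NA_real_)
}

# QTT count only, for permutation loops (no data.frame construction).
qttCountFast <- function(expr, pheno, trait, alpha) {
  st <- partialCorStats(expr, pheno, trait)
  tstat <- st$r * sqrt(st$df) / sqrt(pmax(1 - st$r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), st$df)
  sum(p < alpha & !st$constant)
}

# Permute whole phenotype rows (trait AND sex AND breed together) across
# samples: preserves the transcriptome correlation structure and the
# trait-covariate association structure under the null.
permutePhenotypes <- function(pheno) {
  perm <- sample(nrow(pheno))
  out <- pheno[perm, , drop = FALSE]
  out$sample <- pheno$sample
  rownames(out) <- NULL
  out
}

#' Phenotype-permutation FDR for a QTT set
#'
#' Whole phenotype rows (trait together with its sex/breed covariates) are
#' randomly re-assigned to samples while the expression matrix is untouched,
#' the QTT calling is re-run, and FDR = mean permuted count / observed count.
#' With an observed count of zero the FDR is undefined and returned as `NA`.
#'
#' @param expr samples x probesets matrix
#' @param pheno phenotype table
#' @param trait metabolite column name
#' @param alpha nominal p threshold
#' @param nPerm number of permutations (default 20)
#' @param seed integer seed (deterministic for a fixed seed)
#' @param tissue tissue label for the returned set
#' @return a [QTTSet-class] with `fdrEstimate`, `permMeanCount` and
#'   `nPermutations` filled in; permuted counts in
#'   `attr(x@fdrEstimate, "permCounts")` are not kept — use
#'   `x@permMeanCount * nPerm` for the total
#' @export
permutationFdr <- function(expr, pheno, trait, alpha = 0.01, nPerm = 20L,
                           seed = 1L, tissue = "tissue") {
  if (nPerm < 1) stop("nPerm must be >= 1")
  qtt <- callQtt(expr, pheno, trait, alpha, tissue)
  observed <- qttCount(qtt)
  counts <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i)
      qttCountFast(expr, permutePhenotypes(pheno), trait, alpha), numeric(1))
  })
  qtt@nPermutations <- as.integer(nPerm)
  qtt@permMeanCount <- mean(counts)
  qtt@fdrEstimate <- if (observed == 0) NA_real_ else min(mean(counts) / observed, Inf)
  qtt
}
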