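# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic child seed for stream `stream` of a global seed; kept below
# 2^31 so it is always a valid integer seed.
childSeed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + stream * 9973) %% 2147483647)
}

# Rand index between two partitions of the same nodes (pair-counting
# agreement; used for planted-module recovery checks).
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  (tot + 2 * sij - si - sj) / tot
}

# Sex/breed design matrix for the sample rows of a phenotype table.
# Errors if either factor has a single level or the factors are confounded.
designMatrix <- function(pheno) {
  sex <- factor(pheno$sex)
  breed <- factor(pheno$breed)
  if (nlevels(sex) < 2)
    stop("sex has a single level ('", levels(sex), "'); the sex effect is not estimable")
  if (nlevels(breed) < 2)
    stop("breed has a single level; the breed effect is not estimable")
  X <- stats::model.matrix(~ sex + breed, data = data.frame(sex = sex, breed = breed))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient: sex and breed are confounded in these samples")
  rownames(X) <- pheno$sample
  X
}

# Align an expression matrix (samples x probesets) and a phenotype table on
# shared samples, optionally dropping samples missing the given trait.
alignSamples <- function(expr, pheno, trait = NULL) {
  if (is.null(rownames(expr)))
    stop("expression matrix must have sample rownames")
  common <- intersect(rownames(expr), pheno$sample)
  if (length(common) == 0) stop("no shared samples between expression and phenotypes")
  ph <- pheno[match(common, pheno$sample), , drop = FALSE]
  if (!is.null(trait)) {
    if (!trait %in% names(ph)) stop("trait '", trait, "' not found in phenotype table")
    keep <- !is.na(ph[[trait]])
    ph <- ph[keep, , drop = FALSE]
    common <- common[keep]
  }
  list(expr = expr[common, , drop = FALSE], pheno = ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
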