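#' Sex and breed effects on a metabolite
#'
#' Ordinary least squares of the trait on intercept + sex + breed. Factor
#' p-values are partial (Type II) F-tests for dropping each factor from the
#' joint two-factor model, so they are invariant to factor order, which
#' matters under mild sex-by-breed imbalance. A zero-variance trait is
#' degenerate and reported with both p-values equal to 1.
#'
#' @param pheno phenotype table (see [readPhenotypes()])
#' @param trait metabolite column name
#' @return list of class `EffectTestResult`: `trait`, `pSex`, `pBreed`,
#'   `fSex`, `fBreed` (the partial F statistics), `mean`, `sd`, and per-level
#'   `sexMeans`/`breedMeans`/`sexSds`/`breedSds`
#' @export
fitSexBreed <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype table")
  keep <- !is.na(pheno[[trait]])
  ph <- pheno[keep, , drop = FALSE]
  ph$sex <- droplevels(factor(ph$sex))
  ph$breed <- droplevels(factor(ph$breed))
  if (nlevels(ph$sex) < 2 || nlevels(ph$breed) < 2)
    stop("need >= 2 sex and breed levels after dropping missing values of ", trait)
  y <- ph[[trait]]
  q <- 1L + (nlevels(ph$sex) - 1L) + (nlevels(ph$breed) - 1L)
  if (length(y) - q <= 0) stop("residual df <= 0 for trait ", trait)
  res <- list(trait = trait, mean = mean(y), sd = stats::sd(y),
              sexMeans = tapply(y, ph$sex, mean),
              breedMeans = tapply(y, ph$breed, mean),
              sexSds = tapply(y, ph$sex, stats::sd),
              breedSds = tapply(y, ph$breed, stats::sd))
  if (stats::sd(y) == 0) {
    res$pSex <- 1; res$pBreed <- 1
    res$fSex <- NA_real_; res$fBreed <- NA_real_
  } else {
    fit <- stats::lm(y ~ sex + breed, data = ph)
    dr <- stats::drop1(fit, test = "F")
    res$pSex <- dr["sex", "Pr(>F)"]
    res$pBreed <- dr["breed", "Pr(>F)"]
    res$fSex <- dr["sex", "F value"]
    res$fBreed <- dr["breed", "F value"]
  }
  structure(res, class = "EffectTestResult")
}

#' Pairwise Pearson correlations among metabolites
#'
#' Pairwise-complete observations; a constant trait gets zero correlations
#' and is flagged in `attr(x, "constantTraits")`.
#'
#' @param pheno phenotype table
#' @param traits trait columns to use (default: all, per `attr(pheno, "traits")`)
#' @return symmetric correlation matrix with unit diagonal
#' @export
traitCorrelations <- function(pheno, traits = NULL) {
  traits <- traits %||% attr(pheno, "traits") %||%
    setdiff(names(pheno), c("sample", "sex", "breed"))
  m <- as.matrix(pheno[, traits, drop = FALSE])
  const <- traits[apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                          sum(!is.na(v)) < 3)]
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constantTraits") <- const
  r
}

#' Breed dendrogram on the 1 - r scale
#'
#' Distances between breed profiles are 1 - Pearson r, so identical profiles
#' merge at height 0, uncorrelated ones at 1, and perfectly anti-correlated
#' ones at 2. Agglomeration is average linkage (UPGMA), which keeps merge
#' heights interpretable on the same scale. Correlation is affine-invariant,
#' so any linear rescaling of the profiles leaves the tree unchanged.
#'
#' @param profiles matrix (breeds x variables) or named list of equal-length
#'   numeric vectors, typically standardized mean trait or expression profiles
#' @return an `hclust` object with breed leaf labels; heights lie in [0,2]
#' @seealso [breedProfiles()], [ape::as.phylo()] for Newick export
#' @export
breedDendrogram <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 breeds")
  if (ncol(profiles) < 3) stop("breed profiles must have length >= 3")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile for breed(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(profiles))
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Per-breed standardized expression profiles
#'
#' For each probeset, expression is z-scored across samples; the breed profile
#' is the per-breed mean of these z-scores (a plain z-score summary of breed
#' expression level).
#'
#' @param expr samples x probesets matrix
#' @param pheno phenotype table covering the expression samples
#' @return breeds x probesets matrix of mean z-scores
#' @export
breedProfiles <- function(expr, pheno) {
  al <- alignSamples(expr, pheno)
  z <- scale(al$expr)
  z[, attr(z, "scaled:scale") == 0] <- 0
  rowsum(z, al$pheno$breed) / as.vector(table(al$pheno$breed))
}

#' @export
print.EffectTestResult <- function(x, ...) {
  cat(x$trait, ": mean ", format(x$mean, digits = 4), " (SD ",
      format(x$sd, digits = 3), "), p_sex = ", format(x$pSex, digits = 3),
      ", p_breed = ", format(x$pBreed, digits = 3), "\n", sep = "")
  invisible(x)
}
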