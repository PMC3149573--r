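#' Describe a synthetic multi-breed, multi-tissue cohort
#'
#' The defaults emulate the study design the package replicates: 16 animals
#' (4 breeds x 4 pigs, 2 of each sex), 5 endocrine tissues, 12 plasma
#' metabolites, log2-intensity-like expression with per-probeset baselines in
#' Uniform(2, 12) and residual SD 0.5, additive breed and sex effects on both
#' traits and transcripts, module structure generated from shared latent
#' factors, and trait associations planted through a latent trait factor so
#' that the sex/breed-adjusted analysis is the correct analysis.
#'
#' @param nBreeds number of breeds
#' @param samplesPerBreed animals per breed
#' @param malesPerBreed males per breed (recycled; remainder are females)
#' @param nTissues number of tissues
#' @param tissueNames tissue labels (defaults to the five endocrine tissues)
#' @param nProbesets probesets per tissue
#' @param nTraits number of metabolite traits
#' @param traitNames trait labels (defaults to 12 standard plasma metabolites)
#' @param nTrueQtt truly associated probesets per (trait, tissue): scalar or a
#'   nTraits x nTissues matrix; 0 plants nothing
#' @param qttPartialCorrelation expected partial correlation of a planted
#'   probeset with its trait after sex/breed adjustment, in `[0,1)`
#' @param nModules co-expression modules planted per tissue
#' @param moduleSizes sizes of the planted modules (recycled to `nModules`)
#' @param withinModuleCorrelation expected pairwise correlation within a
#'   planted module, in `[0,1)`
#' @param noiseSd residual SD of a probeset on the log2 scale
#' @param breedEffectSd SD of additive breed effects (traits and transcripts)
#' @param sexEffectSd SD of additive sex effects (traits and transcripts)
#' @param tissueLoadings per-tissue multiplier on the planted QTT loading
#'   (values below 1 weaken that tissue's planted associations); recycled
#' @return object of class `SimulationDesign` (a validated list)
#' @seealso [simulateCohort()]
#' @export
simulationDesign <- function(nBreeds = 4, samplesPerBreed = 4, malesPerBreed = 2,
                             nTissues = 5,
                             tissueNames = c("FATB", "GONA", "AHYP", "THYG", "HYPO"),
                             nProbesets = 2000, nTraits = 12, traitNames = NULL,
                             nTrueQtt = 0, qttPartialCorrelation = 0.85,
                             nModules = 5, moduleSizes = 50,
                             withinModuleCorrelation = 0.7,
                             noiseSd = 0.5, breedEffectSd = 0.5, sexEffectSd = 0.2,
                             tissueLoadings = 1) {
  if (length(tissueNames) < nTissues)
    tissueNames <- c(tissueNames, sprintf("TIS%02d", seq_len(nTissues)))[seq_len(nTissues)]
  tissueNames <- tissueNames[seq_len(nTissues)]
  if (is.null(traitNames)) {
    std <- c("glucose", "hydroxybutyrate", "NEFA", "cholesterol", "HDL_C",
             "LDL_C", "triglyceride", "total_protein", "ALT", "ALP",
             "haptoglobin", "PigMAP")
    traitNames <- if (nTraits <= length(std)) std[seq_len(nTraits)]
                  else c(std, sprintf("trait%02d", seq_len(nTraits)))[seq_len(nTraits)]
  }
  if (length(nTrueQtt) == 1)
    nTrueQtt <- matrix(nTrueQtt, nTraits, nTissues)
  nTrueQtt <- matrix(as.integer(nTrueQtt), nTraits, nTissues,
                     dimnames = list(traitNames, tissueNames))
  moduleSizes <- rep_len(as.integer(moduleSizes), nModules)
  malesPerBreed <- rep_len(as.integer(malesPerBreed), nBreeds)
  tissueLoadings <- stats::setNames(rep_len(tissueLoadings, nTissues), tissueNames)
  if (any(malesPerBreed < 0 | malesPerBreed > samplesPerBreed))
    stop("malesPerBreed must lie in [0, samplesPerBreed]")
  if (qttPartialCorrelation < 0 || qttPartialCorrelation >= 1)
    stop("qttPartialCorrelation must lie in [0,1)")
  if (withinModuleCorrelation < 0 || withinModuleCorrelation >= 1)
    stop("withinModuleCorrelation must lie in [0,1)")
  if (sum(moduleSizes) > nProbesets)
    stop("planted modules (", sum(moduleSizes), " probesets) exceed nProbesets")
  worst <- max(colSums(nTrueQtt))
  if (sum(moduleSizes) + worst > nProbesets)
    stop("infeasible design: modules plus planted QTT exceed nProbesets")
  structure(list(
    nBreeds = nBreeds, samplesPerBreed = samplesPerBreed,
    malesPerBreed = malesPerBreed, nTissues = nTissues,
    tissueNames = tissueNames, nProbesets = nProbesets,
    nTraits = nTraits, traitNames = traitNames, nTrueQtt = nTrueQtt,
    qttPartialCorrelation = qttPartialCorrelation, nModules = nModules,
    moduleSizes = moduleSizes,
    withinModuleCorrelation = withinModuleCorrelation,
    noiseSd = noiseSd, breedEffectSd = breedEffectSd,
    sexEffectSd = sexEffectSd, tissueLoadings = tissueLoadings
  ), class = "SimulationDesign")
}

#' Simulate a phenotype + multi-tissue expression cohort with known truth
#'
#' Traits are built as breed effect + sex effect + planted latent signal +
#' noise; module probesets share a latent factor so that the expected pairwise
#' within-module correlation equals `withinModuleCorrelation`; truly
#' associated probesets share a latent trait factor so that their expected
#' partial correlation with the trait (conditional on sex and breed) equals
#' `qttPartialCorrelation`. Planted QTT probesets are disjoint from planted
#' modules, and the same trait factor is used in every tissue, so planted QTT
#' for one trait are correlated across tissues.
#'
#' @param design a [simulationDesign()]
#' @param seed integer seed; the same seed reproduces the cohort byte for byte
#' @return list with `phenotypes` (data.frame as from [readPhenotypes()]),
#'   `expression` (named list of samples x probesets matrices, one per
#'   tissue), and `truth` (list: `qtt[[tissue]][[trait]]` data.frames of
#'   planted probesets and effects, `modules[[tissue]]` named integer label
#'   vectors, plus the planted breed/sex trait effects)
#' @export
simulateCohort <- function(design, seed) {
  stopifnot(inherits(design, "SimulationDesign"))
  withSeed(seed, {
    d <- design
    n <- d$nBreeds * d$samplesPerBreed
    breed <- factor(rep(paste0("B", seq_len(d$nBreeds)), each = d$samplesPerBreed))
    sex <- factor(unlist(lapply(seq_len(d$nBreeds), function(b)
      c(rep("M", d$malesPerBreed[b]), rep("F", d$samplesPerBreed - d$malesPerBreed[b])))))
    samples <- sprintf("S%02d", seq_len(n))
    maleInd <- as.numeric(sex == "M")

    rho <- d$qttPartialCorrelation
    planted <- d$nTrueQtt > 0 & rho > 0

    breedTraitEff <- matrix(stats::rnorm(d$nBreeds * d$nTraits, 0, d$breedEffectSd),
                            d$nBreeds, d$nTraits,
                            dimnames = list(levels(breed), d$traitNames))
    sexTraitEff <- stats::setNames(stats::rnorm(d$nTraits, 0, d$sexEffectSd), d$traitNames)
    traitFactor <- matrix(stats::rnorm(n * d$nTraits), n, d$nTraits,
                          dimnames = list(samples, d$traitNames))

    pheno <- data.frame(sample = samples, sex = sex, breed = breed,
                        stringsAsFactors = FALSE)
    for (t in seq_len(d$nTraits)) {
      tr <- d$traitNames[t]
      adj <- if (any(planted[t, ]))
        sqrt(rho) * traitFactor[, t] + sqrt(1 - rho) * stats::rnorm(n)
      else stats::rnorm(n)
      pheno[[tr]] <- breedTraitEff[as.integer(breed), t] +
        maleInd * sexTraitEff[t] + adj
    }
    attr(pheno, "traits") <- d$traitNames

    expression <- list()
    truthQtt <- list()
    truthMod <- list()
    modTotal <- sum(d$moduleSizes)
    for (k in seq_len(d$nTissues)) {
      tis <- d$tissueNames[k]
      P <- d$nProbesets
      probes <- sprintf("%s_ps%05d", tis, seq_len(P))
      z <- matrix(stats::rnorm(n * P), n, P)

      modLabel <- integer(P)
      at <- 0L
      for (m in seq_len(d$nModules)) {
        if (d$moduleSizes[m] == 0) next
        idx <- at + seq_len(d$moduleSizes[m])
        at <- at + d$moduleSizes[m]
        modLabel[idx] <- m
        if (d$withinModuleCorrelation > 0) {
          f <- stats::rnorm(n)
          w <- sqrt(d$withinModuleCorrelation)
          z[, idx] <- w * f + sqrt(1 - w^2) * z[, idx, drop = FALSE]
        }
      }

      qttList <- list()
      free <- setdiff(seq_len(P), seq_len(modTotal))
      for (t in seq_len(d$nTraits)) {
        if (!planted[t, k]) next
        nq <- d$nTrueQtt[t, k]
        if (nq > length(free)) stop("infeasible design: ran out of free probesets")
        idx <- free[seq_len(nq)]
        free <- free[-seq_len(nq)]
        w <- min(1, sqrt(rho) * d$tissueLoadings[k])
        z[, idx] <- w * traitFactor[, t] + sqrt(1 - w^2) * z[, idx, drop = FALSE]
        qttList[[d$traitNames[t]]] <- data.frame(
          probeset = probes[idx],
          effect = rho * min(1, d$tissueLoadings[k]),
          stringsAsFactors = FALSE)
      }

      baseline <- stats::runif(P, 2, 12)
      breedShift <- matrix(stats::rnorm(d$nBreeds * P, 0, d$breedEffectSd), d$nBreeds, P)
      sexShift <- stats::rnorm(P, 0, d$sexEffectSd)
      x <- matrix(baseline, n, P, byrow = TRUE) +
        breedShift[as.integer(breed), , drop = FALSE] +
        outer(maleInd, sexShift) + d$noiseSd * z
      dimnames(x) <- list(samples, probes)

      expression[[tis]] <- x
      truthQtt[[tis]] <- qttList
      truthMod[[tis]] <- stats::setNames(modLabel, probes)
    }

    list(phenotypes = pheno, expression = expression,
         truth = list(qtt = truthQtt, modules = truthMod,
                      breedTraitEffects = breedTraitEff,
                      sexTraitEffects = sexTraitEff,
                      design = d))
  })
}

#' Simulate a many-to-one probeset-to-gene mapping
#'
#' Every gene receives at least one probeset (when `nGenes <= length(probesets)`);
#' the remaining probesets are assigned uniformly, mimicking the many-to-one
#' structure of array annotation.
#'
#' @param probesets character vector of probeset ids
#' @param nGenes number of distinct gene symbols
#' @param seed integer seed
#' @return named character vector (names = probesets, values = gene symbols)
#' @export
simulateProbesetGeneMap <- function(probesets, nGenes, seed) {
  withSeed(seed, {
    genes <- sprintf("G%05d", seq_len(nGenes))
    nP <- length(probesets)
    idx <- if (nP <= nGenes) sample(nGenes, nP)
      else c(sample(nGenes), sample(nGenes, nP - nGenes, replace = TRUE))
    stats::setNames(genes[idx], probesets)
  })
}

#' Build gene sets from a simulated cohort's ground truth
#'
#' One "true" set per planted (tissue, trait) signal containing the genes of
#' the truly associated probesets, plus decoy sets drawn uniformly from the
#' mapped gene universe.
#'
#' @param truth `truth` component of [simulateCohort()]
#' @param map probeset-to-gene mapping (named character vector)
#' @param nDecoySets number of decoy sets
#' @param seed integer seed
#' @param decoySize members per decoy set
#' @return named list of gene sets with a `description` attribute, as from
#'   [readGmt()]
#' @export
simulateGeneSets <- function(truth, map, nDecoySets, seed, decoySize = 50) {
  withSeed(seed, {
    universe <- unique(unname(map))
    sets <- list(); desc <- character()
    for (tis in names(truth$qtt)) {
      for (tr in names(truth$qtt[[tis]])) {
        ps <- truth$qtt[[tis]][[tr]]$probeset
        genes <- unique(unname(map[ps[ps %in% names(map)]]))
        genes <- genes[!is.na(genes)]
        if (length(genes) == 0) next
        nm <- paste("true", tis, tr, sep = "_")
        sets[[nm]] <- genes
        desc[nm] <- paste("planted signal:", tis, tr)
      }
    }
    if (nDecoySets > 0) {
      size <- min(decoySize, length(universe))
      for (i in seq_len(nDecoySets)) {
        nm <- sprintf("decoy_%03d", i)
        sets[[nm]] <- sample(universe, size)
        desc[nm] <- "uniform decoy set"
      }
    }
    attr(sets, "description") <- desc
    sets
  })
}
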