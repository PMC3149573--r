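# Pipeline orchestration: simulate/load -> metabolites -> QTT -> overlap ->
# GSEA -> single-tissue networks -> multi-tissue network, driven by one YAML
# config, with a manifest of outputs and a whole-run cache keyed by the
# config file's md5.

.pipelineKeys <- c("seed", "outdir", "simulate", "inputs", "config", "gsea", "multinet")
.simulateKeys <- c(n_breeds = "nBreeds", samples_per_breed = "samplesPerBreed",
                   males_per_breed = "malesPerBreed", n_tissues = "nTissues",
                   n_probesets = "nProbesets", n_traits = "nTraits",
                   n_true_qtt = "nTrueQtt",
                   qtt_partial_correlation = "qttPartialCorrelation",
                   n_modules = "nModules", module_sizes = "moduleSizes",
                   within_module_correlation = "withinModuleCorrelation",
                   noise_sd = "noiseSd", breed_effect_sd = "breedEffectSd",
                   sex_effect_sd = "sexEffectSd", planted_traits = "plantedTraits",
                   n_genes = "nGenes", n_decoy_sets = "nDecoySets")

readPipelineConfig <- function(configPath) {
  y <- yaml::read_yaml(configPath)
  unknown <- setdiff(names(y), .pipelineKeys)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(y$simulate) && is.null(y$inputs))
    stop("config must contain either a 'simulate' block or an 'inputs' block")
  if (!is.null(y$simulate)) {
    unknown <- setdiff(names(y$simulate), names(.simulateKeys))
    if (length(unknown))
      stop("unknown simulate key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$inputs)) {
    need <- c("phenotypes", "expression")
    miss <- setdiff(need, names(y$inputs))
    if (length(miss))
      stop("inputs block lacks: ", paste(miss, collapse = ", "))
  }
  y$seed <- as.integer(y$seed %||% 1L)
  y
}

# Simulate or load the cohort plus gene map and gene sets.
loadPipelineData <- function(y) {
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    nGenes <- sim$n_genes %||% NULL
    nDecoy <- sim$n_decoy_sets %||% 20L
    plantedTraits <- sim$planted_traits %||% NULL
    args <- sim[setdiff(names(sim), c("planted_traits", "n_genes", "n_decoy_sets"))]
    names(args) <- .simulateKeys[names(args)]
    nTrue <- args$nTrueQtt %||% 0
    args$nTrueQtt <- 0
    design <- do.call(simulationDesign, args)
    if (!is.null(plantedTraits) && any(nTrue > 0)) {
      m <- design$nTrueQtt
      m[intersect(plantedTraits, rownames(m)), ] <- nTrue
      args$nTrueQtt <- m
    } else args$nTrueQtt <- nTrue
    design <- do.call(simulationDesign, args)
    cohort <- simulateCohort(design, childSeed(y$seed, 1L))
    probes <- unlist(lapply(cohort$expression, colnames), use.names = FALSE)
    if (is.null(nGenes)) nGenes <- max(2L, round(0.75 * length(probes)))
    map <- simulateProbesetGeneMap(probes, nGenes, childSeed(y$seed, 2L))
    sets <- simulateGeneSets(cohort$truth, map, nDecoy, childSeed(y$seed, 3L))
    list(phenotypes = cohort$phenotypes, expression = cohort$expression,
         truth = cohort$truth, map = map, sets = sets, design = design)
  } else {
    pheno <- readPhenotypes(y$inputs$phenotypes)
    expression <- lapply(y$inputs$expression, readExpression)
    map <- if (!is.null(y$inputs$gene_map)) readProbesetGeneMap(y$inputs$gene_map)
    sets <- if (!is.null(y$inputs$gene_sets)) readGmt(y$inputs$gene_sets)
    list(phenotypes = pheno, expression = expression, truth = NULL,
         map = map, sets = sets, design = NULL)
  }
}

stageSimulate <- function(data, dir) {
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"))
  writePhenotypes(data$phenotypes, paths[["phenotypes"]])
  for (tis in names(data$expression)) {
    p <- file.path(dir, paste0("expression_", tis, ".tsv"))
    writeExpression(data$expression[[tis]], p)
    paths[paste0("expression_", tis)] <- p
  }
  if (!is.null(data$map)) {
    paths["gene_map"] <- file.path(dir, "gene_map.tsv")
    writeProbesetGeneMap(data$map, paths[["gene_map"]])
  }
  if (!is.null(data$sets)) {
    paths["gene_sets"] <- file.path(dir, "gene_sets.gmt")
    writeGmt(data$sets, paths[["gene_sets"]])
  }
  paths
}

stageMetabolites <- function(data, dir) {
  pheno <- data$phenotypes
  traits <- attr(pheno, "traits") %||% setdiff(names(pheno), c("sample", "sex", "breed"))
  tab <- do.call(rbind, lapply(traits, function(tr) {
    f <- fitSexBreed(pheno, tr)
    data.frame(trait = tr, mean = f$mean, sd = f$sd, pSex = f$pSex,
               pBreed = f$pBreed, stringsAsFactors = FALSE)
  }))
  paths <- c(effects = file.path(dir, "metabolite_effects.tsv"),
             correlations = file.path(dir, "trait_correlations.tsv"),
             dendrogram = file.path(dir, "breed_dendrogram.nwk"))
  utils::write.table(tab, paths[["effects"]], sep = "\t", quote = FALSE, row.names = FALSE)
  r <- traitCorrelations(pheno)
  utils::write.table(round(r, 6), paths[["correlations"]], sep = "\t", quote = FALSE,
                     col.names = NA)
  prof <- rowsum(scale(as.matrix(pheno[, traits])), pheno$breed) /
    as.vector(table(pheno$breed))
  hc <- breedDendrogram(prof)
  ape::write.tree(ape::as.phylo(hc), paths[["dendrogram"]])
  paths
}

stageQtt <- function(data, cfg, seed, dir) {
  pheno <- data$phenotypes
  traits <- attr(pheno, "traits") %||% setdiff(names(pheno), c("sample", "sex", "breed"))
  qttSets <- list()
  i <- 0L
  for (tis in names(data$expression)) {
    for (tr in traits) {
      i <- i + 1L
      qttSets[[paste(tis, tr, sep = ".")]] <- permutationFdr(
        data$expression[[tis]], pheno, tr, alpha = cfg@qttAlpha,
        nPerm = cfg@nQttPermutations, seed = childSeed(seed, 100L + i),
        tissue = tis)
    }
  }
  paths <- c(table2 = file.path(dir, "qtt_counts.tsv"),
             members = file.path(dir, "qtt_members.tsv"))
  utils::write.table(makeTable2(qttSets), paths[["table2"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mem <- do.call(rbind, lapply(qttSets, function(s) {
    r <- s@results[s@results$member, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(tissue = s@tissue, trait = s@trait,
               r[, c("probeset", "coefficient", "t", "p", "rPartial")],
               stringsAsFactors = FALSE)
  }))
  if (is.null(mem)) mem <- data.frame(tissue = character(), trait = character(),
                                      probeset = character())
  utils::write.table(mem, paths[["members"]], sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = paths, qttSets = qttSets)
}

stageOverlap <- function(qttSets, universe, dir) {
  res <- overlapScan(qttSets, universe)
  path <- c(overlap = file.path(dir, "qtt_overlap.tsv"))
  utils::write.table(res, path[["overlap"]], sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stageGsea <- function(data, cfg, seed, gseaBlock, dir) {
  if (is.null(data$map) || is.null(data$sets)) return(character())
  pheno <- data$phenotypes
  allTraits <- attr(pheno, "traits") %||% setdiff(names(pheno), c("sample", "sex", "breed"))
  traits <- gseaBlock$traits %||% allTraits[1]
  tissues <- gseaBlock$tissues %||% names(data$expression)[1]
  paths <- character()
  i <- 0L
  for (tis in tissues) {
    geneExpr <- suppressMessages(collapseProbesets(data$expression[[tis]], data$map))
    for (tr in traits) {
      i <- i + 1L
      res <- suppressMessages(gsea(geneExpr, pheno, tr, data$sets,
                  nPerm = cfg@gseaPermutations, seed = childSeed(seed, 200L + i),
                  weightExponent = cfg@gseaWeightExponent))
      p <- file.path(dir, paste0("gsea_", tis, "_", tr, ".tsv"))
      utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0("gsea_", tis, "_", tr)] <- p
      p5 <- file.path(dir, paste0("gsea_top_", tis, "_", tr, ".tsv"))
      utils::write.table(topNes(res), p5, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0("gsea_top_", tis, "_", tr)] <- p5
    }
  }
  paths
}

stageNetworks <- function(data, cfg, dir) {
  paths <- character(); residuals <- list()
  for (tis in names(data$expression)) {
    res <- residualize(data$expression[[tis]], data$phenotypes)
    residuals[[tis]] <- res
    net <- buildCoexpressionNetwork(res, cfg)
    pf <- file.path(dir, paste0("scalefree_", tis, ".tsv"))
    if (length(net@fit))
      utils::write.table(net@fit$fitTable, pf, sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- file.path(dir, paste0("connectivity_", tis, ".tsv"))
    utils::write.table(net@connectivity, pm, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("scalefree_", tis)] <- pf
    paths[paste0("connectivity_", tis)] <- pm
  }
  list(paths = paths, residuals = residuals)
}

stageMultinet <- function(qttSets, residuals, cfg, trait, dir) {
  sel <- Filter(function(s) s@trait == trait && qttCount(s) > 0, qttSets)
  if (length(sel) < 2) {
    message("multi-tissue network skipped: fewer than 2 tissues with QTT for ", trait)
    return(character())
  }
  names(sel) <- vapply(sel, function(s) s@tissue, character(1))
  mt <- multiTissueNetwork(sel, residuals[names(sel)], cfg)
  paths <- c(nodes = file.path(dir, "multinet_nodes.tsv"),
             pairs = file.path(dir, "multinet_tissue_pairs.tsv"),
             modenr = file.path(dir, "multinet_module_enrichment.tsv"),
             edges = file.path(dir, "multinet_hub_edges.tsv"))
  nodeTab <- merge(mt$network@connectivity, mt$interTissue$profile, by = "node")
  nodeTab <- nodeTab[order(nodeTab$module, -nodeTab$kIntra), ]
  utils::write.table(nodeTab, paths[["nodes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mt$tissuePairs$ranking, paths[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mt$moduleEnrichment, paths[["modenr"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mt$hubEdges, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gml <- writeNetwork(mt$network, edgeThreshold = 0.1,
                      file.path(dir, "multinet"))
  paths["graphml"] <- gml[1]
  paths["edgelist"] <- gml[2]
  paths
}

#' Run the full pipeline from one YAML configuration
#'
#' Executes simulate (or load) -> metabolite statistics -> QTT calling with
#' permutation FDR -> cross-tissue overlap -> GSEA -> per-tissue
#' co-expression networks -> multi-tissue network, writing TSV/Newick/GraphML
#' outputs to `outdir` and a `manifest.yaml` listing every output. Re-running
#' with the same config and seed reproduces identical outputs; if the config
#' file is unchanged and all outputs exist the cached manifest is returned
#' without recomputation (unless `force = TRUE`).
#'
#' @param configPath YAML config with keys `seed`, `outdir`, `simulate` (or
#'   `inputs`), optional `config` (see [readRunConfig()] keys), `gsea`
#'   (traits/tissues) and `multinet` (trait)
#' @param outdir output directory (overrides the config's `outdir`)
#' @param force rerun even if a matching cached manifest exists
#' @return the manifest (named list), invisibly written to
#'   `outdir/manifest.yaml`
#' @export
runAll <- function(configPath, outdir = NULL, force = FALSE) {
  y <- readPipelineConfig(configPath)
  dir <- outdir %||% y$outdir
  if (is.null(dir)) stop("no output directory: set 'outdir' in the config or argument")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- unname(tools::md5sum(configPath))
  manifestPath <- file.path(dir, "manifest.yaml")
  if (!force && file.exists(manifestPath)) {
    man <- yaml::read_yaml(manifestPath)
    if (identical(man$configHash, hash) &&
        all(file.exists(unlist(man$outputs))))
      return(invisible(man))
  }
  cfgArgs <- y$config %||% list()
  cfg <- do.call(readRunConfigList, list(cfgArgs))
  seed <- y$seed

  data <- loadPipelineData(y)
  outputs <- list()
  outputs$simulate <- as.list(stageSimulate(data, dir))
  outputs$metabolites <- as.list(stageMetabolites(data, dir))
  qt <- stageQtt(data, cfg, seed, dir)
  outputs$qtt <- as.list(qt$paths)
  universe <- sum(vapply(data$expression, ncol, integer(1)))
  outputs$overlap <- as.list(stageOverlap(qt$qttSets, universe, dir))
  outputs$gsea <- as.list(stageGsea(data, cfg, seed, y$gsea, dir))
  nw <- stageNetworks(data, cfg, dir)
  outputs$networks <- as.list(nw$paths)
  mnTrait <- y$multinet$trait %||% NULL
  if (!is.null(mnTrait))
    outputs$multinet <- as.list(stageMultinet(qt$qttSets, nw$residuals, cfg,
                                              mnTrait, dir))
  manifest <- list(configHash = hash, seed = seed,
                   version = as.character(utils::packageVersion("qttnet")),
                   outputs = outputs)
  yaml::write_yaml(manifest, manifestPath)
  invisible(manifest)
}

# runConfig from a snake_case key list (shared by runAll and the CLI).
readRunConfigList <- function(lst) {
  unknown <- setdiff(names(lst), names(.configKeyMap))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(lst, .configKeyMap[names(lst)])
  do.call(runConfig, args)
}

#' Grid of QTT counts per trait and tissue
#'
#' One row per trait, one `count` column per tissue with the permutation-mean
#' count alongside (`<tissue>_permMean`), mirroring the standard
#' counts-per-metabolite-per-tissue summary table.
#'
#' @param qttSets list of [QTTSet-class] objects
#' @return data.frame, traits in rows
#' @export
makeTable2 <- function(qttSets) {
  tissues <- unique(vapply(qttSets, function(s) s@tissue, character(1)))
  traits <- unique(vapply(qttSets, function(s) s@trait, character(1)))
  out <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (tis in tissues) {
    cnt <- integer(length(traits)); pm <- rep(NA_real_, length(traits))
    for (i in seq_along(traits)) {
      s <- Filter(function(x) x@tissue == tis && x@trait == traits[i], qttSets)
      if (length(s)) {
        cnt[i] <- qttCount(s[[1]])
        pm[i] <- s[[1]]@permMeanCount
      }
    }
    out[[tis]] <- cnt
    out[[paste0(tis, "_permMean")]] <- pm
  }
  out
}
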