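#' Construct a run configuration
#'
#' Defaults follow the study design this package replicates: QTT at nominal
#' p < 0.01 with a 20-permutation FDR, 1000 GSEA permutations, soft-threshold
#' powers 1..20 with a scale-free R^2 cut of 0.8, minimum module size 30, top
#' 10% intramodular hubs, and multi-tissue edges at nominal p < 1e-4 with
#' BH FDR < 0.05.
#'
#' @param qttAlpha nominal QTT p threshold
#' @param nQttPermutations phenotype permutations for the QTT FDR
#' @param gseaPermutations phenotype permutations for GSEA
#' @param gseaWeightExponent exponent on |metric| in the GSEA running sum
#' @param betaCandidates candidate soft-threshold powers
#' @param scaleFreeR2Cut minimum scale-free fit R^2
#' @param minModuleSize smallest reported module
#' @param hubFraction top fraction of intramodular connectivity per module
#' @param edgeAlpha nominal p threshold for multi-tissue edges
#' @param edgeFdr BH q threshold for multi-tissue edges
#' @param rngSeed global seed; every randomized operation derives its own
#'   child stream from it
#' @return a validated [RunConfig-class]
#' @examples
#' runConfig(rngSeed = 1)
#' @export
runConfig <- function(qttAlpha = 0.01, nQttPermutations = 20L,
                      gseaPermutations = 1000L, gseaWeightExponent = 1,
                      betaCandidates = 1:20, scaleFreeR2Cut = 0.8,
                      minModuleSize = 30L, hubFraction = 0.10,
                      edgeAlpha = 1e-4, edgeFdr = 0.05, rngSeed = 1L) {
  new("RunConfig",
      qttAlpha = as.numeric(qttAlpha),
      nQttPermutations = as.integer(nQttPermutations),
      gseaPermutations = as.integer(gseaPermutations),
      gseaWeightExponent = as.numeric(gseaWeightExponent),
      betaCandidates = as.integer(betaCandidates),
      scaleFreeR2Cut = as.numeric(scaleFreeR2Cut),
      minModuleSize = as.integer(minModuleSize),
      hubFraction = as.numeric(hubFraction),
      edgeAlpha = as.numeric(edgeAlpha),
      edgeFdr = as.numeric(edgeFdr),
      rngSeed = as.integer(rngSeed))
}

# snake_case YAML keys -> runConfig() arguments
.configKeyMap <- c(
  qtt_alpha = "qttAlpha", n_qtt_permutations = "nQttPermutations",
  gsea_permutations = "gseaPermutations",
  gsea_weight_exponent = "gseaWeightExponent",
  beta_candidates = "betaCandidates", scale_free_r2_cut = "scaleFreeR2Cut",
  min_module_size = "minModuleSize", hub_fraction = "hubFraction",
  edge_alpha = "edgeAlpha", edge_fdr = "edgeFdr", rng_seed = "rngSeed")

#' Read a run configuration from YAML
#'
#' Strict schema: any key not in the configuration vocabulary is an error.
#'
#' @param path YAML file with snake_case keys (`qtt_alpha`,
#'   `n_qtt_permutations`, `gsea_permutations`, `gsea_weight_exponent`,
#'   `beta_candidates`, `scale_free_r2_cut`, `min_module_size`,
#'   `hub_fraction`, `edge_alpha`, `edge_fdr`, `rng_seed`)
#' @return a validated [RunConfig-class]
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), names(.configKeyMap))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(y, .configKeyMap[names(y)])
  do.call(runConfig, args)
}
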