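#' @import methods
NULL

#' Run configuration for the QTT/network pipeline
#'
#' Holds every tunable threshold of the analysis: the nominal QTT alpha, the
#' number of phenotype permutations for the QTT FDR, GSEA permutations and
#' weight exponent, soft-threshold candidates and the scale-free R^2 cut,
#' minimum module size, hub fraction, and the edge significance thresholds of
#' the multi-tissue network, plus the global RNG seed from which every
#' randomized operation derives its own deterministic stream.
#'
#' @slot qttAlpha nominal p-value threshold defining a QTT (default 0.01)
#' @slot nQttPermutations phenotype permutations for the QTT FDR (default 20)
#' @slot gseaPermutations phenotype permutations for GSEA (default 1000)
#' @slot gseaWeightExponent exponent on |metric| in the running sum (default 1)
#' @slot betaCandidates candidate soft-threshold powers (default 1:20)
#' @slot scaleFreeR2Cut minimum scale-free fit R^2 (default 0.8)
#' @slot minModuleSize smallest module reported by the tree cut (default 30)
#' @slot hubFraction fraction of top intramodular-connectivity nodes per
#'   module called hubs (default 0.10)
#' @slot edgeAlpha nominal p threshold for multi-tissue edges (default 1e-4)
#' @slot edgeFdr BH q threshold for multi-tissue edges (default 0.05)
#' @slot rngSeed integer seed for all randomized operations
#' @seealso [runConfig()], [readRunConfig()]
#' @exportClass RunConfig
setClass("RunConfig", representation(
  qttAlpha = "numeric",
  nQttPermutations = "integer",
  gseaPermutations = "integer",
  gseaWeightExponent = "numeric",
  betaCandidates = "integer",
  scaleFreeR2Cut = "numeric",
  minModuleSize = "integer",
  hubFraction = "numeric",
  edgeAlpha = "numeric",
  edgeFdr = "numeric",
  rngSeed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  prob <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x < 1
  if (!prob(object@qttAlpha)) msg <- c(msg, "qttAlpha must be in (0,1)")
  if (!prob(object@edgeAlpha)) msg <- c(msg, "edgeAlpha must be in (0,1)")
  if (!prob(object@edgeFdr)) msg <- c(msg, "edgeFdr must be in (0,1)")
  if (object@nQttPermutations < 1L) msg <- c(msg, "nQttPermutations must be >= 1")
  if (object@gseaPermutations < 1L) msg <- c(msg, "gseaPermutations must be >= 1")
  if (object@minModuleSize < 1L) msg <- c(msg, "minModuleSize must be >= 1")
  if (length(object@betaCandidates) == 0 || any(object@betaCandidates < 1L))
    msg <- c(msg, "betaCandidates must be a non-empty set of positive integers")
  if (!(object@scaleFreeR2Cut >= 0 && object@scaleFreeR2Cut <= 1))
    msg <- c(msg, "scaleFreeR2Cut must be in [0,1]")
  if (!(object@hubFraction > 0 && object@hubFraction <= 1))
    msg <- c(msg, "hubFraction must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Quantitative trait transcript (QTT) set
#'
#' Association results of every probeset of one tissue with one metabolite,
#' together with the membership threshold and (optionally) the
#' phenotype-permutation FDR. Membership is nominal p below `alpha` on the
#' expression coefficient of the sex/breed-adjusted linear model.
#'
#' @slot tissue tissue label
#' @slot trait metabolite name
#' @slot results data.frame with one row per tested probeset: probeset,
#'   coefficient, t, p, rPartial, member (logical), constant (logical flag for
#'   zero-variance probesets, excluded from membership)
#' @slot alpha the nominal threshold used
#' @slot nPermutations permutations behind `fdrEstimate` (0 if not computed)
#' @slot fdrEstimate mean permuted QTT count / observed count; `NA` when the
#'   observed count is zero (undefined) or the FDR was not computed
#' @slot permMeanCount mean QTT count across phenotype permutations (`NA` if
#'   not computed)
#' @seealso [callQtt()], [permutationFdr()], [qttMembers()]
#' @exportClass QTTSet
setClass("QTTSet", representation(
  tissue = "character",
  trait = "character",
  results = "data.frame",
  alpha = "numeric",
  nPermutations = "integer",
  fdrEstimate = "numeric",
  permMeanCount = "numeric"
))

setValidity("QTTSet", function(object) {
  msg <- character()
  need <- c("probeset", "coefficient", "t", "p", "rPartial", "member", "constant")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    r <- object@results
    if (any(r$member & !(r$p < object@alpha), na.rm = TRUE))
      msg <- c(msg, "every member must have p < alpha")
    if (any(r$p < 0 | r$p > 1, na.rm = TRUE))
      msg <- c(msg, "p values must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted co-expression network
#'
#' Soft-threshold adjacency a_ij = |r_ij|^beta over the probesets (or
#' tissue-tagged nodes) of a residualized expression matrix, with the signed
#' Pearson correlations retained, module labels (0 = unassigned, 1..M ordered
#' by decreasing size) and per-node connectivity statistics once computed.
#'
#' @slot adjacency symmetric matrix in [0,1], unit diagonal by convention
#' @slot correlations the underlying signed Pearson correlation matrix
#' @slot beta the soft-threshold power used
#' @slot modules named integer vector of module labels (may be empty before
#'   module detection)
#' @slot connectivity data.frame (node, module, k, kIntra) or empty
#' @slot tissues named character vector tagging each node with its tissue
#'   (empty for single-tissue networks)
#' @slot fit scale-free fit record from [pickSoftThreshold()] (may be empty)
#' @seealso [softAdjacency()], [buildCoexpressionNetwork()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork", representation(
  adjacency = "matrix",
  correlations = "matrix",
  beta = "numeric",
  modules = "integer",
  connectivity = "data.frame",
  tissues = "character",
  fit = "list"
))

setValidity("CoexpressionNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (any(a < -1e-12 | a > 1 + 1e-12)) msg <- c(msg, "adjacency entries must be in [0,1]")
  if (nrow(a) > 0 && max(abs(a - t(a))) > 1e-10) msg <- c(msg, "adjacency must be symmetric")
  if (length(object@modules) && length(object@modules) != nrow(a))
    msg <- c(msg, "modules must label every node")
  if (length(msg)) msg else TRUE
})
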