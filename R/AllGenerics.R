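#' Probesets that pass the nominal QTT threshold
#'
#' @param x a [QTTSet-class]
#' @return character vector of member probeset ids
#' @export
setGeneric("qttMembers", function(x) standardGeneric("qttMembers"))

#' Number of QTT members
#'
#' @param x a [QTTSet-class]
#' @return integer count of members
#' @export
setGeneric("qttCount", function(x) standardGeneric("qttCount"))

#' Adjacency matrix accessor
#'
#' @param x a [CoexpressionNetwork-class]
#' @return the symmetric soft-threshold adjacency matrix
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Module label accessor
#'
#' @param x a [CoexpressionNetwork-class]
#' @return named integer vector of module labels (0 = unassigned)
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' Connectivity profile accessor
#'
#' @param x a [CoexpressionNetwork-class]
#' @return data.frame with per-node whole-network and intramodular connectivity
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

setMethod("qttMembers", "QTTSet", function(x) {
  x@results$probeset[x@results$member]
})

setMethod("qttCount", "QTTSet", function(x) {
  sum(x@results$member)
})

setMethod("adjacency", "CoexpressionNetwork", function(x) x@adjacency)
setMethod("moduleLabels", "CoexpressionNetwork", function(x) x@modules)
setMethod("connectivity", "CoexpressionNetwork", function(x) x@connectivity)

setMethod("show", "QTTSet", function(object) {
  n <- qttCount(object)
  cat("QTTSet:", object@tissue, "/", object@trait, "\n")
  cat("  ", nrow(object@results), "probesets tested, ", n,
      " QTT at p <", object@alpha, "\n")
  if (object@nPermutations > 0L) {
    cat("  permutation FDR:", format(object@fdrEstimate, digits = 3),
        "(", object@nPermutations, "permutations, mean permuted count",
        format(object@permMeanCount, digits = 4), ")\n")
  }
  invisible(object)
})

setMethod("show", "CoexpressionNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat("CoexpressionNetwork with", n, "nodes, beta =", object@beta, "\n")
  if (length(object@tissues))
    cat("  multi-tissue:", paste(names(table(object@tissues)), table(object@tissues),
                                 sep = "=", collapse = ", "), "\n")
  if (length(object@modules)) {
    tab <- table(object@modules)
    cat("  modules:", paste(names(tab), tab, sep = ":", collapse = ", "),
        "(0 = unassigned)\n")
  }
  invisible(object)
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  QTT: alpha =", object@qttAlpha, ", permutations =", object@nQttPermutations, "\n")
  cat("  GSEA: permutations =", object@gseaPermutations,
      ", weight exponent =", object@gseaWeightExponent, "\n")
  cat("  network: beta candidates", min(object@betaCandidates), "...",
      max(object@betaCandidates), ", R2 cut =", object@scaleFreeR2Cut,
      ", min module size =", object@minModuleSize, "\n")
  cat("  multi-tissue edges: p <", object@edgeAlpha, ", FDR <", object@edgeFdr,
      "; hub fraction =", object@hubFraction, "\n")
  cat("  seed:", object@rngSeed, "\n")
  invisible(object)
})
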