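#' Read a tissue expression matrix
#'
#' Expression files are tab-delimited with probesets in rows (first column
#' `probeset`, the array convention) and samples in columns; in memory the
#' matrix is transposed to samples in rows, probesets in columns, which is the
#' orientation every other function in the package expects.
#'
#' @param path path to a tab-delimited expression file
#' @return numeric matrix, samples x probesets, with dimnames
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"),
#'   c("p1", "p2", "p3"))), tf)
#' readExpression(tf)
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file must have a probeset column plus sample columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated probeset id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1]
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' at probeset ", ids[bad[1]],
             ", sample ", samples[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m)))
    stop("expression values must be finite; found NA/Inf")
  rownames(m) <- ids
  t(m)
}

#' Write a tissue expression matrix
#'
#' Inverse of [readExpression()]: the in-memory samples x probesets matrix is
#' written probesets-in-rows.
#'
#' @param expr numeric matrix, samples x probesets
#' @param path output path
#' @return invisibly, `path`
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(probeset = colnames(expr), t(expr), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns `sample`, `sex`, `breed` followed by one numeric column
#' per metabolite. Missing metabolite values are allowed (samples with a
#' missing value for a trait are dropped for that trait only, downstream).
#'
#' @param path path to the CSV file
#' @return data.frame with `sample` (character), `sex` and `breed` (factors,
#'   2 and >= 2 levels respectively) and numeric trait columns; trait names in
#'   `attr(x, "traits")`
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "sex", "breed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicated sample ids in phenotype file")
  df$sex <- factor(df$sex)
  df$breed <- factor(df$breed)
  if (nlevels(df$sex) != 2)
    stop("sex must have exactly 2 levels, found ", nlevels(df$sex),
         " (", paste(levels(df$sex), collapse = ", "), ")")
  if (nlevels(df$breed) < 2)
    stop("breed must have at least 2 levels")
  traits <- setdiff(names(df), need)
  if (length(traits) == 0) stop("phenotype file has no metabolite columns")
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    bad <- which(is.na(v) & !is.na(df[[tr]]) & df[[tr]] != "")
    if (length(bad))
      stop("non-numeric value '", df[[tr]][bad[1]], "' in trait ", tr,
           ", sample ", df$sample[bad[1]])
    df[[tr]] <- v
  }
  attr(df, "traits") <- traits
  df
}

#' Write a phenotype table
#' @param pheno phenotype data.frame as returned by [readPhenotypes()]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member gene ids.
#' Members are deduplicated within each set.
#'
#' @param path path to a GMT file
#' @return named list of character vectors (the members), with per-set
#'   descriptions in `attr(x, "description")`
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, members)")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("GMT line ", i, " defines an empty set")
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of member vectors (optionally with a `description`
#'   attribute as produced by [readGmt()])
#' @param path output path
#' @return invisibly, `path`
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probeset-to-gene mapping table
#'
#' Two-column TSV (probeset, gene). The mapping may be many probesets to one
#' gene but never one probeset to several genes.
#'
#' @param path path to the TSV file
#' @return named character vector: names are probesets, values gene symbols
#' @export
readProbesetGeneMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("mapping file must have probeset and gene columns")
  ps <- as.character(df[[1]]); gene <- as.character(df[[2]])
  if (anyDuplicated(ps)) {
    dup <- unique(ps[duplicated(ps)])
    conflicting <- dup[vapply(dup, function(p) length(unique(gene[ps == p])) > 1, logical(1))]
    if (length(conflicting))
      stop("probeset(s) mapped to more than one gene: ",
           paste(conflicting, collapse = ", "))
    keep <- !duplicated(ps)
    ps <- ps[keep]; gene <- gene[keep]
  }
  stats::setNames(gene, ps)
}

#' Write a probeset-to-gene mapping table
#' @param map named character vector (names = probesets, values = genes)
#' @param path output path
#' @return invisibly, `path`
#' @export
writeProbesetGeneMap <- function(map, path) {
  utils::write.table(data.frame(probeset = names(map), gene = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-expression network as GraphML and a TSV edge list
#'
#' Emits `<basePath>.graphml` (nodes carry tissue and module attributes) and
#' `<basePath>_edges.tsv` (node1, node2, adjacency, sign of the underlying
#' correlation), keeping only edges with adjacency at or above the threshold.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param edgeThreshold minimum adjacency for an edge to be written, in [0,1]
#'   (a threshold above 1 writes an empty edge set)
#' @param basePath output path without extension
#' @return invisibly, character vector of the two files written
#' @export
writeNetwork <- function(net, edgeThreshold, basePath) {
  stopifnot(is(net, "CoexpressionNetwork"))
  if (edgeThreshold < 0) stop("edgeThreshold must be >= 0")
  a <- net@adjacency
  nodes <- rownames(a) %||% as.character(seq_len(nrow(a)))
  idx <- which(upper.tri(a) & a >= edgeThreshold, arr.ind = TRUE)
  edges <- data.frame(
    node1 = nodes[idx[, 1]],
    node2 = nodes[idx[, 2]],
    adjacency = a[idx],
    sign = ifelse(net@correlations[idx] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  vdf <- data.frame(
    name = nodes,
    tissue = if (length(net@tissues)) unname(net@tissues[nodes]) else NA_character_,
    module = if (length(net@modules)) unname(net@modules[nodes]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  graphml <- paste0(basePath, ".graphml")
  tsv <- paste0(basePath, "_edges.tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  utils::write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml, tsv))
}
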