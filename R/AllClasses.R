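#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<-
NULL

setOldClass("phylo")
setClassUnion("phyloOrNULL", c("phylo", "NULL"))

#' The nine soil covariates used for environmental attribution
#'
#' Column names expected in an environmental factor table: total nitrogen,
#' total phosphorus, total potassium, salinity, soil organic matter, soil
#' urease, soil alkaline phosphatase, soil sucrase and pH.
#'
#' @export
SOIL_FACTORS <- c("TN", "TP", "TK", "salt", "SOM", "SUE", "SALP", "SSC", "pH")

#' CommunityExperiment: an OTU table with sample groups, soil factors and a
#' phylogeny
#'
#' S4 container for a microbial community survey along a disturbance
#' gradient. Extends [SummarizedExperiment::SummarizedExperiment] with taxa
#' as rows and samples as columns; the single assay `"counts"` holds read
#' counts or relative abundances. `colData` carries the mandatory `group`
#' label (the distance class of each sample) and, optionally, the nine soil
#' covariates of [SOIL_FACTORS]. A rooted phylogeny over the taxa may be
#' attached in the `tree` slot; it is required by the phylogenetic null
#' models and ignored elsewhere.
#'
#' Validity requires non-negative abundances, no all-zero sample, unique
#' sample and taxon identifiers, exactly one group label per sample, and —
#' when a tree is attached — that its tip set covers the taxa.
#'
#' @slot tree a rooted `ape::phylo` object or `NULL`.
#' @export
setClass("CommunityExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "phyloOrNULL")
)

setValidity("CommunityExperiment", function(object) {
  msg <- character()
  m <- assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "taxa and samples must be named")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate taxon identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("negative abundance at taxon '%s', sample '%s'",
                          rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  zero <- colSums(m) == 0
  if (any(zero))
    msg <- c(msg, paste0("all-zero sample(s): ",
                         paste(colnames(m)[zero], collapse = ", ")))
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(colData(object)$group))
    msg <- c(msg, "every sample needs a group label")
  if (!is.null(object@tree)) {
    missing <- setdiff(rownames(m), object@tree$tip.label)
    if (length(missing))
      msg <- c(msg, paste0("taxa missing from the tree: ",
                           paste(utils::head(missing, 5L), collapse = ", "),
                           if (length(missing) > 5L) ", ..."))
    if (!is.null(object@tree$edge.length) &&
        any(object@tree$edge.length < 0))
      msg <- c(msg, "tree has negative branch lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityExperiment
#'
#' @param counts numeric matrix of abundances, samples x taxa (the usual
#'   survey-table orientation) with sample ids as rownames and taxon ids as
#'   colnames. Stored internally taxa x samples.
#' @param group factor or character vector of group labels, one per sample,
#'   named by sample id or in the order of `rownames(counts)`.
#' @param env optional data.frame/matrix of soil covariates (samples x
#'   factors), rownames matching sample ids; columns must be a subset of
#'   [SOIL_FACTORS] named exactly.
#' @param tree optional rooted `phylo` whose tips cover the taxa.
#'
#' Sample and taxon order is canonicalised (lexicographic) so downstream
#' output is order-stable regardless of input order.
#'
#' @return a validated [CommunityExperiment-class] object.
#' @export
CommunityExperiment <- function(counts, group, env = NULL, tree = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have sample rownames and taxon colnames")
  if (!is.null(names(group))) {
    miss <- setdiff(rownames(counts), names(group))
    if (length(miss))
      stop("samples absent from metadata: ", paste(miss, collapse = ", "))
    group <- group[rownames(counts)]
  } else if (length(group) != nrow(counts)) {
    stop("'group' must have one label per sample")
  }
  ord_s <- order(rownames(counts))
  ord_t <- order(colnames(counts))
  counts <- counts[ord_s, ord_t, drop = FALSE]
  group <- factor(as.character(group)[ord_s])
  cd <- DataFrame(group = group, row.names = rownames(counts))
  if (!is.null(env)) {
    env <- as.data.frame(env)
    if (is.null(rownames(env)))
      stop("'env' must have sample rownames")
    miss <- setdiff(rownames(counts), rownames(env))
    if (length(miss))
      stop("samples absent from env table: ", paste(miss, collapse = ", "))
    bad <- setdiff(colnames(env), SOIL_FACTORS)
    if (length(bad))
      stop("unknown soil factor column(s): ", paste(bad, collapse = ", "))
    if (anyNA(env))
      stop("env table contains missing values")
    for (f in colnames(env))
      cd[[f]] <- as.numeric(env[rownames(counts), f])
  }
  new("CommunityExperiment",
      SummarizedExperiment(assays = list(counts = t(counts)), colData = cd),
      tree = tree)
}

#' @describeIn CommunityExperiment abundance matrix in samples x taxa
#'   orientation.
#' @param x a `CommunityExperiment`.
#' @export
communityMatrix <- function(x) t(assay(x, "counts"))

#' @describeIn CommunityExperiment named factor of group labels per sample.
#' @export
sampleGroups <- function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
}

#' @describeIn CommunityExperiment soil covariate matrix (samples x
#'   factors), or `NULL` when none are attached.
#' @export
soilFactors <- function(x) {
  fac <- intersect(SOIL_FACTORS, colnames(colData(x)))
  if (!length(fac)) return(NULL)
  m <- as.matrix(as.data.frame(colData(x)[, fac, drop = FALSE]))
  rownames(m) <- colnames(x)
  m
}

#' @describeIn CommunityExperiment the attached phylogeny (`phylo` or
#'   `NULL`).
#' @export
phyloTree <- function(x) x@tree

#' @describeIn CommunityExperiment attach or replace the phylogeny.
#' @param value a rooted `phylo`.
#' @export
`phyloTree<-` <- function(x, value) {
  x@tree <- value
  validObject(x)
  x
}

#' @describeIn CommunityExperiment `TRUE` when every sample row sums to 1
#'   (relative-abundance form).
#' @export
isRelative <- function(x) {
  all(abs(colSums(assay(x, "counts")) - 1) < 1e-9)
}

setMethod("show", "CommunityExperiment", function(object) {
  cat("CommunityExperiment:", ncol(object), "samples x", nrow(object),
      "taxa\n")
  g <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s(%d)", names(g), g), collapse = " "), "\n")
  cat("scale:", if (isRelative(object)) "relative abundance" else "counts",
      "\n")
  fac <- intersect(SOIL_FACTORS, colnames(colData(object)))
  if (length(fac))
    cat("soil factors:", paste(fac, collapse = ", "), "\n")
  if (!is.null(object@tree))
    cat("tree:", length(object@tree$tip.label), "tips\n")
  invisible(NULL)
})

#' Subset a CommunityExperiment to one group's samples
#'
#' @param x a `CommunityExperiment`.
#' @param group group label.
#' @return the `CommunityExperiment` restricted to that group's samples.
#' @export
subsetGroup <- function(x, group) {
  keep <- as.character(colData(x)$group) == group
  if (!any(keep)) stop("no samples in group '", group, "'")
  x[, keep]
}
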