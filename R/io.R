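#' @importFrom utils read.delim read.csv write.table head
#' @importFrom ape read.tree write.tree
NULL

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, row.names = 1,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an OTU table plus sample metadata into a CommunityExperiment
#'
#' The abundance matrix may have taxa as rows (the common OTU-table layout)
#' or samples as rows; the orientation is auto-detected by matching the
#' metadata's sample identifiers against row and column names, or forced
#' with `taxaAsRows`.
#'
#' @param path TSV/CSV dense abundance matrix with row and column names.
#' @param metadataPath TSV/CSV with columns `sample` and `group`.
#' @param envPath optional CSV of soil covariates with a `sample` column and
#'   the nine [SOIL_FACTORS] columns.
#' @param treePath optional newick file; tips must cover the taxa.
#' @param taxaAsRows logical or `NULL` (auto-detect).
#' @return a validated [CommunityExperiment-class].
#' @export
readCommunity <- function(path, metadataPath, envPath = NULL,
                          treePath = NULL, taxaAsRows = NULL) {
  m <- as.matrix(.read_table_auto(path))
  storage.mode(m) <- "double"
  sep <- if (grepl("\\.csv$", metadataPath, ignore.case = TRUE)) "," else "\t"
  meta <- read.delim(metadataPath, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(meta)))
    stop("metadata must have 'sample' and 'group' columns")
  if (anyDuplicated(meta$sample))
    stop("duplicate sample ids in metadata")
  if (is.null(taxaAsRows)) {
    in_cols <- mean(colnames(m) %in% meta$sample)
    in_rows <- mean(rownames(m) %in% meta$sample)
    taxaAsRows <- in_cols >= in_rows
  }
  if (taxaAsRows) m <- t(m)
  unmatched <- setdiff(rownames(m), meta$sample)
  if (length(unmatched))
    stop("samples in matrix but absent from metadata: ",
         paste(unmatched, collapse = ", "))
  group <- stats::setNames(meta$group, meta$sample)[rownames(m)]
  env <- if (!is.null(envPath)) readEnv(envPath) else NULL
  tree <- if (!is.null(treePath)) readTree(treePath, taxa = colnames(m))
          else NULL
  CommunityExperiment(m, group = group, env = env, tree = tree)
}

#' Read a soil covariate table
#'
#' @param path CSV/TSV with a `sample` column and exactly the nine
#'   [SOIL_FACTORS] columns; no missing values allowed.
#' @return data.frame of covariates with sample rownames.
#' @export
readEnv <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  env <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(env))
    stop("env table must have a 'sample' column")
  rownames(env) <- env$sample
  env$sample <- NULL
  missing <- setdiff(SOIL_FACTORS, colnames(env))
  if (length(missing))
    stop("env table missing factor column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(env), SOIL_FACTORS)
  if (length(extra))
    stop("unexpected env column(s): ", paste(extra, collapse = ", "))
  if (anyNA(env)) stop("env table contains missing values")
  env[, SOIL_FACTORS, drop = FALSE]
}

#' Read a rooted newick tree
#'
#' @param path newick file.
#' @param taxa optional taxon ids that must all be tips; missing tips raise
#'   an error naming them.
#' @return an `ape::phylo`.
#' @export
readTree <- function(path, taxa = NULL) {
  tree <- read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  tree
}

#' Convert a CommunityExperiment to relative abundance
#'
#' Total-sum scaling: each sample row is divided by its total so rows sum
#' to one. Idempotent; group metadata, soil factors and tree are preserved.
#'
#' @param x a [CommunityExperiment-class] with positive sample sums.
#' @return the same object on the relative-abundance scale.
#' @export
toRelative <- function(x) {
  m <- assay(x, "counts")
  tot <- colSums(m)
  if (any(tot == 0)) stop("all-zero sample(s) cannot be normalised")
  assays(x)$counts <- sweep(m, 2, tot, "/")
  x
}

#' @importFrom SummarizedExperiment assays assays<-
NULL

#' Seeded rarefaction to even depth (optional; off by default in the
#' pipeline)
#'
#' @param x count-form `CommunityExperiment`.
#' @param depth target reads per sample; defaults to the minimum sample sum.
#' @param seed RNG seed.
#' @return rarefied `CommunityExperiment` (samples below `depth` dropped
#'   with a warning).
#' @export
rarefyCommunity <- function(x, depth = NULL, seed = 1) {
  m <- communityMatrix(x)
  if (any(abs(m - round(m)) > 1e-8))
    stop("rarefaction needs integer counts")
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot)
  drop <- tot < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth)
    m <- m[!drop, , drop = FALSE]
  }
  set.seed(seed)
  r <- vegan::rrarefy(m, depth)
  CommunityExperiment(r, group = sampleGroups(x)[rownames(r)],
                      env = {
                        e <- soilFactors(x)
                        if (is.null(e)) NULL else e[rownames(r), , drop = FALSE]
                      },
                      tree = phyloTree(x))
}

#' Write a CommunityExperiment as OTU table + metadata TSVs
#'
#' The abundance matrix is written taxa-as-rows with an `otu_id` header
#' column; metadata gets `sample` and `group` columns. `readCommunity()` on
#' the two files reproduces the object.
#'
#' @param x a `CommunityExperiment`.
#' @param path OTU table TSV path.
#' @param metadataPath metadata TSV path.
#' @param envPath optional path for the soil covariates (written only when
#'   present).
#' @export
writeCommunity <- function(x, path, metadataPath, envPath = NULL) {
  m <- assay(x, "counts")  # taxa x samples
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(x),
                     group = as.character(colData(x)$group))
  write.table(meta, metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  env <- soilFactors(x)
  if (!is.null(envPath) && !is.null(env)) {
    edf <- data.frame(sample = rownames(env), env, check.names = FALSE)
    write.table(edf, envPath, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write pairwise assembly results in long format
#'
#' @param pairwise data.frame from [assemblyAnalysis()].
#' @param path TSV path.
#' @export
writePairwise <- function(pairwise, path) {
  write.table(pairwise, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a co-occurrence network as GEXF (Gephi) or GraphML
#'
#' Node attributes `module`, `zi`, `pi`, `role` and edge attributes
#' `weight` (Spearman rho) and `sign` are carried when present on the
#' graph. An empty network yields a valid file with zero edges and a
#' warning.
#'
#' @param net an `igraph` network from [buildNetwork()], ideally after
#'   [ziPi()] has annotated roles.
#' @param path output file.
#' @export
writeGEXF <- function(net, path) {
  if (igraph::ecount(net) == 0)
    warning("writing network with zero edges")
  vn <- igraph::V(net)$name
  va <- igraph::vertex_attr_names(net)
  ea <- igraph::edge_attr_names(net)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">')
  natts <- setdiff(va, "name")
  if (length(natts)) {
    lines <- c(lines, '    <attributes class="node">')
    for (i in seq_along(natts)) {
      typ <- if (is.numeric(igraph::vertex_attr(net, natts[i])))
        "double" else "string"
      lines <- c(lines, sprintf(
        '      <attribute id="%d" title="%s" type="%s"/>',
        i - 1L, natts[i], typ))
    }
    lines <- c(lines, "    </attributes>")
  }
  eatts <- setdiff(ea, "weight")
  if (length(eatts)) {
    lines <- c(lines, '    <attributes class="edge">')
    for (i in seq_along(eatts)) {
      typ <- if (is.numeric(igraph::edge_attr(net, eatts[i])))
        "double" else "string"
      lines <- c(lines, sprintf(
        '      <attribute id="e%d" title="%s" type="%s"/>',
        i - 1L, eatts[i], typ))
    }
    lines <- c(lines, "    </attributes>")
  }
  lines <- c(lines, "    <nodes>")
  for (v in seq_along(vn)) {
    atts <- ""
    if (length(natts)) {
      vals <- vapply(natts, function(a)
        as.character(igraph::vertex_attr(net, a, v)), "")
      atts <- paste0(
        "<attvalues>",
        paste0(sprintf('<attvalue for="%d" value="%s"/>',
                       seq_along(natts) - 1L, .xml_escape(vals)),
               collapse = ""),
        "</attvalues>")
    }
    lines <- c(lines, sprintf('      <node id="%s" label="%s">%s</node>',
                              .xml_escape(vn[v]), .xml_escape(vn[v]), atts))
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_edgelist(net)
    w <- if ("weight" %in% ea) igraph::E(net)$weight
         else rep(1, nrow(el))
    for (e in seq_len(nrow(el))) {
      atts <- ""
      if (length(eatts)) {
        vals <- vapply(eatts, function(a)
          as.character(igraph::edge_attr(net, a, e)), "")
        atts <- paste0(
          "<attvalues>",
          paste0(sprintf('<attvalue for="e%d" value="%s"/>',
                         seq_along(eatts) - 1L, .xml_escape(vals)),
                 collapse = ""),
          "</attvalues>")
      }
      lines <- c(lines, sprintf(
        '      <edge id="%d" source="%s" target="%s" weight="%s">%s</edge>',
        e - 1L, .xml_escape(el[e, 1]), .xml_escape(el[e, 2]),
        format(w[e], digits = 10), atts))
    }
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGEXF
#' @export
writeGraphML <- function(net, path) {
  if (igraph::ecount(net) == 0)
    warning("writing network with zero edges")
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
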