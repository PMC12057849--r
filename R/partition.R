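#' Classify taxa as abundant, rare or intermediate within one group
#'
#' A taxon is *abundant* in a distance group when its minimum relative
#' abundance over the group's samples exceeds `abundantThresh` (default
#' 0.1%), and *rare* when its maximum stays below `rareThresh` (default
#' 0.01%); everything else is *intermediate*. Both inequalities are strict.
#' Taxa entirely absent from the group have maximum 0 and classify as rare.
#'
#' @param x relative-abundance [CommunityExperiment-class].
#' @param group group label.
#' @param abundantThresh abundance floor for "abundant" (fraction).
#' @param rareThresh abundance ceiling for "rare" (fraction); must be below
#'   `abundantThresh`.
#' @return named character vector over taxa with values
#'   `"abundant"`, `"rare"` or `"intermediate"`.
#' @export
classifyGroup <- function(x, group, abundantThresh = 0.001,
                          rareThresh = 1e-4) {
  if (abundantThresh <= rareThresh)
    stop("abundantThresh must exceed rareThresh")
  if (!isRelative(x))
    stop("classification needs a relative-abundance table; see toRelative()")
  m <- communityMatrix(subsetGroup(x, group))
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  lab <- rep("intermediate", ncol(m))
  lab[mins > abundantThresh] <- "abundant"
  lab[maxs < rareThresh] <- "rare"
  stats::setNames(lab, colnames(m))
}

#' Partition a community into combined abundant and rare sub-tables
#'
#' Applies [classifyGroup()] to every group, then builds the combined
#' tables: in the abundant table a sample keeps its observed relative
#' abundance for taxon *t* if *t* is abundant in that sample's group and is
#' set to exactly 0 otherwise (symmetrically for rare). Because the labels
#' are per-group, a taxon may be abundant at one distance and rare at
#' another. Columns that are zero everywhere in a combined table are
#' dropped.
#'
#' @inheritParams classifyGroup
#' @return a `communityPartition` list: `labels` (taxa x groups character
#'   matrix), `abundant` and `rare` (combined
#'   [CommunityExperiment-class]s), and the thresholds used.
#' @export
buildPartition <- function(x, abundantThresh = 0.001, rareThresh = 1e-4) {
  groups <- levels(sampleGroups(x))
  if (length(groups) < 2)
    stop("partition needs at least 2 groups")
  labels <- vapply(groups, function(g)
    classifyGroup(x, g, abundantThresh, rareThresh),
    character(nrow(x)))
  m <- communityMatrix(x)
  grp <- as.character(sampleGroups(x))
  mask <- function(kind) {
    keep <- labels[colnames(m), grp, drop = FALSE] == kind  # taxa x samples
    m * t(keep)  # dimnames of m (samples x taxa) win
  }
  sub_table <- function(mm) {
    mm <- mm[, colSums(mm) > 0, drop = FALSE]
    if (ncol(mm) == 0)
      stop("no taxa qualify; thresholds too extreme")
    keepS <- rowSums(mm) > 0
    if (any(!keepS))
      warning("dropping sample(s) with no qualifying taxa: ",
              paste(rownames(mm)[!keepS], collapse = ", "))
    mm <- mm[keepS, , drop = FALSE]
    CommunityExperiment(mm, group = sampleGroups(x)[rownames(mm)],
                        env = {
                          e <- soilFactors(x)
                          if (is.null(e)) NULL
                          else e[rownames(mm), , drop = FALSE]
                        },
                        tree = phyloTree(x))
  }
  structure(list(labels = labels,
                 abundant = sub_table(mask("abundant")),
                 rare = sub_table(mask("rare")),
                 abundantThresh = abundantThresh,
                 rareThresh = rareThresh),
            class = "communityPartition")
}

#' @export
print.communityPartition <- function(x, ...) {
  cat("communityPartition (thresholds", x$abundantThresh, "/",
      x$rareThresh, ")\n")
  tab <- apply(x$labels, 2, function(l) table(factor(
    l, levels = c("abundant", "intermediate", "rare"))))
  print(tab)
  cat("combined abundant table:", ncol(x$abundant), "taxa;",
      "combined rare table:", ncol(x$rare), "taxa\n")
  invisible(x)
}

#' Write partition outputs
#'
#' @param part a `communityPartition`.
#' @param dir output directory; writes `abundant.tsv`, `rare.tsv` (+
#'   metadata files) and `labels.tsv`.
#' @export
writePartition <- function(part, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCommunity(part$abundant, file.path(dir, "abundant.tsv"),
                 file.path(dir, "abundant_metadata.tsv"))
  writeCommunity(part$rare, file.path(dir, "rare.tsv"),
                 file.path(dir, "rare_metadata.tsv"))
  lab <- data.frame(otu_id = rownames(part$labels), part$labels,
                    check.names = FALSE)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
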