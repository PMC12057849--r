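#' @importFrom stats cophenetic as.dist
NULL

#' The five community assembly process labels
#' @export
ASSEMBLY_PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
                        "dispersal_limitation", "homogenizing_dispersal",
                        "undominated")

# row-wise minima of a matrix, vectorised over columns
.row_mins <- function(A) {
  if (ncol(A) == 1L) return(A[, 1L])
  do.call(pmin, lapply(seq_len(ncol(A)), function(j) A[, j]))
}

# beta-mean-nearest-taxon distance for every sample pair.
# D: taxa x taxa patristic distances; W: taxa x samples weights whose
# columns sum to 1 over the taxa present in that sample (zeros elsewhere).
# bMNTD(j, m) = 0.5 * [ sum_i W[i,j] min_{k in m} D[i,k]
#                     + sum_k W[k,m] min_{i in j} D[k,i] ]
# Computed as B = t(W) %*% M with M[i, m] = min over m's taxa of D[i, .],
# then 0.5 * (B + t(B)).
.bmntd_core <- function(D, W) {
  present <- lapply(seq_len(ncol(W)), function(s) which(W[, s] > 0))
  M <- vapply(present, function(idx) .row_mins(D[, idx, drop = FALSE]),
              numeric(nrow(D)))
  B <- crossprod(W, M)
  out <- 0.5 * (B + t(B))
  diag(out) <- 0
  dimnames(out) <- list(colnames(W), colnames(W))
  out
}

.weight_matrix <- function(x, weighted) {
  m <- assay(x, "counts")  # taxa x samples
  if (weighted) {
    sweep(m, 2, colSums(m), "/")
  } else {
    p <- m > 0
    sweep(p * 1, 2, colSums(p), "/")
  }
}

.patristic <- function(x) {
  tree <- phyloTree(x)
  if (is.null(tree))
    stop("betaMNTD needs a phylogeny; attach one with phyloTree<-")
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  cophenetic(tree)[rownames(x), rownames(x)]
}

#' Beta mean nearest taxon distance between all sample pairs
#'
#' For a sample pair (j, m), the abundance-weighted mean over the taxa of
#' each community of the patristic distance to the closest relative in the
#' other community, averaged symmetrically. The unweighted variant gives
#' every present taxon equal weight. Identical communities score 0.
#'
#' @param x a [CommunityExperiment-class] with an attached tree covering
#'   its taxa.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return a `dist` of beta-MNTD values in tree branch-length units.
#' @export
betaMNTD <- function(x, weighted = TRUE) {
  D <- .patristic(x)
  W <- .weight_matrix(x, weighted)
  as.dist(.bmntd_core(D, W))
}

#' Beta nearest taxon index (phylogenetic null model)
#'
#' Standardised effect size of the observed beta-MNTD against a null in
#' which the taxa swap positions on the phylogeny (tip labels shuffled
#' within the regional pool; abundances untouched):
#' `bNTI = (obs - mean(null)) / sd(null)`. `|bNTI| > 2` is read as
#' deterministic assembly; the sign separates heterogeneous (> 2) from
#' homogeneous (< -2) selection. Pairs whose null distribution has zero
#' spread (e.g. identical communities, which every shuffle maps to
#' beta-MNTD 0) are returned as `NA` with a warning.
#'
#' @inheritParams betaMNTD
#' @param nNull number of tip-shuffling null draws (default 999).
#' @param seed RNG seed; results are deterministic given it.
#' @return list with `bmntd` (observed `dist`), `bnti` (`dist` of SES
#'   values, `NA` where degenerate), `nNull`, `seed`.
#' @export
betaNTI <- function(x, nNull = 999, seed = 1, weighted = TRUE) {
  D <- .patristic(x)
  W <- .weight_matrix(x, weighted)
  obs <- .bmntd_core(D, W)
  nt <- nrow(D)
  low <- lower.tri(obs)
  set.seed(seed)
  sums <- 0
  sqs <- 0
  for (r in seq_len(nNull)) {
    p <- sample.int(nt)
    v <- .bmntd_core(D[p, p, drop = FALSE], W)[low]
    sums <- sums + v
    sqs <- sqs + v * v
  }
  mu <- sums / nNull
  sdv <- sqrt(pmax(0, (sqs - nNull * mu^2) / (nNull - 1)))
  ses <- (obs[low] - mu) / sdv
  degen <- sdv < 1e-12
  if (any(degen)) {
    warning(sum(degen), " pair(s) with degenerate null (sd = 0); bNTI = NA")
    ses[degen] <- NA_real_
  }
  out <- obs
  out[] <- 0
  out[low] <- ses
  out <- out + t(out)
  list(bmntd = as.dist(obs), bnti = as.dist(out), nNull = nNull,
       seed = seed)
}

# one null community: fix richness and total reads, draw presences with
# probability proportional to regional occurrence frequency, then allocate
# the remaining individuals multinomially by regional relative abundance
.rc_null_sample <- function(nTaxa, richness, total, occ, relab) {
  idx <- sample.int(nTaxa, richness, prob = occ)
  cnt <- integer(nTaxa)
  cnt[idx] <- 1L
  extra <- total - richness
  if (extra > 0)
    cnt[idx] <- cnt[idx] + rmultinom(1, extra, relab[idx])[, 1L]
  cnt
}

.bray <- function(a, b) sum(abs(a - b)) / (sum(a) + sum(b))

#' Raup-Crick metric on Bray-Curtis (taxonomic null model)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is placed
#' within a null distribution of dissimilarities between communities
#' assembled probabilistically from the regional pool: each null community
#' keeps the sample's observed richness and total reads, draws which taxa
#' occur with probability proportional to regional occurrence frequency,
#' and allocates individuals proportionally to regional relative abundance
#' among the drawn taxa. The result
#' `RC = 2 * ((#\{null < obs\} + 0.5 #\{ties\}) / nNull - 0.5)` lies in
#' `[-1, 1]`; values above +0.95 are read as dispersal limitation, below
#' -0.95 as homogenizing dispersal.
#'
#' @param x count-form [CommunityExperiment-class] (integer reads; the
#'   null assembles individuals).
#' @param nNull null draws per pair (default 999).
#' @param seed RNG seed.
#' @return a `dist` of RC values over samples.
#' @export
raupCrick <- function(x, nNull = 999, seed = 1) {
  m <- communityMatrix(x)
  if (any(abs(m - round(m)) > 1e-8))
    stop("Raup-Crick needs raw integer counts; supply the count table")
  m <- round(m)
  ns <- nrow(m)
  nTaxa <- ncol(m)
  occ <- colMeans(m > 0)
  relab <- colSums(m) / sum(m)
  rich <- rowSums(m > 0)
  tot <- rowSums(m)
  out <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  set.seed(seed)
  for (j in seq_len(ns - 1L)) {
    for (k in (j + 1L):ns) {
      obs <- .bray(m[j, ], m[k, ])
      less <- 0L
      ties <- 0L
      for (r in seq_len(nNull)) {
        a <- .rc_null_sample(nTaxa, rich[j], tot[j], occ, relab)
        b <- .rc_null_sample(nTaxa, rich[k], tot[k], occ, relab)
        bc <- .bray(a, b)
        if (abs(bc - obs) < 1e-10) ties <- ties + 1L
        else if (bc < obs) less <- less + 1L
      }
      out[j, k] <- out[k, j] <- 2 * ((less + 0.5 * ties) / nNull - 0.5)
    }
  }
  as.dist(out)
}

#' Classify a sample pair's assembly process from (bNTI, RCbray)
#'
#' `bNTI > 2` heterogeneous selection; `bNTI < -2` homogeneous selection;
#' otherwise `RC > 0.95` dispersal limitation, `RC < -0.95` homogenizing
#' dispersal, else undominated. `NA` bNTI propagates to an `NA` process.
#'
#' @param bnti,rcbray numeric vectors (recycled to common length).
#' @return character vector of process labels.
#' @export
classifyPair <- function(bnti, rcbray) {
  n <- max(length(bnti), length(rcbray))
  bnti <- rep_len(bnti, n)
  rcbray <- rep_len(rcbray, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(bnti)
  out[ok & bnti > 2] <- "heterogeneous_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  sto <- ok & abs(bnti) <= 2
  out[sto & !is.na(rcbray) & rcbray > 0.95] <- "dispersal_limitation"
  out[sto & !is.na(rcbray) & rcbray < -0.95] <- "homogenizing_dispersal"
  out[sto & !is.na(rcbray) & abs(rcbray) <= 0.95] <- "undominated"
  out
}

#' Full pairwise assembly analysis
#'
#' Runs [betaNTI()] and [raupCrick()] on every unordered sample pair and
#' classifies each pair's assembly process.
#'
#' @param x count-form [CommunityExperiment-class] with an attached tree.
#' @param nNull null draws for both null models (default 999).
#' @param seed RNG seed (the two nulls use `seed` and `seed + 1`).
#' @param weighted abundance-weighted beta-MNTD (default) or
#'   presence-based.
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `group_i`, `group_j`, `bmntd`, `bnti`, `rcbray`,
#'   `process`.
#' @export
assemblyAnalysis <- function(x, nNull = 999, seed = 1, weighted = TRUE) {
  nti <- betaNTI(x, nNull = nNull, seed = seed, weighted = weighted)
  rc <- raupCrick(x, nNull = nNull, seed = seed + 1L)
  labs <- attr(nti$bmntd, "Labels")
  grp <- as.character(sampleGroups(x))[match(labs, colnames(x))]
  idx <- which(lower.tri(matrix(0, length(labs), length(labs))),
               arr.ind = TRUE)
  df <- data.frame(
    sample_i = labs[idx[, 2L]], sample_j = labs[idx[, 1L]],
    group_i = grp[idx[, 2L]], group_j = grp[idx[, 1L]],
    bmntd = as.vector(nti$bmntd), bnti = as.vector(nti$bnti),
    rcbray = as.vector(rc))
  df$process <- classifyPair(df$bnti, df$rcbray)
  df
}

#' Summarise assembly-process contributions
#'
#' @param pairwise data.frame from [assemblyAnalysis()].
#' @param scope `"all"` (every classified pair) or `"within-group"`
#'   (per-group summaries over pairs whose two samples share a group).
#' @return data.frame with `scope`, `process`, `count`, `percent`
#'   (percentages sum to 100 within each scope).
#' @export
summarizeAssembly <- function(pairwise, scope = c("all", "within-group")) {
  scope <- match.arg(scope)
  tally <- function(proc, label) {
    proc <- proc[!is.na(proc)]
    if (!length(proc)) stop("no classified pairs in scope '", label, "'")
    tab <- table(factor(proc, levels = ASSEMBLY_PROCESSES))
    data.frame(scope = label, process = names(tab),
               count = as.integer(tab),
               percent = 100 * as.numeric(tab) / sum(tab),
               row.names = NULL)
  }
  if (scope == "all") return(tally(pairwise$process, "all"))
  within <- pairwise[pairwise$group_i == pairwise$group_j, ]
  if (!nrow(within)) stop("no within-group pairs")
  do.call(rbind, lapply(split(within, within$group_i), function(d)
    tally(d$process, d$group_i[1L])))
}
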