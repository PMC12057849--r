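#' @importFrom vegan diversity specnumber vegdist metaMDS adonis2
#' @importFrom stats aov pt sd
NULL

#' Per-sample alpha diversity
#'
#' Shannon entropy in natural log, Simpson diversity in the `1 - D` form
#' and species richness (count of taxa with nonzero abundance), the
#' conventions of the vegan toolchain.
#'
#' @param x a [CommunityExperiment-class] (counts or relative abundances).
#' @return data.frame with columns `sample`, `group`, `shannon`, `simpson`,
#'   `richness`.
#' @export
alphaDiversity <- function(x) {
  m <- communityMatrix(x)
  data.frame(sample = rownames(m),
             group = as.character(sampleGroups(x)),
             shannon = as.numeric(diversity(m, index = "shannon")),
             simpson = as.numeric(diversity(m, index = "simpson")),
             richness = as.integer(specnumber(m)),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' @param x a [CommunityExperiment-class]; converted to relative abundance
#'   first so sequencing depth does not enter the dissimilarity.
#' @return a `dist` over samples with values in `[0, 1]`.
#' @export
brayCurtis <- function(x) {
  m <- communityMatrix(toRelative(x))
  vegdist(m, method = "bray")
}

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling minimising Kruskal stress-1, with
#' multiple random restarts; deterministic given the seed.
#'
#' @param d a `dist` (e.g. from [brayCurtis()]).
#' @param k number of dimensions (default 2).
#' @param seed RNG seed.
#' @param tryMax random restarts (default 20).
#' @return list with `points` (centred sample coordinates, samples x k) and
#'   `stress`.
#' @export
nmdsOrdination <- function(d, k = 2, seed = 1, tryMax = 20) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  set.seed(seed)
  if (max(d) - min(d) < 1e-12) {
    warning("all dissimilarities equal; returning a degenerate configuration")
    pts <- matrix(0, n, k,
                  dimnames = list(attr(d, "Labels"),
                                  paste0("NMDS", seq_len(k))))
    return(list(points = pts, stress = 0))
  }
  fit <- metaMDS(d, k = k, trymax = tryMax, trace = 0, autotransform = FALSE)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("NMDS", seq_len(k))
  list(points = pts, stress = fit$stress)
}

#' PERMANOVA of a dissimilarity matrix against group labels
#'
#' Permutational multivariate analysis of variance: pseudo-F from among-
#' and within-group sums of squares on the Gower-centred dissimilarity
#' matrix, with a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + nPerm)`.
#'
#' @param d a `dist` over samples.
#' @param groups factor/character of group labels in `attr(d, "Labels")`
#'   order, or named by sample.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `F`, `R2`, `p`, `nPerm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = 1) {
  labs <- attr(d, "Labels")
  if (!is.null(names(groups))) groups <- groups[labs]
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  set.seed(seed)
  df <- data.frame(group = groups)
  fit <- adonis2(d ~ group, data = df, permutations = nPerm)
  list(F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1], nPerm = nPerm)
}

#' One-way ANOVA with LSD pairwise comparisons on an alpha-diversity index
#'
#' Fisher's least-significant-difference procedure: a one-way ANOVA
#' followed by all pairwise t tests using the pooled residual mean square,
#' without multiplicity correction (the LSD convention). An optional
#' `log1p` transform accommodates skewed indices.
#'
#' @param alpha data.frame from [alphaDiversity()].
#' @param index one of `"shannon"`, `"simpson"`, `"richness"`.
#' @param transform `"none"` (default) or `"log1p"`.
#' @return list with `anova` (F, df, p), `means` (per-group means) and
#'   `pairwise` (data.frame of group pairs, mean difference, t, p).
#' @export
alphaAnova <- function(alpha, index = "shannon",
                       transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  y <- alpha[[index]]
  if (transform == "log1p") y <- log1p(y)
  g <- factor(alpha$group)
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  combs <- utils::combn(levels(g), 2)
  pw <- data.frame(group_i = combs[1, ], group_j = combs[2, ])
  pw$diff <- means[pw$group_i] - means[pw$group_j]
  se <- sqrt(mse * (1 / ns[pw$group_i] + 1 / ns[pw$group_j]))
  pw$t <- as.numeric(pw$diff / se)
  pw$p <- 2 * pt(-abs(pw$t), dfe)
  rownames(pw) <- NULL
  list(anova = list(F = an["g", "F value"], df = c(an["g", "Df"], dfe),
                    p = an["g", "Pr(>F)"]),
       means = means, pairwise = pw, transform = transform)
}
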