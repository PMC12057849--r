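#' @importFrom stats lm coef var cor
#' @importFrom vegan decostand rda envfit
NULL

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# R^2 of y on the predictor subset S, from the joint correlation matrix
.subset_r2 <- function(Rxx, rxy, S) {
  if (!length(S)) return(0)
  drop(crossprod(rxy[S], solve(Rxx[S, S, drop = FALSE], rxy[S])))
}

#' Exact LMG relative-importance decomposition of a multiple regression
#'
#' Decomposes the full-model R^2 of `response ~ all soil factors` into
#' non-negative per-factor shares: the LMG share of factor j is its
#' sequential R^2 increase when entering the model, averaged over all
#' orderings of the predictors. Computed exactly from the 2^p subset-R^2
#' table (512 subsets for 9 factors), not by sampling orderings. Shares
#' sum to the full-model R^2; under orthogonal predictors each share
#' equals the factor's marginal R^2.
#'
#' @param env samples x factors matrix/data.frame (standardised
#'   internally).
#' @param response numeric vector per sample (e.g. a Shannon index), named
#'   by sample or in row order of `env`.
#' @return data.frame per factor: `factor`, `lmg` (absolute share of
#'   R^2), `lmg_percent` (share of the explained variance), `sign` (of the
#'   univariate slope); attribute `"totalR2"` carries the full-model R^2.
#' @export
lmgImportance <- function(env, response) {
  env <- as.matrix(as.data.frame(env))
  if (!is.null(names(response)) && !is.null(rownames(env)))
    response <- response[rownames(env)]
  if (nrow(env) < ncol(env) + 2)
    stop("need at least p + 2 samples for p predictors")
  keep <- colnames(env)
  qrX <- qr(scale(env))
  if (qrX$rank < ncol(env)) {
    aliased <- colnames(env)[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping aliased predictor(s): ",
            paste(aliased, collapse = ", "))
    env <- env[, setdiff(colnames(env), aliased), drop = FALSE]
  }
  p <- ncol(env)
  Z <- cbind(scale(env), y = as.numeric(scale(response)))
  R <- crossprod(Z) / (nrow(Z) - 1)
  Rxx <- R[seq_len(p), seq_len(p), drop = FALSE]
  rxy <- R[seq_len(p), p + 1L]

  subsets <- lapply(0:(2^p - 1L), function(code)
    which(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0))
  r2 <- vapply(subsets, function(S) .subset_r2(Rxx, rxy, S), numeric(1))
  names(r2) <- vapply(subsets, function(S)
    paste0("S", paste(S, collapse = ",")), "")
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - 0:(p - 1)) / factorial(p)
  lmg <- vapply(seq_len(p), function(j) {
    others <- lapply(subsets, function(S) if (!(j %in% S)) S else NULL)
    others <- others[!vapply(others, is.null, TRUE)]
    sum(vapply(others, function(S) {
      key_with <- paste0("S", paste(sort(c(S, j)), collapse = ","))
      key_without <- paste0("S", paste(S, collapse = ","))
      wts[length(S) + 1L] * (r2[[key_with]] - r2[[key_without]])
    }, numeric(1)))
  }, numeric(1))
  total <- r2[[paste0("S", paste(seq_len(p), collapse = ","))]]
  signs <- vapply(seq_len(p), function(j)
    sign(coef(lm(response ~ env[, j]))[2L]), numeric(1))
  out <- data.frame(factor = colnames(env), lmg = lmg,
                    lmg_percent = 100 * lmg / total, sign = signs,
                    row.names = NULL)
  dropped <- setdiff(keep, colnames(env))
  if (length(dropped))
    out <- rbind(out, data.frame(factor = dropped, lmg = NA,
                                 lmg_percent = NA, sign = NA))
  attr(out, "totalR2") <- total
  out
}

#' Univariate linear regressions of a diversity index on each soil factor
#'
#' @inheritParams lmgImportance
#' @return data.frame per factor: `factor`, `slope`, `r2`, `p` (t test on
#'   the slope), `stars`. Zero-variance factors yield `NA` with a warning.
#' @export
univariateTrends <- function(env, response) {
  env <- as.data.frame(env)
  if (!is.null(names(response)) && !is.null(rownames(env)))
    response <- response[rownames(env)]
  out <- do.call(rbind, lapply(colnames(env), function(f) {
    xv <- env[[f]]
    if (var(xv) < .Machine$double.eps) {
      warning("zero-variance factor: ", f)
      return(data.frame(factor = f, slope = NA_real_, r2 = NA_real_,
                        p = NA_real_))
    }
    fit <- summary(lm(response ~ xv))
    data.frame(factor = f, slope = fit$coefficients[2L, 1L],
               r2 = fit$r.squared, p = fit$coefficients[2L, 4L])
  }))
  out$stars <- .stars(out$p)
  rownames(out) <- NULL
  out
}

#' RDA ordination with Monte Carlo (permutation) tests of each soil factor
#'
#' Redundancy analysis of the (Hellinger-transformed) community on the
#' standardised soil factors, reporting the variance explained by the
#' first two constrained axes, and for each factor the squared correlation
#' (R^2) with its best-fit direction in the 2-axis site-score plane plus a
#' permutation p-value (sample rows shuffled), in the style of a
#' vegan-envfit Monte Carlo test.
#'
#' @param x a [CommunityExperiment-class].
#' @param env samples x factors table (defaults to the attached
#'   [soilFactors()]).
#' @param nPerm permutations (default 999).
#' @param seed RNG seed.
#' @param transform community transform before RDA: `"hellinger"`
#'   (default), `"none"` or `"log1p"`.
#' @param method `"axes"` (envfit on the 2-axis site scores, default) or
#'   `"margin"` (marginal permutation test of each term in the RDA).
#' @return list with `axisVariance` (% of community variance on RDA1/2)
#'   and `fit` (data.frame `factor`, `r2`, `p`, `stars`).
#' @export
envfitMC <- function(x, env = soilFactors(x), nPerm = 999, seed = 1,
                     transform = c("hellinger", "none", "log1p"),
                     method = c("axes", "margin")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (is.null(env)) stop("no soil factors available")
  env <- as.data.frame(env)
  m <- communityMatrix(toRelative(x))
  if (ncol(env) > nrow(m) - 1)
    stop("more factors than samples - 1")
  Y <- switch(transform,
              hellinger = decostand(m, "hellinger"),
              log1p = log1p(m),
              none = m)
  Z <- as.data.frame(scale(env))
  ord <- rda(Y ~ ., data = Z)
  axisVar <- 100 * ord$CCA$eig[1:2] / ord$tot.chi
  set.seed(seed)
  if (method == "axes") {
    ef <- envfit(ord, Z, permutations = nPerm, choices = 1:2,
                 display = "sites")
    fit <- data.frame(factor = rownames(ef$vectors$arrows),
                      r2 = as.numeric(ef$vectors$r),
                      p = as.numeric(ef$vectors$pvals), row.names = NULL)
  } else {
    an <- stats::anova(ord, by = "margin", permutations = nPerm)
    fac <- setdiff(rownames(an), "Residual")
    fit <- data.frame(factor = fac,
                      r2 = an[fac, "Variance"] / ord$tot.chi,
                      p = an[fac, "Pr(>F)"], row.names = NULL)
  }
  fit$stars <- .stars(fit$p)
  list(axisVariance = stats::setNames(as.numeric(axisVar),
                                      c("RDA1", "RDA2")),
       fit = fit)
}

#' Regression of pairwise beta-NTI on pairwise environmental differences
#'
#' OLS of bNTI on `|env_i - env_j|` over sample pairs, with significance
#' by Mantel-type permutation: the sample-to-environment assignment is
#' shuffled and the pair differences recomputed, respecting the shared-
#' sample dependence structure of pairwise data (a naive OLS t test would
#' not).
#'
#' @param pairwise data.frame from [assemblyAnalysis()] (needs `sample_i`,
#'   `sample_j`, `bnti`).
#' @param env samples x factors table with rownames.
#' @param factor factor name (one of the columns of `env`).
#' @param nPerm permutations (default 999).
#' @param seed RNG seed.
#' @return list with `slope`, `intercept`, `r2`, `p`, `n` (pairs used).
#' @export
bntiEnvRegression <- function(pairwise, env, factor, nPerm = 999,
                              seed = 1) {
  env <- as.data.frame(env)
  if (!factor %in% colnames(env))
    stop("factor '", factor, "' not in env table")
  ok <- is.finite(pairwise$bnti)
  pw <- pairwise[ok, ]
  samples <- sort(unique(c(pw$sample_i, pw$sample_j)))
  e <- stats::setNames(env[samples, factor], samples)
  if (anyNA(e)) stop("env values missing for some samples")
  if (var(e) < .Machine$double.eps) {
    warning("constant environmental factor: ", factor)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                p = NA_real_, n = nrow(pw)))
  }
  d <- abs(e[pw$sample_i] - e[pw$sample_j])
  fit <- lm(pw$bnti ~ d)
  obs <- abs(cor(pw$bnti, d))
  set.seed(seed)
  exceed <- 0L
  for (r in seq_len(nPerm)) {
    ep <- stats::setNames(sample(e), samples)
    dp <- abs(ep[pw$sample_i] - ep[pw$sample_j])
    if (stats::sd(dp) < .Machine$double.eps) next
    if (abs(cor(pw$bnti, dp)) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = summary(fit)$r.squared, p = (1 + exceed) / (1 + nPerm),
       n = nrow(pw))
}
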