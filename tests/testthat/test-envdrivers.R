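test_that("LMG shares sum to the full-model R2 and respect orthogonality", {
  set.seed(6)
  n <- 40
  # orthogonal zero-mean predictors: shares must equal marginal R2 exactly
  Q <- unclass(stats::poly(seq_len(n), degree = 4))
  colnames(Q) <- c("TN", "TP", "TK", "salt")
  y <- Q %*% c(2, 1, 0.5, 0) + rnorm(n, sd = 0.5)
  res <- lmgImportance(Q, as.numeric(y))
  marginal <- sapply(colnames(Q), function(f)
    summary(lm(y ~ Q[, f]))$r.squared)
  expect_equal(res$lmg, unname(marginal[res$factor]), tolerance = 1e-9)
  expect_equal(sum(res$lmg), attr(res, "totalR2"), tolerance = 1e-12)

  # the invariant holds on arbitrary correlated data
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(n * 5), n, 5) %*% matrix(runif(25, -1, 1), 5, 5)
    colnames(X) <- c("TN", "TP", "TK", "salt", "SOM")
    yy <- rnorm(n)
    r <- lmgImportance(X, yy)
    expect_equal(sum(r$lmg), attr(r, "totalR2"), tolerance = 1e-9)
    expect_true(all(r$lmg >= -1e-12))
  }
})

test_that("LMG attributes a planted signal and splits duplicates", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("TN", "TP", "TK", "salt", "SOM")))
  y <- 3 * X[, "salt"] + rnorm(n, sd = 0.5)
  res <- lmgImportance(X, y)
  expect_gte(res$lmg[res$factor == "salt"] / attr(res, "totalR2"), 0.8)
  expect_equal(res$sign[res$factor == "salt"], 1)

  # two noisy copies of one signal share the credit about equally
  sig <- rnorm(n)
  X2 <- cbind(TN = sig + rnorm(n, sd = 0.1),
              TP = sig + rnorm(n, sd = 0.1),
              TK = rnorm(n))
  y2 <- sig + rnorm(n, sd = 0.3)
  r2 <- lmgImportance(X2, y2)
  a <- r2$lmg[r2$factor == "TN"]
  b <- r2$lmg[r2$factor == "TP"]
  expect_lt(abs(a - b) / (a + b), 0.15)

  # exactly aliased columns are dropped with a warning
  X3 <- cbind(TN = sig, TP = sig, TK = rnorm(n))
  expect_warning(r3 <- lmgImportance(X3, y2), "aliased")
  expect_true(anyNA(r3$lmg))
})

test_that("univariate regressions recover slopes and handle degeneracy", {
  set.seed(5)
  n <- 60
  env <- data.frame(TN = rnorm(n), TP = rnorm(n), TK = rep(1, n))
  rownames(env) <- sprintf("s%02d", 1:n)
  y <- 2 * env$TN + rnorm(n, sd = 0.5)
  expect_warning(res <- univariateTrends(env, y), "zero-variance")
  tn <- res[res$factor == "TN", ]
  expect_gt(tn$slope, 1.5)
  expect_lt(tn$p, 1e-6)
  expect_equal(tn$stars, "***")
  expect_true(is.na(res$slope[res$factor == "TK"]))
  # perfectly linear response
  res2 <- suppressWarnings(
    univariateTrends(env[, c("TN", "TP")], 3 * env$TN))
  expect_equal(res2$r2[res2$factor == "TN"], 1)
})

test_that("the RDA Monte Carlo test finds planted gradients only", {
  sim <- smallSim()
  x <- sim$community
  env <- as.data.frame(soilFactors(x))
  # the generator's soil factors load on the same latent axis that
  # filters composition, so at least one factor must test significant
  ef <- envfitMC(x, env[, c("TN", "salt", "SOM")], nPerm = 199, seed = 1)
  expect_true(all(ef$fit$r2 >= 0 & ef$fit$r2 <= 1))
  expect_true(any(ef$fit$p <= 0.05))
  expect_length(ef$axisVariance, 2)
  expect_true(all(ef$axisVariance > 0))

  # identical factors get identical statistics
  env2 <- data.frame(TN = env$TN, TP = env$TN, TK = rnorm(nrow(env)))
  rownames(env2) <- rownames(env)
  ef2 <- envfitMC(x, env2, nPerm = 99, seed = 2)
  expect_equal(ef2$fit$r2[ef2$fit$factor == "TN"],
               ef2$fit$r2[ef2$fit$factor == "TP"], tolerance = 1e-9)

  # a factor shuffled against composition (tested alongside two real
  # gradient factors) is usually non-significant
  hits <- 0L
  for (s in 1:15) {
    set.seed(300 + s)
    env3 <- data.frame(TN = env$TN, SOM = env$SOM,
                       TK = sample(env$TK))
    rownames(env3) <- rownames(env)
    fit <- envfitMC(x, env3, nPerm = 99, seed = s)$fit
    if (fit$p[fit$factor == "TK"] > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 11)

  expect_error(envfitMC(x[, 1:5], env, nPerm = 9), "more factors")
})

test_that("bNTI-environment regression uses Mantel-style permutation", {
  set.seed(12)
  samples <- sprintf("s%02d", 1:10)
  e <- stats::setNames(seq(0, 9), samples)
  pairs <- t(combn(samples, 2))
  d <- abs(e[pairs[, 1]] - e[pairs[, 2]])
  pw <- data.frame(sample_i = pairs[, 1], sample_j = pairs[, 2],
                   bnti = 0.4 * d + rnorm(length(d), sd = 0.3))
  env <- data.frame(TN = e, salt = rnorm(10), row.names = samples)
  res <- bntiEnvRegression(pw, env, "TN", nPerm = 199, seed = 3)
  expect_gt(res$slope, 0.2)
  expect_lt(res$p, 0.05)

  # unrelated factor: permutation p well above the planted one
  res2 <- bntiEnvRegression(pw, env, "salt", nPerm = 199, seed = 3)
  expect_gt(res2$p, res$p)

  env$flat <- 1
  expect_warning(res3 <- bntiEnvRegression(pw, env, "flat", nPerm = 9),
                 "constant")
  expect_true(is.na(res3$slope))
  expect_error(bntiEnvRegression(pw, env, "missing"), "not in env")
})
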