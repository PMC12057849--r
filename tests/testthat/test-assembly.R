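test_that("beta-MNTD matches hand computation on a 3-tip tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- rbind(j = c(A = 5, B = 0, C = 0), k = c(A = 0, B = 0, C = 3),
             l = c(A = 5, B = 0, C = 0))
  x <- CommunityExperiment(m, group = c("g1", "g1", "g2"), tree = tr)
  b <- as.matrix(betaMNTD(x))
  expect_equal(b["j", "k"], 4)  # single-taxon communities: d(A, C)
  expect_equal(b["j", "l"], 0)  # identical communities
})

test_that("beta-MNTD equals the brute-force double-loop oracle", {
  for (s in 1:10) {
    set.seed(s)
    nt <- sample(4:10, 1)
    tr <- simulateTree(nt, seed = 100 + s)
    m <- matrix(rpois(3 * nt, 3), 3, nt,
                dimnames = list(paste0("s", 1:3), tr$tip.label))
    m[1, ] <- m[1, ] + 1  # no all-zero rows
    m[2, 1] <- m[2, 1] + 1
    m[3, nt] <- m[3, nt] + 1
    x <- CommunityExperiment(m, group = c("A", "A", "B"), tree = tr)
    D <- cophenetic(tr)[colnames(communityMatrix(x)),
                        colnames(communityMatrix(x))]
    mm <- communityMatrix(x)
    for (w in c(TRUE, FALSE)) {
      got <- as.matrix(betaMNTD(x, weighted = w))
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        want <- unname(bmntdOracle(D, mm[pair[1], ], mm[pair[2], ],
                                   weighted = w))
        expect_equal(got[pair[1], pair[2]], want, tolerance = 1e-10)
      }
    }
  }
})

test_that("beta-MNTD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  sim <- smallSim()
  x <- sim$community[, 1:5]
  mine <- as.matrix(betaMNTD(x))
  ref <- as.matrix(picante::comdistnt(
    communityMatrix(x), cophenetic(phyloTree(x)),
    abundance.weighted = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)],
               tolerance = 1e-10)
})

test_that("beta-NTI is seed-deterministic and NA for degenerate nulls", {
  tr <- simulateTree(20, seed = 1)
  set.seed(7)
  m <- matrix(rpois(4 * 20, 2), 4, 20,
              dimnames = list(paste0("s", 1:4), tr$tip.label))
  m[cbind(1:4, 1:4)] <- m[cbind(1:4, 1:4)] + 1  # no all-zero rows
  m[2, ] <- m[1, ]  # identical pair
  x <- CommunityExperiment(m, group = c("A", "A", "B", "B"), tree = tr)
  expect_warning(res <- betaNTI(x, nNull = 49, seed = 5), "degenerate")
  b <- as.matrix(res$bnti)
  expect_true(is.na(b["s1", "s2"]))
  expect_false(anyNA(b["s3", "s4"]))
  res2 <- suppressWarnings(betaNTI(x, nNull = 49, seed = 5))
  expect_equal(as.vector(res$bnti), as.vector(res2$bnti))
})

test_that("beta-NTI is equivariant under consistent taxon relabeling", {
  sim <- smallSim()
  x <- sim$community[, 1:4]
  r1 <- betaMNTD(x)
  # rename two taxa consistently in table and tree (a and b trade names)
  m <- communityMatrix(x)
  tr <- phyloTree(x)
  a <- colnames(m)[1]
  b <- colnames(m)[2]
  rename <- function(v) ifelse(v == a, b, ifelse(v == b, a, v))
  colnames(m) <- rename(colnames(m))
  tr$tip.label <- rename(tr$tip.label)
  x2 <- CommunityExperiment(m, group = sampleGroups(x), tree = tr)
  r2 <- betaMNTD(x2)
  expect_equal(as.vector(r1), as.vector(r2), tolerance = 1e-10)
})

test_that("Raup-Crick hits its extremes and stays in [-1, 1]", {
  set.seed(2)
  # disjoint supports from a shared pool -> RC near +1
  nt <- 40
  tr <- simulateTree(nt, seed = 2)
  a <- integer(nt); a[1:20] <- rpois(20, 10) + 1
  b <- integer(nt); b[21:40] <- rpois(20, 10) + 1
  filler <- matrix(rpois(2 * nt, 3) + 1, 2, nt)
  m <- rbind(a, b, filler)
  dimnames(m) <- list(paste0("s", 1:4), tr$tip.label)
  x <- CommunityExperiment(m, group = c("A", "A", "B", "B"))
  rc <- as.matrix(raupCrick(x, nNull = 199, seed = 4))
  expect_gt(rc["s1", "s2"], 0.9)
  expect_true(all(abs(rc) <= 1))

  expect_error(raupCrick(CommunityExperiment(
    matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2,
           dimnames = list(c("x", "y"), c("t1", "t2"))),
    group = c("A", "A")), nNull = 9), "integer counts")
})

test_that("Raup-Crick is 0 when every null draw ties (one-taxon pool)", {
  m <- matrix(c(5L, 7L), 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  x <- CommunityExperiment(m, group = c("A", "A"))
  rc <- raupCrick(x, nNull = 99, seed = 1)
  expect_equal(as.vector(rc), 0)
})

test_that("the five-way classification follows the decision boundaries", {
  cases <- data.frame(
    bnti  = c(2.5, 2.01, -2.5, -2.01, 0.0, 1.99, -1.0, 0.0, 2.0),
    rc    = c(0.1, -0.5, 0.0, 0.5, 0.96, -0.96, -0.3, 0.95, 0.99),
    want  = c("heterogeneous_selection", "heterogeneous_selection",
              "homogeneous_selection", "homogeneous_selection",
              "dispersal_limitation", "homogenizing_dispersal",
              "undominated", "undominated", "dispersal_limitation"))
  expect_equal(classifyPair(cases$bnti, cases$rc), cases$want)
  expect_true(is.na(classifyPair(NA, 0.5)))
})

test_that("assembly summaries count and percentage correctly", {
  pw <- data.frame(
    sample_i = c("a", "a", "a", "b"), sample_j = c("b", "c", "d", "c"),
    group_i = c("g", "g", "g", "g"), group_j = c("g", "g", "g", "g"),
    bmntd = 1, bnti = c(3, 0, 0, 0), rcbray = c(0, 0.99, 0.99, 0.5))
  pw$process <- classifyPair(pw$bnti, pw$rcbray)
  s <- summarizeAssembly(pw)
  expect_equal(sum(s$percent), 100)
  expect_equal(s$percent[s$process == "heterogeneous_selection"], 25)
  expect_equal(s$percent[s$process == "dispersal_limitation"], 50)
  expect_equal(s$percent[s$process == "undominated"], 25)

  wg <- summarizeAssembly(pw, "within-group")
  expect_true(all(wg$scope == "g"))
  expect_error(summarizeAssembly(pw[0, ]), "no classified pairs")
})

test_that("pairwise analysis assembles the long-format result", {
  sim <- smallSim()
  x <- sim$community[, 1:5]
  pw <- assemblyAnalysis(x, nNull = 49, seed = 2)
  expect_equal(nrow(pw), choose(5, 2))
  expect_named(pw, c("sample_i", "sample_j", "group_i", "group_j",
                     "bmntd", "bnti", "rcbray", "process"))
  expect_true(all(pw$rcbray >= -1 & pw$rcbray <= 1))
  ok <- !is.na(pw$bnti)
  expect_equal(pw$process[ok], classifyPair(pw$bnti[ok], pw$rcbray[ok]))
})
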