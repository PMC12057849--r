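# shared fixtures, built in code and cached across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 3 samples x 4 taxa hand table (counts)
tinyCounts <- function() {
  m <- matrix(c(2, 2, 6, 0,
                1, 1, 1, 1,
                0, 5, 0, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  m
}

tinyCommunity <- function() {
  CommunityExperiment(tinyCounts(),
                      group = c(s1 = "A", s2 = "A", s3 = "B"))
}

# small two-group simulated dataset reused by several files
smallSim <- function() {
  cached("smallSim", simulateDataset(
    simConfig(nTaxa = 150, nGroups = 2, repsPerGroup = c(4, 4),
              depth = 2000, seed = 42)))
}

# five-group dataset matching the survey design (reduced pool/depth)
gradientSim <- function() {
  cached("gradientSim", simulateDataset(
    simConfig(nTaxa = 400, nGroups = 5, repsPerGroup = c(9, 6, 6, 6, 6),
              depth = 5000, seed = 7)))
}

# brute-force beta-MNTD oracle: explicit double loop over present taxa
bmntdOracle <- function(D, xj, xm, weighted = TRUE) {
  Pj <- which(xj > 0)
  Pm <- which(xm > 0)
  fj <- if (weighted) xj[Pj] / sum(xj[Pj]) else rep(1 / length(Pj),
                                                    length(Pj))
  fm <- if (weighted) xm[Pm] / sum(xm[Pm]) else rep(1 / length(Pm),
                                                    length(Pm))
  a <- 0
  for (i in seq_along(Pj)) {
    best <- Inf
    for (k in seq_along(Pm))
      best <- min(best, D[Pj[i], Pm[k]])
    a <- a + fj[i] * best
  }
  b <- 0
  for (k in seq_along(Pm)) {
    best <- Inf
    for (i in seq_along(Pj))
      best <- min(best, D[Pm[k], Pj[i]])
    b <- b + fm[k] * best
  }
  0.5 * (a + b)
}

# neutral-regime calibration batch: 7 independent flat-filter datasets of
# 3 + 3 samples over 200 taxa (105 sample pairs), 199 null draws
neutralCalibration <- function() {
  cached("neutralCalibration", {
    bnti <- c(); rc <- c()
    for (s in 1:7) {
      cfg <- simRegimeNeutral(nTaxa = 200, nGroups = 2,
                              repsPerGroup = c(3, 3), depth = 1000,
                              seed = 200 + s)
      sim <- simulateDataset(cfg)
      nti <- suppressWarnings(betaNTI(sim$community, nNull = 199,
                                      seed = s))
      bnti <- c(bnti, as.vector(nti$bnti))
      rc <- c(rc, as.vector(raupCrick(sim$community, nNull = 199,
                                      seed = 1000 + s)))
    }
    list(bnti = bnti, rc = rc, process = classifyPair(bnti, rc))
  })
}

# strong-divergent-selection batch: 3 datasets, between-group pairs pooled
selectionRecovery <- function() {
  cached("selectionRecovery", {
    pool <- NULL
    for (s in 1:3) {
      cfg <- simRegimeSelection(nTaxa = 200, nGroups = 2,
                                repsPerGroup = c(3, 3), depth = 1000,
                                seed = 500 + s)
      sim <- simulateDataset(cfg)
      pw <- suppressWarnings(assemblyAnalysis(sim$community, nNull = 199,
                                              seed = s))
      pool <- rbind(pool, pw[pw$group_i != pw$group_j, ])
    }
    pool
  })
}

# two groups of 6 replicates: enough samples for correlation networks
netSim <- function() {
  cached("netSim", simulateDataset(
    simConfig(nTaxa = 150, nGroups = 2, repsPerGroup = c(6, 6),
              depth = 3000, seed = 33)))
}
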