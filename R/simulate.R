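#' @importFrom ape rphylo rTraitCont node.depth.edgelength
#' @importFrom stats rnorm rmultinom setNames
NULL

#' Configuration for the synthetic gradient microbiome generator
#'
#' The generator emulates a rhizosphere survey along a disturbance
#' gradient: `nGroups` distance classes with `repsPerGroup` replicate
#' samples each, drawn from a regional species pool of `nTaxa` taxa whose
#' one-dimensional niche optima evolve by Brownian motion on a simulated
#' phylogeny. Each group has an environmental optimum on a latent
#' disturbance axis; samples are multinomial draws at `depth` reads from
#' taxon weights
#' \deqn{w_{si} \propto (1-d)\, a_i e^{\eta_{si}}
#'   \exp\{-(\mu_i - e_g)^2 / (2\sigma^2)\} + d\, a_i}
#' where \eqn{a_i} is the regional (log-normal) abundance, \eqn{\mu_i} the
#' taxon's niche optimum, \eqn{e_g} the group optimum,
#' \eqn{\sigma} = `selectionStrength` the width of the Gaussian
#' environmental filter, \eqn{d} = `dispersalRate` the mass-effect
#' mixing fraction with the regional pool, and
#' \eqn{\eta_{si} \sim N(0, \mathrm{driftSD}^2)} a per-sample ecological
#' drift term: with low dispersal each local community fluctuates
#' independently around the pool, which is what produces
#' dispersal-limitation-like turnover, while at `dispersalRate = 1` the
#' drift term vanishes and composition equals the regional pool (pure
#' mass effect). `neutral = TRUE` switches the filter off entirely (a
#' flat filter); `selectionStrength = 0` with a spread-out gradient is
#' rejected as a degenerate filter.
#'
#' The nine soil covariates load linearly on the latent axis (fixed
#' loadings) plus replicate-level Gaussian noise, so the environmental
#' table carries the same gradient that filters the communities.
#'
#' @param nTaxa regional pool size (default 2000).
#' @param nGroups number of distance classes (default 5).
#' @param repsPerGroup replicates per group; default `c(9, 6, 6, 6, 6)`,
#'   the survey design the generator emulates (more replicates at the most
#'   disturbed site).
#' @param depth reads per sample (default 30000).
#' @param selectionStrength Gaussian filter width \eqn{\sigma} (latent-axis
#'   units); small values relative to the optimum spread mean strong
#'   selection.
#' @param dispersalRate mass-effect mixing in `[0, 1]`.
#' @param envGradient per-group optima on the latent axis (length
#'   `nGroups`), or a `nGroups x 9` matrix of per-factor optima. Default:
#'   equally spaced on `[-2, 2]`.
#' @param nicheSignal Brownian-motion standard deviation per unit branch
#'   length for the niche optima (0 = no phylogenetic signal, all optima at
#'   the root value).
#' @param driftSD s.d. of the per-sample log-normal drift term. The
#'   default 0.26 is the self-consistency point at which neutral, weakly
#'   dispersing communities show the same assembly stochasticity as the
#'   Raup-Crick null model itself (calibrated at the reference scale of
#'   200 taxa, depth 1000), so the neutral regime sits mid-null rather
#'   than artificially homogenised or dispersed.
#' @param poolSigma s.d. of the log-normal regional species-abundance
#'   distribution (default 1.0).
#' @param envNoise replicate-level s.d. of the soil covariates around their
#'   group optimum.
#' @param neutral logical; `TRUE` disables the environmental filter.
#' @param seed RNG seed; all outputs are bit-reproducible from the config.
#' @return a `simConfig` list.
#' @export
simConfig <- function(nTaxa = 2000, nGroups = 5,
                      repsPerGroup = c(9, 6, 6, 6, 6), depth = 30000,
                      selectionStrength = 0.5, dispersalRate = 0.1,
                      envGradient = NULL, nicheSignal = 1,
                      driftSD = 0.26, poolSigma = 1.0,
                      envNoise = 0.2, neutral = FALSE, seed = 1) {
  if (nTaxa < 3) stop("nTaxa must be >= 3")
  if (length(repsPerGroup) == 1L)
    repsPerGroup <- rep(repsPerGroup, nGroups)
  if (length(repsPerGroup) != nGroups)
    stop("repsPerGroup must have one entry per group")
  if (any(repsPerGroup < 2)) stop("each group needs >= 2 replicates")
  if (dispersalRate < 0 || dispersalRate > 1)
    stop("dispersalRate must lie in [0, 1]")
  if (nicheSignal < 0 || selectionStrength < 0 || envNoise < 0 ||
      driftSD < 0 || poolSigma < 0)
    stop("rates and sigmas must be non-negative")
  if (is.null(envGradient))
    envGradient <- seq(-2, 2, length.out = nGroups)
  spread <- if (is.matrix(envGradient)) max(apply(envGradient, 2, stats::sd))
            else stats::sd(envGradient)
  if (!neutral && selectionStrength == 0 && spread > 0)
    stop("selectionStrength = 0 with a spread-out gradient is a ",
         "degenerate filter; use neutral = TRUE for a flat filter")
  structure(list(nTaxa = nTaxa, nGroups = nGroups,
                 repsPerGroup = repsPerGroup, depth = depth,
                 selectionStrength = selectionStrength,
                 dispersalRate = dispersalRate, envGradient = envGradient,
                 nicheSignal = nicheSignal, driftSD = driftSD,
                 poolSigma = poolSigma, envNoise = envNoise,
                 neutral = neutral, seed = seed),
            class = "simConfig")
}

#' Canonical regime presets for the generator
#'
#' `simRegimeSelection()` is the strong-divergent-selection condition:
#' the environmental filter is strong relative to the spread of the group
#' optima but wide enough (`selectionStrength = 0.7` against optima
#' spanning 4 niche units) that each group retains a whole clade rather
#' than collapsing to one or two taxa — a filter that is too narrow
#' destabilises the nearest-taxon distances it is meant to inflate.
#' Combined with strong phylogenetic niche signal (`nicheSignal = 2`) and
#' nearly closed communities (`dispersalRate = 0.01`), between-group pairs
#' are assembled by heterogeneous selection. `simRegimeNeutral()` is the
#' flat filter with low dispersal, so pairs fall to the stochastic classes
#' (dispersal limitation / undominated).
#'
#' @param ... overrides passed to [simConfig()].
#' @return a `simConfig`.
#' @export
simRegimeSelection <- function(...) {
  args <- list(selectionStrength = 0.7, dispersalRate = 0.01,
               nicheSignal = 2, neutral = FALSE)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

#' @rdname simRegimeSelection
#' @export
simRegimeNeutral <- function(...) {
  args <- list(dispersalRate = 0.05, neutral = TRUE)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

#' Simulate a pure-birth phylogeny scaled to unit depth
#'
#' @param nTaxa number of tips (>= 3).
#' @param seed RNG seed.
#' @return rooted ultrametric `phylo` with tip labels `otu0001, ...` and
#'   tree depth 1.
#' @export
simulateTree <- function(nTaxa, seed = 1) {
  if (nTaxa < 3) stop("nTaxa must be >= 3")
  set.seed(seed)
  tree <- rphylo(nTaxa, birth = 1, death = 0)
  depth <- max(node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("otu%04d", seq_len(nTaxa))
  tree
}

#' Evolve one-dimensional niche optima by Brownian motion on a tree
#'
#' @param tree rooted `phylo`.
#' @param nicheSignal BM standard deviation per unit branch length; 0 gives
#'   every tip the root value 0 (no phylogenetic signal in selection).
#' @param seed RNG seed.
#' @return named numeric vector of tip optima.
#' @export
assignNiches <- function(tree, nicheSignal = 1, seed = 1) {
  if (nicheSignal == 0)
    return(setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  set.seed(seed)
  rTraitCont(tree, model = "BM", sigma = nicheSignal, root.value = 0)
}

.group_labels <- function(nGroups) {
  if (nGroups == 5) c("H0", "H1", "H2", "H3", "H5")
  else sprintf("G%d", seq_len(nGroups))
}

# fixed loadings of the 9 soil covariates on the latent disturbance axis
.SOIL_LOADINGS <- c(TN = 0.8, TP = 0.6, TK = 0.5, salt = -0.9, SOM = 0.85,
                    SUE = 0.7, SALP = 0.6, SSC = 0.4, pH = -0.3)

#' Simulate a full gradient dataset with known ground truth
#'
#' Runs the sampling model of [simConfig()]: simulates the phylogeny and
#' niche optima, the regional log-normal abundance pool, per-group filtered
#' taxon weights, multinomial reads per sample, and the soil covariate
#' table. Deterministic given the config (which includes the seed).
#'
#' @param cfg a [simConfig()].
#' @return list with `community` (a [CommunityExperiment-class] holding
#'   counts, groups, soil factors and the tree), `tree`, `niches`,
#'   `regionalAbundance`, `groupWeights` (expected composition per group)
#'   and `truth` (regime label and the config).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  tree <- simulateTree(cfg$nTaxa, seed = cfg$seed)
  niches <- assignNiches(tree, cfg$nicheSignal, seed = cfg$seed + 1L)
  set.seed(cfg$seed + 2L)
  regional <- exp(rnorm(cfg$nTaxa, mean = 0, sd = cfg$poolSigma))
  regional <- regional / sum(regional)
  names(regional) <- tree$tip.label

  labels <- .group_labels(cfg$nGroups)
  latent <- if (is.matrix(cfg$envGradient)) {
    # project the per-factor optima back on the latent axis for filtering
    as.numeric(cfg$envGradient %*% .SOIL_LOADINGS /
                 sum(.SOIL_LOADINGS^2))
  } else cfg$envGradient

  filt <- sapply(seq_len(cfg$nGroups), function(g) {
    if (cfg$neutral) rep(1, cfg$nTaxa)
    else exp(-(niches - latent[g])^2 / (2 * cfg$selectionStrength^2))
  })
  groupW <- sapply(seq_len(cfg$nGroups), function(g) {
    # drift-free expected composition of the group
    w <- (1 - cfg$dispersalRate) * regional * filt[, g] +
      cfg$dispersalRate * regional
    if (sum(w) <= 0) stop("degenerate filter: all taxon weights zero")
    w / sum(w)
  })
  colnames(groupW) <- labels
  rownames(groupW) <- tree$tip.label

  nSamp <- sum(cfg$repsPerGroup)
  grp <- rep(labels, cfg$repsPerGroup)
  sid <- unlist(lapply(seq_len(cfg$nGroups), function(g)
    sprintf("%s_s%02d", labels[g], seq_len(cfg$repsPerGroup[g]))))
  counts <- matrix(0L, nrow = nSamp, ncol = cfg$nTaxa,
                   dimnames = list(sid, tree$tip.label))
  for (s in seq_len(nSamp)) {
    g <- match(grp[s], labels)
    eta <- rnorm(cfg$nTaxa, 0, cfg$driftSD)
    w <- (1 - cfg$dispersalRate) * regional * exp(eta) * filt[, g] +
      cfg$dispersalRate * regional
    if (sum(w) <= 0) stop("degenerate filter: all taxon weights zero")
    counts[s, ] <- rmultinom(1, cfg$depth, w / sum(w))[, 1]
  }

  envOpt <- if (is.matrix(cfg$envGradient)) cfg$envGradient
            else outer(latent, .SOIL_LOADINGS)
  env <- envOpt[match(grp, labels), , drop = FALSE] +
    matrix(rnorm(nSamp * 9, sd = cfg$envNoise), nSamp, 9)
  colnames(env) <- SOIL_FACTORS
  rownames(env) <- sid

  comm <- CommunityExperiment(counts, group = setNames(grp, sid),
                              env = as.data.frame(env), tree = tree)
  truth <- list(regime = if (cfg$neutral) "neutral" else "selection",
                latentOptima = setNames(latent, labels), config = cfg)
  list(community = comm, tree = tree, niches = niches,
       regionalAbundance = regional, groupWeights = groupW, truth = truth)
}

#' Write all artifacts of a simulated dataset to a directory
#'
#' @param sim output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `otu_table.tsv`, `metadata.tsv`,
#'   `env.csv`, `tree.nwk` and `truth.json`.
#' @export
writeSimulated <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCommunity(sim$community,
                 file.path(dir, "otu_table.tsv"),
                 file.path(dir, "metadata.tsv"),
                 file.path(dir, "env.csv"))
  write.tree(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
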