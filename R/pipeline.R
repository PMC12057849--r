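#' Pipeline configuration
#'
#' Collects every threshold and seed of the workflow in one validated
#' list. Thresholds default to the conventions used throughout the
#' package: abundant/rare at 0.1%/0.01%, network edges at `|rho| > 0.8`
#' and `p < 0.01`, selection at `|bNTI| = 2`, dispersal at `|RC| = 0.95`,
#' hub roles at `Zi = 2.5` / `Pi = 0.62`.
#'
#' @param abundantThresh,rareThresh partition thresholds (fractions).
#' @param rhoThresh,pThresh network edge thresholds.
#' @param topOtus taxa per group entering the network (default 250).
#' @param nNull null-model draws (default 999).
#' @param nPerm permutations for PERMANOVA/Monte Carlo tests.
#' @param seed master RNG seed; stage seeds derive from it.
#' @param alphaIndex diversity index driving the environmental regressions.
#' @param runAssembly,runNetwork,runDrivers stage switches.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(abundantThresh = 0.001, rareThresh = 1e-4,
                           rhoThresh = 0.8, pThresh = 0.01, topOtus = 250,
                           nNull = 999, nPerm = 999, seed = 1,
                           alphaIndex = "shannon", runAssembly = TRUE,
                           runNetwork = TRUE, runDrivers = TRUE) {
  stopifnot(abundantThresh > rareThresh, rareThresh > 0, rhoThresh > 0,
            pThresh > 0, nNull > 0, nPerm > 0, topOtus > 0)
  structure(list(abundantThresh = abundantThresh, rareThresh = rareThresh,
                 rhoThresh = rhoThresh, pThresh = pThresh,
                 topOtus = topOtus, nNull = nNull, nPerm = nPerm,
                 seed = as.integer(seed), alphaIndex = alphaIndex,
                 runAssembly = runAssembly, runNetwork = runNetwork,
                 runDrivers = runDrivers),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.stage <- function(name, outDir, expr) {
  marker <- file.path(outDir, ".partial")
  file.create(marker)
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  unlink(marker)
  res
}

#' Run the full workflow on a community
#'
#' Orchestrates partition, diversity, assembly null models, per-group
#' networks and environmental attribution over the three taxa scopes
#' (total, abundant, rare), writing each stage's tables under
#' `<outDir>/<scope>/<stage>/` plus a run manifest with versions, seeds
#' and thresholds. Reruns with the same inputs and config are
#' bit-reproducible.
#'
#' @param x count-form [CommunityExperiment-class]; a tree must be
#'   attached when `runAssembly` is on, and soil factors when `runDrivers`
#'   is on.
#' @param config a [pipelineConfig()] (or path to a YAML file).
#' @param outDir output directory.
#' @return (invisibly) a nested list of the in-memory results per scope.
#' @export
runPipeline <- function(x, config = pipelineConfig(), outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  if (config$runAssembly && is.null(phyloTree(x)))
    stop("pipeline stage 'assembly' needs a phylogeny; ",
         "attach one or set runAssembly = FALSE")
  if (config$runDrivers && is.null(soilFactors(x)))
    stop("pipeline stage 'drivers' needs soil factors; ",
         "attach them or set runDrivers = FALSE")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rel <- toRelative(x)
  part <- .stage("partition", outDir,
                 buildPartition(rel, config$abundantThresh,
                                config$rareThresh))
  writePartition(part, file.path(outDir, "partition"))

  scale_counts <- function(relScope) {
    # rebuild integer counts for the scope by masking the original table
    keep <- colnames(communityMatrix(relScope))
    cnt <- communityMatrix(x)[rownames(communityMatrix(relScope)), keep,
                              drop = FALSE]
    mask <- communityMatrix(relScope) > 0
    CommunityExperiment(cnt * mask,
                        group = sampleGroups(relScope),
                        env = soilFactors(relScope),
                        tree = phyloTree(relScope))
  }
  scopes <- list(total = x, abundant = scale_counts(part$abundant),
                 rare = scale_counts(part$rare))

  results <- list()
  for (sc in names(scopes)) {
    xs <- scopes[[sc]]
    scDir <- file.path(outDir, sc)
    res <- list()

    divDir <- file.path(scDir, "diversity")
    dir.create(divDir, recursive = TRUE, showWarnings = FALSE)
    res$diversity <- .stage("diversity", divDir, {
      alpha <- alphaDiversity(xs)
      bc <- brayCurtis(xs)
      nm <- nmdsOrdination(bc, seed = config$seed)
      pm <- permanovaTest(bc, sampleGroups(xs), nPerm = config$nPerm,
                          seed = config$seed)
      .write_tsv(alpha, file.path(divDir, "alpha.tsv"))
      .write_tsv(as.data.frame(as.matrix(bc)),
                 file.path(divDir, "braycurtis.tsv"))
      .write_tsv(data.frame(sample = rownames(nm$points), nm$points,
                            stress = nm$stress),
                 file.path(divDir, "nmds.tsv"))
      writeLines(sprintf("pseudo_F\t%g\nR2\t%g\np\t%g\nn_perm\t%d",
                         pm$F, pm$R2, pm$p, pm$nPerm),
                 file.path(divDir, "permanova.txt"))
      list(alpha = alpha, braycurtis = bc, nmds = nm, permanova = pm)
    })

    if (config$runAssembly) {
      asmDir <- file.path(scDir, "assembly")
      dir.create(asmDir, recursive = TRUE, showWarnings = FALSE)
      res$assembly <- .stage("assembly", asmDir, {
        pw <- assemblyAnalysis(xs, nNull = config$nNull,
                               seed = config$seed)
        writePairwise(pw, file.path(asmDir, "pairwise.tsv"))
        .write_tsv(summarizeAssembly(pw, "all"),
                   file.path(asmDir, "summary_all.tsv"))
        byg <- tryCatch(summarizeAssembly(pw, "within-group"),
                        error = function(e) NULL)
        if (!is.null(byg))
          .write_tsv(byg, file.path(asmDir, "summary_by_group.tsv"))
        list(pairwise = pw, summary = summarizeAssembly(pw, "all"),
             byGroup = byg)
      })
    }

    if (config$runNetwork) {
      netDir <- file.path(scDir, "network")
      dir.create(netDir, recursive = TRUE, showWarnings = FALSE)
      res$network <- .stage("network", netDir, {
        nets <- list()
        for (g in levels(sampleGroups(xs))) {
          gx <- tryCatch(selectTopOtus(xs, g, n = config$topOtus),
                         error = function(e) NULL)
          if (is.null(gx)) next
          net <- buildNetwork(gx, rhoThresh = config$rhoThresh,
                              pThresh = config$pThresh)
          if (igraph::vcount(net) == 0) next
          net <- annotateRoles(net)
          topo <- networkTopology(net)
          zp <- ziPi(net)
          rbR <- robustnessCurve(net, "random", nReps = 50,
                                 seed = config$seed)
          rbT <- robustnessCurve(net, "targeted", seed = config$seed)
          .write_tsv(cbind(group = g, topo),
                     file.path(netDir, paste0("topology_", g, ".tsv")))
          .write_tsv(zp, file.path(netDir, paste0("nodes_", g, ".tsv")))
          el <- igraph::as_edgelist(net)
          .write_tsv(data.frame(from = el[, 1], to = el[, 2],
                                weight = igraph::E(net)$weight,
                                sign = igraph::E(net)$sign),
                     file.path(netDir, paste0("edges_", g, ".tsv")))
          writeGEXF(net, file.path(netDir, paste0("network_", g, ".gexf")))
          .write_tsv(rbR, file.path(netDir,
                                    paste0("robustness_random_", g, ".tsv")))
          .write_tsv(rbT, file.path(netDir,
                                    paste0("robustness_targeted_", g,
                                           ".tsv")))
          nets[[g]] <- list(net = net, topology = topo, ziPi = zp)
        }
        nets
      })
    }

    if (config$runDrivers) {
      drvDir <- file.path(scDir, "drivers")
      dir.create(drvDir, recursive = TRUE, showWarnings = FALSE)
      res$drivers <- .stage("drivers", drvDir, {
        env <- soilFactors(xs)
        alpha <- res$diversity$alpha
        resp <- stats::setNames(alpha[[config$alphaIndex]], alpha$sample)
        imp <- lmgImportance(env, resp)
        uni <- univariateTrends(env, resp)
        ef <- envfitMC(xs, env, nPerm = config$nPerm, seed = config$seed)
        .write_tsv(cbind(imp, total_r2 = attr(imp, "totalR2")),
                   file.path(drvDir, "importance.tsv"))
        .write_tsv(uni, file.path(drvDir, "univariate.tsv"))
        .write_tsv(ef$fit, file.path(drvDir, "envfit.tsv"))
        bn <- NULL
        if (config$runAssembly) {
          bn <- do.call(rbind, lapply(SOIL_FACTORS, function(f) {
            r <- bntiEnvRegression(res$assembly$pairwise, env, f,
                                   nPerm = config$nPerm,
                                   seed = config$seed)
            data.frame(factor = f, slope = r$slope, r2 = r$r2, p = r$p,
                       n = r$n)
          }))
          bn$stars <- .stars(bn$p)
          .write_tsv(bn, file.path(drvDir, "bnti_env.tsv"))
        }
        list(importance = imp, univariate = uni, envfit = ef,
             bntiEnv = bn)
      })
    }
    results[[sc]] <- res
  }

  manifest <- list(
    package = "micasm",
    package_version = as.character(utils::packageVersion("micasm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(config),
    n_samples = ncol(x), n_taxa = nrow(x),
    groups = as.list(table(sampleGroups(x))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
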