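#' @importFrom stats cor pt
NULL

#' Select the most abundant taxa within a group
#'
#' The `n` taxa with highest mean relative abundance over the group's
#' samples (ties broken lexicographically by taxon id), the usual screen
#' before co-occurrence network construction. Taxa with zero abundance in
#' the group never qualify; if fewer than `n` nonzero taxa exist, all are
#' taken with a warning.
#'
#' @param x a [CommunityExperiment-class].
#' @param group group label.
#' @param n number of taxa to keep (default 250).
#' @return a `CommunityExperiment` of the group's samples by the selected
#'   taxa.
#' @export
selectTopOtus <- function(x, group, n = 250) {
  sub <- subsetGroup(x, group)
  if (ncol(sub) < 5)
    stop("group '", group, "' has fewer than 5 samples; ",
         "correlation needs replicates")
  m <- communityMatrix(toRelative(sub))
  means <- colMeans(m)
  nz <- names(means)[means > 0]
  if (length(nz) < n) {
    warning("only ", length(nz), " taxa with nonzero abundance in group '",
            group, "'; taking all")
    n <- length(nz)
  }
  ord <- order(-means[nz], nz)
  keep <- nz[ord][seq_len(n)]
  sub[keep, ]
}

# Spearman rho and two-sided p for every taxon pair.
# approx: t approximation on rho with average-rank ties;
# exact: full permutation distribution of rho (all n! orderings), only
# sensible for small n.
.spearman_all <- function(m, method = c("approx", "exact")) {
  method <- match.arg(method)
  n <- nrow(m)
  rho <- cor(m, method = "spearman")
  if (method == "approx") {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
  } else {
    if (n > 8) stop("exact permutation p only supported for n <= 8 samples")
    R <- apply(m, 2, rank)
    perms <- .all_perms(n)
    exceed <- matrix(0L, ncol(m), ncol(m))
    for (i in seq_len(nrow(perms))) {
      rp <- cor(R[perms[i, ], , drop = FALSE], R)
      exceed <- exceed + (abs(rp) >= abs(rho) - 1e-12)
    }
    p <- exceed / nrow(perms)
    p <- (p + t(p)) / 2
  }
  diag(p) <- 1
  list(rho = rho, p = p)
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Build a signed Spearman co-occurrence network
#'
#' Correlates all taxon pairs over the samples; a pair becomes an edge when
#' `|rho| > rhoThresh` and `p < pThresh` (both strict, no multiplicity
#' correction unless `bh = TRUE`). Zero-variance taxa are excluded with a
#' warning and isolated nodes are dropped, so node counts can fall below
#' the number of selected taxa.
#'
#' @param x a [CommunityExperiment-class], typically from
#'   [selectTopOtus()]; at least 5 samples.
#' @param rhoThresh correlation magnitude threshold (default 0.8).
#' @param pThresh p-value threshold (default 0.01).
#' @param method `"approx"` (t approximation, default) or `"exact"`
#'   (permutation, n <= 8).
#' @param bh apply Benjamini-Hochberg correction to the edge p-values
#'   (default off).
#' @return an undirected simple `igraph`; edge attributes `weight`
#'   (Spearman rho) and `sign` (`"+"`/`"-"`); graph attributes
#'   `excluded_taxa` (zero variance) and `isolated_taxa` (dropped).
#' @export
buildNetwork <- function(x, rhoThresh = 0.8, pThresh = 0.01,
                         method = c("approx", "exact"), bh = FALSE) {
  m <- communityMatrix(toRelative(x))
  if (nrow(m) < 5) stop("need at least 5 samples")
  v <- apply(m, 2, function(col) stats::var(col))
  constant <- colnames(m)[v < .Machine$double.eps]
  if (length(constant)) {
    warning("excluding ", length(constant), " zero-variance taxa")
    m <- m[, setdiff(colnames(m), constant), drop = FALSE]
  }
  sp <- .spearman_all(m, method)
  p <- sp$p
  if (bh) {
    low <- lower.tri(p)
    p[low] <- stats::p.adjust(p[low], method = "BH")
    p <- pmin(p, t(p))
  }
  keep <- abs(sp$rho) > rhoThresh & p < pThresh
  keep[upper.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  taxa <- colnames(m)
  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  igraph::V(g)$name <- taxa
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.vector(rbind(taxa[idx[, 2L]],
                                              taxa[idx[, 1L]])))
    igraph::E(g)$weight <- sp$rho[idx]
    igraph::E(g)$sign <- ifelse(sp$rho[idx] > 0, "+", "-")
  }
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, iso)
  g$excluded_taxa <- constant
  g$isolated_taxa <- iso
  g
}

#' Topology report of a co-occurrence network
#'
#' Node/edge counts and signs, average degree `2E/N`, density
#' `2E/(N(N-1))`, average shortest-path length and diameter over connected
#' pairs (unweighted), mean local clustering coefficient (nodes of degree
#' < 2 contribute 0) and the modularity of the partition found by greedy
#' modularity maximisation (deterministic).
#'
#' @param net an `igraph` from [buildNetwork()].
#' @param modules optional membership vector (named by node); computed by
#'   [moduleMembership()] when absent.
#' @return one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `n_positive`, `n_negative`, `average_degree`, `average_path_length`,
#'   `diameter`, `density`, `clustering_coefficient`, `modularity`.
#' @export
networkTopology <- function(net, modules = NULL) {
  nN <- igraph::vcount(net)
  nE <- igraph::ecount(net)
  if (nN == 0) stop("empty network")
  sgn <- if (nE > 0 && "sign" %in% igraph::edge_attr_names(net))
    igraph::E(net)$sign else character()
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0  # degree-1 nodes contribute 0
  if (is.null(modules)) modules <- moduleMembership(net)
  mod <- igraph::modularity(net, membership = modules[igraph::V(net)$name],
                            weights = rep(1, nE))
  data.frame(
    n_nodes = nN, n_edges = nE,
    n_positive = sum(sgn == "+"), n_negative = sum(sgn == "-"),
    average_degree = 2 * nE / nN,
    average_path_length = igraph::mean_distance(net, directed = FALSE,
                                                unconnected = TRUE,
                                                weights = NA),
    diameter = igraph::diameter(net, directed = FALSE, weights = NA),
    density = 2 * nE / (nN * (nN - 1)),
    clustering_coefficient = mean(loc),
    modularity = mod)
}

#' Module membership by modularity maximisation
#'
#' @param net an `igraph`.
#' @param method `"greedy"` (fast-greedy agglomeration, deterministic,
#'   default) or `"louvain"`.
#' @param seed RNG seed (used by louvain).
#' @return named integer vector of module ids per node.
#' @export
moduleMembership <- function(net, method = c("greedy", "louvain"),
                             seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  cl <- switch(method,
    greedy = igraph::cluster_fast_greedy(net, weights = NA),
    louvain = igraph::cluster_louvain(net, weights = NA))
  mem <- igraph::membership(cl)
  stats::setNames(as.integer(mem), igraph::V(net)$name)
}

#' Zi-Pi node roles (within-module degree z, participation coefficient)
#'
#' `Zi = (k_within - mean(k_within in module)) / sd(k_within in module)`
#' (0 when the module's sd is 0);
#' `Pi = 1 - sum_m (k_{i,m} / k_i)^2` (0 for isolated nodes). Roles:
#' peripheral (`Zi < 2.5, Pi < 0.62`), module hub (`Zi > 2.5, Pi < 0.62`),
#' connector (`Zi < 2.5, Pi > 0.62`), network hub (`Zi > 2.5, Pi > 0.62`);
#' exact threshold values fall to the non-hub side.
#'
#' @param net an `igraph`.
#' @param modules named membership vector (default from
#'   [moduleMembership()]).
#' @return data.frame per node: `node`, `degree`, `module`, `zi`, `pi`,
#'   `role`.
#' @export
ziPi <- function(net, modules = NULL) {
  if (is.null(modules)) modules <- moduleMembership(net)
  nodes <- igraph::V(net)$name
  modules <- modules[nodes]
  deg <- igraph::degree(net)
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  kim <- vapply(sort(unique(modules)), function(mo)
    rowSums(adj[, modules == mo, drop = FALSE]), numeric(length(nodes)))
  kwithin <- kim[cbind(seq_along(nodes),
                       match(modules, sort(unique(modules))))]
  zi <- numeric(length(nodes))
  for (mo in unique(modules)) {
    sel <- modules == mo
    s <- stats::sd(kwithin[sel])
    zi[sel] <- if (is.na(s) || s < 1e-12) 0
               else (kwithin[sel] - mean(kwithin[sel])) / s
  }
  pi <- ifelse(deg == 0, 0, 1 - rowSums((kim / pmax(deg, 1))^2))
  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network_hub", "module_hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(node = nodes, degree = as.integer(deg),
             module = as.integer(modules), zi = zi, pi = as.numeric(pi),
             role = role, row.names = NULL)
}

#' Annotate a network with module, Zi, Pi and role attributes
#'
#' Convenience for export: attaches the [ziPi()] columns as vertex
#' attributes so [writeGEXF()]/[writeGraphML()] carry them.
#'
#' @inheritParams ziPi
#' @return the annotated `igraph`.
#' @export
annotateRoles <- function(net, modules = NULL) {
  zp <- ziPi(net, modules)
  igraph::V(net)$module <- zp$module
  igraph::V(net)$zi <- zp$zi
  igraph::V(net)$pi <- zp$pi
  igraph::V(net)$role <- zp$role
  net
}

#' Natural connectivity of a graph
#'
#' `ln(mean(exp(lambda_i)))` over the eigenvalues of the (unweighted)
#' adjacency matrix; a spectral robustness measure that is 0 for an empty
#' graph and grows with redundancy of routes.
#'
#' @param net an `igraph`.
#' @return non-negative scalar.
#' @export
naturalConnectivity <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  A <- (A != 0) * 1
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  # log-sum-exp for numerical safety on large graphs
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Robustness curve under node removal
#'
#' Natural connectivity of the remaining graph (isolated nodes included)
#' after removing `floor(f * N)` nodes, for removal fractions `0..fMax` in
#' steps of `step`. `"random"` averages over `nReps` seeded draws;
#' `"targeted"` is an adaptive degree attack: the highest-degree node of
#' the *remaining* graph is removed at each step (ties by node id).
#' Fractions leaving fewer than 2 nodes are truncated from the curve.
#'
#' @param net an `igraph` with >= 3 nodes.
#' @param mode `"random"` or `"targeted"`.
#' @param fMax largest removal fraction (default 0.8).
#' @param step fraction increment (default 0.05).
#' @param nReps random-mode repetitions (default 100).
#' @param seed RNG seed.
#' @return data.frame with `fraction`, `n_removed`,
#'   `natural_connectivity` (mean over reps in random mode) and `mode`.
#' @export
robustnessCurve <- function(net, mode = c("random", "targeted"),
                            fMax = 0.8, step = 0.05, nReps = 100,
                            seed = 1) {
  mode <- match.arg(mode)
  n <- igraph::vcount(net)
  if (n < 3) stop("need at least 3 nodes")
  fracs <- seq(0, fMax, by = step)
  nrem <- floor(fracs * n)
  keep <- n - nrem >= 2
  if (any(!keep)) {
    message("truncating curve: fractions leaving < 2 nodes dropped")
    fracs <- fracs[keep]
    nrem <- nrem[keep]
  }
  set.seed(seed)
  if (mode == "targeted") {
    nc <- numeric(length(fracs))
    g <- net
    removed <- 0L
    for (i in seq_along(fracs)) {
      while (removed < nrem[i]) {
        deg <- igraph::degree(g)
        victim <- igraph::V(g)$name[order(-deg, igraph::V(g)$name)][1L]
        g <- igraph::delete_vertices(g, victim)
        removed <- removed + 1L
      }
      nc[i] <- naturalConnectivity(g)
    }
  } else {
    nc <- vapply(seq_along(fracs), function(i) {
      k <- nrem[i]
      if (k == 0) return(naturalConnectivity(net))
      mean(vapply(seq_len(nReps), function(r) {
        naturalConnectivity(
          igraph::delete_vertices(net, sample.int(n, k)))
      }, numeric(1)))
    }, numeric(1))
  }
  data.frame(fraction = fracs, n_removed = nrem,
             natural_connectivity = nc, mode = mode)
}
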